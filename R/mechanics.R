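#' Bond-modeling options for the mechanical framework
#'
#' Maps each interaction kind to its mechanical model: `"hinge"` (removes 5
#' of the 6 relative degrees of freedom between two bodies) or `bars(b)`
#' with `1 <= b <= 6` independent distance constraints. Defaults follow the
#' standard molecular modeling convention: rotatable covalent single bonds,
#' disulfides and hydrogen bonds are hinges; non-rotatable peptide and
#' double bonds are locked with 6 bars; hydrophobic contacts contribute 3
#' bars.
#'
#' @param covalent_single,peptide,covalent_double,disulfide,hydrogen_bond,hydrophobic
#'   Either the string `"hinge"` or an integer bar count in `[1, 6]`.
#' @return A `modeling_options` list mapping kind -> list(model, bars).
#' @export
modeling_options <- function(covalent_single = "hinge", peptide = 6L,
                             covalent_double = 6L, disulfide = "hinge",
                             hydrogen_bond = "hinge", hydrophobic = 3L) {
  raw <- list(covalent_single = covalent_single, peptide = peptide,
              covalent_double = covalent_double, disulfide = disulfide,
              hydrogen_bond = hydrogen_bond, hydrophobic = hydrophobic)
  out <- lapply(raw, function(v) {
    if (identical(v, "hinge")) return(list(model = "hinge", bars = NA_integer_))
    if (is.numeric(v) && length(v) == 1L && v == as.integer(v) &&
        v >= 1 && v <= 6) {
      return(list(model = "bars", bars = as.integer(v)))
    }
    stop("invalid bond model '", deparse(v),
         "': must be \"hinge\" or an integer bar count in [1, 6]")
  })
  structure(out, class = "modeling_options")
}

#' Assign rigid bodies to atoms
#'
#' One `atom_hub` body per atom with covalent degree >= 2, containing that
#' atom and all its covalent neighbours; adjacent hub bodies therefore
#' overlap on the two atoms of their shared bond (the future hinge axis).
#' Degree-1 atoms belong only to their neighbour's body; isolated atoms
#' become singleton bodies. A bonded pair in which both atoms have degree 1
#' (a diatomic) forms a single two-atom body.
#'
#' @param molecule A `molecule` with perceived covalent bonds.
#' @return List of bodies: `list(id, atoms, kind, hub)`.
#' @export
build_bodies <- function(molecule) {
  serials <- molecule$atoms$serial
  b <- molecule$bonds
  deg <- setNames(integer(length(serials)), serials)
  for (k in seq_len(nrow(b))) {
    deg[as.character(b$i[k])] <- deg[as.character(b$i[k])] + 1L
    deg[as.character(b$j[k])] <- deg[as.character(b$j[k])] + 1L
  }
  adj <- covalent_adjacency(molecule)
  bodies <- list()
  covered <- character(0)
  for (s in serials) {
    if (deg[as.character(s)] >= 2L) {
      nb <- get(as.character(s), adj)
      atoms <- sort(unique(c(s, nb)))
      bodies[[length(bodies) + 1L]] <-
        list(id = length(bodies) + 1L, atoms = atoms, kind = "atom_hub",
             hub = s)
      covered <- union(covered, as.character(atoms))
    }
  }
  for (s in serials) {
    if (deg[as.character(s)] == 0L) {
      bodies[[length(bodies) + 1L]] <-
        list(id = length(bodies) + 1L, atoms = s, kind = "atom_hub", hub = s)
      covered <- union(covered, as.character(s))
    }
  }
  # degree-1 atoms bonded to a degree-1 atom (diatomic pairs)
  for (s in serials) {
    if (deg[as.character(s)] == 1L && !(as.character(s) %in% covered)) {
      nb <- get(as.character(s), adj)
      atoms <- sort(c(s, nb))
      bodies[[length(bodies) + 1L]] <-
        list(id = length(bodies) + 1L, atoms = atoms, kind = "atom_hub",
             hub = atoms[1])
      covered <- union(covered, as.character(atoms))
    }
  }
  bodies
}

# body id hubbed at an atom (NA if the atom is not a hub)
hub_index <- function(bodies) {
  hubs <- vapply(bodies, `[[`, numeric(1), "hub")
  setNames(vapply(bodies, `[[`, numeric(1), "id"), hubs)
}

# map atom serial -> body to attach non-covalent constraints to:
# the body hubbed at the atom if it is a hub, else its unique containing body
attachment_body <- function(serial, bodies, hub_idx) {
  s <- as.character(serial)
  if (!is.na(hub_idx[s])) return(unname(hub_idx[s]))
  for (b in bodies) if (serial %in% b$atoms) return(b$id)
  NA_integer_
}

#' Build the body-bar-hinge model
#'
#' Covalent bonds between two hub atoms become hinges between their bodies
#' (axis = the bond, unless options model that kind as bars); non-covalent
#' interactions between atoms in distinct bodies become hinge or bar
#' connections per `options`. Interactions internal to a single body produce
#' no connection but are logged.
#'
#' @param bodies From [build_bodies()].
#' @param network An `interaction_network`.
#' @param options [modeling_options()].
#' @return A `bbh_model`: bodies, connection table, internal-interaction log.
#' @export
assign_connections <- function(bodies, network,
                               options = modeling_options()) {
  stopifnot(inherits(options, "modeling_options"))
  hub_idx <- hub_index(bodies)
  conns <- list()
  internal <- list()
  covalent_kinds <- c("covalent_single", "covalent_double", "peptide",
                      "disulfide")
  for (x in network$interactions) {
    opt <- options[[x$kind]]
    if (is.null(opt)) stop("no modeling option for kind '", x$kind, "'")
    if (x$kind %in% covalent_kinds) {
      bi <- hub_idx[as.character(x$atoms[1])]
      bj <- hub_idx[as.character(x$atoms[2])]
      if (is.na(bi) || is.na(bj)) {
        # bond to a terminal atom lies inside its hub's body
        internal[[length(internal) + 1L]] <- x$id
        next
      }
      axis <- x$atoms
    } else {
      # attach hydrogen bonds via the hydrogen and acceptor atoms
      att <- if (x$kind == "hydrogen_bond") c(x$hydrogen, x$acceptor) else x$atoms
      bi <- attachment_body(att[1], bodies, hub_idx)
      bj <- attachment_body(att[2], bodies, hub_idx)
      axis <- att
    }
    if (is.na(bi) || is.na(bj) || bi == bj) {
      internal[[length(internal) + 1L]] <- x$id
      next
    }
    conns[[length(conns) + 1L]] <- data.frame(
      id = length(conns) + 1L, body_i = min(bi, bj), body_j = max(bi, bj),
      model = opt$model, bars = opt$bars, interaction_id = x$id,
      kind = x$kind, axis_i = axis[1], axis_j = axis[2],
      stringsAsFactors = FALSE)
  }
  connections <- if (length(conns) > 0L) do.call(rbind, conns) else
    data.frame(id = integer(0), body_i = integer(0), body_j = integer(0),
               model = character(0), bars = integer(0),
               interaction_id = integer(0), kind = character(0),
               axis_i = integer(0), axis_j = integer(0),
               stringsAsFactors = FALSE)
  structure(list(bodies = bodies, connections = connections,
                 internal = unlist(internal) %||% integer(0),
                 molecule = network$molecule, network = network,
                 options = options),
            class = "bbh_model")
}

#' @export
print.bbh_model <- function(x, ...) {
  cat(sprintf("<bbh_model> %d bodies, %d connections (%d hinge, %d bar), %d internal\n",
              length(x$bodies), nrow(x$connections),
              sum(x$connections$model == "hinge"),
              sum(x$connections$model == "bars"),
              length(x$internal)))
  invisible(x)
}

#' Multigraph constructor
#'
#' @param n_vertices Number of vertices (ids `1..n`).
#' @param edges Data frame with columns `u`, `v` (vertex ids) and optionally
#'   `conn_id` (source connection id; defaults to the row number).
#' @return A `multigraph`.
#' @export
multigraph <- function(n_vertices, edges = NULL) {
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(u = integer(0), v = integer(0), conn_id = integer(0))
  }
  if (is.null(edges$conn_id)) edges$conn_id <- seq_len(nrow(edges))
  stopifnot(all(edges$u >= 1), all(edges$v >= 1),
            all(edges$u <= n_vertices), all(edges$v <= n_vertices))
  structure(list(n_vertices = as.integer(n_vertices),
                 edges = data.frame(u = as.integer(edges$u),
                                    v = as.integer(edges$v),
                                    conn_id = as.integer(edges$conn_id))),
            class = "multigraph")
}

#' Convert a body-bar-hinge model to its multigraph
#'
#' One vertex per body; 5 parallel edges per hinge connection and `b`
#' parallel edges per `bars(b)` connection, each tagged with the source
#' connection id so the model's connection multiset can be reconstructed.
#'
#' @param model A `bbh_model`.
#' @return A `multigraph`.
#' @export
to_multigraph <- function(model) {
  cn <- model$connections
  mult <- ifelse(cn$model == "hinge", 5L, cn$bars)
  idx <- rep(seq_len(nrow(cn)), times = mult)
  g <- multigraph(length(model$bodies),
                  data.frame(u = cn$body_i[idx], v = cn$body_j[idx],
                             conn_id = cn$id[idx]))
  g
}

#' @export
print.multigraph <- function(x, ...) {
  cat(sprintf("<multigraph> %d vertices, %d edges\n",
              x$n_vertices, nrow(x$edges)))
  invisible(x)
}

#' Write / read a multigraph as an edge-list text file
#'
#' One line per edge: `u v conn_id` (tab-separated, `# n_vertices` header).
#' @param graph A `multigraph`.
#' @param path File path.
#' @export
write_multigraph <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# n_vertices\t", graph$n_vertices), con)
  if (nrow(graph$edges) > 0L) {
    writeLines(sprintf("%d\t%d\t%d", graph$edges$u, graph$edges$v,
                       graph$edges$conn_id), con)
  }
  invisible(path)
}

#' @rdname write_multigraph
#' @export
read_multigraph <- function(path) {
  lines <- readLines(path)
  n <- as.integer(strsplit(lines[1], "\t")[[1]][2])
  body <- lines[-1]
  if (length(body) == 0L) return(multigraph(n))
  m <- do.call(rbind, lapply(strsplit(body, "\t"), as.integer))
  multigraph(n, data.frame(u = m[, 1], v = m[, 2], conn_id = m[, 3]))
}
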