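#' Hydrogen-bond dilution series (simulated unfolding)
#'
#' Removes hydrogen bonds one at a time in the requested order and records
#' the rigid cluster decomposition after every removal; step 0 is the
#' undiluted decomposition. Each snapshot equals a from-scratch analysis of
#' the remaining network. Orders: `weakest_first` (default; energy value
#' closest to zero removed first), `strongest_first`, and `depth`
#' (shallowest bond first, by [bond_depth()]).
#'
#' @param molecule A `molecule` with perceived covalent bonds.
#' @param network A pruned `interaction_network` containing >= 1 hydrogen
#'   bond.
#' @param options [modeling_options()].
#' @param order One of `"weakest_first"`, `"strongest_first"`, `"depth"`.
#' @return A `dilution_series`: list of steps
#'   `(removed_id, energy, decomposition)`.
#' @export
dilute <- function(molecule, network, options = modeling_options(),
                   order = c("weakest_first", "strongest_first", "depth")) {
  order <- match.arg(order)
  kinds <- network_kinds(network)
  hb <- network$interactions[kinds == "hydrogen_bond"]
  if (length(hb) == 0L) stop("dilution requires at least one hydrogen bond")
  ids <- vapply(hb, `[[`, integer(1), "id")
  energies <- vapply(hb, `[[`, numeric(1), "energy")
  ord <- switch(order,
    weakest_first = order(-energies, ids),
    strongest_first = order(energies, ids),
    depth = {
      depths <- vapply(hb, function(x) bond_depth(molecule, x), numeric(1))
      order(depths, ids)
    })
  removal <- ids[ord]

  analyze <- function(net) {
    bodies <- build_bodies(molecule)
    model <- assign_connections(bodies, net, options)
    components_to_clusters(run_pebble_game(to_multigraph(model)), model)
  }
  steps <- list(list(removed_id = NA_integer_, energy = NA_real_,
                     decomposition = analyze(network)))
  net <- network
  for (id in removal) {
    net <- remove_interactions(net, id)
    steps[[length(steps) + 1L]] <- list(
      removed_id = id,
      energy = energies[match(id, ids)],
      decomposition = analyze(net))
  }
  structure(list(steps = steps, order = order,
                 molecule = molecule, options = options),
            class = "dilution_series")
}

#' @export
print.dilution_series <- function(x, ...) {
  n0 <- summary(x$steps[[1]]$decomposition)
  nT <- summary(x$steps[[length(x$steps)]]$decomposition)
  cat(sprintf(
    "<dilution_series> %d steps (%s): clusters %d -> %d, largest %d -> %d atoms\n",
    length(x$steps), x$order, n0$n_clusters, nT$n_clusters,
    n0$largest_size, nT$largest_size))
  invisible(x)
}

# refinement check: every cluster at step t+1 must be contained in some
# cluster at step t (hinge-overlap atoms may also sit in a second parent)
dilution_refines <- function(series) {
  for (t in seq_len(length(series$steps) - 1L)) {
    parents <- series$steps[[t]]$decomposition$clusters
    children <- series$steps[[t + 1L]]$decomposition$clusters
    for (ch in children) {
      contained <- any(vapply(parents, function(p) {
        all(ch$atoms %in% p$atoms)
      }, logical(1)))
      if (!contained) return(t)
    }
  }
  TRUE
}

#' Serialize a dilution series (deterministic JSON)
#' @param series A `dilution_series`.
#' @return JSON string.
#' @export
serialize_dilution_series <- function(series) {
  obj <- lapply(series$steps, function(s) {
    list(removed_id = s$removed_id,
         energy = if (is.na(s$energy)) NULL else round(s$energy, 9),
         clusters = lapply(s$decomposition$clusters, function(c) {
           list(label = c$label, atoms = as.integer(c$atoms))
         }))
  })
  as.character(jsonlite::toJSON(list(order = series$order, steps = obj),
                                auto_unbox = TRUE, digits = NA))
}

#' Per-step, per-residue cluster-label table (1D dilution plot data)
#'
#' For each dilution step and each residue, the label of the cluster holding
#' the residue's alpha carbon (majority atom if no CA) -- the data behind a
#' one-dimensional dilution plot along the protein sequence.
#'
#' @param series A `dilution_series`.
#' @return Data frame: `step`, `chain`, `resseq`, `cluster_label`.
#' @export
dilution_plot_table <- function(series) {
  a <- series$molecule$atoms
  res <- unique(a[, c("chain", "resseq")])
  rows <- list()
  for (t in seq_along(series$steps)) {
    d <- series$steps[[t]]$decomposition
    for (r in seq_len(nrow(res))) {
      ra <- a[a$chain == res$chain[r] & a$resseq == res$resseq[r], ]
      marker <- if ("CA" %in% ra$name) {
        ra$serial[ra$name == "CA"][1]
      } else ra$serial[1]
      labs <- vapply(d$clusters, function(c) marker %in% c$atoms, logical(1))
      lab <- if (any(labs)) min(which(labs)) else NA_integer_
      rows[[length(rows) + 1L]] <- data.frame(
        step = t - 1L, chain = res$chain[r], resseq = res$resseq[r],
        cluster_label = lab, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Plot a dilution series
#'
#' One-dimensional dilution plot: residues along the x axis, dilution steps
#' down the y axis, cells coloured by the consistent (inherited) cluster
#' colouring.
#'
#' @param x A `dilution_series`.
#' @param palette A [cluster_palette()].
#' @param ... Unused.
#' @export
plot.dilution_series <- function(x, palette = cluster_palette(), ...) {
  tab <- dilution_plot_table(x)
  assignments <- color_dilution_series(x, palette)
  res <- unique(tab[, c("chain", "resseq")])
  n_steps <- length(x$steps)
  graphics::plot(NULL, xlim = c(0.5, nrow(res) + 0.5),
                 ylim = c(n_steps + 0.5, 0.5),
                 xlab = "residue", ylab = "dilution step", yaxt = "n")
  graphics::axis(2, at = seq_len(n_steps), labels = seq_len(n_steps) - 1L)
  for (t in seq_len(n_steps)) {
    asg <- assignments[[t]]
    sub <- tab[tab$step == t - 1L, ]
    for (r in seq_len(nrow(res))) {
      row <- sub[sub$chain == res$chain[r] & sub$resseq == res$resseq[r], ]
      col <- if (is.na(row$cluster_label[1])) palette$neutral else
        asg$color[match(row$cluster_label[1], asg$label)]
      graphics::rect(r - 0.5, t - 0.45, r + 0.5, t + 0.45,
                     col = col, border = NA)
    }
  }
  invisible(x)
}

# supporting planes of the convex hull, by brute force over point triples;
# exact for the facet-distance depth and robust to coplanar degeneracies
convex_hull_planes <- function(coords, tol = 1e-9) {
  pts <- unique(round(coords, 10))
  n <- nrow(pts)
  if (n < 4L) stop("convex hull undefined: fewer than 4 distinct atoms")
  centered <- sweep(pts, 2, colMeans(pts))
  if (qr(centered)$rank < 3L) {
    stop("convex hull undefined: atoms are coplanar")
  }
  if (n > 400L) stop("brute-force hull limited to 400 distinct points")
  triples <- utils::combn(n, 3L)
  p1 <- pts[triples[1, ], , drop = FALSE]
  p2 <- pts[triples[2, ], , drop = FALSE]
  p3 <- pts[triples[3, ], , drop = FALSE]
  u <- p2 - p1; v <- p3 - p1
  nx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
  ny <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
  nz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
  nrm <- sqrt(nx^2 + ny^2 + nz^2)
  ok <- nrm > 1e-8  # skip collinear triples
  normals <- cbind(nx, ny, nz)[ok, , drop = FALSE] / nrm[ok]
  base <- p1[ok, , drop = FALSE]
  s <- normals %*% t(pts) - rowSums(normals * base)  # signed dists, per plane
  smax <- do.call(pmax, as.data.frame(s))
  smin <- do.call(pmin, as.data.frame(s))
  upper <- smax <= tol   # all points on or below the plane
  lower <- smin >= -tol  # all points on or above
  planes <- rbind(
    cbind(normals[upper, , drop = FALSE],
          rowSums(normals * base)[upper]),
    cbind(-normals[lower, , drop = FALSE],
          -rowSums(normals * base)[lower]))
  if (nrow(planes) == 0L) stop("hull facet enumeration failed")
  planes  # columns: outward normal (3), offset; hull = {x : n.x <= offset}
}

#' Burial depth of a bond
#'
#' Distance from the bond midpoint to the nearest facet of the convex hull
#' of all atom coordinates; 0 for midpoints on or outside the hull.
#' Rotation- and translation-invariant.
#'
#' @param molecule A `molecule` with >= 4 non-coplanar atoms.
#' @param interaction An interaction (its `atoms` pair defines the bond).
#' @param planes Optional precomputed hull planes (from repeated calls).
#' @return Depth in Angstrom.
#' @export
bond_depth <- function(molecule, interaction, planes = NULL) {
  coords <- atom_coords(molecule)
  if (is.null(planes)) planes <- convex_hull_planes(coords)
  mid <- colMeans(coords[as.character(interaction$atoms), , drop = FALSE])
  d <- planes[, 4] - planes[, 1:3] %*% mid
  max(0, min(d))
}

#' Simulated alanine point mutation
#'
#' Removes every hydrogen bond and hydrophobic contact with at least one
#' participant atom in the residue's side chain beyond the beta carbon, then
#' recomputes the rigid cluster decomposition. Covalent topology is left
#' untouched. GLY, ALA and PRO are skipped with a warning result.
#'
#' @param molecule A `molecule`.
#' @param network A pruned `interaction_network`.
#' @param options [modeling_options()].
#' @param residue Residue identifier `"chain:resseq"` (e.g. `"A:5"`).
#' @return A `mutation_result`: residue, removed interaction ids, mutant
#'   decomposition, destabilization score (wild-type largest cluster minus
#'   mutant largest cluster, in atoms).
#' @export
mutate_to_alanine <- function(molecule, network,
                              options = modeling_options(), residue) {
  a <- molecule$atoms
  uid <- residue_uid(a$chain, a$resseq)
  sel <- uid == residue & a$record == "ATOM"
  if (!any(sel)) stop("unknown residue id '", residue, "'")
  resname <- a$resname[sel][1]
  analyze <- function(net) {
    bodies <- build_bodies(molecule)
    model <- assign_connections(bodies, net, options)
    components_to_clusters(run_pebble_game(to_multigraph(model)), model)
  }
  wt <- analyze(network)
  wt_largest <- summary(wt)$largest_size
  if (resname %in% c("GLY", "ALA", "PRO")) {
    warning("residue ", residue, " is ", resname,
            ": alanine substitution skipped")
    return(structure(list(residue = residue, resname = resname,
                          skipped = TRUE, removed_ids = integer(0),
                          decomposition = wt, score = 0L,
                          d_clusters = 0L),
                     class = "mutation_result"))
  }
  backbone_cb <- c("N", "CA", "C", "O", "OXT", "CB",
                   "H", "H1", "H2", "H3", "HN", "HA", "HA2", "HA3",
                   "HB", "HB1", "HB2", "HB3", "HXT")
  side_serials <- a$serial[sel & !(a$name %in% backbone_cb)]
  removed <- integer(0)
  for (x in network$interactions) {
    if (!x$kind %in% c("hydrogen_bond", "hydrophobic")) next
    touch <- c(x$atoms, x$hydrogen)
    touch <- touch[!is.na(touch)]
    if (any(touch %in% side_serials)) removed <- c(removed, x$id)
  }
  mutant <- analyze(remove_interactions(network, removed))
  structure(list(residue = residue, resname = resname, skipped = FALSE,
                 removed_ids = removed, decomposition = mutant,
                 score = wt_largest - summary(mutant)$largest_size,
                 d_clusters = summary(mutant)$n_clusters -
                   summary(wt)$n_clusters),
            class = "mutation_result")
}

#' Rank alanine mutations by destabilization
#'
#' Score: wild-type largest-cluster atom count minus mutant largest-cluster
#' atom count; ties broken by the increase in cluster count, then by input
#' (residue) order. Sorted descending with a stable sort.
#'
#' @param results List of `mutation_result`s sharing a wild type.
#' @param wild_type The wild-type `rigid_decomposition`.
#' @return Data frame: residue, score, d_clusters, rank.
#' @export
rank_mutations <- function(results, wild_type) {
  if (length(results) == 0L) {
    return(data.frame(residue = character(0), score = integer(0),
                      d_clusters = integer(0), rank = integer(0),
                      stringsAsFactors = FALSE))
  }
  wt_largest <- summary(wild_type)$largest_size
  wt_n <- summary(wild_type)$n_clusters
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(residue = r$residue,
               score = wt_largest - summary(r$decomposition)$largest_size,
               d_clusters = summary(r$decomposition)$n_clusters - wt_n,
               stringsAsFactors = FALSE)
  }))
  ord <- order(-df$score, -df$d_clusters, seq_len(nrow(df)))
  out <- df[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Classify non-covalent bonds as redundant or critical
#'
#' A bond is redundant if its removal does not change the rigid cluster
#' decomposition, and critical otherwise. Applied by the definition: each
#' hydrogen bond and hydrophobic contact is removed in turn, the
#' decomposition recomputed from scratch, and the cluster atom sets
#' compared.
#'
#' @param molecule A `molecule`.
#' @param network A pruned `interaction_network`.
#' @param options [modeling_options()].
#' @return Data frame: `interaction_id`, `kind`, `classification`.
#' @export
classify_redundancy <- function(molecule, network,
                                options = modeling_options()) {
  analyze <- function(net) {
    bodies <- build_bodies(molecule)
    model <- assign_connections(bodies, net, options)
    components_to_clusters(run_pebble_game(to_multigraph(model)), model)
  }
  reference <- analyze(network)
  kinds <- network_kinds(network)
  ids <- network_ids(network)
  sel <- which(kinds %in% c("hydrogen_bond", "hydrophobic"))
  rows <- lapply(sel, function(i) {
    trial <- analyze(remove_interactions(network, ids[i]))
    data.frame(interaction_id = ids[i], kind = kinds[i],
               classification = if (same_decomposition(reference, trial))
                 "redundant" else "critical",
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(interaction_id = integer(0), kind = character(0),
               classification = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
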