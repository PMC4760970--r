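#' Convert pebble-game components to atom-level rigid clusters
#'
#' Each rigid component becomes a cluster whose atom set is the union of its
#' bodies' atoms; bodies in no component become singleton-body clusters.
#' Adjacent clusters may overlap on the two atoms of a shared hinge axis.
#' Clusters are ordered by decreasing size, ties broken by smallest atom
#' serial, and labelled `1..n`. Flexible connections (hinges/bars joining
#' bodies in distinct clusters) are inherited from the model.
#'
#' @param result A `pebble_result` computed from `model`'s multigraph.
#' @param model The `bbh_model` the graph was built from.
#' @return A `rigid_decomposition`.
#' @export
components_to_clusters <- function(result, model) {
  stopifnot(inherits(result, "pebble_result"), inherits(model, "bbh_model"))
  if (result$n_vertices != length(model$bodies)) {
    stop("pebble result does not match model: vertex/body counts differ")
  }
  comps <- result$components %||% list()
  n_bodies <- length(model$bodies)
  body_cluster <- rep(NA_integer_, n_bodies)
  raw <- list()
  for (comp in comps) {
    atoms <- sort(unique(unlist(lapply(model$bodies[comp], `[[`, "atoms"))))
    raw[[length(raw) + 1L]] <- list(atoms = atoms, bodies = comp)
    body_cluster[comp] <- length(raw)
  }
  for (b in which(is.na(body_cluster))) {
    raw[[length(raw) + 1L]] <- list(atoms = sort(model$bodies[[b]]$atoms),
                                    bodies = b)
    body_cluster[b] <- length(raw)
  }
  sizes <- vapply(raw, function(x) length(x$atoms), integer(1))
  min_serial <- vapply(raw, function(x) min(x$atoms), numeric(1))
  atom_key <- vapply(raw, function(x) paste(x$atoms, collapse = ","),
                     character(1))
  ord <- order(-sizes, min_serial, atom_key)
  clusters <- lapply(seq_along(ord), function(i) {
    x <- raw[[ord[i]]]
    list(label = i, size = length(x$atoms), atoms = x$atoms,
         bodies = sort(as.integer(x$bodies)))
  })
  relabel <- integer(length(raw)); relabel[ord] <- seq_along(ord)
  body_cluster <- relabel[body_cluster]

  cn <- model$connections
  flex <- data.frame(cluster_i = integer(0), cluster_j = integer(0),
                     kind = character(0), interaction_id = integer(0),
                     stringsAsFactors = FALSE)
  if (nrow(cn) > 0L) {
    ci <- body_cluster[cn$body_i]; cj <- body_cluster[cn$body_j]
    sel <- ci != cj
    if (any(sel)) {
      flex <- data.frame(cluster_i = pmin(ci[sel], cj[sel]),
                         cluster_j = pmax(ci[sel], cj[sel]),
                         kind = cn$kind[sel],
                         interaction_id = cn$interaction_id[sel],
                         stringsAsFactors = FALSE)
      rownames(flex) <- NULL
    }
  }
  structure(list(clusters = clusters, flexible = flex,
                 body_cluster = body_cluster,
                 provenance = list(options = model$options,
                                   cutoff = model$network$pruned_at %||% NA)),
            class = "rigid_decomposition")
}

#' @export
print.rigid_decomposition <- function(x, ...) {
  s <- summary(x)
  cat(sprintf(
    "<rigid_decomposition> %d cluster(s), largest %d atoms, %d atom(s) covered, %d flexible connection(s)\n",
    s$n_clusters, s$largest_size, s$atom_coverage, s$n_flexible))
  invisible(x)
}

#' Summarize a rigid cluster decomposition
#'
#' @param object A `rigid_decomposition`.
#' @param ... Unused.
#' @return List: `n_clusters`, `largest_size`, `atom_coverage` (distinct
#'   atoms across clusters), `n_flexible`.
#' @export
summary.rigid_decomposition <- function(object, ...) {
  cl <- object$clusters
  list(
    n_clusters = length(cl),
    largest_size = if (length(cl) == 0L) 0L else max(vapply(cl, `[[`, integer(1), "size")),
    atom_coverage = length(unique(unlist(lapply(cl, `[[`, "atoms")))),
    n_flexible = nrow(object$flexible)
  )
}

#' Shared-atom overlap matrix between two decompositions
#'
#' Entry `(i, j)` counts the atoms shared by cluster `i` of `a` and cluster
#' `j` of `b`. The decompositions must reference overlapping atom universes.
#'
#' @param a,b `rigid_decomposition` objects.
#' @return Integer matrix, rows = clusters of `a`, columns = clusters of `b`.
#' @export
overlap_matrix <- function(a, b) {
  ua <- unique(unlist(lapply(a$clusters, `[[`, "atoms")))
  ub <- unique(unlist(lapply(b$clusters, `[[`, "atoms")))
  if (length(intersect(ua, ub)) == 0L) {
    stop("decompositions have disjoint atom universes")
  }
  m <- matrix(0L, nrow = length(a$clusters), ncol = length(b$clusters))
  for (i in seq_along(a$clusters)) {
    for (j in seq_along(b$clusters)) {
      m[i, j] <- length(intersect(a$clusters[[i]]$atoms,
                                  b$clusters[[j]]$atoms))
    }
  }
  m
}

# canonical form for decomposition equality: the multiset of cluster atom
# sets, label- and order-independent
canonical_clusters <- function(decomposition) {
  keys <- vapply(decomposition$clusters,
                 function(c) paste(sort(c$atoms), collapse = ","),
                 character(1))
  sort(keys)
}

# the flexible connections as a label-independent multiset: each connection
# named by the atom sets of its two clusters plus its kind
canonical_flexible <- function(decomposition) {
  fl <- decomposition$flexible
  if (is.null(fl) || nrow(fl) == 0L) return(character(0))
  key_of <- vapply(decomposition$clusters,
                   function(c) paste(sort(c$atoms), collapse = ","),
                   character(1))
  labels <- vapply(decomposition$clusters, `[[`, integer(1), "label")
  ki <- key_of[match(fl$cluster_i, labels)]
  kj <- key_of[match(fl$cluster_j, labels)]
  sort(paste(pmin(ki, kj), pmax(ki, kj), fl$kind, sep = "|"))
}

#' Test two decompositions for equality
#'
#' Decompositions are equal when their cluster atom sets coincide and the
#' flexible connections joining the clusters coincide (as a multiset of
#' cluster-pair/kind records). Including the connections matters for bond
#' classification: removing a hinge that joins two flexible clusters leaves
#' the cluster atom sets untouched but changes the flexible framework, so
#' such a bond is critical, not redundant.
#'
#' @param a,b `rigid_decomposition` objects.
#' @return TRUE/FALSE.
#' @export
same_decomposition <- function(a, b) {
  identical(canonical_clusters(a), canonical_clusters(b)) &&
    identical(canonical_flexible(a), canonical_flexible(b))
}

#' Write / read a rigid cluster decomposition (versioned JSON schema)
#'
#' Schema: `{schema, provenance, clusters: [{label, size, atom_serials}],
#' flexible: [{cluster_i, cluster_j, kind}]}`. Round-tripping preserves
#' labels and ordering exactly.
#'
#' @param decomposition A `rigid_decomposition`.
#' @param path File path.
#' @export
write_decomposition <- function(decomposition, path) {
  obj <- list(
    schema = "rigidmol/decomposition/1",
    provenance = list(cutoff = decomposition$provenance$cutoff %||% NA),
    clusters = lapply(decomposition$clusters, function(c) {
      list(label = c$label, size = c$size, atom_serials = as.integer(c$atoms))
    }),
    flexible = if (nrow(decomposition$flexible) > 0L) {
      lapply(seq_len(nrow(decomposition$flexible)), function(r) {
        list(cluster_i = decomposition$flexible$cluster_i[r],
             cluster_j = decomposition$flexible$cluster_j[r],
             kind = decomposition$flexible$kind[r])
      })
    } else list()
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_decomposition
#' @export
read_decomposition <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  clusters <- lapply(j$clusters, function(c) {
    atoms <- as.integer(unlist(c$atom_serials))
    list(label = as.integer(c$label), size = as.integer(c$size),
         atoms = atoms, bodies = integer(0))
  })
  flex <- if (length(j$flexible) > 0L) {
    do.call(rbind, lapply(j$flexible, function(f) {
      data.frame(cluster_i = as.integer(f$cluster_i),
                 cluster_j = as.integer(f$cluster_j),
                 kind = f$kind, interaction_id = NA_integer_,
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(cluster_i = integer(0), cluster_j = integer(0),
               kind = character(0), interaction_id = integer(0),
               stringsAsFactors = FALSE)
  }
  structure(list(clusters = clusters, flexible = flex,
                 body_cluster = NULL,
                 provenance = list(cutoff = j$provenance$cutoff %||% NA)),
            class = "rigid_decomposition")
}

#' Per-atom cluster membership table
#'
#' Flat table (one row per atom-cluster membership; hinge-shared atoms
#' appear twice) suitable for plotting tools.
#'
#' @param decomposition A `rigid_decomposition`.
#' @return Data frame with columns `atom_serial`, `cluster_label`.
#' @export
atom_cluster_table <- function(decomposition) {
  rows <- lapply(decomposition$clusters, function(c) {
    data.frame(atom_serial = c$atoms, cluster_label = c$label)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$atom_serial, out$cluster_label), , drop = FALSE]
  rownames(out) <- NULL
  out
}
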