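#' Rigidity analysis of a molecule
#'
#' The package's main entry point: builds (or reuses) the interaction
#' network, prunes hydrogen bonds at the energy cutoff, constructs the
#' body-bar-hinge mechanical framework and its multigraph, runs the
#' (6,6)-pebble game, and converts the rigid components back to atom-level
#' clusters.
#'
#' @param molecule A `molecule` (covalent bonds are perceived if absent).
#' @param params [interaction_params()] (detection gates, energy constants,
#'   cutoff).
#' @param options [modeling_options()] (hinge/bar assignment per bond kind).
#' @param network Optional precomputed `interaction_network`; when supplied
#'   it is pruned at `params$energy_cutoff` and used as-is.
#' @return A `rigidity` object: the molecule, pruned network, `bbh_model`,
#'   multigraph, `pebble_result` and `rigid_decomposition`.
#' @examples
#' helix <- make_fixture("toy_helix", n_res = 8)
#' fit <- rigidity(helix)
#' summary(fit)
#' @export
rigidity <- function(molecule, params = interaction_params(),
                     options = modeling_options(), network = NULL) {
  stopifnot(inherits(molecule, "molecule"))
  if (nrow(molecule$bonds) == 0L) {
    molecule <- perceive_covalent_bonds(molecule)
  }
  if (is.null(network)) {
    network <- build_interaction_network(molecule, params)
  }
  pruned <- prune_by_cutoff(network, params$energy_cutoff)
  bodies <- build_bodies(molecule)
  model <- assign_connections(bodies, pruned, options)
  graph <- to_multigraph(model)
  pebble <- run_pebble_game(graph, pebble_params(6L, 6L))
  decomposition <- components_to_clusters(pebble, model)
  structure(list(molecule = molecule, network = pruned, model = model,
                 graph = graph, pebble = pebble,
                 decomposition = decomposition,
                 params = params, options = options),
            class = "rigidity")
}

#' @export
print.rigidity <- function(x, ...) {
  s <- summary(x$decomposition)
  cat("Rigidity analysis (body-bar-hinge framework, (6,6)-pebble game)\n")
  cat(sprintf("  atoms: %d   bodies: %d   multigraph edges: %d\n",
              nrow(x$molecule$atoms), length(x$model$bodies),
              nrow(x$graph$edges)))
  cat(sprintf("  rank: %d   free DoF: %d   redundant edges: %d\n",
              x$pebble$rank, free_dof(x$pebble),
              length(x$pebble$redundant)))
  cat(sprintf("  rigid clusters: %d (largest %d atoms), flexible connections: %d\n",
              s$n_clusters, s$largest_size, s$n_flexible))
  invisible(x)
}

#' @export
summary.rigidity <- function(object, ...) {
  s <- summary(object$decomposition)
  kinds <- network_kinds(object$network)
  out <- list(
    n_atoms = nrow(object$molecule$atoms),
    n_bodies = length(object$model$bodies),
    n_interactions = length(kinds),
    n_hydrogen_bonds = sum(kinds == "hydrogen_bond"),
    n_hydrophobic = sum(kinds == "hydrophobic"),
    rank = object$pebble$rank,
    free_dof = free_dof(object$pebble),
    n_redundant_edges = length(object$pebble$redundant),
    n_clusters = s$n_clusters,
    largest_cluster = s$largest_size,
    n_flexible = s$n_flexible
  )
  class(out) <- "summary.rigidity"
  out
}

#' @export
print.summary.rigidity <- function(x, ...) {
  cat("Rigidity analysis summary\n")
  for (nm in names(unclass(x))) {
    cat(sprintf("  %-18s %s\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Plot a rigid cluster decomposition
#'
#' Barplot of cluster sizes coloured with the size-based palette; neutral
#' colour marks sub-threshold clusters.
#'
#' @param x A `rigidity` object.
#' @param palette A [cluster_palette()].
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.rigidity <- function(x, palette = cluster_palette(), ...) {
  d <- x$decomposition
  if (length(d$clusters) == 0L) {
    graphics::plot.new(); graphics::title("empty decomposition")
    return(invisible(x))
  }
  sizes <- vapply(d$clusters, `[[`, integer(1), "size")
  asg <- color_by_size(d, palette)
  cols <- asg$color[match(seq_along(sizes), asg$label)]
  graphics::barplot(sizes, col = cols, border = NA,
                    names.arg = seq_along(sizes),
                    xlab = "cluster label", ylab = "atoms", ...)
  invisible(x)
}
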