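#' Cluster colour palette
#'
#' Ordered distinct colours for dominant clusters, a reserved neutral colour
#' for clusters below the size threshold, and the threshold itself.
#'
#' @param colors Character vector of distinct colour identifiers.
#' @param neutral Neutral colour for sub-threshold clusters (not in the main
#'   list).
#' @param threshold Minimum cluster size (atoms) to receive a palette colour
#'   (default 5).
#' @return A `cluster_palette`.
#' @export
cluster_palette <- function(colors = c("#1F77B4", "#FF7F0E", "#2CA02C",
                                       "#D62728", "#9467BD", "#8C564B",
                                       "#E377C2", "#7F7F7F", "#BCBD22",
                                       "#17BECF"),
                            neutral = "#C8C8C8", threshold = 5L) {
  if (anyDuplicated(colors)) stop("palette colours must be distinct")
  if (neutral %in% colors) stop("neutral colour must not be in the main list")
  structure(list(colors = colors, neutral = neutral,
                 threshold = as.integer(threshold)),
            class = "cluster_palette")
}

# endless deterministic colour supply: palette colours, then synthesized
# hues not colliding with them
fresh_color <- function(palette, used) {
  for (c in palette$colors) if (!(c %in% used)) return(c)
  i <- 0L
  repeat {
    i <- i + 1L
    c <- grDevices::hsv(h = (i * 0.6180339887) %% 1, s = 0.65, v = 0.85)
    c <- toupper(c)
    if (!(c %in% used) && c != palette$neutral &&
        !(c %in% palette$colors)) return(c)
  }
}

#' Colour clusters by size
#'
#' Clusters in label order (labels are sorted by decreasing size, ties by
#' smallest atom serial) receive the palette colours in order; clusters
#' below the size threshold get the neutral colour. If there are more
#' dominant clusters than palette colours, colours cycle and the result is
#' flagged with attribute `cycled = TRUE`.
#'
#' @param decomposition A `rigid_decomposition`.
#' @param palette A [cluster_palette()].
#' @return Data frame `label`, `color` (attribute `cycled`).
#' @export
color_by_size <- function(decomposition, palette = cluster_palette()) {
  cl <- decomposition$clusters
  if (length(cl) == 0L) {
    out <- data.frame(label = integer(0), color = character(0),
                      stringsAsFactors = FALSE)
    attr(out, "cycled") <- FALSE
    return(out)
  }
  sizes <- vapply(cl, `[[`, integer(1), "size")
  labels <- vapply(cl, `[[`, integer(1), "label")
  dominant <- sizes >= palette$threshold
  colors <- rep(palette$neutral, length(cl))
  nd <- sum(dominant)
  cycled <- nd > length(palette$colors)
  if (cycled) {
    warning("more dominant clusters (", nd, ") than palette colours (",
            length(palette$colors), "): colours cycle")
  }
  if (nd > 0L) {
    colors[dominant] <-
      palette$colors[((seq_len(nd) - 1L) %% length(palette$colors)) + 1L]
  }
  out <- data.frame(label = labels, color = colors, stringsAsFactors = FALSE)
  attr(out, "cycled") <- cycled
  out
}

#' Consistent colouring of a dilution series
#'
#' Step 0 is coloured by size. At each later step, each parent cluster's
#' colour is inherited by its largest child (ties broken by smallest atom
#' serial); other children at or above the size threshold receive a fresh
#' unused colour, smaller children the neutral colour. No colour is ever
#' shared by two simultaneously existing (non-neutral) clusters.
#'
#' @param series A `dilution_series` whose snapshots refine monotonically.
#' @param palette A [cluster_palette()].
#' @return List of per-step assignment data frames (`label`, `color`).
#' @export
color_dilution_series <- function(series, palette = cluster_palette()) {
  bad <- dilution_refines(series)
  if (!isTRUE(bad)) {
    stop("dilution series does not refine monotonically at step ", bad)
  }
  steps <- series$steps
  assignments <- vector("list", length(steps))
  assignments[[1]] <- color_by_size(steps[[1]]$decomposition, palette)
  ever_used <- setdiff(unique(assignments[[1]]$color), palette$neutral)
  for (t in seq_len(length(steps) - 1L)) {
    parents <- steps[[t]]$decomposition$clusters
    children <- steps[[t + 1L]]$decomposition$clusters
    prev <- assignments[[t]]
    # parent of each child: the step-t cluster containing all its atoms
    # (hinge atoms may also sit in a second parent; largest overlap wins)
    parent_of <- vapply(children, function(ch) {
      ov <- vapply(parents, function(p) {
        if (all(ch$atoms %in% p$atoms)) length(ch$atoms) else -1L
      }, integer(1))
      which.max(ov)
    }, integer(1))
    colors <- rep(NA_character_, length(children))
    for (pi in unique(parent_of)) {
      kids <- which(parent_of == pi)
      sizes <- vapply(children[kids], `[[`, integer(1), "size")
      mins <- vapply(children[kids], function(c) min(c$atoms), numeric(1))
      heir <- kids[order(-sizes, mins)][1]
      pcolor <- prev$color[match(parents[[pi]]$label, prev$label)]
      colors[heir] <- pcolor
      for (kid in setdiff(kids, heir)) {
        if (children[[kid]]$size >= palette$threshold) {
          c <- fresh_color(palette, c(ever_used, colors))
          colors[kid] <- c
          ever_used <- c(ever_used, c)
        } else {
          colors[kid] <- palette$neutral
        }
      }
    }
    assignments[[t + 1L]] <- data.frame(
      label = vapply(children, `[[`, integer(1), "label"),
      color = colors, stringsAsFactors = FALSE)
  }
  assignments
}

# Gale-Shapley deferred acceptance; proposer preferences and acceptor
# rankings as lists of candidate indices in preference order
gale_shapley <- function(prop_prefs, acc_ranks, n_acc) {
  n_prop <- length(prop_prefs)
  next_idx <- rep(1L, n_prop)
  match_of_acc <- rep(NA_integer_, n_acc)
  free <- seq_len(n_prop)
  while (length(free) > 0L) {
    p <- free[1]
    prefs <- prop_prefs[[p]]
    if (next_idx[p] > length(prefs)) { free <- free[-1]; next }
    a <- prefs[next_idx[p]]
    next_idx[p] <- next_idx[p] + 1L
    rank <- acc_ranks[[a]]
    if (!(p %in% rank)) next  # unacceptable to the acceptor
    cur <- match_of_acc[a]
    if (is.na(cur)) {
      match_of_acc[a] <- p
      free <- free[-1]
    } else if (match(p, rank) < match(cur, rank)) {
      match_of_acc[a] <- p
      free <- c(free[-1], cur)
    }
  }
  match_of_acc
}

#' Match two decompositions via stable matching and colour them consistently
#'
#' Each side ranks the other's clusters by shared-atom count (ties broken by
#' label); zero-overlap pairs are mutually unacceptable. The first argument
#' proposes (stable matchings are side-dependent, so the proposer is fixed
#' for determinism). Matched pairs share a colour; unmatched dominant
#' clusters get fresh colours, sub-threshold ones the neutral colour.
#'
#' @param a,b `rigid_decomposition` objects over a shared atom universe.
#' @param palette A [cluster_palette()].
#' @return List: `matching` (data frame `a_label`, `b_label`, `shared`),
#'   `colors_a`, `colors_b` (assignment data frames).
#' @export
match_decompositions <- function(a, b, palette = cluster_palette()) {
  m <- overlap_matrix(a, b)  # errors on disjoint universes
  na <- nrow(m); nb <- ncol(m)
  prop_prefs <- lapply(seq_len(na), function(i) {
    js <- which(m[i, ] > 0L)
    js[order(-m[i, js], js)]
  })
  acc_ranks <- lapply(seq_len(nb), function(j) {
    is <- which(m[, j] > 0L)
    is[order(-m[is, j], is)]
  })
  match_of_b <- gale_shapley(prop_prefs, acc_ranks, nb)
  matching <- data.frame(a_label = integer(0), b_label = integer(0),
                         shared = integer(0))
  for (j in which(!is.na(match_of_b))) {
    i <- match_of_b[j]
    matching <- rbind(matching,
                      data.frame(a_label = a$clusters[[i]]$label,
                                 b_label = b$clusters[[j]]$label,
                                 shared = m[i, j]))
  }
  matching <- matching[order(matching$a_label), , drop = FALSE]
  rownames(matching) <- NULL

  colors_a <- color_by_size(a, palette)
  labels_b <- vapply(b$clusters, `[[`, integer(1), "label")
  sizes_b <- vapply(b$clusters, `[[`, integer(1), "size")
  col_b <- rep(NA_character_, length(labels_b))
  for (r in seq_len(nrow(matching))) {
    bi <- match(matching$b_label[r], labels_b)
    col_b[bi] <- colors_a$color[match(matching$a_label[r], colors_a$label)]
  }
  used <- unique(c(colors_a$color, col_b))
  used <- setdiff(used[!is.na(used)], palette$neutral)
  for (bi in which(is.na(col_b))) {
    if (sizes_b[bi] >= palette$threshold) {
      c <- fresh_color(palette, used)
      col_b[bi] <- c
      used <- c(used, c)
    } else {
      col_b[bi] <- palette$neutral
    }
  }
  colors_b <- data.frame(label = labels_b, color = col_b,
                         stringsAsFactors = FALSE)
  list(matching = matching, colors_a = colors_a, colors_b = colors_b)
}

#' Write a colour assignment as JSON (label -> colour)
#' @param assignment Assignment data frame (`label`, `color`).
#' @param path File path.
#' @export
write_color_assignment <- function(assignment, path) {
  obj <- as.list(setNames(assignment$color, assignment$label))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
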