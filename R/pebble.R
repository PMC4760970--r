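#' Pebble game parameters
#'
#' `k` pebbles per vertex (a body's degrees of freedom; 6 in 3D) and
#' sparsity offset `l` (6 for body-bar-hinge frameworks: every vertex subset
#' `S`, `|S| >= 2`, may span at most `6|S| - 6` independent edges).
#'
#' @param k Pebbles per vertex (default 6).
#' @param l Sparsity offset (default 6); must satisfy `0 <= l <= 2k - 1`.
#' @return A `pebble_params` list.
#' @export
pebble_params <- function(k = 6L, l = 6L) {
  k <- as.integer(k); l <- as.integer(l)
  stopifnot(k >= 1L, l >= 0L, l <= 2L * k - 1L)
  structure(list(k = k, l = l), class = "pebble_params")
}

# Mutable pebble-game state held in an environment:
#   adj : list of integer vectors, adj[[v]] = out-neighbours (with multiplicity)
#   peb : integer vector of free pebbles per vertex
new_pebble_state <- function(n, k) {
  st <- new.env(parent = emptyenv())
  st$adj <- rep(list(integer(0)), n)
  st$peb <- rep.int(k, n)
  st$n <- n
  st
}

# DFS from `from` for a vertex (not in `forbid`) holding a free pebble;
# on success the path is reversed and a pebble moves to `from`.
# Returns TRUE/FALSE; on failure st$last_reach holds the visited set.
pebble_search <- function(st, from, forbid) {
  n <- st$n
  visited <- logical(n)
  parent <- integer(n)
  visited[from] <- TRUE
  visited[forbid] <- TRUE
  stack <- from
  found <- 0L
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in unique(st$adj[[v]])) {
      if (visited[w]) next
      visited[w] <- TRUE
      parent[w] <- v
      if (st$peb[w] > 0L) { found <- w; break }
      stack <- c(stack, w)
    }
    if (found > 0L) break
  }
  if (found == 0L) {
    visited[forbid] <- FALSE
    st$last_reach <- which(visited)
    return(FALSE)
  }
  # reverse the path found -> ... -> from and move the pebble
  w <- found
  while (w != from) {
    v <- parent[w]
    # remove one v -> w edge instance, add w -> v
    idx <- match(w, st$adj[[v]])
    st$adj[[v]] <- st$adj[[v]][-idx]
    st$adj[[w]] <- c(st$adj[[w]], v)
    w <- v
  }
  st$peb[found] <- st$peb[found] - 1L
  st$peb[from] <- st$peb[from] + 1L
  TRUE
}

# Gather `target` pebbles onto {u, v}; returns TRUE on success.
gather_pebbles <- function(st, u, v, target) {
  repeat {
    if (st$peb[u] + st$peb[v] >= target) return(TRUE)
    if (pebble_search(st, u, v)) next
    if (pebble_search(st, v, u)) next
    return(FALSE)
  }
}

#' Run the (k,l)-pebble game
#'
#' Computes a maximum independent (k,l)-sparse edge subset, the redundant
#' edges, the matroid rank, per-vertex free pebble counts, and (for `k = l`,
#' the body-bar-hinge case) the rigid components: maximal vertex sets
#' spanning exactly `k|S| - l` independent edges. Edges are inserted in a
#' deterministic order (by connection id, then endpoints) so the identity of
#' the redundant edges is reproducible; rank and components are invariant
#' under any insertion order.
#'
#' @param graph A [multigraph()] (loop-free).
#' @param params [pebble_params()]; defaults to the (6,6) game.
#' @return A `pebble_result`: `independent` and `redundant` (edge row
#'   indices into `graph$edges`), `rank`, `free_pebbles` (per vertex),
#'   `components` (list of integer vertex vectors, `k = l` only).
#' @export
run_pebble_game <- function(graph, params = pebble_params()) {
  stopifnot(inherits(graph, "multigraph"))
  e <- graph$edges
  if (any(e$u == e$v)) {
    stop("self-loops are inadmissible for the (", params$k, ",", params$l,
         ")-pebble game")
  }
  k <- params$k; l <- params$l
  n <- graph$n_vertices
  st <- new_pebble_state(n, k)
  ord <- order(e$conn_id, pmin(e$u, e$v), pmax(e$u, e$v))
  independent <- logical(nrow(e))
  for (idx in ord) {
    u <- e$u[idx]; v <- e$v[idx]
    if (gather_pebbles(st, u, v, l + 1L)) {
      tail_v <- if (st$peb[u] > 0L) u else v
      head_v <- if (tail_v == u) v else u
      st$adj[[tail_v]] <- c(st$adj[[tail_v]], head_v)
      st$peb[tail_v] <- st$peb[tail_v] - 1L
      independent[idx] <- TRUE
    }
  }
  components <- if (k == l) detect_components(st, e, l) else NULL
  structure(list(
    independent = which(independent),
    redundant = which(!independent),
    rank = sum(independent),
    free_pebbles = st$peb,
    components = components,
    params = params,
    n_vertices = n,
    n_edges = nrow(e)
  ), class = "pebble_result")
}

# Components for k = l: two adjacent vertices lie in a common tight set
# exactly when l + 1 pebbles cannot be gathered on them; for k = l the
# union of tight sets sharing a vertex is tight, so the union-find closure
# over failing adjacent pairs yields the maximal tight sets.
detect_components <- function(st, edges, l) {
  if (nrow(edges) == 0L) return(list())
  uf <- seq_len(st$n)
  find <- function(x) { while (uf[x] != x) { uf[x] <<- uf[uf[x]]; x <- uf[x] }; x }
  pairs <- unique(data.frame(u = pmin(edges$u, edges$v),
                             v = pmax(edges$u, edges$v)))
  for (r in seq_len(nrow(pairs))) {
    u <- pairs$u[r]; v <- pairs$v[r]
    if (find(u) == find(v)) next
    if (!gather_pebbles(st, u, v, l + 1L)) {
      uf[find(u)] <- find(v)
    }
  }
  roots <- vapply(seq_len(st$n), find, integer(1))
  groups <- split(seq_len(st$n), roots)
  comps <- Filter(function(g) length(g) >= 2L, groups)
  comps <- lapply(comps, function(g) sort(as.integer(g)))
  comps <- comps[order(vapply(comps, min, integer(1)))]
  unname(comps)
}

#' @export
print.pebble_result <- function(x, ...) {
  cat(sprintf(
    "<pebble_result> (%d,%d) game: rank %d, %d redundant, %d free DoF, %d component(s)\n",
    x$params$k, x$params$l, x$rank, length(x$redundant),
    sum(x$free_pebbles), length(x$components %||% list())))
  invisible(x)
}

#' Total free degrees of freedom
#'
#' Sum of free pebbles, `k|V| - rank`; at least 6 for any non-empty graph
#' under the (6,6) game (the trivial rigid motions of 3-space).
#'
#' @param result A `pebble_result`.
#' @return Integer DoF count.
#' @export
free_dof <- function(result) {
  stopifnot(inherits(result, "pebble_result"))
  if (result$n_vertices == 0L) stop("free DoF undefined for an empty graph")
  sum(result$free_pebbles)
}

#' Exhaustive sparsity check
#'
#' Verifies that an edge set is (k,l)-sparse by counting, for every vertex
#' subset `S` with `|S| >= 2`, the edges spanned by `S` against the bound
#' `k|S| - l`. Exponential in `|V|`; intended as a certificate on small
#' graphs.
#'
#' @param edges Data frame with columns `u`, `v`.
#' @param n_vertices Vertex count (`<= 16`).
#' @param params [pebble_params()].
#' @return TRUE/FALSE.
#' @export
verify_sparsity <- function(edges, n_vertices, params = pebble_params()) {
  stopifnot(n_vertices <= 16L)
  if (nrow(edges) == 0L) return(TRUE)
  k <- params$k; l <- params$l
  emask <- bitwOr(bitwShiftL(1L, edges$u - 1L), bitwShiftL(1L, edges$v - 1L))
  for (s in seq_len(2^n_vertices - 1L)) {
    sz <- sum(bitwAnd(s, bitwShiftL(1L, 0:(n_vertices - 1L))) != 0L)
    if (sz < 2L) next
    cnt <- sum(bitwAnd(emask, s) == emask)
    if (cnt > k * sz - l) return(FALSE)
  }
  TRUE
}

#' Brute-force rank oracle
#'
#' Rank of the (k,l)-sparsity matroid by greedy augmentation with exhaustive
#' sparsity verification over all vertex subsets. Independent of the pebble
#' game; used to certify it on small graphs.
#'
#' @param graph A [multigraph()] with `|V| <= 8` and `|E| <= 48`.
#' @param params [pebble_params()].
#' @return Integer rank.
#' @export
oracle_rank <- function(graph, params = pebble_params()) {
  n <- graph$n_vertices
  e <- graph$edges
  if (n > 8L || nrow(e) > 48L) {
    stop("oracle_rank limited to |V| <= 8, |E| <= 48")
  }
  if (any(e$u == e$v)) stop("self-loops are inadmissible")
  oracle_rank_masks(
    bitwOr(bitwShiftL(1L, e$u - 1L), bitwShiftL(1L, e$v - 1L)), n, params)
}

# core of the oracle on precomputed edge bitmasks; maintains per-subset
# spanned-edge counts incrementally
oracle_rank_masks <- function(emask, n, params) {
  k <- params$k; l <- params$l
  if (length(emask) == 0L) return(0L)
  subsets <- seq_len(2^n - 1L)
  sizes <- vapply(subsets, function(s) {
    sum(bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) != 0L)
  }, numeric(1))
  keep <- sizes >= 2L
  subsets <- subsets[keep]
  bounds <- k * sizes[keep] - l
  cnt <- integer(length(subsets))
  rank <- 0L
  for (m in emask) {
    spans <- bitwAnd(subsets, m) == m
    if (all(cnt[spans] + 1L <= bounds[spans])) {
      cnt[spans] <- cnt[spans] + 1L
      rank <- rank + 1L
    }
  }
  rank
}

#' Brute-force component oracle
#'
#' All maximal vertex sets `S`, `|S| >= 2`, whose induced subgraph has
#' oracle rank exactly `k|S| - l`. Exponential; `|V| <= 8`.
#'
#' @param graph A [multigraph()].
#' @param params [pebble_params()].
#' @return List of sorted integer vertex vectors.
#' @export
oracle_components <- function(graph, params = pebble_params()) {
  n <- graph$n_vertices
  if (n > 8L) stop("oracle_components limited to |V| <= 8")
  e <- graph$edges
  if (nrow(e) > 0L && any(e$u == e$v)) stop("self-loops are inadmissible")
  emask <- if (nrow(e) > 0L) {
    bitwOr(bitwShiftL(1L, e$u - 1L), bitwShiftL(1L, e$v - 1L))
  } else integer(0)
  k <- params$k; l <- params$l
  tight <- integer(0)
  for (s in seq_len(2^n - 1L)) {
    verts <- which(bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) != 0L)
    if (length(verts) < 2L) next
    induced <- emask[bitwAnd(emask, s) == emask]
    r <- oracle_rank_masks(induced, n, params)
    if (r == k * length(verts) - l) tight <- c(tight, s)
  }
  maximal <- tight[vapply(tight, function(s) {
    !any(tight != s & bitwAnd(tight, s) == s)
  }, logical(1))]
  comps <- lapply(maximal, function(s) {
    which(bitwAnd(s, bitwShiftL(1L, 0:(n - 1L))) != 0L)
  })
  comps[order(vapply(comps, min, integer(1)))]
}

#' Seeded random multigraph generator
#'
#' Small random multigraphs for property tests: vertex count in
#' `[2, n_max]`, edge count in `[0, e_max]`, endpoints uniform without
#' self-loops, parallel edges allowed.
#'
#' @param n_max,e_max Size bounds.
#' @param seed Integer seed.
#' @return A [multigraph()].
#' @export
random_multigraph <- function(n_max = 6L, e_max = 40L, seed = 1L) {
  r <- local({ set.seed(seed); list(n = sample(2:n_max, 1L),
                                    m = sample(0:e_max, 1L)) })
  set.seed(seed + 1000003L)
  n <- r$n; m <- r$m
  if (m == 0L) return(multigraph(n))
  u <- sample(n, m, replace = TRUE)
  v <- sample(n - 1L, m, replace = TRUE)
  v <- ifelse(v >= u, v + 1L, v)
  multigraph(n, data.frame(u = pmin(u, v), v = pmax(u, v),
                           conn_id = seq_len(m)))
}
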