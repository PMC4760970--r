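test_that("size-based colouring assigns palette colours in label order", {
  pal <- cluster_palette()
  d <- make_decomp(list(1:50, 51:70, 71:73))
  asg <- color_by_size(d, pal)
  expect_equal(asg$color, c(pal$colors[1], pal$colors[2], pal$neutral))

  empty <- color_by_size(make_decomp(list()), pal)
  expect_equal(nrow(empty), 0L)

  # equal sizes: smallest-atom-serial tie-break fixes the colour order
  tied <- make_decomp(list(11:20, 1:10))
  asg2 <- color_by_size(tied, pal)
  lab_of_min <- tied$clusters[[which.min(vapply(tied$clusters, function(c) {
    min(c$atoms)
  }, numeric(1)))]]$label
  expect_equal(asg2$color[asg2$label == lab_of_min], pal$colors[1])

  # cycling beyond the palette flags the assignment
  many <- make_decomp(lapply(0:11, function(i) (i * 10 + 1):(i * 10 + 6)))
  expect_warning(cy <- color_by_size(many, pal), "cycle")
  expect_true(attr(cy, "cycled"))
})

test_that("dilution colouring obeys the largest-child inheritance rule", {
  helix <- make_fixture("toy_helix", n_res = 8)
  fit <- rigidity(helix)
  series <- dilute(helix, fit$network, fit$options)
  pal <- cluster_palette()
  assignments <- color_dilution_series(series, pal)
  expect_length(assignments, length(series$steps))
  expect_true(verify_inheritance(series, assignments))
  # injectivity: within any step, non-neutral colours are unique
  for (asg in assignments) {
    cols <- asg$color[asg$color != pal$neutral]
    expect_equal(anyDuplicated(cols), 0L)
  }
})

test_that("synthetic series with two splits colours every snapshot consistently", {
  steps <- list(
    list(removed_id = NA, energy = NA,
         decomposition = make_decomp(list(1:20, 21:30))),
    list(removed_id = 1L, energy = -1,
         decomposition = make_decomp(list(1:12, 13:20, 21:30))),
    list(removed_id = 2L, energy = -2,
         decomposition = make_decomp(list(1:12, 13:20, 21:26, 27:30))))
  series <- structure(list(steps = steps, order = "weakest_first"),
                      class = "dilution_series")
  pal <- cluster_palette()
  assignments <- color_dilution_series(series, pal)
  expect_true(verify_inheritance(series, assignments))
  # the 12-atom child keeps the colour of the 20-atom parent
  a0 <- assignments[[1]]; a1 <- assignments[[2]]
  col_parent <- a0$color[a0$label == 1]  # 1:20 is largest at step 0
  lab_child <- Filter(function(c) identical(c$atoms, 1:12),
                      steps[[2]]$decomposition$clusters)[[1]]$label
  expect_equal(a1$color[a1$label == lab_child], col_parent)
  # no-split final step inherits everything: compare colours by atom set
  key <- function(step, asg) {
    sets <- vapply(step$decomposition$clusters, function(c) {
      paste(c$atoms, collapse = ",")
    }, character(1))
    setNames(asg$color, sets)
  }
  k1 <- key(steps[[2]], assignments[[2]])
  k2 <- key(steps[[3]], assignments[[3]])
  for (s in intersect(names(k1), names(k2))) {
    expect_equal(k2[[s]], k1[[s]])
  }

  # a non-refining series is rejected with the violating step named
  bad <- series
  bad$steps[[3]]$decomposition <- make_decomp(list(1:25, 26:30))
  expect_error(color_dilution_series(bad, pal), "step 2")
})

test_that("stable matching has no blocking pair and recovers known matchings", {
  pal <- cluster_palette()
  # identical decompositions: identity matching, identical colours
  a <- make_decomp(list(1:10, 11:16))
  res <- match_decompositions(a, a, pal)
  expect_equal(res$matching$a_label, res$matching$b_label)
  expect_equal(res$colors_b$color, res$colors_a$color)
  expect_equal(res$colors_b$label, res$colors_a$label)

  # overlap matrix [[8,1],[2,5]] -> {(1,1),(2,2)}, verified exhaustively
  a2 <- make_decomp(list(1:9, 10:16))
  b2 <- make_decomp(list(c(1:8, 10:11), c(9, 12:16)))
  expect_equal(overlap_matrix(a2, b2), rbind(c(8L, 1L), c(2L, 5L)))
  res2 <- match_decompositions(a2, b2, pal)
  expect_equal(res2$matching$a_label, c(1L, 2L))
  expect_equal(res2$matching$b_label, c(1L, 2L))
  m <- overlap_matrix(a2, b2)
  expect_true(verify_stable_matching(m, res2$matching))
  # uniqueness: the only stable matching among all candidate matchings
  all_matchings <- list(
    data.frame(a_label = integer(0), b_label = integer(0)),
    data.frame(a_label = 1L, b_label = 1L),
    data.frame(a_label = 1L, b_label = 2L),
    data.frame(a_label = 2L, b_label = 1L),
    data.frame(a_label = 2L, b_label = 2L),
    data.frame(a_label = c(1L, 2L), b_label = c(1L, 2L)),
    data.frame(a_label = c(1L, 2L), b_label = c(2L, 1L)))
  stable <- Filter(function(mm) verify_stable_matching(m, mm), all_matchings)
  expect_length(stable, 1L)
  expect_equal(stable[[1]], res2$matching[, c("a_label", "b_label")])

  # partial overlap: single match, unmatched clusters get fresh colours
  a3 <- make_decomp(list(1:10, 21:28, 31:37))
  b3 <- make_decomp(list(1:9))
  res3 <- match_decompositions(a3, b3, pal)
  expect_equal(nrow(res3$matching), 1L)
  expect_equal(res3$matching$b_label, 1L)
  matched_a <- res3$matching$a_label
  expect_equal(res3$colors_b$color,
               res3$colors_a$color[res3$colors_a$label == matched_a])
  unmatched_colors <- res3$colors_a$color[res3$colors_a$label != matched_a]
  expect_false(any(unmatched_colors %in% res3$colors_b$color))

  expect_error(match_decompositions(make_decomp(list(1:5)),
                                    make_decomp(list(50:55)), pal),
               "disjoint")
})

test_that("random matchings up to 5x5 never admit a blocking pair", {
  pal <- cluster_palette()
  set.seed(77)
  for (rep in 1:25) {
    na <- sample(1:5, 1); nb <- sample(1:5, 1)
    # random partitions of a shared universe into na and nb clusters
    universe <- 1:40
    cut_a <- sort(sample(2:39, na - 1)); cut_b <- sort(sample(2:39, nb - 1))
    part <- function(cuts) {
      bounds <- c(0, cuts, 40)
      lapply(seq_len(length(bounds) - 1L), function(i) {
        universe[(bounds[i] + 1):bounds[i + 1]]
      })
    }
    a <- make_decomp(part(cut_a)); b <- make_decomp(part(cut_b))
    res <- match_decompositions(a, b, pal)
    m <- overlap_matrix(a, b)
    expect_true(verify_stable_matching(m, res$matching),
                info = paste("rep", rep))
    # matched pairs share colours; non-neutral colours stay injective
    for (side in list(res$colors_a, res$colors_b)) {
      cols <- side$color[side$color != pal$neutral]
      expect_equal(anyDuplicated(cols), 0L)
    }
  }
})
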