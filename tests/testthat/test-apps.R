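test_that("dilution removes bonds in order and matches from-scratch recomputation", {
  helix <- make_fixture("toy_helix", n_res = 8)
  fit <- rigidity(helix)
  series <- dilute(helix, fit$network, fit$options)
  expect_length(series$steps, 5L)  # step 0 + 4 hydrogen bonds

  # weakest-first: removal energies are non-decreasing in magnitude
  energies <- vapply(series$steps[-1], `[[`, numeric(1), "energy")
  expect_true(all(diff(energies) <= 1e-12))

  # every snapshot equals an independent from-scratch analysis
  removed <- integer(0)
  for (t in seq_along(series$steps)) {
    if (t > 1L) removed <- c(removed, series$steps[[t]]$removed_id)
    net <- fit$network
    keep <- !vapply(net$interactions, function(x) x$id %in% removed,
                    logical(1))
    net$interactions <- net$interactions[keep]
    oracle <- rigidity(helix, fit$params, fit$options,
                       network = net)$decomposition
    expect_true(same_decomposition(series$steps[[t]]$decomposition, oracle),
                info = paste("step", t - 1L))
  }
})

remove_hb <- function(net) {
  keep <- vapply(net$interactions, function(x) x$kind != "hydrogen_bond",
                 logical(1))
  net$interactions <- net$interactions[keep]
  net
}

test_that("dilution snapshots refine monotonically and serialization is deterministic", {
  helix <- make_fixture("toy_helix", n_res = 8)
  fit <- rigidity(helix)
  for (ord in c("weakest_first", "strongest_first")) {
    series <- dilute(helix, fit$network, fit$options, order = ord)
    for (t in seq_len(length(series$steps) - 1L)) {
      parents <- series$steps[[t]]$decomposition$clusters
      for (ch in series$steps[[t + 1L]]$decomposition$clusters) {
        expect_true(any(vapply(parents, function(p) {
          all(ch$atoms %in% p$atoms)
        }, logical(1))), info = paste(ord, "step", t))
      }
    }
  }
  s1 <- serialize_dilution_series(dilute(helix, fit$network, fit$options))
  s2 <- serialize_dilution_series(dilute(helix, fit$network, fit$options))
  expect_identical(s1, s2)
  expect_error(dilute(helix, remove_hb(fit$network)), "hydrogen bond")
})

test_that("removing the last hydrogen bond separates a two-cluster toy", {
  dimer <- water_dimer(2.8)
  fit <- rigidity(dimer)
  # two water bodies joined only by the hydrogen-bond hinge
  expect_length(fit$decomposition$clusters, 2L)
  expect_equal(nrow(fit$decomposition$flexible), 1L)
  series <- dilute(dimer, fit$network, fit$options)
  final <- series$steps[[length(series$steps)]]$decomposition
  expect_length(final$clusters, 2L)
  expect_equal(nrow(final$flexible), 0L)  # fully separated
  expect_false(same_decomposition(fit$decomposition, final))
})

test_that("bond depth equals closed-form tetrahedron geometry and is invariant", {
  a <- 6
  verts <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) *
    (a / (2 * sqrt(2)))
  centroid <- colMeans(verts)
  eps <- 0.05
  atoms <- data.frame(
    serial = 1:6, name = c(paste0("C", 1:4), "X1", "X2"), element = "C",
    alt_loc = "", resname = "UNK", chain = "A", resseq = 1L, icode = "",
    x = c(verts[, 1], centroid[1] - eps, centroid[1] + eps),
    y = c(verts[, 2], centroid[2], centroid[2]),
    z = c(verts[, 3], centroid[3], centroid[3]),
    occupancy = 1, b_factor = 0, record = "HETATM", stringsAsFactors = FALSE)
  mol <- rigidmol_new_molecule(atoms, data.frame(i = integer(0),
                                                 j = integer(0),
                                                 order = character(0)))
  centre_bond <- list(atoms = c(5L, 6L))
  r_in <- a / (2 * sqrt(6))  # inradius of a regular tetrahedron
  expect_equal(bond_depth(mol, centre_bond), r_in, tolerance = 1e-9)

  # bond between two hull vertices: midpoint on a hull edge -> depth 0
  expect_equal(bond_depth(mol, list(atoms = c(1L, 2L))), 0)

  # translation invariance
  shifted <- mol
  shifted$atoms$x <- shifted$atoms$x + 11.3
  shifted$atoms$y <- shifted$atoms$y - 2.2
  expect_equal(bond_depth(shifted, centre_bond), r_in, tolerance = 1e-9)

  flat <- mol
  flat$atoms$z <- 0
  expect_error(bond_depth(flat, centre_bond), "coplanar")
})

test_that("depth-ordered dilution uses shallowest-first ordering", {
  helix <- make_fixture("toy_helix", n_res = 8)
  fit <- rigidity(helix)
  series <- dilute(helix, fit$network, fit$options, order = "depth")
  ids <- vapply(series$steps[-1], `[[`, integer(1), "removed_id")
  hb_ids <- ids
  depths <- vapply(hb_ids, function(id) {
    x <- Filter(function(i) i$id == id, fit$network$interactions)[[1]]
    bond_depth(helix, x)
  }, numeric(1))
  expect_true(all(diff(depths) >= -1e-9))
})

test_that("alanine mutation removes only side-chain interactions and reanalyses", {
  toy <- ser_toy(attached = TRUE)
  net <- prune_by_cutoff(build_interaction_network(toy), -1)
  wt <- rigidity(toy, network = net)$decomposition

  res <- mutate_to_alanine(toy, net, residue = "A:1")
  expect_false(res$skipped)
  expect_gte(summary(res$decomposition)$n_clusters,
             summary(wt)$n_clusters + 1L)
  # removed interactions all touch the side chain beyond C-beta
  side <- toy$atoms$serial[toy$atoms$resseq == 1 &
                             toy$atoms$name %in% c("OG", "HG")]
  for (id in res$removed_ids) {
    x <- Filter(function(i) i$id == id, net$interactions)[[1]]
    expect_true(any(c(x$atoms, x$hydrogen) %in% side))
  }
  # mutant equals a from-scratch analysis of the reduced network
  reduced <- net
  keep <- !vapply(reduced$interactions, function(x) x$id %in% res$removed_ids,
                  logical(1))
  reduced$interactions <- reduced$interactions[keep]
  oracle <- rigidity(toy, network = reduced)$decomposition
  expect_true(same_decomposition(res$decomposition, oracle))
  # untouched interactions survive verbatim (mutagenesis locality)
  expect_setequal(
    setdiff(vapply(net$interactions, `[[`, integer(1), "id"),
            res$removed_ids),
    vapply(reduced$interactions, `[[`, integer(1), "id"))

  # detached toy: nothing to remove, decomposition unchanged, score 0
  lonely <- ser_toy(attached = FALSE)
  lnet <- prune_by_cutoff(build_interaction_network(lonely), -1)
  res0 <- mutate_to_alanine(lonely, lnet, residue = "A:1")
  expect_length(res0$removed_ids, 0L)
  expect_equal(res0$score, 0L)

  expect_error(mutate_to_alanine(toy, net, residue = "A:99"),
               "unknown residue")
  helix <- make_fixture("toy_helix", n_res = 4)
  hnet <- prune_by_cutoff(build_interaction_network(helix), -1)
  expect_warning(skipped <- mutate_to_alanine(helix, hnet, residue = "A:2"),
                 "skipped")
  expect_true(skipped$skipped)
})

test_that("mutation ranking is stable and matches a brute-force sort", {
  wt <- make_decomp(list(1:20, 21:25))
  mk <- function(res, largest, nclust) {
    structure(list(residue = res,
                   decomposition = make_decomp(
                     c(list(1:largest),
                       split(26:(26 + nclust * 2 - 1),
                             rep(seq_len(nclust), each = 2)))),
                   skipped = FALSE),
              class = "mutation_result")
  }
  # all scores zero -> input order preserved
  same <- lapply(c("A:1", "A:2", "A:3"), function(r) {
    structure(list(residue = r, decomposition = wt, skipped = FALSE),
              class = "mutation_result")
  })
  expect_equal(rank_mutations(same, wt)$residue, c("A:1", "A:2", "A:3"))

  results <- list(mk("A:1", 18, 1), mk("A:2", 10, 2), mk("A:3", 18, 2))
  ranked <- rank_mutations(results, wt)
  # brute-force pairwise comparison oracle
  score <- c(2, 10, 2)
  dcl <- vapply(results, function(r) {
    summary(r$decomposition)$n_clusters - summary(wt)$n_clusters
  }, integer(1))
  better <- function(i, j) {
    if (score[i] != score[j]) return(score[i] > score[j])
    if (dcl[i] != dcl[j]) return(dcl[i] > dcl[j])
    i < j
  }
  oracle_order <- c("A:1", "A:2", "A:3")[order(
    vapply(1:3, function(i) sum(vapply(1:3, function(j) {
      j != i && better(j, i)
    }, logical(1))), integer(1)))]
  expect_equal(ranked$residue, oracle_order)
  expect_equal(ranked$residue[1], "A:2")
})

test_that("redundancy labels agree with the remove-and-recompute definition", {
  # single-bond toy: the only hydrogen bond is critical
  dimer <- water_dimer(2.8)
  dnet <- prune_by_cutoff(build_interaction_network(dimer), -1)
  cls <- classify_redundancy(dimer, dnet)
  expect_equal(cls$classification, "critical")

  # helix and random sub-networks: definitional oracle via rigidity()
  helix <- make_fixture("toy_helix", n_res = 8)
  net <- prune_by_cutoff(build_interaction_network(helix), -1)
  check_against_oracle <- function(net) {
    cls <- classify_redundancy(helix, net)
    ref <- rigidity(helix, network = net)$decomposition
    for (r in seq_len(nrow(cls))) {
      reduced <- net
      keep <- !vapply(reduced$interactions, function(x) {
        x$id == cls$interaction_id[r]
      }, logical(1))
      reduced$interactions <- reduced$interactions[keep]
      trial <- rigidity(helix, network = reduced)$decomposition
      expected <- if (same_decomposition(ref, trial)) "redundant" else
        "critical"
      expect_equal(cls$classification[r], expected,
                   info = paste("interaction", cls$interaction_id[r]))
    }
    cls
  }
  full <- check_against_oracle(net)
  expect_true(all(c("redundant", "critical") %in% full$classification))
  set.seed(31)
  for (rep in 1:3) {
    sub <- net
    kinds <- vapply(sub$interactions, `[[`, character(1), "kind")
    noncov <- which(kinds %in% c("hydrogen_bond", "hydrophobic"))
    drop <- sample(noncov, 3L)
    sub$interactions <- sub$interactions[-drop]
    check_against_oracle(sub)
  }
})
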