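test_that("hydrogen-bond detection applies geometric gates", {
  near <- water_dimer(2.8)
  hb <- detect_hydrogen_bonds(near)
  expect_length(hb, 1L)
  expect_equal(hb[[1]]$donor, 1L)
  expect_equal(hb[[1]]$acceptor, 4L)
  expect_lt(hb[[1]]$energy, 0)

  far <- water_dimer(10)
  expect_length(detect_hydrogen_bonds(far), 0L)

  bare <- water_dimer(2.8)
  bare$atoms <- bare$atoms[bare$atoms$element != "H", ]
  bare$bonds <- bare$bonds[0, ]
  expect_error(detect_hydrogen_bonds(bare), "hydrogens")
})

test_that("stored energies re-evaluate from the recorded geometry", {
  # independent re-implementation of the documented closed form
  mayo <- function(r, th, d0 = 8, r0 = 2.8) {
    d0 * min(0, 5 * (r0 / r)^12 - 6 * (r0 / r)^10) * cos(th * pi / 180)^2
  }
  dimer <- water_dimer(2.9)
  hb <- detect_hydrogen_bonds(dimer)[[1]]
  expect_equal(hb$energy, mayo(hb$geometry$r_da, hb$geometry$theta_dha),
               tolerance = 1e-12)
  expect_equal(hb$energy, hydrogen_bond_energy(hb$geometry))
  for (x in detect_hydrogen_bonds(make_fixture("toy_helix", n_res = 8))) {
    expect_equal(x$energy, hydrogen_bond_energy(x$geometry))
    expect_equal(x$energy, mayo(x$geometry$r_da, x$geometry$theta_dha),
                 tolerance = 1e-12)
  }
})

test_that("the energy form has its minimum at (R0, 180) and vanishes at the angular gate", {
  # grid-search oracle over the admissible geometry space
  grid <- expand.grid(r = seq(2.0, 3.5, by = 0.005),
                      th = seq(90, 180, by = 0.5))
  e <- mapply(function(r, th) {
    hydrogen_bond_energy(list(r_da = r, theta_dha = th))
  }, grid$r, grid$th)
  best <- grid[which.min(e), ]
  expect_equal(best$r, 2.8)
  expect_equal(best$th, 180)
  expect_equal(min(e), -8)

  expect_equal(hydrogen_bond_energy(list(r_da = 2.8, theta_dha = 90)), 0)
  # monotone in alignment at fixed distance
  es <- vapply(seq(90, 180, by = 1), function(th) {
    hydrogen_bond_energy(list(r_da = 2.9, theta_dha = th))
  }, numeric(1))
  expect_true(all(diff(es) <= 1e-12))
  expect_error(hydrogen_bond_energy(list(r_da = 4.0, theta_dha = 170)),
               "outside gates")
  expect_error(hydrogen_bond_energy(list(r_da = 2.9, theta_dha = 45)),
               "outside gates")
})

test_that("hydrophobic detection keeps one closest contact per residue pair", {
  contact <- function(d) {
    atoms <- data.frame(
      serial = 1:2, name = c("CB", "CB"), element = "C", alt_loc = "",
      resname = "ALA", chain = "A", resseq = c(1L, 2L), icode = "",
      x = c(0, d), y = 0, z = 0, occupancy = 1, b_factor = 0,
      record = "ATOM", stringsAsFactors = FALSE)
    rigidmol_new_molecule(atoms, data.frame(i = integer(0), j = integer(0),
                                            order = character(0)))
  }
  expect_length(detect_hydrophobic(contact(3.5)), 1L)   # <= 3.4 + 0.25
  expect_length(detect_hydrophobic(contact(8.0)), 0L)

  # three residues with several carbons each: result equals brute force
  set.seed(11)
  n <- 9L
  atoms <- data.frame(
    serial = 1:n, name = paste0("C", 1:n), element = "C", alt_loc = "",
    resname = "LEU", chain = "A", resseq = rep(1:3, each = 3), icode = "",
    x = runif(n, 0, 6), y = runif(n, 0, 6), z = runif(n, 0, 6),
    occupancy = 1, b_factor = 0, record = "ATOM", stringsAsFactors = FALSE)
  mol <- rigidmol_new_molecule(atoms, data.frame(i = integer(0),
                                                 j = integer(0),
                                                 order = character(0)))
  got <- detect_hydrophobic(mol)
  got_pairs <- sort(vapply(got, function(x) {
    paste(sort(x$atoms), collapse = "-")
  }, character(1)))
  # oracle: exhaustive pair scan + per-residue-pair minimisation
  cutoff <- 1.7 + 1.7 + 0.25
  best <- list()
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (atoms$resseq[i] == atoms$resseq[j]) next
    d <- sqrt(sum((atoms[i, c("x", "y", "z")] - atoms[j, c("x", "y", "z")])^2))
    if (d > cutoff) next
    key <- paste(sort(c(atoms$resseq[i], atoms$resseq[j])), collapse = "|")
    if (is.null(best[[key]]) || d < best[[key]]$d) {
      best[[key]] <- list(d = d, pair = paste(i, j, sep = "-"))
    }
  }
  expect_setequal(got_pairs, vapply(best, `[[`, character(1), "pair"))
})

test_that("disulfide detection equals an exhaustive SG pair scan", {
  cys_pair <- function(d12, d13 = 10, d23 = 10) {
    # three CYS SG atoms; place first two d12 apart, third far or near
    atoms <- data.frame(
      serial = 1:3, name = "SG", element = "S", alt_loc = "",
      resname = "CYS", chain = "A", resseq = 1:3, icode = "",
      x = c(0, d12, 0), y = c(0, 0, d13), z = 0,
      occupancy = 1, b_factor = 0, record = "ATOM", stringsAsFactors = FALSE)
    rigidmol_new_molecule(atoms, data.frame(i = integer(0), j = integer(0),
                                            order = character(0)))
  }
  expect_length(detect_disulfides(cys_pair(2.05)), 1L)
  expect_length(detect_disulfides(cys_pair(4.0)), 0L)
  # three mutually close SG atoms -> all three pairs
  m3 <- cys_pair(2.1, 2.1)
  m3$atoms$x[3] <- 1.05; m3$atoms$y[3] <- 1.4
  got <- detect_disulfides(m3)
  xyz <- as.matrix(m3$atoms[, c("x", "y", "z")])
  oracle <- sum(stats::dist(xyz) <= 2.5)
  expect_length(got, oracle)
})

test_that("energy-cutoff pruning is monotone and leaves other kinds untouched", {
  helix <- make_fixture("toy_helix", n_res = 8)
  net <- build_interaction_network(helix)
  survivors <- function(cut) {
    sum(network_kinds(prune_by_cutoff(net, cut)) == "hydrogen_bond")
  }
  expect_equal(survivors(0), 4L)       # all survive
  expect_equal(survivors(-100), 0L)    # none survive
  expect_equal(survivors(-1), 4L)      # helix bonds are ~ -5 kcal/mol
  # monotone nesting over a cutoff ladder
  cuts <- seq(-8, 0, by = 0.5)
  sets <- lapply(cuts, function(ct) {
    ids <- network_ids(prune_by_cutoff(net, ct))
  })
  for (i in seq_along(cuts)[-1]) {
    expect_true(all(sets[[i - 1]] %in% sets[[i]]))
  }
  # non-hydrogen-bond interactions are never pruned
  pruned <- prune_by_cutoff(net, -100)
  expect_equal(sum(network_kinds(pruned) != "hydrogen_bond"),
               sum(network_kinds(net) != "hydrogen_bond"))
})

test_that("synthetic energy ladder prunes exactly at the cutoff", {
  energies <- c(-3, -1, -0.2)
  net <- structure(list(
    molecule = NULL,
    interactions = lapply(seq_along(energies), function(i) {
      x <- list(kind = "hydrogen_bond", atoms = c(i, i + 10L),
                energy = energies[i], donor = i, hydrogen = i + 20L,
                acceptor = i + 10L, geometry = list(), id = i)
      x
    }),
    params = interaction_params()), class = "interaction_network")
  expect_length(prune_by_cutoff(net, -0.5)$interactions, 2L)
  expect_length(prune_by_cutoff(net, 0)$interactions, 3L)
  expect_length(prune_by_cutoff(net, -10)$interactions, 0L)
})

test_that("detection is invariant under rigid motion", {
  helix <- make_fixture("toy_helix", n_res = 8)
  ref <- detect_hydrogen_bonds(helix)
  # random rotation + translation
  set.seed(3)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
              c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
  R <- Rz %*% Rx
  xyz <- as.matrix(helix$atoms[, c("x", "y", "z")]) %*% t(R)
  moved <- helix
  moved$atoms$x <- xyz[, 1] + 13.7
  moved$atoms$y <- xyz[, 2] - 4.2
  moved$atoms$z <- xyz[, 3] + 0.9
  got <- detect_hydrogen_bonds(moved)
  expect_length(got, length(ref))
  for (k in seq_along(ref)) {
    expect_equal(got[[k]]$atoms, ref[[k]]$atoms)
    expect_equal(got[[k]]$energy, ref[[k]]$energy, tolerance = 1e-9)
  }
})
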