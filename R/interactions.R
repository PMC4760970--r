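#' Interaction detection parameters
#'
#' @param max_da_distance Maximum donor--acceptor distance in Angstrom
#'   (default 3.5).
#' @param min_dha_angle Minimum donor--hydrogen--acceptor angle in degrees
#'   (default 90).
#' @param hydrophobic_slack van der Waals slack for hydrophobic contacts in
#'   Angstrom (default 0.25).
#' @param energy_cutoff Hydrogen-bond energy cutoff E_cut in kcal/mol
#'   (default -1.0); bonds with energy above (weaker than) the cutoff are
#'   pruned. Must be <= 0.
#' @param hb_well_depth,hb_optimal_r Constants of the hydrogen-bond energy
#'   form (kcal/mol well depth D0, optimal donor--acceptor distance R0 in
#'   Angstrom); see [hydrogen_bond_energy()].
#' @return An `interaction_params` list.
#' @export
interaction_params <- function(max_da_distance = 3.5, min_dha_angle = 90,
                               hydrophobic_slack = 0.25, energy_cutoff = -1.0,
                               hb_well_depth = 8.0, hb_optimal_r = 2.8) {
  stopifnot(max_da_distance > 0, hydrophobic_slack >= 0, hb_optimal_r > 0)
  if (energy_cutoff > 0) stop("energy_cutoff must be <= 0 (kcal/mol)")
  structure(list(max_da_distance = max_da_distance,
                 min_dha_angle = min_dha_angle,
                 hydrophobic_slack = hydrophobic_slack,
                 energy_cutoff = energy_cutoff,
                 hb_well_depth = hb_well_depth,
                 hb_optimal_r = hb_optimal_r),
            class = "interaction_params")
}

new_interaction <- function(kind, atoms, energy = NA_real_,
                            donor = NA_integer_, hydrogen = NA_integer_,
                            acceptor = NA_integer_, geometry = list()) {
  list(kind = kind, atoms = as.integer(atoms), energy = energy,
       donor = donor, hydrogen = hydrogen, acceptor = acceptor,
       geometry = geometry)
}

#' Hydrogen-bond energy (Mayo-style closed form)
#'
#' `E(R, theta) = D0 * min(0, 5 (R0/R)^12 - 6 (R0/R)^10) * cos^2(theta)`
#' with `R` the donor--acceptor distance, `theta` the donor--hydrogen--
#' acceptor angle, well depth `D0` (default 8 kcal/mol) and optimal distance
#' `R0` (default 2.8 A). The radial 12-10 factor is clamped at zero so
#' separations tighter than the well never contribute a destabilising
#' (positive) energy; the angular factor vanishes at the 90 degree gate and
#' grows monotonically toward linearity. The global minimum is `-D0` at
#' `(R0, 180 deg)`.
#'
#' @param geometry List with `r_da` (Angstrom) and `theta_dha` (degrees).
#' @param params [interaction_params()].
#' @return Energy in kcal/mol (<= 0).
#' @export
hydrogen_bond_energy <- function(geometry, params = interaction_params()) {
  r <- geometry$r_da; th <- geometry$theta_dha
  if (!is.finite(r) || !is.finite(th)) stop("non-finite hydrogen-bond geometry")
  if (r <= 0 || r > params$max_da_distance || th < params$min_dha_angle ||
      th > 180) {
    stop(sprintf(
      "geometry outside gates (r_da = %.3f A, theta_dha = %.1f deg): energy undefined",
      r, th))
  }
  x <- params$hb_optimal_r / r
  radial <- min(0, 5 * x^12 - 6 * x^10)
  ang <- cos(th * pi / 180)^2
  params$hb_well_depth * radial * ang
}

# donor heavy atoms: N or O carrying >= 1 covalent hydrogen
# acceptors: O always; N only when it carries no hydrogen (amide N excluded)
hb_donors_acceptors <- function(molecule) {
  a <- molecule$atoms
  adj <- covalent_adjacency(molecule)
  is_h <- a$element == "H"
  h_serials <- a$serial[is_h]
  heavy <- a$serial[a$element %in% c("N", "O")]
  donors <- list()
  for (s in heavy) {
    nb <- get(as.character(s), adj)
    hs <- intersect(nb, h_serials)
    for (h in hs) donors[[length(donors) + 1L]] <- c(donor = s, hydrogen = h)
  }
  has_h <- vapply(heavy, function(s) {
    length(intersect(get(as.character(s), adj), h_serials)) > 0L
  }, logical(1))
  el <- a$element[match(heavy, a$serial)]
  acceptors <- heavy[el == "O" | (el == "N" & !has_h)]
  list(donors = donors, acceptors = acceptors, adj = adj)
}

#' Detect hydrogen bonds
#'
#' One interaction per (donor, hydrogen, acceptor) triple passing the
#' geometric gates (donor--acceptor distance, donor--hydrogen--acceptor
#' angle), scored with [hydrogen_bond_energy()]. Donors are N/O atoms
#' carrying a hydrogen; acceptors are O atoms and hydrogen-free N atoms.
#' Pairs within 3 covalent bonds of each other are excluded (they describe
#' near-covalent geometry, not hydrogen bonding).
#'
#' @param molecule A `molecule` with hydrogens and perceived covalent bonds.
#' @param params [interaction_params()].
#' @return List of hydrogen-bond interactions.
#' @export
detect_hydrogen_bonds <- function(molecule, params = interaction_params()) {
  a <- molecule$atoms
  if (!any(a$element == "H")) {
    stop("no hydrogens present: hydrogen-bond detection requires a ",
         "protonated structure (add hydrogens before analysis)")
  }
  da <- hb_donors_acceptors(molecule)
  if (length(da$donors) == 0L || length(da$acceptors) == 0L) return(list())
  xyz <- atom_coords(molecule)
  pos <- function(s) xyz[as.character(s), ]
  out <- list()
  for (dh in da$donors) {
    D <- pos(dh["donor"]); H <- pos(dh["hydrogen"])
    for (acc in da$acceptors) {
      if (acc == dh["donor"]) next
      A <- pos(acc)
      r_da <- sqrt(sum((D - A)^2))
      if (r_da > params$max_da_distance) next
      if (covalent_separation(da$adj, dh[["donor"]], acc, 3L) <= 3L) next
      v1 <- D - H; v2 <- A - H
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      theta <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (theta < params$min_dha_angle) next
      geom <- list(r_da = r_da, r_ha = sqrt(sum((H - A)^2)),
                   theta_dha = theta)
      out[[length(out) + 1L]] <- new_interaction(
        "hydrogen_bond", c(dh[["donor"]], acc),
        energy = hydrogen_bond_energy(geom, params),
        donor = dh[["donor"]], hydrogen = dh[["hydrogen"]], acceptor = acc,
        geometry = geom)
    }
  }
  dedupe_interactions(out)
}

dedupe_interactions <- function(ints) {
  if (length(ints) == 0L) return(ints)
  key <- vapply(ints, function(x) {
    paste(x$kind, bond_key(x$atoms[1], x$atoms[2]),
          x$hydrogen %||% NA_integer_)
  }, character(1))
  ints[!duplicated(key)]
}

#' Detect hydrophobic contacts
#'
#' Carbon/sulfur atom pairs in different residues with
#' `d <= r_vdw(a) + r_vdw(b) + slack`; at most one contact is retained per
#' residue pair (the closest atom pair wins), preventing bar-count inflation
#' in the mechanical model.
#'
#' @inheritParams detect_hydrogen_bonds
#' @return List of hydrophobic interactions.
#' @export
detect_hydrophobic <- function(molecule, params = interaction_params()) {
  a <- molecule$atoms
  sel <- which(a$element %in% c("C", "S"))
  if (length(sel) < 2L) return(list())
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  rv <- vdw_radius(a$element[sel])
  res <- paste(a$chain[sel], a$resseq[sel], a$icode[sel], sep = "\r")
  best <- list()  # residue-pair key -> c(d, i, j)
  for (i in seq_along(sel)[-length(sel)]) {
    for (j in seq(i + 1L, length(sel))) {
      if (res[i] == res[j]) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d > rv[i] + rv[j] + params$hydrophobic_slack) next
      key <- paste(sort(c(res[i], res[j])), collapse = "|")
      if (is.null(best[[key]]) || d < best[[key]][1]) {
        best[[key]] <- c(d, sel[i], sel[j])
      }
    }
  }
  lapply(unname(best), function(b) {
    new_interaction("hydrophobic", a$serial[b[2:3]],
                    geometry = list(distance = b[1]))
  })
}

#' Detect disulfide bonds
#'
#' SG--SG pairs of distinct cysteine residues within 2.5 Angstrom.
#'
#' @param molecule A `molecule`.
#' @return List of disulfide interactions.
#' @export
detect_disulfides <- function(molecule) {
  a <- molecule$atoms
  sel <- which(a$resname == "CYS" & a$name == "SG")
  out <- list()
  if (length(sel) < 2L) return(out)
  xyz <- as.matrix(a[sel, c("x", "y", "z")])
  for (i in seq_along(sel)[-length(sel)]) {
    for (j in seq(i + 1L, length(sel))) {
      same_res <- a$chain[sel[i]] == a$chain[sel[j]] &&
        a$resseq[sel[i]] == a$resseq[sel[j]]
      if (same_res) next
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d <= 2.5) {
        out[[length(out) + 1L]] <- new_interaction(
          "disulfide", a$serial[sel[c(i, j)]],
          geometry = list(distance = d))
      }
    }
  }
  out
}

#' Assemble the interaction network
#'
#' Imports the molecule's covalent bonds as interactions (single/double/
#' peptide/disulfide) and appends detected hydrogen bonds, hydrophobic
#' contacts and geometric disulfides. Interaction ids are assigned in a
#' deterministic order.
#'
#' @param molecule A `molecule` with perceived covalent bonds.
#' @param params [interaction_params()].
#' @param detect Character vector among `"hydrogen_bond"`, `"hydrophobic"`,
#'   `"disulfide"` naming the non-covalent classes to detect.
#' @return An `interaction_network`.
#' @export
build_interaction_network <- function(molecule, params = interaction_params(),
                                      detect = c("hydrogen_bond",
                                                 "hydrophobic", "disulfide")) {
  b <- molecule$bonds
  cov <- lapply(seq_len(nrow(b)), function(k) {
    kind <- switch(b$order[k], single = "covalent_single",
                   double = "covalent_double", peptide = "peptide",
                   disulfide = "disulfide")
    new_interaction(kind, c(b$i[k], b$j[k]))
  })
  ints <- cov
  if ("disulfide" %in% detect) {
    ss <- detect_disulfides(molecule)
    existing <- vapply(ints, function(x) bond_key(x$atoms[1], x$atoms[2]),
                       character(1))
    ss <- ss[!vapply(ss, function(x) {
      bond_key(x$atoms[1], x$atoms[2]) %in% existing
    }, logical(1))]
    ints <- c(ints, ss)
  }
  if ("hydrogen_bond" %in% detect) {
    ints <- c(ints, detect_hydrogen_bonds(molecule, params))
  }
  if ("hydrophobic" %in% detect) {
    ints <- c(ints, detect_hydrophobic(molecule, params))
  }
  for (k in seq_along(ints)) ints[[k]]$id <- k
  structure(list(molecule = molecule, interactions = ints, params = params),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  kinds <- vapply(x$interactions, `[[`, character(1), "kind")
  cat("<interaction_network>", length(kinds), "interactions\n")
  print(table(kinds))
  invisible(x)
}

#' Prune hydrogen bonds by energy cutoff
#'
#' Removes hydrogen bonds with energy above (weaker than) `cutoff`; all
#' other interaction kinds are untouched. The input network is not modified.
#'
#' @param network An `interaction_network`.
#' @param cutoff Energy cutoff in kcal/mol.
#' @return A pruned `interaction_network` (original interaction ids kept).
#' @export
prune_by_cutoff <- function(network, cutoff = network$params$energy_cutoff) {
  keep <- vapply(network$interactions, function(x) {
    x$kind != "hydrogen_bond" || x$energy <= cutoff
  }, logical(1))
  network$interactions <- network$interactions[keep]
  network$pruned_at <- cutoff
  network
}

# drop interactions by id (used by dilution / mutagenesis / redundancy)
remove_interactions <- function(network, ids) {
  keep <- !vapply(network$interactions, function(x) x$id %in% ids, logical(1))
  network$interactions <- network$interactions[keep]
  network
}

network_kinds <- function(network) {
  vapply(network$interactions, `[[`, character(1), "kind")
}

network_ids <- function(network) {
  vapply(network$interactions, `[[`, integer(1), "id")
}

#' Write an interaction network to a tab-separated file
#'
#' Columns: id, kind, atom serials, energy, geometry summary.
#'
#' @param network An `interaction_network`.
#' @param path Output path.
#' @export
write_interactions_tsv <- function(network, path) {
  rows <- lapply(network$interactions, function(x) {
    data.frame(id = x$id, kind = x$kind, atom_i = x$atoms[1],
               atom_j = x$atoms[2],
               energy = if (is.na(x$energy)) NA else round(x$energy, 6),
               r_da = x$geometry$r_da %||% NA,
               theta_dha = x$geometry$theta_dha %||% NA,
               distance = x$geometry$distance %||% NA,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
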