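# shared builders for tests: PDB text snippets, toy molecules, toy graphs,
# and independent verifiers used as oracles

pdb_line <- function(record, serial, name, resname, chain, resseq,
                     x, y, z, occ = 1, b = 0, elem = "", alt = "") {
  sprintf("%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name, alt, resname, chain, resseq, x, y, z,
          occ, b, elem)
}

water_pdb_text <- function() {
  c(pdb_line("HETATM", 1, "O", "HOH", "A", 1, 0, 0, 0, elem = "O"),
    pdb_line("HETATM", 2, "H1", "HOH", "A", 1, 0.957, 0, 0, elem = "H"),
    pdb_line("HETATM", 3, "H2", "HOH", "A", 1, -0.24, 0.927, 0, elem = "H"),
    "END")
}

two_model_pdb_text <- function() {
  c("MODEL     1",
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 0, 0, 0, elem = "C"),
    "ENDMDL",
    "MODEL     2",
    pdb_line("ATOM", 1, "CA", "ALA", "A", 1, 5, 0, 0, elem = "C"),
    "ENDMDL", "END")
}

# 10 protein atoms over two chains plus two waters
two_chain_pdb_text <- function() {
  lines <- character(0)
  s <- 0L
  for (ch in c("A", "B")) {
    for (r in 1:5) {
      s <- s + 1L
      lines <- c(lines, pdb_line("ATOM", s, "CA", "GLY", ch, r,
                                 r * 3.8, ifelse(ch == "A", 0, 10), 0,
                                 elem = "C"))
    }
  }
  c(lines,
    pdb_line("HETATM", 11, "O", "HOH", "A", 101, 20, 20, 20, elem = "O"),
    pdb_line("HETATM", 12, "O", "HOH", "B", 102, 25, 25, 25, elem = "O"),
    "END")
}

# two waters joined by one linear O-H...O hydrogen bond (D-A = r_da)
water_dimer <- function(r_da = 2.8) {
  a <- 104.52 * pi / 180
  atoms <- data.frame(
    serial = 1:6,
    name = c("O", "H1", "H2", "O", "H1", "H2"),
    element = c("O", "H", "H", "O", "H", "H"),
    alt_loc = "",
    resname = "HOH",
    chain = c("A", "A", "A", "B", "B", "B"),
    resseq = c(1L, 1L, 1L, 2L, 2L, 2L),
    icode = "",
    x = c(0, 0.9572, 0.9572 * cos(a), r_da, r_da + 0.9572 * cos(a),
          r_da + 0.9572 * cos(a)),
    y = c(0, 0, 0.9572 * sin(a), 0, 0.9572 * sin(a), -0.9572 * sin(a)),
    z = 0,
    occupancy = 1, b_factor = 0, record = "HETATM",
    stringsAsFactors = FALSE)
  bonds <- data.frame(i = c(1L, 1L, 4L, 4L), j = c(2L, 3L, 5L, 6L),
                      order = "single", stringsAsFactors = FALSE)
  rigidmol_new_molecule(atoms, bonds)
}

# access the internal constructor without exporting it
rigidmol_new_molecule <- function(atoms, bonds) {
  getFromNamespace("new_molecule", "rigidmol")(atoms, bonds)
}

# serine residue whose side-chain hydroxyl exchanges a reciprocal pair of
# hydrogen bonds with a water (OG-HG...OW and OW-H1...OG), rigidifying the
# hydroxyl and water bodies into one cluster; `attached` controls whether
# the water sits at bonding distance (TRUE) or 15 A away (FALSE)
ser_toy <- function(attached = TRUE) {
  og <- c(2, -2, 1)
  u <- c(0, -1, 0)
  shift <- if (attached) 0 else 15
  ow <- og + (2.8 + shift) * u
  atoms <- data.frame(
    serial = 1:14,
    name = c("N", "H", "CA", "HA", "C", "O", "CB", "HB2", "HB3", "OG", "HG",
             "O", "H1", "H2"),
    element = c("N", "H", "C", "H", "C", "O", "C", "H", "H", "O", "H",
                "O", "H", "H"),
    alt_loc = "",
    resname = c(rep("SER", 11), rep("HOH", 3)),
    chain = c(rep("A", 11), rep("B", 3)),
    resseq = c(rep(1L, 11), rep(2L, 3)),
    icode = "",
    x = c(0, -0.5, 1.46, 1.8, 2.2, 3.4, 2.0, 1.4, 2.95, og[1], og[1],
          ow[1], ow[1], ow[1] - 0.8),
    y = c(0, 0.85, 0, 0.9, 1.3, 1.4, -1.1, -1.7, -1.2, og[2], og[2] - 0.96,
          ow[2], ow[2] + 0.96, ow[2] - 0.6),
    z = c(0, 0, 0, 0.6, 0, 0, 1.1, 1.9, 1.4, og[3], og[3],
          ow[3], ow[3], ow[3]),
    occupancy = 1, b_factor = 0,
    record = c(rep("ATOM", 11), rep("HETATM", 3)),
    stringsAsFactors = FALSE)
  mol <- rigidmol_new_molecule(atoms, data.frame(i = integer(0),
                                                 j = integer(0),
                                                 order = character(0)))
  perceive_covalent_bonds(mol)
}

# cyclopropane: 3 pairwise-bonded carbon hubs (a hinge triangle)
cyclopropane <- function() {
  cc <- 1.51
  cpos <- rbind(c(0, 0, 0), c(cc, 0, 0), c(cc / 2, cc * sqrt(3) / 2, 0))
  hz <- 0.9
  atoms <- data.frame(
    serial = 1:9,
    name = c("C1", "C2", "C3", "H11", "H12", "H21", "H22", "H31", "H32"),
    element = c(rep("C", 3), rep("H", 6)),
    alt_loc = "", resname = "CPR", chain = "A", resseq = 1L, icode = "",
    x = c(cpos[, 1], cpos[rep(1:3, each = 2), 1]),
    y = c(cpos[, 2], cpos[rep(1:3, each = 2), 2] - 0.5),
    z = c(cpos[, 3], rep(c(hz, -hz), 3)),
    occupancy = 1, b_factor = 0, record = "HETATM",
    stringsAsFactors = FALSE)
  bonds <- data.frame(
    i = c(1L, 1L, 2L, 1L, 1L, 2L, 2L, 3L, 3L),
    j = c(2L, 3L, 3L, 4L, 5L, 6L, 7L, 8L, 9L),
    order = "single", stringsAsFactors = FALSE)
  rigidmol_new_molecule(atoms, bonds)
}

hinge_chain_graph <- function(n) {
  edges <- do.call(rbind, lapply(seq_len(n - 1L), function(i) {
    data.frame(u = rep(i, 5), v = rep(i + 1L, 5), conn_id = i)
  }))
  multigraph(n, edges)
}

hinge_triangle_graph <- function() {
  multigraph(3, data.frame(
    u = c(rep(1L, 5), rep(1L, 5), rep(2L, 5)),
    v = c(rep(2L, 5), rep(3L, 5), rep(3L, 5)),
    conn_id = rep(1:3, each = 5)))
}

# build a rigid_decomposition directly from atom-set lists (labels follow
# the package's ordering rule: size desc, then smallest atom serial)
make_decomp <- function(atom_sets) {
  sizes <- lengths(atom_sets)
  mins <- vapply(atom_sets, min, numeric(1))
  ord <- order(-sizes, mins)
  clusters <- lapply(seq_along(ord), function(i) {
    list(label = i, size = length(atom_sets[[ord[i]]]),
         atoms = sort(atom_sets[[ord[i]]]), bodies = integer(0))
  })
  structure(list(clusters = clusters,
                 flexible = data.frame(cluster_i = integer(0),
                                       cluster_j = integer(0),
                                       kind = character(0),
                                       interaction_id = integer(0)),
                 provenance = list()),
            class = "rigid_decomposition")
}

# independent stability verifier: TRUE iff the matching (data frame with
# a_label/b_label) admits no blocking pair under shared-atom preferences
verify_stable_matching <- function(m, matching) {
  na <- nrow(m); nb <- ncol(m)
  match_a <- rep(NA_integer_, na)
  match_b <- rep(NA_integer_, nb)
  for (r in seq_len(nrow(matching))) {
    match_a[matching$a_label[r]] <- matching$b_label[r]
    match_b[matching$b_label[r]] <- matching$a_label[r]
  }
  prefers <- function(vec, cand, cur) {
    # strict preference for cand over cur (NA cur = unmatched, always worse
    # than an acceptable candidate); ties broken by smaller index
    if (vec[cand] == 0L) return(FALSE)
    if (is.na(cur)) return(TRUE)
    vec[cand] > vec[cur] || (vec[cand] == vec[cur] && cand < cur)
  }
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (m[i, j] == 0L) next
      if (identical(match_a[i], j)) next
      if (prefers(m[i, ], j, match_a[i]) && prefers(m[, j], i, match_b[j])) {
        return(FALSE)
      }
    }
  }
  TRUE
}

# independent dilution-colouring verifier: walks parent/child containment
# itself and checks that every parent's largest child keeps its colour
verify_inheritance <- function(series, assignments) {
  for (t in seq_len(length(series$steps) - 1L)) {
    parents <- series$steps[[t]]$decomposition$clusters
    children <- series$steps[[t + 1L]]$decomposition$clusters
    prev <- assignments[[t]]; cur <- assignments[[t + 1L]]
    for (p in parents) {
      kids <- Filter(function(ch) all(ch$atoms %in% p$atoms), children)
      if (length(kids) == 0L) next
      sizes <- vapply(kids, `[[`, integer(1), "size")
      mins <- vapply(kids, function(c) min(c$atoms), numeric(1))
      heir <- kids[[order(-sizes, mins)[1]]]
      pcol <- prev$color[match(p$label, prev$label)]
      hcol <- cur$color[match(heir$label, cur$label)]
      if (!identical(pcol, hcol)) return(FALSE)
    }
  }
  TRUE
}
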