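# Intra-residue covalent bond templates for the 20 standard amino acids
# (atom name pairs; heavy atoms only -- hydrogens are attached by name
# convention below). Orders: "d" marks double bonds.
amino_acid_templates <- function() {
  bb <- list(c("N", "CA"), c("CA", "C"), c("CA", "CB"))
  bbo <- list(c("C", "O", "d"), c("C", "OXT"))
  t <- list(
    GLY = list(c("N", "CA"), c("CA", "C")),
    ALA = list(),
    SER = list(c("CB", "OG")),
    CYS = list(c("CB", "SG")),
    THR = list(c("CB", "OG1"), c("CB", "CG2")),
    VAL = list(c("CB", "CG1"), c("CB", "CG2")),
    LEU = list(c("CB", "CG"), c("CG", "CD1"), c("CG", "CD2")),
    ILE = list(c("CB", "CG1"), c("CB", "CG2"), c("CG1", "CD1")),
    MET = list(c("CB", "CG"), c("CG", "SD"), c("SD", "CE")),
    PRO = list(c("CB", "CG"), c("CG", "CD"), c("CD", "N")),
    PHE = list(c("CB", "CG"), c("CG", "CD1", "d"), c("CG", "CD2"),
               c("CD1", "CE1"), c("CD2", "CE2", "d"), c("CE1", "CZ", "d"),
               c("CE2", "CZ")),
    TYR = list(c("CB", "CG"), c("CG", "CD1", "d"), c("CG", "CD2"),
               c("CD1", "CE1"), c("CD2", "CE2", "d"), c("CE1", "CZ", "d"),
               c("CE2", "CZ"), c("CZ", "OH")),
    TRP = list(c("CB", "CG"), c("CG", "CD1", "d"), c("CG", "CD2"),
               c("CD1", "NE1"), c("NE1", "CE2"), c("CD2", "CE2", "d"),
               c("CD2", "CE3"), c("CE3", "CZ3", "d"), c("CZ3", "CH2"),
               c("CH2", "CZ2", "d"), c("CZ2", "CE2")),
    ASP = list(c("CB", "CG"), c("CG", "OD1", "d"), c("CG", "OD2")),
    GLU = list(c("CB", "CG"), c("CG", "CD"), c("CD", "OE1", "d"),
               c("CD", "OE2")),
    ASN = list(c("CB", "CG"), c("CG", "OD1", "d"), c("CG", "ND2")),
    GLN = list(c("CB", "CG"), c("CG", "CD"), c("CD", "OE1", "d"),
               c("CD", "NE2")),
    LYS = list(c("CB", "CG"), c("CG", "CD"), c("CD", "CE"), c("CE", "NZ")),
    ARG = list(c("CB", "CG"), c("CG", "CD"), c("CD", "NE"), c("NE", "CZ"),
               c("CZ", "NH1", "d"), c("CZ", "NH2")),
    HIS = list(c("CB", "CG"), c("CG", "ND1"), c("CG", "CD2", "d"),
               c("ND1", "CE1", "d"), c("CE1", "NE2"), c("NE2", "CD2"))
  )
  for (nm in names(t)) {
    extra <- if (nm == "GLY") bbo else c(bb, bbo)
    t[[nm]] <- c(extra, t[[nm]])
  }
  t
}

# heavy atom each standard hydrogen name attaches to
hydrogen_parent <- function(hname) {
  h <- sub("^[0-9]+", "", hname)      # 1HB2 -> HB2
  if (h %in% c("H", "H1", "H2", "H3", "HN")) return("N")
  if (h %in% c("HA", "HA2", "HA3")) return("CA")
  if (h == "HXT") return("OXT")
  core <- sub("^H", "", h)
  core <- sub("[0-9]$", "", core)
  if (core == "") return("N")
  candidates <- paste0(c("C", "O", "N", "S"), core)
  candidates
}

#' Perceive covalent bonds
#'
#' Coordinate-free template perception for standard residues: intra-residue
#' bonds from a bundled amino-acid template table (hydrogens attached to
#' their parent heavy atom by name convention), inter-residue peptide bonds
#' between consecutive `resseq` C -> N within a chain. Residues without a
#' template fall back to a distance rule
#' `d <= r_cov(a) + r_cov(b) + 0.4 A` over bundled covalent radii. Perceived
#' bonds are merged with any bonds already present (e.g. from CONECT).
#'
#' @param molecule A `molecule`.
#' @param tol Fallback distance slack in Angstrom (default 0.4).
#' @return The `molecule` with its covalent bond table filled in.
#' @export
perceive_covalent_bonds <- function(molecule, tol = 0.4) {
  a <- molecule$atoms
  templates <- amino_acid_templates()
  res_key <- paste(a$chain, a$resseq, a$icode, sep = "\r")
  bonds <- list(molecule$bonds)

  for (rk in unique(res_key)) {
    ix <- which(res_key == rk)
    resname <- a$resname[ix[1]]
    if (resname %in% names(templates)) {
      lookup <- ix[!duplicated(a$name[ix])]
      names(lookup) <- a$name[lookup]
      for (tpl in templates[[resname]]) {
        i <- lookup[tpl[1]]; j <- lookup[tpl[2]]
        if (is.na(i) || is.na(j)) next
        ord <- if (length(tpl) == 3L && tpl[3] == "d") "double" else "single"
        bonds[[length(bonds) + 1L]] <-
          data.frame(i = a$serial[i], j = a$serial[j], order = ord,
                     stringsAsFactors = FALSE)
      }
      # hydrogens by name convention
      for (i in ix[a$element[ix] == "H"]) {
        parents <- hydrogen_parent(a$name[i])
        p <- lookup[parents]
        p <- p[!is.na(p)][1]
        if (!is.na(p)) {
          bonds[[length(bonds) + 1L]] <-
            data.frame(i = a$serial[p], j = a$serial[i], order = "single",
                       stringsAsFactors = FALSE)
        }
      }
    } else {
      # non-template residue: all-pairs distance rule within the residue
      bonds[[length(bonds) + 1L]] <- distance_bonds(a[ix, , drop = FALSE], tol)
    }
  }

  # peptide bonds: consecutive residue numbers within a chain, C -> N
  for (ch in unique(a$chain)) {
    prot <- a[a$chain == ch & a$resname %in% names(templates), , drop = FALSE]
    if (nrow(prot) == 0L) next
    rs <- sort(unique(prot$resseq))
    for (r in rs) {
      if (!(r + 1L) %in% rs) next
      ci <- prot$serial[prot$resseq == r & prot$name == "C"][1]
      ni <- prot$serial[prot$resseq == r + 1L & prot$name == "N"][1]
      if (!is.na(ci) && !is.na(ni)) {
        bonds[[length(bonds) + 1L]] <-
          data.frame(i = ci, j = ni, order = "peptide",
                     stringsAsFactors = FALSE)
      }
    }
  }

  merged <- do.call(rbind, bonds)
  if (nrow(merged) > 0L) {
    key <- bond_key(merged$i, merged$j)
    # later (template/peptide) assignments win over raw CONECT "single"
    merged <- merged[!duplicated(key, fromLast = TRUE), , drop = FALSE]
    rownames(merged) <- NULL
  }
  molecule$bonds <- merged
  molecule
}

# brute-force pairwise distance perception for one residue's atoms
distance_bonds <- function(atoms, tol) {
  n <- nrow(atoms)
  if (n < 2L) return(empty_bonds())
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  r <- covalent_radius(atoms$element)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      if (d <= r[i] + r[j] + tol && d > 0.4) {
        out[[length(out) + 1L]] <-
          data.frame(i = atoms$serial[i], j = atoms$serial[j],
                     order = "single", stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty_bonds())
  do.call(rbind, out)
}

# covalent adjacency as a list serial -> integer vector of bonded serials
covalent_adjacency <- function(molecule) {
  adj <- new.env(hash = TRUE, parent = emptyenv())
  for (s in molecule$atoms$serial) assign(as.character(s), integer(0), adj)
  b <- molecule$bonds
  for (k in seq_len(nrow(b))) {
    i <- as.character(b$i[k]); j <- as.character(b$j[k])
    assign(i, c(get(i, adj), b$j[k]), adj)
    assign(j, c(get(j, adj), b$i[k]), adj)
  }
  adj
}

# graph distance (number of covalent bonds) between two atoms, capped
covalent_separation <- function(adj, from, to, max_depth = 4L) {
  if (from == to) return(0L)
  frontier <- from
  seen <- as.character(from)
  for (depth in seq_len(max_depth)) {
    nxt <- unique(unlist(lapply(as.character(frontier),
                                function(s) get(s, adj))))
    nxt <- nxt[!(as.character(nxt) %in% seen)]
    if (to %in% nxt) return(depth)
    if (length(nxt) == 0L) return(Inf)
    seen <- c(seen, as.character(nxt))
    frontier <- nxt
  }
  Inf
}
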