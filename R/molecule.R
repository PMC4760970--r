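#' @title Molecule container
#' @description Internal constructor for the curated structural input: an atom
#'   table plus a covalent bond list. Atom serials are the stable public
#'   identifiers; internal row indices are never exposed.
#' @keywords internal
#' @noRd
new_molecule <- function(atoms, bonds = empty_bonds(), provenance = list()) {
  stopifnot(is.data.frame(atoms))
  required <- c("serial", "name", "element", "alt_loc", "resname",
                "chain", "resseq", "icode", "x", "y", "z", "occupancy",
                "b_factor", "record")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0L) {
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  bad <- !(atoms$element %in% periodic_symbols())
  if (any(bad)) {
    stop("unknown element symbol(s): ",
         paste(unique(atoms$element[bad]), collapse = ", "))
  }
  validate_bonds(bonds, atoms$serial)
  rownames(atoms) <- NULL
  structure(
    list(atoms = atoms, bonds = bonds,
         chains = unique(atoms$chain), provenance = provenance),
    class = "molecule"
  )
}

empty_bonds <- function() {
  data.frame(i = integer(0), j = integer(0), order = character(0),
             stringsAsFactors = FALSE)
}

validate_bonds <- function(bonds, serials) {
  stopifnot(is.data.frame(bonds), all(c("i", "j", "order") %in% names(bonds)))
  if (nrow(bonds) == 0L) return(invisible(TRUE))
  if (any(bonds$i == bonds$j)) stop("covalent bond endpoints must be distinct")
  if (!all(c(bonds$i, bonds$j) %in% serials)) {
    stop("covalent bond references a non-existent atom serial")
  }
  key <- bond_key(bonds$i, bonds$j)
  if (anyDuplicated(key)) stop("duplicate covalent bond")
  ok <- bonds$order %in% c("single", "double", "peptide", "disulfide")
  if (!all(ok)) stop("invalid bond order: ", paste(unique(bonds$order[!ok]), collapse = ", "))
  invisible(TRUE)
}

bond_key <- function(i, j) {
  paste(pmin(i, j), pmax(i, j), sep = "-")
}

#' Periodic-table element symbols recognised in atom records
#' @return Character vector of element symbols.
#' @keywords internal
#' @noRd
periodic_symbols <- function() {
  c("H", "HE", "LI", "BE", "B", "C", "N", "O", "F", "NE",
    "NA", "MG", "AL", "SI", "P", "S", "CL", "AR", "K", "CA",
    "SC", "TI", "V", "CR", "MN", "FE", "CO", "NI", "CU", "ZN",
    "GA", "GE", "AS", "SE", "BR", "KR", "RB", "SR", "Y", "ZR",
    "MO", "RU", "PD", "AG", "CD", "I", "XE", "CS", "BA", "W",
    "PT", "AU", "HG", "PB", "U")
}

# Covalent radii (Angstrom, Cordero-style consensus values) for the
# distance-based bond perception fallback.
covalent_radius <- function(element) {
  r <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, S = 1.05, P = 1.07,
         F = 0.57, CL = 1.02, BR = 1.20, I = 1.39, SE = 1.20,
         FE = 1.32, ZN = 1.22, MG = 1.41, CA = 1.76, "NA" = 1.66,
         K = 2.03, MN = 1.39, CU = 1.32)
  out <- unname(r[toupper(element)])
  out[is.na(out)] <- 1.5  # generous default for exotic elements
  out
}

# van der Waals radii (Angstrom, Bondi) used for hydrophobic contacts.
vdw_radius <- function(element) {
  r <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
         F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90)
  out <- unname(r[toupper(element)])
  out[is.na(out)] <- 1.8
  out
}

atom_coords <- function(molecule, serials = NULL) {
  a <- molecule$atoms
  if (!is.null(serials)) a <- a[match(serials, a$serial), , drop = FALSE]
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$serial
  m
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %d atoms, %d covalent bonds, chains: %s\n",
              nrow(x$atoms), nrow(x$bonds),
              paste(x$chains, collapse = ", ")))
  if (!is.null(x$provenance$source)) {
    cat("  source:", x$provenance$source, "\n")
  }
  invisible(x)
}

#' Serialize a molecule to a canonical text form
#'
#' Byte-stable serialization used by the curation replay contract and the
#' fixture determinism tests: fixed column order, fixed numeric formatting
#' (coordinates to 3 decimals, occupancy/B to 2), atoms in table order.
#'
#' @param molecule A `molecule` object.
#' @return A single character string.
#' @export
serialize_molecule <- function(molecule) {
  a <- molecule$atoms
  atom_lines <- sprintf(
    "%d\t%s\t%s\t%s\t%s\t%s\t%d\t%s\t%.3f\t%.3f\t%.3f\t%.2f\t%.2f\t%s",
    a$serial, a$name, a$element, a$alt_loc, a$resname, a$chain,
    a$resseq, a$icode, a$x, a$y, a$z, a$occupancy, a$b_factor, a$record)
  b <- molecule$bonds
  if (nrow(b) > 0L) {
    o <- order(pmin(b$i, b$j), pmax(b$i, b$j))
    b <- b[o, , drop = FALSE]
  }
  bond_lines <- sprintf("%d\t%d\t%s", pmin(b$i, b$j), pmax(b$i, b$j), b$order)
  paste(c("#atoms", atom_lines, "#bonds", bond_lines), collapse = "\n")
}

# residue identifier "chain:resseq" used across the apps module
residue_uid <- function(chain, resseq) paste(chain, resseq, sep = ":")
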