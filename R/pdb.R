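#' Parse PDB-format text into a molecule
#'
#' Reads ATOM/HETATM records (via the standard \pkg{bio3d} reader), resolves
#' MODEL blocks to the requested model and scans CONECT records from the raw
#' text. Alternate-location indicators are retained as deposited; they are
#' resolved later by [curate()].
#'
#' @param text Character scalar or vector of PDB-format lines.
#' @param model_index 1-based model to extract from multi-model files.
#' @return A `molecule` object (atoms in file order, CONECT bonds if present).
#' @export
parse_pdb <- function(text, model_index = 1L) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  has_coords <- any(grepl("^(ATOM  |HETATM)", lines))
  if (!has_coords) {
    stop("parse error: no ATOM or HETATM coordinate records found")
  }
  n_models <- sum(grepl("^MODEL", lines))
  if (n_models > 0L && model_index > n_models) {
    stop("requested model ", model_index, " absent; available models: 1..",
         n_models)
  }
  if (model_index < 1L) stop("model_index must be >= 1")
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, multi = n_models > 1L, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  xyz <- if (n_models > 1L) {
    matrix(pdb$xyz[model_index, ], ncol = 3, byrow = TRUE)
  } else {
    as.matrix(at[, c("x", "y", "z")])
  }
  elem <- toupper(trimws(at$elesy))
  # infer element from the atom name when the element column is blank
  blank <- is.na(elem) | elem == ""
  if (any(blank)) {
    guess <- toupper(sub("^[0-9]*", "", trimws(at$elety[blank])))
    two <- substr(guess, 1, 2)
    one <- substr(guess, 1, 1)
    elem[blank] <- ifelse(two %in% periodic_symbols() &
                            !one %in% c("C", "N", "O", "H", "P", "S"),
                          two, one)
  }
  atoms <- data.frame(
    serial = at$eleno,
    name = trimws(at$elety),
    element = elem,
    alt_loc = ifelse(is.na(at$alt) | at$alt == "", "", at$alt),
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain), "", at$chain),
    resseq = at$resno,
    icode = ifelse(is.na(at$insert) | at$insert == "", "", at$insert),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b_factor = ifelse(is.na(at$b), 0, at$b),
    record = at$type,
    stringsAsFactors = FALSE
  )
  bonds <- parse_conect(lines, atoms$serial)
  new_molecule(atoms, bonds,
               provenance = list(source = "pdb", model_index = model_index,
                                 n_models = max(1L, n_models)))
}

# CONECT records -> unique covalent bonds (order "single"; refined later by
# template perception, with which they are merged).
parse_conect <- function(lines, serials) {
  con <- lines[grepl("^CONECT", lines)]
  if (length(con) == 0L) return(empty_bonds())
  pairs <- list()
  for (ln in con) {
    flds <- suppressWarnings(as.integer(
      substring(ln, seq(7, 27, by = 5), seq(11, 31, by = 5))))
    flds <- flds[!is.na(flds)]
    if (length(flds) < 2L) next
    from <- flds[1]
    for (to in flds[-1]) {
      if (from %in% serials && to %in% serials && from != to) {
        pairs[[length(pairs) + 1L]] <- c(min(from, to), max(from, to))
      }
    }
  }
  if (length(pairs) == 0L) return(empty_bonds())
  m <- unique(do.call(rbind, pairs))
  data.frame(i = m[, 1], j = m[, 2], order = "single", stringsAsFactors = FALSE)
}

#' Curation configuration
#'
#' @param chains Chains to keep (character vector; empty = keep all).
#' @param prune_water Remove water residues (HOH/WAT/DOD)?
#' @param prune_ligands Remove non-water HETATM groups?
#' @param keep_nucleic Keep nucleic-acid chains? (When `FALSE`, standard
#'   nucleotide residues are removed.)
#' @param model_index Model used when parsing multi-model files (recorded).
#' @param hbond_energy_cutoff Hydrogen-bond energy cutoff in kcal/mol carried
#'   into downstream interaction pruning.
#' @return A `curation_config` list.
#' @export
curation_config <- function(chains = character(0), prune_water = TRUE,
                            prune_ligands = FALSE, keep_nucleic = TRUE,
                            model_index = 1L, hbond_energy_cutoff = -1.0) {
  if (!is.null(model_index) && model_index < 1L) {
    stop("model_index must be >= 1")
  }
  structure(list(chains = as.character(chains), prune_water = prune_water,
                 prune_ligands = prune_ligands, keep_nucleic = keep_nucleic,
                 model_index = as.integer(model_index),
                 hbond_energy_cutoff = hbond_energy_cutoff),
            class = "curation_config")
}

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")
NUCLEIC_RESNAMES <- c("A", "C", "G", "U", "T", "DA", "DC", "DG", "DT", "DU")

#' Curate a molecule reproducibly
#'
#' Applies chain selection, water/ligand pruning and alternate-location
#' resolution (highest occupancy wins, ties broken alphabetically), recording
#' every action in an ordered log. Replaying the log on the same input with
#' [replay_curation()] reproduces a byte-identical molecule serialization.
#'
#' @param molecule A `molecule`.
#' @param config A [curation_config()].
#' @return A list with elements `molecule` (curated) and `log`
#'   (a `curation_log`).
#' @export
curate <- function(molecule, config = curation_config()) {
  stopifnot(inherits(molecule, "molecule"))
  if (length(config$chains) > 0L) {
    missing <- setdiff(config$chains, molecule$chains)
    if (length(missing) > 0L) {
      stop("chain(s) not present in molecule: ",
           paste(missing, collapse = ", "))
    }
  }
  log <- list()
  seqno <- 0L
  note <- function(action, params) {
    seqno <<- seqno + 1L
    log[[seqno]] <<- list(seq = seqno, action = action, params = params)
  }
  a <- molecule$atoms

  if (length(config$chains) > 0L) {
    keep <- a$chain %in% config$chains
    note("keep_chains", list(chains = config$chains,
                             removed = sum(!keep)))
    a <- a[keep, , drop = FALSE]
  }
  if (isTRUE(config$prune_water)) {
    drop <- a$resname %in% WATER_RESNAMES
    note("prune_water", list(removed = sum(drop)))
    a <- a[!drop, , drop = FALSE]
  }
  if (isTRUE(config$prune_ligands)) {
    drop <- a$record == "HETATM" & !(a$resname %in% WATER_RESNAMES)
    note("prune_ligands", list(removed = sum(drop)))
    a <- a[!drop, , drop = FALSE]
  }
  if (!isTRUE(config$keep_nucleic)) {
    drop <- a$resname %in% NUCLEIC_RESNAMES
    note("prune_nucleic", list(removed = sum(drop)))
    a <- a[!drop, , drop = FALSE]
  }
  # alt_loc resolution: within each (chain, resseq, icode, atom name) group
  # keep the record with highest occupancy; ties -> alphabetically first
  # alt_loc indicator (blank sorts first).
  if (any(a$alt_loc != "")) {
    grp <- paste(a$chain, a$resseq, a$icode, a$name, sep = "\r")
    keep_idx <- unlist(lapply(split(seq_len(nrow(a)), grp), function(ix) {
      if (length(ix) == 1L) return(ix)
      occ <- a$occupancy[ix]
      best <- ix[occ == max(occ)]
      best[order(a$alt_loc[best])][1L]
    }), use.names = FALSE)
    removed <- nrow(a) - length(keep_idx)
    note("resolve_alt_loc", list(policy = "highest_occupancy_then_alpha",
                                 removed = removed))
    a <- a[sort(keep_idx), , drop = FALSE]
    a$alt_loc <- ""
  }
  if (nrow(a) == 0L) stop("curation removed all atoms (empty molecule)")

  keep_serials <- a$serial
  b <- molecule$bonds
  b <- b[b$i %in% keep_serials & b$j %in% keep_serials, , drop = FALSE]
  out <- new_molecule(a, b,
                      provenance = c(molecule$provenance,
                                     list(curated = TRUE)))
  log_obj <- structure(list(actions = log, config = config),
                       class = "curation_log")
  list(molecule = out, log = log_obj)
}

#' Replay a curation log
#'
#' Re-applies the configuration recorded in a curation log to an uncurated
#' molecule; the result is byte-identical (via [serialize_molecule()]) to the
#' molecule originally produced with it.
#'
#' @param molecule The original (uncurated) `molecule`.
#' @param log A `curation_log` from [curate()].
#' @return The curated `molecule`.
#' @export
replay_curation <- function(molecule, log) {
  stopifnot(inherits(log, "curation_log"))
  curate(molecule, log$config)$molecule
}

#' Write / read a curation log as JSON
#' @param log A `curation_log`.
#' @param path File path.
#' @return `read_curation_log` returns a `curation_log`.
#' @export
write_curation_log <- function(log, path) {
  stopifnot(inherits(log, "curation_log"))
  jsonlite::write_json(
    list(schema = "rigidmol/curation-log/1",
         config = unclass(log$config),
         actions = lapply(log$actions, function(x) x)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_curation_log
#' @export
read_curation_log <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = FALSE)
  cfg <- j$config
  config <- curation_config(
    chains = unlist(cfg$chains) %||% character(0),
    prune_water = isTRUE(cfg$prune_water),
    prune_ligands = isTRUE(cfg$prune_ligands),
    keep_nucleic = isTRUE(cfg$keep_nucleic),
    model_index = cfg$model_index %||% 1L,
    hbond_energy_cutoff = cfg$hbond_energy_cutoff %||% -1.0)
  structure(list(actions = j$actions, config = config),
            class = "curation_log")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect chain gaps
#'
#' A gap is a pair of consecutive observed residues in a chain whose residue
#' numbers differ by more than 1 (insertion codes are treated as continuity).
#'
#' @param molecule A `molecule`.
#' @return Data frame with columns `chain` and `resseq_before_gap`.
#' @export
detect_gaps <- function(molecule) {
  a <- molecule$atoms[molecule$atoms$record == "ATOM", , drop = FALSE]
  out <- data.frame(chain = character(0), resseq_before_gap = integer(0),
                    stringsAsFactors = FALSE)
  for (ch in unique(a$chain)) {
    rs <- sort(unique(a$resseq[a$chain == ch]))
    if (length(rs) < 2L) next
    d <- diff(rs)
    at <- which(d > 1L)
    if (length(at) > 0L) {
      out <- rbind(out, data.frame(chain = ch, resseq_before_gap = rs[at],
                                   stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}
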