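#' @importFrom methods as is
NULL

# Batch-convert SMILES to a ChemmineR SDFset, with per-molecule validation.
# OpenBabel silently drops unparseable records, so counts are checked and the
# offending ids reported.
smiles_to_sdfset <- function(smiles, ids = names(smiles)) {
  stopifnot(length(smiles) >= 1L)
  if (is.null(ids)) ids <- sprintf("M%04d", seq_along(smiles))
  if (anyDuplicated(ids)) stop("duplicate molecule ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  smi <- as.character(smiles)
  names(smi) <- ids
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smi)),
    error = function(e) stop("SMILES parsing failed: ", conditionMessage(e))
  )
  got <- ChemmineR::sdfid(sdf)
  if (length(sdf) != length(smi) || !all(ids %in% got)) {
    bad <- setdiff(ids, got)
    stop("unparseable SMILES for id(s): ", paste(bad, collapse = ", "))
  }
  sdf[match(ids, got)]
}

#' Canonicalize SMILES strings
#'
#' Round-trips SMILES through OpenBabel canonicalization so that identical
#' structures written differently collapse to one string (fingerprints and
#' duplicate detection are then deterministic).
#'
#' @param smiles Character vector of SMILES.
#' @return Character vector of canonical SMILES, same length and names.
#' @export
canonical_smiles <- function(smiles) {
  if (!length(smiles)) return(character())
  ids <- sprintf("S%06d", seq_along(smiles))
  txt <- paste0(paste(smiles, ids, sep = "\t"), collapse = "\n")
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(txt, "\n"))
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  can <- vapply(parts, `[`, character(1), 1L)
  got <- trimws(vapply(parts, function(p) if (length(p) >= 2) p[2] else NA_character_, character(1)))
  if (length(can) != length(smiles) || !all(ids %in% got)) {
    bad <- which(!(ids %in% got))
    stop("unparseable SMILES at position(s): ", paste(bad, collapse = ", "))
  }
  res <- can[match(ids, got)]
  names(res) <- names(smiles)
  res
}

# Net formal charge from a (canonical) SMILES string: sum of the charge
# tokens of bracket atoms, e.g. [O-], [NH3+], [Fe+2]. Atoms outside brackets
# are neutral by the SMILES grammar.
smiles_net_charge <- function(smiles) {
  vapply(smiles, function(s) {
    br <- regmatches(s, gregexpr("\\[[^][]*\\]", s))[[1]]
    if (!length(br)) return(0L)
    total <- 0L
    for (b in br) {
      chg <- regmatches(b, gregexpr("[+-][0-9]*", b))[[1]]
      for (tok in chg) {
        sign <- if (substr(tok, 1, 1) == "+") 1L else -1L
        mag <- if (nchar(tok) > 1L) as.integer(substr(tok, 2, nchar(tok))) else 1L
        total <- total + sign * mag
      }
    }
    total
  }, integer(1), USE.NAMES = FALSE)
}

# SMARTS for single, acyclic, non-terminal, non-triple-bond-adjacent bonds:
# the conventional rotatable-bond count.
ROTATABLE_SMARTS <- "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]"

#' Build a molecule table from SMILES
#'
#' The molecule table is the package's central 2D-chemistry container: one row
#' per molecule with canonical SMILES, computed physicochemical properties
#' (MW, clogP via the toolkit's atom-contribution estimator, donor/acceptor
#' counts, rotatable bonds, net formal charge), optional activity (pChEMBL)
#' and docking energy, and a 1024-bit ECFP4 fingerprint stored as a
#' list-column of [chem_fp] objects.
#'
#' @param smiles Character vector of SMILES.
#' @param id Molecule identifiers; defaults to `names(smiles)` or `M0001`...
#' @param pchembl Optional numeric vector of pChEMBL values (-log10 molar
#'   activity), recycled NA when absent.
#' @param energy Optional numeric vector of docking energies (kcal/mol, lower
#'   is better).
#' @param nbits Fingerprint length (default 1024).
#' @return A `data.frame` of class `molecule_table` with columns `id`,
#'   `smiles`, `mw`, `clogp`, `hbd`, `hba`, `rotatable_bonds`, `net_charge`,
#'   `pchembl`, `energy` and list-column `fp`.
#' @export
molecule_table <- function(smiles, id = NULL, pchembl = NULL, energy = NULL,
                           nbits = 1024L) {
  if (is.null(id)) id <- names(smiles)
  if (is.null(id)) id <- sprintf("M%04d", seq_along(smiles))
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate molecule ids")
  can <- canonical_smiles(as.character(smiles))
  names(can) <- id
  sdf <- smiles_to_sdfset(can, id)
  props <- ChemmineR::propOB(sdf)
  rot <- ChemmineR::smartsSearchOB(sdf, ROTATABLE_SMARTS, uniqueMatches = TRUE)
  fps <- ecfp4(stats::setNames(unname(can), id), nbits = nbits)
  out <- data.frame(
    id = id,
    smiles = unname(can),
    mw = props$MW,
    clogp = props$logP,
    hbd = props$HBD,
    hba = props$HBA1,
    rotatable_bonds = as.integer(unname(rot)),
    net_charge = smiles_net_charge(unname(can)),
    pchembl = if (is.null(pchembl)) NA_real_ else as.numeric(pchembl),
    energy = if (is.null(energy)) NA_real_ else as.numeric(energy),
    stringsAsFactors = FALSE
  )
  out$fp <- fps
  class(out) <- c("molecule_table", "data.frame")
  out
}

#' @export
print.molecule_table <- function(x, ...) {
  cat(sprintf("<molecule_table: %d molecules, %d-bit ECFP4>\n",
              nrow(x), if (nrow(x)) attr(x$fp[[1]], "nbits") else NA_integer_))
  print.data.frame(utils::head(x[, setdiff(names(x), "fp")], 10), ...)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

# Subsetting keeps the class and the fp list-column intact.
#' @export
`[.molecule_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && "fp" %in% names(out)) class(out) <- c("molecule_table", "data.frame")
  out
}

#' Collapse duplicate structures in a molecule table
#'
#' Molecules with identical canonical SMILES are merged to one row. `keep`
#' selects which duplicate survives: the lowest docking energy or the highest
#' pChEMBL.
#'
#' @param mols A [molecule_table].
#' @param keep One of `"lowest_energy"`, `"highest_pchembl"`, `"first"`.
#' @return Deduplicated `molecule_table`; the number of rows removed is
#'   attached as attribute `n_duplicates`.
#' @export
dedupe_molecules <- function(mols, keep = c("lowest_energy", "highest_pchembl", "first")) {
  keep <- match.arg(keep)
  ord <- switch(keep,
    lowest_energy   = order(mols$smiles, mols$energy, mols$id),
    highest_pchembl = order(mols$smiles, -xtfrm(mols$pchembl), mols$id),
    first           = order(mols$smiles, seq_len(nrow(mols)))
  )
  sorted <- mols[ord, ]
  kept <- sorted[!duplicated(sorted$smiles), ]
  kept <- kept[order(match(kept$id, mols$id)), ]
  attr(kept, "n_duplicates") <- nrow(mols) - nrow(kept)
  kept
}

#' Read molecules from a .smi file
#'
#' Expects the conventional "SMILES<whitespace>id" layout, one molecule per
#' line; lines without an id get sequential ones.
#'
#' @param path Path to a .smi file.
#' @param ... Passed to [molecule_table()].
#' @return A [molecule_table].
#' @export
read_smi <- function(path, ...) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "[ \t]+")
  smi <- vapply(parts, `[`, character(1), 1L)
  ids <- vapply(seq_along(parts), function(i) {
    if (length(parts[[i]]) >= 2) parts[[i]][2] else sprintf("M%04d", i)
  }, character(1))
  molecule_table(smi, id = ids, ...)
}

#' Write molecules to a .smi file
#'
#' @param mols A [molecule_table].
#' @param path Output path.
#' @export
write_smi <- function(mols, path) {
  writeLines(paste(mols$smiles, mols$id, sep = "\t"), path)
  invisible(path)
}

#' Read molecules from an SDF file
#'
#' @param path Path to an SDF file; molecule ids are taken from the title
#'   lines.
#' @param ... Passed to [molecule_table()].
#' @return A [molecule_table].
#' @export
read_sdf_molecules <- function(path, ...) {
  sdf <- ChemmineR::read.SDFset(path)
  ChemmineR::cid(sdf) <- ChemmineR::sdfid(sdf)
  smi <- as.character(ChemmineR::sdf2smiles(sdf))
  molecule_table(smi, id = ChemmineR::sdfid(sdf), ...)
}

#' Write molecules to an SDF file
#'
#' @param mols A [molecule_table].
#' @param path Output path.
#' @export
write_sdf_molecules <- function(mols, path) {
  sdf <- smiles_to_sdfset(stats::setNames(mols$smiles, mols$id), mols$id)
  ChemmineR::write.SDF(sdf, path, cid = TRUE)
  invisible(path)
}

#' Attach a property table to molecules
#'
#' Merges an external property CSV (keyed by `id`) onto a molecule table,
#' overwriting any overlapping columns; used to supply vendor-computed
#' properties, docking energies or pChEMBL values.
#'
#' @param mols A [molecule_table].
#' @param properties A data.frame with an `id` column, or a path to a CSV.
#' @return The merged `molecule_table`.
#' @export
attach_properties <- function(mols, properties) {
  if (is.character(properties)) properties <- utils::read.csv(properties, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(properties))
  idx <- match(mols$id, properties$id)
  for (col in setdiff(names(properties), "id")) {
    vals <- properties[[col]][idx]
    hit <- !is.na(idx)
    if (col %in% names(mols)) {
      mols[[col]][hit] <- vals[hit]
    } else {
      mols[[col]] <- vals
    }
  }
  mols
}
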