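#' Construct a bit-set fingerprint
#'
#' A fingerprint is stored sparsely as the sorted positions (1-based) of its
#' on bits, with the total bit length kept as an attribute. This is the
#' representation used by all Tanimoto arithmetic in the package.
#'
#' @param bits Integer vector of on-bit positions (1-based, within `nbits`).
#' @param nbits Total fingerprint length in bits (default 1024).
#' @return An object of class `chem_fp`.
#' @export
chem_fp <- function(bits, nbits = 1024L) {
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) && (min(bits) < 1L || max(bits) > nbits)) {
    stop("fingerprint bit positions must lie in [1, nbits]")
  }
  structure(bits, nbits = as.integer(nbits), class = "chem_fp")
}

#' @export
print.chem_fp <- function(x, ...) {
  cat(sprintf("<chem_fp: %d/%d bits set>\n", length(x), attr(x, "nbits")))
  invisible(x)
}

#' Tanimoto coefficient between two fingerprints
#'
#' Computes |A intersect B| / |A union B| over the on-bit sets. By the field's
#' convention the similarity of two empty fingerprints is 0.
#'
#' @param a,b `chem_fp` fingerprints of equal bit length.
#' @return Similarity in \[0, 1\].
#' @export
tanimoto <- function(a, b) {
  if (!identical(attr(a, "nbits"), attr(b, "nbits"))) {
    stop("fingerprint lengths differ: ", attr(a, "nbits"), " vs ", attr(b, "nbits"))
  }
  n_int <- length(intersect(unclass(a), unclass(b)))
  n_uni <- length(a) + length(b) - n_int
  if (n_uni == 0L) return(0)
  n_int / n_uni
}

#' Pairwise Tanimoto matrix between two fingerprint lists
#'
#' @param fps_a,fps_b Lists of `chem_fp` objects.
#' @return Numeric matrix of dim `length(fps_a)` x `length(fps_b)`.
#' @export
tanimoto_matrix <- function(fps_a, fps_b = fps_a) {
  out <- matrix(0, nrow = length(fps_a), ncol = length(fps_b))
  for (i in seq_along(fps_a)) {
    for (j in seq_along(fps_b)) {
      out[i, j] <- tanimoto(fps_a[[i]], fps_b[[j]])
    }
  }
  rownames(out) <- names(fps_a)
  colnames(out) <- names(fps_b)
  out
}

#' ECFP4 fingerprints from SMILES
#'
#' Extended-connectivity fingerprints of radius 2 (diameter 4), hashed to
#' `nbits` bits. The OpenBabel ECFP4 implementation emits 4096-bit
#' fingerprints; these are folded to the requested length by OR-ing bit `i`
#' onto `i mod nbits`, the standard folding scheme.
#'
#' @param smiles Character vector of SMILES strings.
#' @param nbits Folded fingerprint length (default 1024).
#' @param backend `"auto"` (default: the `obabel` executable when on the
#'   PATH, library binding otherwise), `"obabel"`, or `"library"`. Both
#'   backends produce identical bit sets; the executable is much faster on
#'   large batches.
#' @return A list of `chem_fp`, named after `names(smiles)` when present.
#' @export
ecfp4 <- function(smiles, nbits = 1024L, backend = c("auto", "obabel", "library")) {
  backend <- match.arg(backend)
  if (!length(smiles)) return(list())
  ids <- names(smiles)
  if (is.null(ids)) ids <- sprintf("M%04d", seq_along(smiles))
  use_cli <- switch(backend,
                    auto = nzchar(Sys.which("obabel")),
                    obabel = TRUE, library = FALSE)
  raw <- if (use_cli) ecfp4_bits_obabel(smiles, ids) else ecfp4_bits_library(smiles, ids)
  out <- lapply(raw, function(on) chem_fp(((on - 1L) %% nbits) + 1L, nbits = nbits))
  names(out) <- ids
  out
}

# 4096-bit ECFP4 on-bit positions via the ChemmineOB library binding.
ecfp4_bits_library <- function(smiles, ids) {
  sdf <- smiles_to_sdfset(smiles, ids)
  m <- ChemmineR::fingerprintOB(sdf, "ECFP4")@fpma
  lapply(seq_len(nrow(m)), function(i) which(m[i, ] != 0))
}

# Same bit sets via one batched call of the obabel executable (fpt output,
# hex). OpenBabel prints the 128 32-bit words highest-word first; bit b of
# word w (counting from the least-significant bit) is fingerprint position
# (128 - w) * 32 + b + 1, matching the library binding's bit order.
ecfp4_bits_obabel <- function(smiles, ids) {
  smi_file <- tempfile(fileext = ".smi")
  on.exit(unlink(smi_file))
  writeLines(paste(smiles, ids, sep = "\t"), smi_file)
  out <- system2("obabel", c(smi_file, "-ofpt", "-xfECFP4", "-xh"),
                 stdout = TRUE, stderr = FALSE)
  headers <- grep("^>", out)
  if (length(headers) != length(smiles)) {
    stop("obabel fingerprinting dropped ", length(smiles) - length(headers),
         " molecule(s)")
  }
  got <- sub("^>([^ \t]+).*$", "\\1", out[headers])
  if (!identical(got, ids)) stop("obabel fingerprint ids out of order")
  ends <- c(headers[-1] - 1L, length(out))
  lapply(seq_along(headers), function(k) {
    block <- if (ends[k] > headers[k]) out[(headers[k] + 1L):ends[k]] else character(0)
    words <- unlist(strsplit(paste(block, collapse = " "), "[ \t]+"))
    # keep only the 32-bit hex words; fpt also prints similarity annotations
    words <- words[grepl("^[0-9a-fA-F]{8}$", words)]
    vals <- as.numeric(paste0("0x", words))
    nw <- length(words)
    bits <- integer(0)
    for (w in which(vals > 0)) {
      b <- which(floor(vals[w] / 2^(0:31)) %% 2 == 1) - 1L
      bits <- c(bits, (nw - w) * 32L + b + 1L)
    }
    sort(bits)
  })
}
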