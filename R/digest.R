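# In-silico tryptic digestion and peptide-to-protein sequence coverage.

#' Tryptic digest of a protein sequence
#'
#' Cleaves C-terminal to K and R except when the next residue is P (the
#' conventional trypsin rule) and enumerates all peptides with up to
#' `missed_max` missed cleavages.
#'
#' @param sequence Protein sequence.
#' @param missed_max Maximum number of missed cleavages (>= 0).
#' @return Data frame of class `digest_result` with columns `sequence`,
#'   `start`, `end`, `missed` (1-based inclusive coordinates). The
#'   zero-missed peptides tile the protein exactly.
#' @examples
#' tryptic_digest("AKRPGKT")
#' @export
tryptic_digest <- function(sequence, missed_max = 0L) {
  letters <- validate_sequence(sequence)
  missed_max <- as.integer(missed_max)
  stopifnot(missed_max >= 0L)
  n <- length(letters)
  cut_after <- which(letters %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n & letters[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)            # fragment i spans (bounds[i], bounds[i+1]]
  nf <- length(bounds) - 1L
  rows <- list()
  for (i in seq_len(nf)) {
    for (m in 0:min(missed_max, nf - i)) {
      s <- bounds[i] + 1L
      e <- bounds[i + 1L + m]
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = paste(letters[s:e], collapse = ""),
        start = s, end = e, missed = m, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("digest_result", "data.frame")
  out
}

#' Map peptides onto a protein to build a coverage mask
#'
#' Marks every residue belonging to any exact substring occurrence of any
#' peptide (case-insensitive, I and L not equated); overlaps count once.
#' Peptides with no occurrence are reported in the `unmatched` field.
#'
#' @param protein Protein sequence.
#' @param peptides Character vector of peptide sequences (may be empty).
#' @return Object of class `coverage_mask`: list with `protein_length`,
#'   `covered` (logical vector), `unmatched` (character vector).
#' @export
map_peptides <- function(protein, peptides) {
  validate_sequence(protein)
  protein <- toupper(protein)
  n <- nchar(protein)
  covered <- logical(n)
  unmatched <- character(0)
  for (pep in peptides) {
    pep <- toupper(pep)
    hits <- gregexpr(pep, protein, fixed = TRUE)[[1]]
    if (hits[1] == -1L) {
      unmatched <- c(unmatched, pep)
      next
    }
    for (h in hits) covered[h:(h + nchar(pep) - 1L)] <- TRUE
  }
  structure(list(protein_length = n, covered = covered,
                 unmatched = unmatched),
            class = "coverage_mask")
}

#' Build a coverage mask directly from a logical vector
#'
#' @param covered Logical vector, one element per residue.
#' @return A `coverage_mask`.
#' @export
coverage_mask <- function(covered) {
  stopifnot(is.logical(covered), length(covered) > 0L, !anyNA(covered))
  structure(list(protein_length = length(covered), covered = covered,
                 unmatched = character(0)),
            class = "coverage_mask")
}

#' Sequence coverage of a mask
#'
#' Reports coverage both as an exact percentage and as the nearest integer
#' (round half up). Note that rounding conventions differ between software;
#' both values are returned so either can be compared.
#'
#' @param mask A `coverage_mask`.
#' @return List with `percent` (float), `percent_int` (integer, half-up),
#'   `n_covered`, `n_total`.
#' @examples
#' coverage_percent(coverage_mask(rep(c(TRUE, FALSE), c(441, 76))))
#' @export
coverage_percent <- function(mask) {
  stopifnot(inherits(mask, "coverage_mask"))
  if (mask$protein_length <= 0L) stop("protein length must be positive")
  pct <- 100 * sum(mask$covered) / mask$protein_length
  list(percent = pct, percent_int = as.integer(floor(pct + 0.5)),
       n_covered = sum(mask$covered), n_total = mask$protein_length)
}
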