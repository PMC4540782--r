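# Residue and constant mass tables. Values are the standard ExPASy/Unimod
# amino-acid residue masses; everything downstream sums these, so they are
# stored to the full published precision.

.RESIDUE_MONO <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

.RESIDUE_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167,
  V = 99.1326, T = 101.1051, C = 103.1388, L = 113.1594,
  I = 113.1594, N = 114.1038, D = 115.0886, Q = 128.1307,
  K = 128.1741, E = 129.1155, M = 131.1926, H = 137.1411,
  F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132
)

.MASS_CONST <- list(
  water_mono    = 18.0105646863,
  water_avg     = 18.01528,
  hydrogen_mono = 1.0078250319,
  hydrogen_avg  = 1.00794,
  # mass of a proton; the electron mass is neglected throughout, consistent
  # with conventional [M + zH]z+ bookkeeping for QTOF data
  proton        = 1.00727646688
)

.STANDARD_RESIDUES <- names(.RESIDUE_MONO)

#' Residue mass table
#'
#' The built-in amino-acid residue masses used by all mass arithmetic in the
#' package.
#'
#' @param scale `"mono"` (monoisotopic) or `"avg"` (average).
#' @return Named numeric vector of residue masses in Da, one entry per
#'   standard one-letter amino-acid code.
#' @examples
#' residue_masses("mono")[["G"]]
#' @export
residue_masses <- function(scale = c("mono", "avg")) {
  scale <- match.arg(scale)
  if (scale == "mono") .RESIDUE_MONO else .RESIDUE_AVG
}

#' Mass constants
#'
#' Water and hydrogen masses on both scales, plus the proton mass used for
#' protonation arithmetic.
#'
#' @return Named list of masses in Da.
#' @export
mass_constants <- function() .MASS_CONST

#' Export the residue mass table as TSV
#'
#' Writes the built-in residue masses (both scales) to a tab-separated file
#' for external audit.
#'
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_residue_table <- function(path) {
  df <- data.frame(
    residue = .STANDARD_RESIDUES,
    mono = unname(.RESIDUE_MONO),
    avg = unname(.RESIDUE_AVG),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Define a covalent modification
#'
#' A mass delta applied to a proteoform, e.g. phosphorylation or oxidation.
#'
#' @param name Label for the modification.
#' @param delta_mono Mass delta in Da, monoisotopic scale.
#' @param delta_avg Mass delta in Da, average scale.
#' @param targets Optional character vector of residue letters or the terminus
#'   flags `"N-term"`/`"C-term"` the modification can sit on (annotation only;
#'   mass arithmetic does not localize).
#' @param max_count Maximum number of copies allowed on one proteoform.
#' @return An object of class `modification`.
#' @export
modification <- function(name, delta_mono, delta_avg, targets = NULL,
                         max_count = 1L) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(delta_mono) || !is.finite(delta_avg))
    stop("modification deltas must be finite")
  max_count <- as.integer(max_count)
  if (is.na(max_count) || max_count < 0L)
    stop("max_count must be a non-negative integer")
  structure(
    list(name = name, delta_mono = delta_mono, delta_avg = delta_avg,
         targets = targets, max_count = max_count),
    class = "modification"
  )
}

#' Built-in modification table
#'
#' Modifications relevant to intact-mass reconciliation of plant polyphenol
#' oxidases. `x80` is the +80.0 Da species observed on the intact protein,
#' which cannot be distinguished between a phosphorylation and a sulfation at
#' intact-mass resolution; it is carried as exactly +80.00 Da on both scales.
#' `phospho` and `sulfo` carry the true elemental deltas for peptide-level
#' work, `oxidation` the ~16 Da satellite shifts, and `carbamidomethyl` the
#' standard cysteine alkylation of tryptic workflows.
#'
#' @return Named list of [modification] objects.
#' @export
builtin_modifications <- function() {
  list(
    phospho = modification("phospho", 79.966331, 79.9799,
                           targets = c("S", "T", "Y")),
    sulfo = modification("sulfo", 79.956815, 80.0632, targets = "Y"),
    x80 = modification("x80", 80.0, 80.0, targets = "Y"),
    oxidation = modification("oxidation", 15.994915, 15.9994, max_count = 10L),
    carbamidomethyl = modification("carbamidomethyl", 57.021464, 57.0513,
                                   targets = "C")
  )
}

#' Crosslink mass delta
#'
#' Both disulfide (Cys-Cys) and thioether (Cys-His) bridges cost two hydrogen
#' atoms on formation; disulfides are opened by reductant (DTT), the thioether
#' is not.
#'
#' @param kind `"disulfide"` or `"thioether"`.
#' @param scale `"mono"` or `"avg"`.
#' @return Mass delta per link in Da (negative).
#' @export
crosslink_delta <- function(kind = c("disulfide", "thioether"),
                            scale = c("mono", "avg")) {
  kind <- match.arg(kind)
  scale <- match.arg(scale)
  h <- if (scale == "mono") .MASS_CONST$hydrogen_mono else .MASS_CONST$hydrogen_avg
  -2 * h
}

#' Is a crosslink kind opened by reductant?
#'
#' @param kind `"disulfide"` or `"thioether"`.
#' @return Logical.
#' @export
crosslink_reducible <- function(kind = c("disulfide", "thioether")) {
  match.arg(kind) == "disulfide"
}
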