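# Exact mass arithmetic for chains and proteoforms. A proteoform is one or
# more independently hydrolyzed backbones (each contributing one water) held
# together by declared crosslinks, plus counted modifications.

#' Define a peptide/protein chain
#'
#' A chain is an independently hydrolyzed backbone with 1-based inclusive
#' coordinates on the mature protein (numbering starts at the mature
#' N-terminus; any transit peptide is removed before coordinates are set).
#'
#' @param sequence Residue string (standard one-letter codes).
#' @param id Optional label.
#' @param start 1-based start coordinate in the mature protein.
#' @param end 1-based end coordinate; defaults to `start + nchar(sequence) - 1`.
#' @return An object of class `chain`.
#' @examples
#' chain("DGVFTTPCDPEYAGG", start = 438)
#' @export
chain <- function(sequence, id = NULL, start = 1L, end = NULL) {
  validate_sequence(sequence)
  start <- as.integer(start)
  if (is.null(end)) end <- start + nchar(sequence) - 1L
  end <- as.integer(end)
  if (end - start + 1L != nchar(sequence))
    stop("chain coordinates inconsistent with sequence length: ",
         start, "-", end, " vs ", nchar(sequence), " residues")
  structure(
    list(id = if (is.null(id)) sequence else id,
         sequence = toupper(sequence), start = start, end = end),
    class = "chain"
  )
}

validate_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence))
    stop("sequence must be a single character string")
  if (nchar(sequence) == 0L) stop("sequence must be non-empty")
  letters <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- which(!(letters %in% .STANDARD_RESIDUES))
  if (length(bad) > 0L)
    stop("unknown residue letter '", letters[bad[1]],
         "' at position ", bad[1])
  invisible(letters)
}

as_chain <- function(x) {
  if (inherits(x, "chain")) x else chain(x)
}

#' Neutral mass of a chain
#'
#' Sum of residue masses plus one water, on the requested scale.
#'
#' @param x A [chain] or a plain sequence string.
#' @param scale `"mono"` or `"avg"`.
#' @return Neutral mass in Da.
#' @examples
#' chain_mass("DGVFTTPCDPEYAGG", "mono")
#' @export
chain_mass <- function(x, scale = c("mono", "avg")) {
  scale <- match.arg(scale)
  seq <- if (inherits(x, "chain")) x$sequence else x
  letters <- validate_sequence(seq)
  tab <- residue_masses(scale)
  water <- if (scale == "mono") .MASS_CONST$water_mono else .MASS_CONST$water_avg
  sum(tab[letters]) + water
}

#' Define a proteoform hypothesis
#'
#' Chains plus crosslink counts, counted modifications and the measurement
#' condition. Under `condition = "reducing"` the disulfide contribution to the
#' mass is zeroed (DTT opens disulfides) while the thioether contribution is
#' unchanged.
#'
#' @param chains A [chain], a character vector of sequences, or a list of
#'   chains. Each chain contributes one water (independently hydrolyzed
#'   backbone).
#' @param n_disulfide Number of disulfide bridges (each -2H when effective).
#' @param n_thioether Number of thioether bridges (each -2H, never reduced).
#' @param modifications List of `list(mod = <modification>, count = <int>)`
#'   entries.
#' @param condition `"non_reducing"` or `"reducing"`.
#' @return An object of class `proteoform`.
#' @examples
#' p <- proteoform(c("ACDK", "GGW"), n_disulfide = 1)
#' proteoform_mass(p, "avg")
#' @export
proteoform <- function(chains, n_disulfide = 0L, n_thioether = 0L,
                       modifications = list(),
                       condition = c("non_reducing", "reducing")) {
  condition <- match.arg(condition)
  if (inherits(chains, "chain")) chains <- list(chains)
  if (is.character(chains)) chains <- lapply(chains, chain)
  if (!is.list(chains) || length(chains) == 0L)
    stop("a proteoform needs at least one chain")
  chains <- lapply(chains, as_chain)
  n_disulfide <- as.integer(n_disulfide)
  n_thioether <- as.integer(n_thioether)
  if (n_disulfide < 0L || n_thioether < 0L)
    stop("crosslink counts must be non-negative")
  for (m in modifications) {
    if (!inherits(m$mod, "modification") || is.null(m$count))
      stop("modifications must be entries of the form list(mod =, count =)")
    if (m$count < 0L) stop("modification counts must be non-negative")
    if (m$count > m$mod$max_count)
      stop("count ", m$count, " of modification '", m$mod$name,
           "' exceeds its max_count ", m$mod$max_count)
  }
  structure(
    list(chains = chains, n_disulfide = n_disulfide,
         n_thioether = n_thioether, modifications = modifications,
         condition = condition),
    class = "proteoform"
  )
}

#' Neutral mass of a proteoform
#'
#' Sum of chain masses, minus 2H per effective crosslink, plus modification
#' deltas. Under the reducing condition the disulfide term is zero; the
#' thioether term always applies.
#'
#' @param p A [proteoform].
#' @param scale `"mono"` or `"avg"`.
#' @return Neutral mass in Da.
#' @export
proteoform_mass <- function(p, scale = c("mono", "avg")) {
  scale <- match.arg(scale)
  stopifnot(inherits(p, "proteoform"))
  h2 <- -crosslink_delta("disulfide", scale)  # +2H magnitude
  eff_ss <- if (p$condition == "reducing") 0L else p$n_disulfide
  m <- sum(vapply(p$chains, chain_mass, numeric(1), scale = scale))
  m <- m - h2 * eff_ss - h2 * p$n_thioether
  for (mod in p$modifications) {
    delta <- if (scale == "mono") mod$mod$delta_mono else mod$mod$delta_avg
    m <- m + delta * mod$count
  }
  m
}

#' @export
print.proteoform <- function(x, ...) {
  chains <- vapply(x$chains, function(ch)
    sprintf("%s(%d-%d)", ch$id, ch$start, ch$end), character(1))
  mods <- if (length(x$modifications) == 0L) "none" else
    paste(vapply(x$modifications, function(m)
      sprintf("%dx %s", m$count, m$mod$name), character(1)), collapse = ", ")
  cat("<proteoform> ", paste(chains, collapse = " // "), "\n",
      "  S-S: ", x$n_disulfide, "  thioether: ", x$n_thioether,
      "  mods: ", mods, "  [", x$condition, "]\n",
      "  M(mono) = ", format(proteoform_mass(x, "mono"), nsmall = 4),
      "  M(avg) = ", format(proteoform_mass(x, "avg"), nsmall = 2), "\n",
      sep = "")
  invisible(x)
}

#' m/z of a protonated species
#'
#' `(neutral + z * proton) / z` for an `[M + zH]z+` ion.
#'
#' @param neutral Neutral mass in Da.
#' @param z Charge state (positive integer), may be a vector.
#' @return m/z in Th.
#' @examples
#' mz_from_mass(1527.6188, 2)
#' @export
mz_from_mass <- function(neutral, z) {
  if (any(z < 1) || any(z != round(z))) stop("z must be a positive integer")
  (neutral + z * .MASS_CONST$proton) / z
}

#' Neutral mass from an observed m/z
#'
#' Inverse of [mz_from_mass]: `z * (observed - proton)`.
#'
#' @param observed Observed m/z in Th; must exceed the proton mass.
#' @param z Charge state (positive integer), may be a vector.
#' @return Neutral mass in Da.
#' @export
mass_from_mz <- function(observed, z) {
  if (any(z < 1) || any(z != round(z))) stop("z must be a positive integer")
  if (any(observed <= .MASS_CONST$proton))
    stop("observed m/z must exceed the proton mass")
  z * (observed - .MASS_CONST$proton)
}
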