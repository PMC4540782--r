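# Charge deconvolution of multiply protonated electrospray envelopes.
# Neutral-mass candidates are generated from peak pairs under the
# adjacent-charge relation and clustered; clusters supported by at least two
# charge states become neutral-mass estimates.

#' Construct a peak list
#'
#' @param mz m/z values (Th); stored sorted and must be strictly increasing
#'   after sorting (no duplicate m/z).
#' @param intensity Non-negative intensities (arbitrary units).
#' @param condition,sample Optional metadata labels.
#' @return A data frame of class `peak_list` with columns `mz`, `intensity`.
#' @export
peak_list <- function(mz, intensity, condition = NA_character_,
                      sample = NA_character_) {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  if (any(!is.finite(mz)) || any(mz <= 0)) stop("mz must be positive finite")
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensities must be non-negative")
  ord <- order(mz)
  mz <- mz[ord]; intensity <- intensity[ord]
  if (any(diff(mz) <= 0)) stop("mz values must be strictly increasing")
  structure(
    data.frame(mz = mz, intensity = intensity),
    condition = condition, sample = sample,
    class = c("peak_list", "data.frame")
  )
}

#' Assign candidate charge states to peaks
#'
#' Every peak pair (b at the lower m/z, a at the higher) is tested under the
#' adjacent-charge hypothesis: if a carries z protons and b carries z + 1,
#' then `z = round((b - proton) / (a - b))`. A pair is kept when both members
#' map to the same neutral mass within `tol_da`. Peaks from co-eluting species
#' interleave in m/z, so all pairs are examined, not only neighbours.
#'
#' @param peaks A [peak_list] (at least 2 peaks).
#' @param z_range Integer interval `c(zmin, zmax)` within \[1, 100\].
#' @param tol_da Neutral-mass agreement tolerance in Da.
#' @return Data frame with one row per accepted (peak, charge) assignment:
#'   `mz`, `intensity`, `z`, `neutral`. Empty (zero rows) when no consistent
#'   pair exists.
#' @export
assign_charges <- function(peaks, z_range = c(1L, 100L), tol_da = 1.0) {
  stopifnot(inherits(peaks, "peak_list"))
  z_range <- as.integer(z_range)
  if (length(z_range) != 2L || z_range[1] < 1L || z_range[2] > 100L ||
      z_range[1] > z_range[2])
    stop("z_range must be an integer interval within [1, 100]")
  empty <- data.frame(mz = numeric(0), intensity = numeric(0),
                      z = integer(0), neutral = numeric(0))
  n <- nrow(peaks)
  if (n < 2L) return(empty)
  p <- .MASS_CONST$proton
  mz <- peaks$mz; int <- peaks$intensity
  rows <- vector("list", 0L)
  for (i in seq_len(n - 1L)) {
    b <- mz[i]
    for (j in (i + 1L):n) {
      a <- mz[j]
      z <- round((b - p) / (a - b))
      # a carries z, b carries z + 1; both must sit in the allowed window
      if (z < z_range[1] || z + 1L > z_range[2]) next
      m_a <- z * (a - p)
      m_b <- (z + 1L) * (b - p)
      if (abs(m_a - m_b) > tol_da) next
      rows[[length(rows) + 1L]] <- data.frame(
        mz = c(a, b), intensity = c(int[j], int[i]),
        z = c(as.integer(z), as.integer(z + 1L)), neutral = c(m_a, m_b))
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out[, c("mz", "z")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Deconvolute a peak list into neutral masses
#'
#' Neutral-mass candidates from [assign_charges] are clustered by
#' single-linkage within `tol_da`; each cluster with support from at least two
#' charge states is reported as an intensity-weighted mean mass with the
#' spread across charge states as its uncertainty. Estimates are sorted by
#' total intensity, descending.
#'
#' @param peaks A [peak_list].
#' @param z_range Charge window; default `c(20, 60)` suits intact 40-60 kDa
#'   proteins, use `c(1, 4)` for peptide-scale spectra.
#' @param tol_da Clustering tolerance in Da; default 1.0 for intact proteins,
#'   0.02 is appropriate at peptide scale.
#' @return Data frame of class `neutral_mass_estimates` with columns `mass`,
#'   `mass_sd`, `n_charges`, `z_support` (list column), `total_intensity`.
#' @export
deconvolute <- function(peaks, z_range = c(20L, 60L), tol_da = 1.0) {
  stopifnot(inherits(peaks, "peak_list"))
  if (nrow(peaks) == 0L) stop("empty peak list")
  asg <- assign_charges(peaks, z_range, tol_da)
  empty <- structure(
    data.frame(mass = numeric(0), mass_sd = numeric(0),
               n_charges = integer(0), total_intensity = numeric(0)),
    class = c("neutral_mass_estimates", "data.frame"))
  empty$z_support <- list()
  if (nrow(asg) == 0L) return(empty)

  ord <- order(asg$neutral)
  asg <- asg[ord, , drop = FALSE]
  cluster <- cumsum(c(1, diff(asg$neutral) > tol_da))

  ests <- lapply(split(asg, cluster), function(cl) {
    zs <- sort(unique(cl$z))
    if (length(zs) < 2L) return(NULL)
    # one intensity contribution per distinct peak
    upk <- cl[!duplicated(cl$mz), , drop = FALSE]
    df <- data.frame(
      mass = stats::weighted.mean(cl$neutral, cl$intensity),
      mass_sd = stats::sd(cl$neutral),
      n_charges = length(zs),
      total_intensity = sum(upk$intensity),
      z_support = I(list(zs))
    )
    df$peaks <- I(list(unique(cl$mz)))
    df
  })
  ests <- ests[!vapply(ests, is.null, logical(1))]
  if (length(ests) == 0L) return(empty)
  out <- do.call(rbind, ests)
  out <- out[order(-out$total_intensity), , drop = FALSE]
  # Harmonic/composite suppression: walking down in intensity, an estimate is
  # genuine only if it owns at least one peak not already claimed by a
  # stronger estimate (half-mass harmonics and cross-species composites reuse
  # claimed peaks exclusively).
  claimed <- numeric(0)
  keep <- logical(nrow(out))
  for (i in seq_len(nrow(out))) {
    own <- setdiff(out$peaks[[i]], claimed)
    if (length(own) > 0L) {
      keep[i] <- TRUE
      claimed <- c(claimed, out$peaks[[i]])
    }
  }
  out <- out[keep, setdiff(names(out), "peaks"), drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("neutral_mass_estimates", "data.frame")
  out
}
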