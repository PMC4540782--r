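# Seeded synthetic-data generators emulating the instrument data the pipeline
# consumes. The forward models here are written independently of the analysis
# code (the deconvolver, integrators and fitters), so that recovery tests are
# non-circular at the code level. All generators are deterministic under their
# seed.

#' Synthesize a multiply protonated charge envelope
#'
#' Centroided sticks at `(mass + z * proton) / z` for each charge in the
#' window, with Gaussian m/z jitter expressed in ppm and a Gaussian-shaped
#' intensity envelope over charge states.
#'
#' @param mass Neutral mass in Da (> 0).
#' @param z_range Integer interval `c(zmin, zmax)`, non-empty.
#' @param ppm_noise Standard deviation of the m/z jitter in ppm (0 = exact
#'   theoretical positions).
#' @param seed Integer seed (mandatory).
#' @param total_intensity Summed intensity of the envelope.
#' @return A [peak_list].
#' @export
synth_charge_envelope <- function(mass, z_range, ppm_noise = 0,
                                  seed, total_intensity = 1) {
  stopifnot(mass > 0)
  z_range <- as.integer(z_range)
  if (length(z_range) != 2L || z_range[1] > z_range[2] || z_range[1] < 1L)
    stop("z_range must be a non-empty integer interval with zmin >= 1")
  if (ppm_noise < 0) stop("ppm_noise must be non-negative")
  withr::with_seed(seed, {
    df <- envelope_sticks(mass, z_range, ppm_noise, total_intensity)
  })
  peak_list(df$mz, df$intensity)
}

# unseeded forward model (own protonation arithmetic)
envelope_sticks <- function(mass, z_range, ppm_noise, total_intensity) {
  proton <- 1.00727646688
  z <- z_range[1]:z_range[2]
  mz <- (mass + z * proton) / z
  if (ppm_noise > 0)
    mz <- mz * (1 + stats::rnorm(length(mz), 0, ppm_noise * 1e-6))
  w <- exp(-0.5 * ((z - mean(z)) / max((z_range[2] - z_range[1]) / 4, 1))^2)
  data.frame(mz = mz, intensity = w / sum(w) * total_intensity)
}

#' Synthesize a mixed-species spectrum
#'
#' Superimposes one charge envelope per species, scaled to the requested
#' intensity ratios.
#'
#' @param masses Neutral masses in Da.
#' @param ratios Relative total intensities (same length as `masses`).
#' @param z_range Charge window shared by all species.
#' @param ppm_noise m/z jitter in ppm.
#' @param seed Integer seed.
#' @return A [peak_list].
#' @export
synth_mixture <- function(masses, ratios, z_range, ppm_noise = 0, seed) {
  stopifnot(length(masses) == length(ratios), all(masses > 0),
            all(ratios > 0))
  withr::with_seed(seed, {
    parts <- lapply(seq_along(masses), function(i)
      envelope_sticks(masses[i], as.integer(z_range), ppm_noise, ratios[i]))
  })
  df <- do.call(rbind, parts)
  peak_list(df$mz, df$intensity)
}

#' Synthesize Michaelis-Menten initial-rate data
#'
#' `v = Vmax * S / (Km + S)` with multiplicative Gaussian noise of coefficient
#' of variation `cv`, replicated `n_rep` times per substrate concentration.
#'
#' @param Km Michaelis constant (same concentration unit as `S_grid`).
#' @param Vmax Limiting rate.
#' @param S_grid Substrate concentrations.
#' @param cv Coefficient of variation of the multiplicative noise (>= 0).
#' @param n_rep Replicates per concentration.
#' @param seed Integer seed.
#' @return Data frame `S`, `v`, `replicate`.
#' @export
synth_initial_rates <- function(Km, Vmax, S_grid, cv = 0.03, n_rep = 4L,
                                seed) {
  stopifnot(Km > 0, Vmax > 0, all(S_grid > 0), n_rep >= 1L)
  if (cv < 0) stop("cv must be non-negative")
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n_rep), function(r) {
      v0 <- Vmax * S_grid / (Km + S_grid)
      v <- v0 * (1 + stats::rnorm(length(S_grid), 0, cv))
      data.frame(S = S_grid, v = v, replicate = r)
    })
  })
  do.call(rbind, rows)
}

#' Synthesize kinetic progress curves
#'
#' Closed-form model curves plus additive Gaussian signal noise, one curve per
#' enzyme concentration:
#' * `scenario = "suicide"`: `P(t) = r * E0 * (1 - exp(-k_obs * t))`
#'   (`params`: `r_partition`, `k_obs`).
#' * `scenario = "latent"`: the threshold-activation model; during the lag
#'   `P(t) = (a0 * c_star / (1 - a0)) * (exp((1 - a0) * vE * t / c_star) - 1)`
#'   with `vE = v_spec * E0`, switching to the fully active line of slope `vE`
#'   once `P` reaches `c_star` (`params`: `c_star`, `a0`, `v_spec`).
#'
#' @param scenario `"suicide"` or `"latent"`.
#' @param params Named list of scenario parameters (see above). Missing
#'   entries default to `r_partition = 8000`, `k_obs = 0.15` min^-1,
#'   `c_star = 23` uM, `a0 = 0.05`, `v_spec = 0.7` uM min^-1 nM^-1.
#' @param E0_list Enzyme concentrations in nM; defaults to the assay ladders
#'   `c(1.2, 0.6, 0.3, 0.15)` (suicide) and `c(7.2, 3.6, 1.8, 0.9)` (latent).
#' @param noise_sd Additive Gaussian signal noise, uM (0 = noiseless).
#' @param seed Integer seed.
#' @param t_grid Optional shared time grid (min); by default each curve gets
#'   a grid long enough to cover its plateau or its activation transition.
#' @param n_points Points per curve when `t_grid` is auto-chosen.
#' @return List of [progress_curve]s.
#' @export
synth_progress_curves <- function(scenario = c("suicide", "latent"),
                                  params = list(), E0_list = NULL,
                                  noise_sd = 0, seed, t_grid = NULL,
                                  n_points = 400L) {
  scenario <- match.arg(scenario)
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  defaults <- list(r_partition = 8000, k_obs = 0.15,
                   c_star = 23, a0 = 0.05, v_spec = 0.7)
  params <- utils::modifyList(defaults, params)
  if (is.null(E0_list))
    E0_list <- if (scenario == "suicide") c(1.2, 0.6, 0.3, 0.15)
               else c(7.2, 3.6, 1.8, 0.9)
  stopifnot(all(E0_list > 0))

  curves <- withr::with_seed(seed, lapply(E0_list, function(E0) {
    if (scenario == "suicide") {
      tg <- if (is.null(t_grid))
        seq(0, 6 / params$k_obs, length.out = n_points) else t_grid
      P <- params$r_partition * E0 * 1e-3 * (1 - exp(-params$k_obs * tg))
      substrate <- "sulfuretin"
    } else {
      vE <- params$v_spec * E0
      a0 <- params$a0; cs <- params$c_star
      t_star <- cs * log(1 / a0) / ((1 - a0) * vE)
      tg <- if (is.null(t_grid))
        seq(0, t_star + 1.2 * cs / vE, length.out = n_points) else t_grid
      P <- ifelse(
        tg <= t_star,
        (a0 * cs / (1 - a0)) * (exp((1 - a0) * vE * tg / cs) - 1),
        cs + vE * (tg - t_star))
      substrate <- "fisetin"
    }
    if (noise_sd > 0) P <- P + stats::rnorm(length(P), 0, noise_sd)
    progress_curve(tg, P, enzyme_nM = E0, substrate = substrate,
                   substrate_conc0 = 50)
  }))
  curves
}

#' Synthesize a protein and a peptide subset of chosen coverage
#'
#' Draws a random protein sequence, digests it (0 missed cleavages) and
#' selects tryptic peptides whose union covers `floor(coverage_target *
#' length)` residues. Selection prefers exactness: peptides adding at most the
#' remaining residue deficit are taken first (largest gain), and only when
#' none fits is the smallest overshooting peptide taken, so the achieved
#' coverage exceeds the target by at most one peptide.
#'
#' @param length Protein length in residues.
#' @param coverage_target Fraction in \[0, 1\].
#' @param seed Integer seed.
#' @return List: `sequence`, `peptides` (character vector), `mask`
#'   (a `coverage_mask`), `achieved` (residues covered), `target_n`.
#' @export
synth_protein_and_peptides <- function(length, coverage_target, seed) {
  stopifnot(length >= 1L)
  if (coverage_target < 0 || coverage_target > 1)
    stop("coverage_target must be in [0, 1]")
  seq <- withr::with_seed(seed,
    paste(sample(.STANDARD_RESIDUES, length, replace = TRUE), collapse = ""))
  target_n <- floor(coverage_target * length)
  dig <- tryptic_digest(seq, missed_max = 0L)
  covered <- logical(length)
  chosen <- integer(0)
  if (target_n > 0L) {
    repeat {
      deficit <- target_n - sum(covered)
      if (deficit <= 0L) break
      remaining <- setdiff(seq_len(nrow(dig)), chosen)
      if (length(remaining) == 0L) break
      gain <- vapply(remaining, function(i)
        sum(!covered[dig$start[i]:dig$end[i]]), integer(1))
      remaining <- remaining[gain > 0L]; gain <- gain[gain > 0L]
      if (length(remaining) == 0L) break
      fits <- gain <= deficit
      pick <- if (any(fits)) remaining[fits][which.max(gain[fits])]
              else remaining[which.min(gain)]
      chosen <- c(chosen, pick)
      covered[dig$start[pick]:dig$end[pick]] <- TRUE
    }
  }
  peptides <- dig$sequence[chosen]
  mask <- coverage_mask(covered)
  list(sequence = seq, peptides = peptides, mask = mask,
       achieved = sum(covered), target_n = target_n)
}
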