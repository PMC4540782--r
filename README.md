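# aurokin

Intact-mass proteoform reconciliation and enzyme kinetics for latent plant
polyphenol oxidases (PPOs), built around the characterization workflow of
aurone synthase — the type-3 copper enzyme that oxidizes the chalcone butein
to the aurone sulfuretin in yellow-flowered Asteraceae.

It is written for protein chemists who have (i) deconvoluted or raw
electrospray peak lists of a heterogeneously processed enzyme and need to
explain every mass, and (ii) photometric kinetic data from an enzyme that
both kills itself during turnover and, in its latent pro-form, switches
itself on with its own reaction product.

## What it computes

**Mass bookkeeping.** A proteoform is a set of independently hydrolyzed
chains plus declared crosslinks and counted modifications:

    M = Σ M_chain − 2·m_H·(n_SS_eff + n_thioether) + Σ count·Δ_mod

Each chain contributes one water; each disulfide and each Cys–His thioether
costs 2 H; under reducing (DTT) conditions the disulfide term is zero while
the thioether survives. Monoisotopic and average scales are both supported.

**Charge deconvolution.** Neutral masses from multiply protonated envelopes
via the adjacent-charge relation `z = round((b − m_H+)/(a − b))`, a
pair-consistency check, single-linkage clustering, a minimum of two
supporting charge states, and suppression of half-mass harmonics.

**Proteoform search.** Enumerates ragged C-termini × attached C-terminal
peptide × modifications × reducing condition (plus uncleaved latent
variants), matches observed masses within tolerance, ranks by error with
parsimony tie-breaks, and explains pairwise mass shifts from known deltas.

**Digest coverage.** Conventional trypsin rule (cleave after K/R, not
before P), missed cleavages, exact-substring coverage masks, and percentage
arithmetic.

**Kinetics.** Beer–Lambert conversion; Michaelis–Menten fitting by
Levenberg–Marquardt; pseudo-first-order efficiency (`kcat/Km`) with a
curvature check; suicide-inactivation progress curves
`P(t) = r·E0·(1 − exp(−k·t))` whose plateau is proportional to enzyme; and
a threshold-activation model of the latent enzyme,
`dP/dt = v·E0·[a0 + (1−a0)·min(P/c*, 1)]`, with an estimator for the
critical product concentration `c*` at which activation is complete.

**Synthetic data.** Seeded generators for envelopes, mixtures, initial
rates, progress curves and coverage fixtures, implemented independently of
the fitters so recovery tests are non-circular.

## Worked example

```r
library(aurokin)

## the disulfide-attached C-terminal peptide released by reduction
M <- chain_mass("DGVFTTPCDPEYAGG", "mono")
c(M, mz_from_mass(M, 1), mz_from_mass(M, 2))
#> 1527.6188 1528.6261  764.8167

## deconvolute a synthetic two-species spectrum (z = 25..45, 1.4:1)
pk  <- synth_mixture(c(41559.0, 41639.0), c(1.4, 1), c(25, 45),
                     ppm_noise = 0, seed = 1)
est <- deconvolute(pk, c(20, 60), tol_da = 1.0)
est[, c("mass", "n_charges", "total_intensity")]
#>    mass n_charges total_intensity
#> 1 41559        21             1.4
#> 2 41639        21             1.0

## what is the 80 Da split between them?
explain_shift(est$mass[2], est$mass[1], tol = 0.5)
#>   explanation   delta  error
#> 1         x80 80.0000 0.0000
#> 2     phospho 79.9799 0.0201
#> 3       sulfo 80.0632 0.0632

## Michaelis-Menten recovery from simulated butein initial rates
rates <- synth_initial_rates(Km = 52, Vmax = 489,
                             S_grid = c(10, 15, 20, 30, 40, 50, 60, 75),
                             cv = 0.03, n_rep = 4, seed = 1)
fit_michaelis_menten(rates$S, rates$v)
#> <mm_fit>  Km = 50.54527 +/- 2.478578   Vmax = 482.5889 +/- 12.50362   converged: TRUE

## critical activation concentration from latent-enzyme progress curves
fam <- synth_progress_curves("latent", noise_sd = 0.23, seed = 1)
estimate_critical_concentration(fam)$c_star
#> [1] 22.04
```

The first block reproduces the reference peptide's protonated masses to four
decimals from the residue table alone. The deconvolution block recovers both
co-occurring species, their 1.4:1 intensity ratio and the 80.0 Da spacing,
which `explain_shift()` attributes to a phosphorylation or sulfation — the
two are indistinguishable at intact-mass resolution. The kinetics blocks
recover the Michaelis constant (truth 52 µM) and the activation threshold
(truth 23 µM) from noisy simulated assays.

## Documentation

Every exported function carries roxygen documentation;
`vignettes/aurokin-methods.Rmd` describes the models, unit conventions,
default parameters and their rationale, the estimators' numerical choices,
and what the synthetic generators do and do not emulate.
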