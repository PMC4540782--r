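---
title: "Methods: intact-mass reconciliation and kinetics of a latent plant polyphenol oxidase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: intact-mass reconciliation and kinetics of a latent plant polyphenol oxidase}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aurokin)
```

## Scope

`aurokin` implements the computational core of an intact-mass and kinetic
characterization of aurone synthase, a latent plant polyphenol oxidase (PPO):

1. exact mass arithmetic for multi-chain proteoforms with crosslink and
   modification bookkeeping (`chain_mass()`, `proteoform_mass()`);
2. charge deconvolution of multiply protonated electrospray envelopes
   (`assign_charges()`, `deconvolute()`);
3. enumeration and tolerance matching of proteoform hypotheses
   (`search_space()`, `enumerate_hypotheses()`, `match_proteoforms()`,
   `explain_shift()`);
4. in-silico tryptic digestion and sequence coverage (`tryptic_digest()`,
   `map_peptides()`, `coverage_percent()`);
5. enzyme-kinetic models and fitters (`fit_michaelis_menten()`,
   `fit_pseudo_first_order()`, `simulate_suicide()`, `fit_suicide()`,
   `simulate_latent_activation()`, `estimate_critical_concentration()`);
6. seeded synthetic-data generators standing in for the instrument
   (`synth_*()`).

## Mass model

A *chain* is an independently hydrolyzed backbone: its neutral mass is the
sum of residue masses plus one water. A *proteoform* is a set of chains held
together covalently:

$$M = \sum_i M_{\text{chain},i} \;-\; 2m_H\,(n_{SS}^{\text{eff}} + n_{TE})
      \;+\; \sum_j c_j\,\Delta_j$$

where each disulfide ($n_{SS}$) and each Cys–His thioether ($n_{TE}$) costs
two hydrogen atoms, and $c_j$ counts copies of modification $j$. Under the
reducing condition (DTT treatment) the *effective* disulfide count is zero —
reduced species keep their thioether — which is exactly how a
disulfide-attached C-terminal peptide reveals itself as a $-$1.5 kDa shift
plus a newly appearing peptide peak.

Conventions, chosen to match how such results are conventionally reported:

* **Scales.** Intact-protein values use average masses; peptide-scale values
  use monoisotopic masses. Residue masses are the standard ExPASy values
  (audit them with `write_residue_table()`).
* **Protonation.** $m/z = (M + z\,m_{H^+})/z$ with the proton at
  1.00727647 Da; the electron mass is neglected, which reproduces the
  reference peptide's $[\mathrm{M{+}H}]^+$ 1528.6261 and
  $[\mathrm{M{+}2H}]^{2+}$ 764.8167 to four decimals.
* **The +80 species.** At intact-mass resolution a phosphorylation
  (+79.9663 mono) cannot be told from a sulfation (+79.9568 mono); the
  built-in `x80` modification carries the conventional flat +80.00 Da for
  intact work, while `phospho`/`sulfo` carry true deltas for peptide work.
  Both remain co-ranked candidates throughout; the package never resolves
  the ambiguity.
* **Coordinates.** 1-based, inclusive, numbered on the mature protein (the
  transit peptide is removed first; `mature_sequence()` trims a precursor
  using an anchor peptide of known mature coordinates).
* **Crosslink topology is declared, not inferred.** Cysteines are free
  thiols unless a crosslink is declared; the disulfide count per topology
  (e.g. 2 internal + 1 core–peptide link when the residual C-terminal
  peptide is attached) is part of the search space.

## Charge deconvolution

Electrospray puts a 40–60 kDa protein into a ladder of charge states
$z \approx 25\ldots45$. For two peaks $a > b$ under the hypothesis that they
are adjacent charges ($a$ at $z$, $b$ at $z+1$),

$$z = \operatorname{round}\!\left(\frac{b - m_{H^+}}{a - b}\right),$$

and the pair is accepted only if both members map to the same neutral mass
within a tolerance. All peak pairs are tested, not just neighbours in $m/z$:
in a two-species mixture the same-species adjacent-charge peaks interleave
with the other species' peaks. Accepted neutral-mass candidates are
clustered by single linkage (default tolerance 1.0 Da for intact work,
matching the sub-Da spreads such experiments report; 0.02 Da for peptides),
and each cluster is summarized as an intensity-weighted mean with the spread
across charge states as its uncertainty.

Two guards keep the output honest:

* clusters supported by fewer than two distinct charge states are discarded
  as unverifiable (a single peak is underdetermined);
* estimates are accepted strongest-first, and an estimate must own at least
  one peak not already claimed by a stronger estimate. This removes the
  half-mass harmonics (even-charge subsets re-interpreted at half charge)
  and cross-species composites that coincidence pairing otherwise produces.

The synthetic generator emits centroided sticks with Gaussian $m/z$ jitter
in ppm and a Gaussian intensity envelope over charge. It does not emulate
instrument resolution, isotope structure, adducts or baseline; passing
round-trip tests therefore demonstrate correctness of the charge arithmetic
and clustering, not robustness to raw instrument artifacts.

## Proteoform search

The search space mirrors how a latent PPO is processed: a fixed mature
N-terminus, unspecific proteolysis giving a ragged main-core C-terminus, an
optional disulfide-attached residual C-terminal peptide with its own ragged
end, uncleaved pro-enzyme variants, and counted modifications (the +80
species; up to `oxidation_max` ~16 Da oxidations as satellites). Only
C-terminal raggedness is enumerated because that is where such processing is
observed; the N-terminus is held fixed.

Matching ranks hypotheses by absolute mass error with parsimony tie-breaks
(fewer modifications, then fewer chains), so an oxidized satellite never
outranks an unmodified assignment at equal error. The default intact
tolerance is $\max(3\sigma_{\text{obs}}, 0.5\ \text{Da})$; peptide-scale
matching uses ppm. `explain_shift()` searches sums of at most two known
deltas (modifications, single-residue losses, water, 2H) for a mass
difference — e.g. 80.0 → phosphorylation/sulfation, 70.2 → loss of one
alanine.

## Digestion and coverage

Trypsin is modelled with the conventional rule — cleave C-terminal to K/R
except before P; the zero-missed peptides tile the protein exactly, and
missed-cleavage variants are concatenations of consecutive fragments.
Coverage is the union of exact substring matches (case-insensitive, I/L not
equated), reported both as an exact percentage and as a half-up integer.
441/517 gives 85.30 → 85; note 272/350 = 77.71 rounds half-up to 78 while
some software floors it to 77 — both raw numbers are returned so either
convention can be compared.

## Kinetic models

**Beer–Lambert.** `absorbance_to_concentration()` converts absorbance to
product concentration via the differential extinction coefficient
($c\,[\mu M] = 10^6 A/(\Delta\varepsilon\,\ell)$); `extinction_table()`
ships the assay constants (e.g. butein 415 nm, 9320 L mol⁻¹ cm⁻¹; fisetin
280 nm, 5345 — at which 120 mAU corresponds to ≈22.5 µM product).

**Michaelis–Menten.** $v = V_{\max}S/(K_m+S)$ is fitted by
Levenberg–Marquardt (`minpack.lm::nlsLM`) with standard errors from the
covariance at the optimum. The fit is flagged non-converged when the
optimizer fails or $K_m$ lands beyond 10× the largest substrate
concentration (the data then do not constrain $K_m$ — the practical reason
low-solubility substrates are handled by the pseudo-first-order route
instead). Units: µM and minutes internally; `kcat` (s⁻¹) and `kcat/Km`
(mM⁻¹ s⁻¹) require the enzyme molarity. Specific activities
(µmol min⁻¹ mg⁻¹) convert to turnover numbers only given an explicit molar
mass (`kcat_from_specific_activity()`); no default mass is assumed because a
heterogeneously processed enzyme offers several defensible bases (active
core ≈41.6 kDa, pro-enzyme ≈58.9 kDa, or an intermediate convention).

**Pseudo-first-order.** For $S \ll K_m$, $v \approx (k_{cat}/K_m)E\,S$; the
slope of $v$ vs $S$ through the origin estimates the efficiency. The
straight line *underestimates* $V_{\max}/K_m$ by a factor
$\approx 1/(1+S/K_m)$, i.e. by up to 7.5 % when sampling reaches
$S = 0.075K_m$; a quadratic lack-of-fit test at the 5 % level warns when
curvature says the regime assumption fails.

**Suicide inactivation.** PPOs inactivate during turnover. With substrate in
excess and active enzyme decaying exponentially,

$$P(t) = r\,E_0\,(1 - e^{-k_{obs}t}),$$

so the plateau is proportional to enzyme with partition ratio $r$ (product
per enzyme before death). This is a declared minimal model — the observation
is a decelerating curve with an enzyme-proportional plateau, and this is the
simplest form reproducing it; no mechanistic copper-state modelling is
attempted. `fit_suicide()` recovers $(P_\infty, k_{obs})$ and warns when the
last decile of the curve still has more than 10 % of the initial slope (no
plateau ⇒ $P_\infty$ unidentifiable).

**Threshold activation of the latent enzyme.** The latent pro-enzyme shows a
lag that shortens with enzyme concentration while steady state always begins
at the same product concentration, and a basal few-percent rate on
substrates whose products do not activate (chalcones — no quinoid product).
The minimal model with these three properties makes the active fraction
piecewise-linear in accumulated product:

$$\frac{dP}{dt} = v_{\text{spec}}E_0\left[a_0 + (1-a_0)\min(P/c^\*,1)\right],$$

with basal fraction $a_0$ and critical concentration $c^\*$. Ultrasensitive
or quadratic activation variants are deliberately out of scope. The
simulator integrates with a fixed step capped at
$0.01\,c^\*/(v_{\text{spec}}E_0)$ (default 5× finer; the generator uses the
closed-form solution instead, see below).

**Estimating $c^\*$.** The running slope $s(t)$ of each curve (local linear
regression, window ≈ $n/20$ points) is rescaled between its basal and
steady-state levels, $\alpha = (s - s_0)/(s_f - s_0)$. Under the model
$\alpha = P/c^\*$ exactly, so the product level at the first crossing of
$\alpha = 0.95$, divided by 0.95, estimates $c^\*$ without bias from the
basal activity — a naive "product level where the slope reaches 95 % of
final" reads low by $\tfrac{0.95 - a_0}{0.95(1-a_0)}$ (≈5 % at $a_0=0.05$),
which is why the normalized form is used. Curves that never reach steady
state are excluded with a warning; the across-curve spread is flagged when
it exceeds 15 % of the mean, since agreement across enzyme concentrations is
precisely what distinguishes a fixed product threshold from time- or
enzyme-dependent activation.

## Synthetic data: what it emulates, and what it does not

Generators are seeded (`withr::with_seed`; identical spec ⇒ identical
output) and implement their forward models in a code path separate from the
fitters and the integrator, so recovery tests are non-circular at the code
level — e.g. the latent generator uses the closed-form lag solution
$P(t) = \frac{a_0 c^\*}{1-a_0}\bigl(e^{(1-a_0)v_{\text{spec}}E_0 t/c^\*}-1\bigr)$
while `simulate_latent_activation()` integrates the ODE.

Default study conditions baked into the generators:

* **Envelopes**: charge window 25–45 for intact species, jitter 0–5 ppm
  (the stated instrument accuracy class), two-species mixtures at 1.4:1.
* **Initial rates**: truth $K_m = 52$ µM, $V_{\max} = 489$ for the
  best-substrate chalcone; 8 concentrations spanning 10–75 µM
  (10, 15, 20, 30, 40, 50, 60, 75 — the assay's stated range; the grid
  itself is this package's choice), 4 replicates, 3 % multiplicative noise.
* **Suicide curves**: enzyme ladder 1.2/0.6/0.3/0.15 nM. The partition
  ratio (8000) and $k_{obs}$ (0.15 min⁻¹) are this package's choices: they
  give a ≈9.6 µM plateau at 1.2 nM — a minority of the 50 µM substrate —
  on a tens-of-minutes timescale, as observed.
* **Latent activation**: enzyme ladder 7.2/3.6/1.8/0.9 nM, $c^\* = 23$ µM,
  $a_0 = 0.05$ ("a few percent" basal activity), $v_{\text{spec}} = 0.7$
  µM min⁻¹ nM⁻¹ (chosen once to put lags on the observed tens-of-minutes
  scale); "1 % signal noise" is additive with sd $= 0.01c^\* = 0.23$ µM.
* **Coverage fixtures**: random sequences with a tryptic-peptide subset
  selected to hit a target residue count exactly when possible (overshoot
  at most one peptide).

Not emulated: isotopic fine structure, peak shape and resolution, adducts,
chromatography, substrate depletion in progress curves, or product
polymerization (which in real suicide assays eventually *decreases* the
absorbance). Tests passing on these generators validate the estimators
against their stated models, not against every behaviour of real data.

## Problem sizes and numerical choices

Test and acceptance runs use deliberately modest sizes — envelopes of ~20–40
peaks, 32 rate observations, 4 progress curves of 400 points — which
complete in seconds while leaving the estimators' error well inside the
tolerances asserted. Tie-breaks, degenerate inputs and honesty flags
(non-convergence, no plateau, no steady state, inconsistent thresholds) are
part of the tested contract; see the test suite for the full battery.

## Known limitations

* Intact-mass validation of the specific reported species requires the mature
  enzyme sequence; the package ships the arithmetic and the trimming helper
  but not the sequence itself, which must be supplied (e.g. from UniProt)
  by the user.
* The deconvolver assumes protonated positive-mode species only.
* The activation and suicide models are phenomenological; their parameters
  summarize curve shape and are not mechanistic constants.
* Localization of modifications (which residue carries the +80) is out of
  scope — it requires fragment-ion evidence, not intact masses.
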