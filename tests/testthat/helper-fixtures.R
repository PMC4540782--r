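# Shared helpers for the test suite: seeded random sequences and an
# independent brute-force mass oracle used to cross-check the matcher.

random_sequence <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(names(residue_masses("mono")), n, replace = TRUE),
          collapse = ""))
}

# Independent mass arithmetic: sums the residue table by hand, applies the
# crosslink and modification bookkeeping in its own code path.
oracle_mass <- function(sequences, n_ss, n_thio, mod_deltas = numeric(0),
                        reducing = FALSE, scale = "avg") {
  tab <- residue_masses(scale)
  const <- mass_constants()
  water <- if (scale == "mono") const$water_mono else const$water_avg
  h <- if (scale == "mono") const$hydrogen_mono else const$hydrogen_avg
  total <- 0
  for (s in sequences) {
    letters <- strsplit(s, "")[[1]]
    total <- total + sum(tab[letters]) + water
  }
  eff_ss <- if (reducing) 0 else n_ss
  total - 2 * h * (eff_ss + n_thio) + sum(mod_deltas)
}

# Forward m/z arithmetic written out independently of mz_from_mass().
oracle_mz <- function(mass, z) (mass + z * 1.00727646688) / z
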