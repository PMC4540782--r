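make_space <- function(seq_len = 80, seed = 1, ...) {
  search_space(random_sequence(seq_len, seed = seed), ...)
}

test_that("enumeration cardinality matches the closed-form product", {
  mods <- builtin_modifications()
  cases <- list(
    list(core = 58:60, ps = 65, pe = 78:79, lat = NULL, mods = list(mods$x80),
         ox = 0, cond = "non_reducing", n = 3 * (1 + 2) * 2 * 1),
    list(core = 50:55, ps = NULL, pe = NULL, lat = NULL, mods = list(),
         ox = 0, cond = c("non_reducing", "reducing"), n = 6 * 1 * 2),
    list(core = 60, ps = 62, pe = 75:77, lat = 79:80, mods = list(mods$x80),
         ox = 2, cond = "non_reducing", n = (1 * (1 + 3) + 2) * 2 * 3),
    list(core = 55:56, ps = NULL, pe = NULL, lat = 80, mods = list(),
         ox = 1, cond = c("non_reducing", "reducing"), n = (2 + 1) * 2 * 2)
  )
  for (cs in cases) {
    sp <- make_space(80, seed = 2, core_end_window = cs$core,
                     peptide_start = cs$ps, peptide_end_window = cs$pe,
                     latent_end_window = cs$lat, mods = cs$mods,
                     oxidation_max = cs$ox, conditions = cs$cond)
    expect_length(enumerate_hypotheses(sp), cs$n)
  }
})

test_that("invalid search windows are rejected", {
  expect_error(make_space(core_end_window = 200), "bounds")
  expect_error(make_space(core_end_window = 70, peptide_start = 60,
                          peptide_end_window = 75), "overlap")
  expect_error(make_space(peptide_start = 60), "peptide_end_window required")
})

test_that("matching agrees with a brute-force oracle on random spaces", {
  for (trial in 1:5) {
    seq <- random_sequence(60, seed = 700 + trial)
    x80 <- builtin_modifications()$x80
    sp <- search_space(seq, core_end_window = 40:42, peptide_start = 48,
                       peptide_end_window = 57:58, mods = list(x80),
                       conditions = c("non_reducing", "reducing"))
    # oracle: nested loops over the space, own mass arithmetic
    oracle <- list()
    for (e in 40:42) for (pep in c(NA, 57, 58)) for (nx in 0:1)
      for (red in c(FALSE, TRUE)) {
        chains <- substr(seq, 1, e)
        nss <- 2
        if (!is.na(pep)) {
          chains <- c(chains, substr(seq, 48, pep))
          nss <- 3
        }
        oracle[[length(oracle) + 1L]] <- oracle_mass(
          chains, nss, 1, mod_deltas = rep(80, nx), reducing = red)
      }
    oracle <- unlist(oracle)
    withr::with_seed(trial, {
      truth <- sample(oracle, 1)
      obs <- truth + runif(1, -0.05, 0.05)
    })
    res <- match_proteoforms(obs, sp, tol_da = 0.4)
    best <- res[res$rank == 1, ]
    expect_equal(best$calc_mass, oracle[which.min(abs(obs - oracle))],
                 tolerance = 1e-9)
    expect_equal(best$delta_da, obs - best$calc_mass, tolerance = 1e-12)
  }
})

test_that("a forward-simulated hypothesis is recovered at rank 1", {
  for (trial in 1:4) {
    sp <- make_space(70, seed = 800 + trial, core_end_window = 50:53,
                     peptide_start = 58, peptide_end_window = 68:70,
                     mods = list(builtin_modifications()$x80))
    hyps <- enumerate_hypotheses(sp)
    masses <- vapply(hyps, proteoform_mass, numeric(1), scale = "avg")
    pick <- withr::with_seed(trial, sample(seq_along(hyps), 1))
    res <- match_proteoforms(masses[pick], sp, tol_da = 1e-6)
    expect_equal(res$label[res$rank == 1], attr(hyps[[pick]], "label"))
    expect_equal(res$delta_da[res$rank == 1], 0, tolerance = 1e-9)
  }
})

test_that("matching with synthetic 5 ppm data keeps rank-1 errors in spec", {
  sp <- make_space(400, seed = 31, core_end_window = 330:333,
                   peptide_start = 340, peptide_end_window = 380:382)
  hyps <- enumerate_hypotheses(sp)
  masses <- vapply(hyps, proteoform_mass, numeric(1), scale = "avg")
  withr::with_seed(5, {
    obs <- masses * (1 + rnorm(length(masses), 0, 5e-6))
  })
  res <- match_proteoforms(obs, sp, tol_ppm = 15)
  top <- res[res$rank == 1 & !is.na(res$rank), ]
  expect_true(all(abs(top$delta_ppm) <= 15))
})

test_that("ties are broken by parsimony: unmodified beats modified", {
  # two hypotheses at identical calculated mass: a longer unmodified core
  # versus a shorter core plus a fake modification equal to the length delta
  seq <- paste0(random_sequence(30, seed = 44), "GG")
  gdelta <- residue_masses("avg")[["G"]]
  fake <- modification("gshift", gdelta, gdelta, max_count = 1)
  sp <- search_space(seq, core_end_window = 31:32, mods = list(fake))
  hyps <- enumerate_hypotheses(sp)
  masses <- vapply(hyps, proteoform_mass, numeric(1), scale = "avg")
  target <- proteoform_mass(
    proteoform(substr(seq, 1, 32), n_disulfide = 2, n_thioether = 1), "avg")
  res <- match_proteoforms(target, sp, tol_da = 0.001)
  expect_gte(nrow(res), 2L)
  expect_equal(res$n_mods[res$rank == 1], 0)
})

test_that("unmatched estimates are reported as such", {
  sp <- make_space(50, seed = 9, core_end_window = 40)
  res <- match_proteoforms(c(1e6, proteoform_mass(
    enumerate_hypotheses(sp)[[1]], "avg")), sp, tol_da = 0.5)
  expect_true(any(is.na(res$label)))
  expect_true(any(!is.na(res$label)))
})

test_that("explain_shift finds the canonical assignments", {
  # the +80 satellite: phosphorylation and sulfation both qualify
  hits <- explain_shift(41639.0, 41559.0, tol = 0.5)
  expect_true(all(c("phospho", "sulfo") %in% hits$explanation))
  # the 70.2 Da latent split: loss of one alanine
  hits <- explain_shift(58928.2, 58858.0, tol = 1.5)
  expect_true("loss_A" %in% hits$explanation[hits$error < 1])
  # a ~16 Da satellite: oxidation
  hits <- explain_shift(41575.0, 41559.0, tol = 0.5)
  expect_true("oxidation" %in% hits$explanation)
  # zero shift explains nothing
  expect_equal(nrow(explain_shift(500, 500, tol = 0.5)), 0L)
  expect_error(explain_shift(1, 2, tol = 0), "positive")
})

test_that("explanations are sorted by error and respect the pair limit", {
  hits <- explain_shift(30000, 30000 - 160.1, tol = 2)
  expect_false(is.unsorted(hits$error))
  singles <- explain_shift(30000, 30000 - 160.1, tol = 2, max_items = 1)
  expect_false(any(grepl("+", singles$explanation, fixed = TRUE)))
})

test_that("mature_sequence trims a precursor by anchor coordinates", {
  mature <- random_sequence(60, seed = 77)
  anchor <- substr(mature, 41, 52)
  precursor <- paste0(random_sequence(25, seed = 78), mature)
  expect_equal(mature_sequence(precursor, anchor, 41), mature)
  expect_error(mature_sequence(mature, "WWWWWWWW", 5), "not found")
})
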