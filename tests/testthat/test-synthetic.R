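test_that("a null effect yields no mean paired change at large n", {
  spec <- cohort_spec(
    features = list(rin = list(mean = 75, sem = 4.7, effect = 1.0)),
    n_cells = 1000, sem_n = 17, dispersion_cv = list(rin = 0.25),
    noise_sd = list(rin = 2), seed = 5)
  coh <- generate_paired_cohort(spec)
  pct <- 100 * mean(coh$treatment$rin / coh$control$rin - 1)
  expect_lt(abs(pct), 2)
})

test_that("the PKC-activator preset recovers its input-resistance effect", {
  spec <- cohort_preset("pma", n_cells = 1000, seed = 9)
  coh <- generate_paired_cohort(spec)
  ratio <- mean(coh$treatment$input_resistance) / mean(coh$control$input_resistance)
  expect_equal(ratio, 105.1 / 74.8, tolerance = 0.03)
  # all four features present, pairing preserved, ages in range
  expect_setequal(setdiff(names(coh$control), c("cell", "age")),
                  c("input_resistance", "rheobase", "fi_slope", "ahp"))
  expect_identical(coh$control$cell, coh$treatment$cell)
  expect_true(all(coh$control$age >= 11 & coh$control$age <= 27))
})

test_that("generation is reproducible and physically sane", {
  spec <- cohort_preset("ifn", seed = 21)
  c1 <- generate_paired_cohort(spec)
  c2 <- generate_paired_cohort(spec)
  expect_identical(c1, c2)
  vals <- unlist(c(c1$control[, -(1:2)], c1$treatment[, -(1:2)]))
  expect_true(all(vals > 0))
})

test_that("an impossible specification is rejected with a diagnostic", {
  spec <- cohort_spec(
    features = list(ahp = list(mean = 0.35, sem = 0.5, effect = 0.5)),
    n_cells = 10, seed = 1)
  expect_error(generate_paired_cohort(spec), "negative")
})

test_that("the age-effect scenario induces a negative effect-age correlation", {
  spec <- cohort_preset("ifn", n_cells = 200, age_scenario = "ifn_rin_age",
                        seed = 3)
  coh <- generate_paired_cohort(spec)
  eff <- coh$treatment$input_resistance / coh$control$input_resistance
  expect_lt(effect_age_correlation(eff, coh$control$age)$r, 0)
})

test_that("noiseless trace fixtures invert the feature extractor exactly", {
  targets <- list(rheobase = 125, fi_slope = 80, input_resistance = 100, ahp = 5)
  fam <- generate_trace_fixture(targets, noise_sd = 0)
  ft <- extract_features(fam, ahp_trace = fam$traces[[length(fam)]])
  expect_equal(ft$rheobase, 125)
  expect_equal(ft$fi_slope, 80)
  expect_equal(ft$input_resistance, 100)
  expect_equal(ft$ahp_amplitude, 5, tolerance = 0.02)
  # zero-AHP target: extractor returns zero
  fam0 <- generate_trace_fixture(
    list(rheobase = 125, fi_slope = 80, input_resistance = 100, ahp = 0),
    noise_sd = 0)
  expect_equal(ahp_amplitude(fam0$traces[[length(fam0)]]), 0)
  expect_error(generate_trace_fixture(list(rheobase = 900, fi_slope = 80)),
               "amplitude grid")
})

test_that("same-seed fixtures are identical, different seeds differ", {
  targets <- list(rheobase = 100, fi_slope = 70)
  a <- generate_trace_fixture(targets, noise_sd = 0.3, seed = 4)
  b <- generate_trace_fixture(targets, noise_sd = 0.3, seed = 4)
  d <- generate_trace_fixture(targets, noise_sd = 0.3, seed = 5)
  expect_identical(a$traces[[5]]$values, b$traces[[5]]$values)
  expect_false(identical(a$traces[[5]]$values, d$traces[[5]]$values))
})

test_that("noisy fixtures recover the rheobase within the calibrated band", {
  targets <- list(rheobase = 125, fi_slope = 80, input_resistance = 100, ahp = 5)
  hits <- 0L
  n_seeds <- 12
  for (s in seq_len(n_seeds)) {
    fam <- generate_trace_fixture(targets, noise_sd = 0.3, seed = s)
    if (abs(fi_features(fam)$rheobase - 125) <= 10) hits <- hits + 1L
  }
  expect_gte(hits / n_seeds, 0.95 - 1e-9)
})

test_that("cohort tables round-trip through the per-cell file format", {
  coh <- generate_paired_cohort(cohort_preset("bryostatin", seed = 2))
  path <- tempfile(fileext = ".tsv")
  write_cohort_table(coh, path)
  back <- read_cohort_table(path)
  expect_equal(back$control$input_resistance, coh$control$input_resistance,
               tolerance = 1e-12)
  expect_equal(back$treatment$ahp, coh$treatment$ahp, tolerance = 1e-12)
})
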