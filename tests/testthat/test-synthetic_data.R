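test_that("study fixtures match the shipped design table field for field", {
  fixtures <- study_fixtures()
  expect_length(fixtures, 8)
  designs <- read.csv(pbpk_extdata("study_designs.csv"), comment.char = "#")
  expect_equal(sum(designs$population == "healthy"), 5)
  expect_equal(sum(designs$population == "CP-A"), 2)
  expect_equal(sum(designs$population == "CKD-severe"), 1)
  for (i in seq_along(fixtures)) {
    s <- fixtures[[i]]; row <- designs[i, ]
    expect_equal(s$id, row$study_id)
    expect_identical(s$population, row$population)
    expect_identical(s$route, row$route)
    expect_equal(s$dose$amount, row$dose)
    expect_identical(s$dose$amount_basis,
                     if (row$dose_unit == "mg/kg") "mg_per_kg" else "absolute_mg")
    expect_equal(s$cohort$n, row$n_subjects)
    expect_equal(s$cohort$age_range, c(row$age_min, row$age_max))
    expect_equal(s$cohort$female_fraction, row$n_female / row$n_subjects)
  }
  # the renal scenario encodes its printed design verbatim
  renal <- fixtures[[8]]
  expect_equal(renal$dose$amount, 1)
  expect_identical(renal$dose$amount_basis, "mg_per_kg")
  expect_equal(renal$cohort$n, 4)
  expect_equal(renal$cohort$age_range, c(37, 70))
  expect_equal(renal$cohort$weight_range, c(75, 87))
  # healthy oral scenarios dose 200 mg with unreported weights
  for (s in fixtures[1:2]) {
    expect_equal(s$dose$amount, 200)
    expect_true(s$cohort$weight_assumed)
  }
})

test_that("synthetic observations interpolate the truth exactly at cv = 0", {
  t <- seq(0, 12, by = 0.05)
  truth <- concentration_profile(t, 100 * exp(-0.3 * t),
                                 dose = dose_event("iv_infusion", 1), weight = 70)
  nm <- noise_model(0, sampling_times = c(0.5, 1, 2, 4, 8), seed = 5)
  obs <- generate_observed(truth, nm)
  expect_equal(obs$concentration, 100 * exp(-0.3 * c(0.5, 1, 2, 4, 8)),
               tolerance = 1e-6)
  expect_identical(attr(obs, "provenance"), "synthetic")
})

test_that("synthetic observations are seed-reproducible and span-checked", {
  t <- seq(0, 12, by = 0.05)
  truth <- concentration_profile(t, 100 * exp(-0.3 * t))
  nm <- noise_model(0.25, sampling_times = c(0.5, 1, 2, 4, 8), seed = 12)
  expect_identical(generate_observed(truth, nm), generate_observed(truth, nm))
  nm2 <- noise_model(0.25, sampling_times = c(0.5, 1, 2, 4, 8), seed = 13)
  expect_false(identical(generate_observed(truth, nm),
                         generate_observed(truth, nm2)))
  bad <- noise_model(0.1, sampling_times = c(1, 20), seed = 1)
  expect_error(generate_observed(truth, bad), "span")
})

test_that("the residual error model is mean-one multiplicative log-normal", {
  t <- seq(0, 10, by = 0.1)
  truth <- concentration_profile(t, rep(100, length(t)))
  nm <- noise_model(0.2, sampling_times = seq(0.5, 9.5, by = 0.1), seed = 77)
  obs <- generate_observed(truth, nm)
  eps <- obs$concentration / 100
  expect_equal(mean(eps), 1, tolerance = 0.05)
  expect_equal(sd(eps) / mean(eps), 0.2, tolerance = 0.25)
})

test_that("recovery experiment structure and noise-free exactness", {
  scen <- study_fixtures()[[3]]  # healthy IV 0.5 mg/kg, n = 6, CL truth 63 L/h
  nm0 <- noise_model(0, sampling_times = clinical_sampling_times(48), seed = 2)
  rec0 <- recovery_experiment(scen, nm0, replicates = 3, t_end = 48)
  expect_equal(nrow(rec0$replicates), 3)
  expect_equal(rec0$truth$clearance, 63, tolerance = 1e-9)
  # with no residual error every replicate equals the noise-free estimate
  expect_equal(unname(rec0$summary$cl_vs_noisefree["bias"]), 0, tolerance = 1e-12)
  expect_equal(unname(rec0$summary$cmax_vs_noisefree["bias"]), 0, tolerance = 1e-12)
})

test_that("residual-error bias shrinks monotonically as cv decreases", {
  # oral route: the max statistic sits on a flat region of the profile, so
  # the residual error induces a clean upward Cmax bias that grows with cv
  scen <- study_fixtures()[[1]]
  biases <- vapply(c(0.3, 0.1, 0), function(cv) {
    nm <- noise_model(cv, sampling_times = clinical_sampling_times(48), seed = 6)
    rec <- recovery_experiment(scen, nm, replicates = 50, t_end = 48)
    unname(rec$summary$cmax_vs_noisefree["bias"])
  }, numeric(1))
  expect_true(all(diff(biases) < 0))
  expect_true(all(biases >= 0))
  expect_equal(biases[3], 0, tolerance = 1e-12)
})
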