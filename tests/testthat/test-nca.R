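test_that("trapezoid AUC is exact for piecewise-linear inputs", {
  # rectangle
  p <- concentration_profile(c(0, 1, 2, 3, 4), rep(10, 5))
  s <- nca_summary(p)
  expect_equal(s$auc_0_t, 40)
  expect_equal(s$cmax, 10)
  # triangle
  tri <- nca_summary(concentration_profile(c(0, 1, 2), c(0, 2, 0)))
  expect_equal(tri$auc_0_t, 2)
  expect_equal(tri$tmax, 1)
  # additivity over a refined grid: piecewise-linear values are reproduced
  t1 <- c(0, 2, 5, 8)
  c1 <- c(0, 6, 3, 1)
  t2 <- sort(unique(c(t1, seq(0, 8, by = 0.25))))
  c2 <- approx(t1, c1, t2)$y
  expect_equal(nca_summary(concentration_profile(t1, c1))$auc_0_t,
               nca_summary(concentration_profile(t2, c2))$auc_0_t,
               tolerance = 1e-12)
})

test_that("mono-exponential profile recovers the closed-form parameters", {
  t <- seq(0, 24, by = 0.05)
  p <- concentration_profile(t, 100 * exp(-0.5 * t))
  s <- nca_summary(p)
  expect_equal(s$auc_0_inf, 200, tolerance = 0.005)       # C0/k
  expect_equal(s$half_life, log(2) / 0.5, tolerance = 0.01)
  expect_equal(s$lambda_z, 0.5, tolerance = 0.01)
  expect_false(s$lambda_z_flagged)
})

test_that("clearance from dose and extrapolated AUC, labeled per route", {
  t <- seq(0, 24, by = 0.05)
  conc <- 100 * exp(-0.5 * t)
  # 1 mg dose, AUC0-inf 200 ng.h/mL -> CL = 1e6/200/1000 = 5 L/h
  p_iv <- concentration_profile(t, conc, dose = dose_event("iv_infusion", 1), weight = 70)
  s_iv <- nca_summary(p_iv)
  expect_equal(s_iv$clearance, 5, tolerance = 0.005)
  expect_identical(s_iv$clearance_type, "CL")
  p_oral <- concentration_profile(t, conc, dose = dose_event("oral", 1), weight = 70)
  expect_identical(nca_summary(p_oral)$clearance_type, "CL/F")
})

test_that("degenerate profiles are handled explicitly", {
  zero <- nca_summary(concentration_profile(0:5, rep(0, 6)))
  expect_equal(zero$auc_0_t, 0)
  expect_equal(zero$cmax, 0)
  expect_true(is.na(zero$lambda_z))
  expect_true(zero$lambda_z_flagged)
  expect_error(concentration_profile(c(0, 1, 1), c(1, 2, 3)), "time")
  expect_error(concentration_profile(c(0, 1), c(1, 2)), "time")
  expect_error(concentration_profile(0:2, c(1, -1, 0)), "concentration")
})

test_that("noisy terminal phases are flagged by the regression diagnostic", {
  t <- seq(0, 10, by = 1)
  set.seed(4)
  conc <- 100 * exp(-0.4 * t) * exp(rnorm(length(t), 0, 0.8))
  s <- nca_summary(concentration_profile(t, conc), terminal_points = 6)
  expect_true(is.na(s$lambda_z) || s$lambda_z_flagged || s$lambda_z_r_squared < 0.9)
})

test_that("the lin-log rule matches the exponential tail more closely", {
  t <- seq(0, 12, by = 1)  # coarse grid exaggerates the trapezoid bias
  p <- concentration_profile(t, 100 * exp(-0.5 * t))
  lin <- nca_summary(p, auc_method = "linear")$auc_0_t
  ll <- nca_summary(p, auc_method = "linlog")$auc_0_t
  truth <- 200 * (1 - exp(-0.5 * 12))
  expect_lt(abs(ll - truth), abs(lin - truth))
})

test_that("observed table reader returns the packaged transcription", {
  tab <- observed_table_reader()
  expect_equal(nrow(tab), 24)
  expect_equal(tab$observed[tab$study_id == 3 & tab$parameter == "cmax"], 144.244)
  expect_equal(tab$observed[tab$study_id == 8 & tab$parameter == "auc_0_t"], 590.26)
  expect_equal(tab$predicted[tab$study_id == 6 & tab$parameter == "cmax"], 144.1995)
})

test_that("reader validates schema and tolerates empty files", {
  tmp <- tempfile(fileext = ".csv")
  writeLines("study_id,route,population,parameter,observed,unit", tmp)
  expect_equal(nrow(observed_table_reader(tmp)), 0)
  writeLines(c("study_id,route,population,parameter,observed,unit",
               "1,iv,healthy,vd,10,L"), tmp)
  expect_error(observed_table_reader(tmp), "parameter")
  writeLines(c("study_id,route,population,parameter,observed,unit",
               "1,iv,healthy,cmax,-3,ng/mL"), tmp)
  expect_error(observed_table_reader(tmp), "observed")
  writeLines("study_id,route,parameter", tmp)
  expect_error(observed_table_reader(tmp), "missing columns")
})
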