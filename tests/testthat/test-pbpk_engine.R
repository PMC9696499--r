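test_that("assembled system has the documented structure", {
  sys <- ref_system()
  expect_equal(anyDuplicated(sys$labels), 0L)
  expect_length(grep("^gi_segment_", sys$labels), 7L)
  expect_true(all(c("gi_stomach", "gi_unabsorbed") %in% sys$labels))
  organ_states <- setdiff(sys$labels, c(grep("^gi_|^eliminated_", sys$labels, value = TRUE)))
  expect_gte(length(organ_states), 12L)
})

test_that("halving the gastric emptying time doubles the emptying rate", {
  ind <- ref_individual()
  ind$gastric_emptying_time <- ind$gastric_emptying_time / 2
  sys2 <- assemble_model(ind, ref_drug(), ref_partition(), ref_clearance())
  expect_equal(sys2$gastric_emptying_rate, 2 * ref_system()$gastric_emptying_rate,
               tolerance = 1e-12)
})

test_that("a missing organ aborts assembly with its name", {
  part <- ref_partition()
  part$kp <- part$kp[setdiff(names(part$kp), "muscle")]
  expect_error(assemble_model(ref_individual(), ref_drug(), part, ref_clearance()),
               "muscle")
})

test_that("dose validation rejects degenerate events", {
  expect_error(dose_event("iv_infusion", 0), "amount")
  expect_error(dose_event("oral", -5), "amount")
  expect_error(dose_event("iv_infusion", 10, infusion_duration = 0), "infusion_duration")
  expect_error(simulate_pbpk(ref_system(), dose_event("oral", 100, start = 5), t_end = 4),
               "t_end")
})

test_that("with kp = 1 and no clearance all compartments equilibrate", {
  setup <- zero_clearance_setup()
  sim <- simulate_pbpk(setup$system, dose_event("iv_infusion", 35, "absolute_mg",
                                                infusion_duration = 0.1),
                       t_end = 600, dt_out = 1)
  final <- sim$amounts[nrow(sim$amounts), ]
  organs <- c("arterial_blood", "venous_blood", "lung", "liver", "kidney", "gut",
              "muscle", "adipose", "skin", "brain", "heart", "bone", "rest")
  conc <- final[organs] / unlist(setup$individual$organ_volumes[organs])
  expect_lt(diff(range(conc)) / mean(conc), 1e-6)
  # nothing eliminated, ever
  expect_equal(max(sim$amounts[, "eliminated_hepatic"]), 0)
  expect_equal(max(sim$amounts[, "eliminated_renal"]), 0)
})

test_that("IV AUC0-inf equals Dose/CL independent of kp and infusion duration", {
  # central engine oracle: linear-system identity AUC = Dose / CL
  target <- 35e6 / 63 / 1000  # ng over L/h -> ng.h/mL = 555.56
  n1 <- nca_summary(as_profile(ref_iv_sim_long()))
  expect_equal(n1$auc_0_inf, target, tolerance = 0.005)

  # different infusion duration
  s2 <- simulate_pbpk(ref_system(), dose_event("iv_infusion", 0.5, "mg_per_kg",
                                               infusion_duration = 0.5),
                      t_end = 240, dt_out = 0.1)
  expect_equal(nca_summary(as_profile(s2))$auc_0_inf, target, tolerance = 0.005)

  # different distribution (recalibrated kp) leaves AUC unchanged
  part2 <- calibrate_kp_scale(ref_partition(), ref_individual(), 6)
  sys2 <- assemble_model(ref_individual(), ref_drug(), part2, ref_clearance())
  s3 <- simulate_pbpk(sys2, dose_event("iv_infusion", 0.5, "mg_per_kg"),
                      t_end = 240, dt_out = 0.1)
  expect_equal(nca_summary(as_profile(s3))$auc_0_inf, target, tolerance = 0.005)
})

test_that("NCA clearance on a long IV run recovers the engine clearance", {
  n <- nca_summary(as_profile(ref_iv_sim_long()))
  expect_equal(n$clearance, 63, tolerance = 0.02)
  expect_identical(n$clearance_type, "CL")
})

test_that("mass is conserved and the ledger classifies oral dispositions", {
  oral <- simulate_pbpk(ref_system(), dose_event("oral", 200), t_end = 12)
  expect_lte(mass_balance(oral)$max_relative_error, 1e-3)
  iv <- simulate_pbpk(ref_system(), dose_event("iv_infusion", 0.5, "mg_per_kg"), t_end = 8)
  expect_lte(mass_balance(iv)$max_relative_error, 1e-3)
  # oral: systemically available fraction strictly < 1
  led <- oral$mass_ledger[nrow(oral$mass_ledger), ]
  absorbed_frac <- 1 - led$unabsorbed / led$dosed
  expect_lt(led$eliminated_hepatic + led$eliminated_renal + led$in_body, led$dosed * 1.001)
  expect_gt(led$unabsorbed, 0)
  expect_lt(absorbed_frac, 1)
})

test_that("zero absorption routes the whole oral dose to the unabsorbed sink", {
  d <- ref_drug()
  d$intestinal_permeability <- 0
  part <- compute_partition_coefficients(d, ref_individual())
  part <- calibrate_kp_scale(part, ref_individual(), 11)
  sys <- assemble_model(ref_individual(), d, part, ref_clearance())
  sim <- simulate_pbpk(sys, dose_event("oral", 200), t_end = 48, dt_out = 0.5)
  led <- sim$mass_ledger[nrow(sim$mass_ledger), ]
  expect_gt(led$unabsorbed / led$dosed, 0.999)
  expect_equal(max(sim$plasma_concentration), 0)
})

test_that("doubling the dose doubles Cmax and AUC (linearity)", {
  s1 <- simulate_pbpk(ref_system(), dose_event("iv_infusion", 0.5, "mg_per_kg"), t_end = 8)
  s2 <- simulate_pbpk(ref_system(), dose_event("iv_infusion", 1.0, "mg_per_kg"), t_end = 8)
  n1 <- nca_summary(as_profile(s1)); n2 <- nca_summary(as_profile(s2))
  expect_equal(n2$cmax / n1$cmax, 2, tolerance = 1e-3)
  expect_equal(n2$auc_0_t / n1$auc_0_t, 2, tolerance = 1e-3)
})

test_that("oral bioavailability is below 1 and inside the clinical bracket", {
  iv <- nca_summary(as_profile(ref_iv_sim_long()))
  oral_sim <- simulate_pbpk(ref_system(), dose_event("oral", 200), t_end = 240, dt_out = 0.1)
  oral <- nca_summary(as_profile(oral_sim))
  f <- (oral$auc_0_inf / 200) / (iv$auc_0_inf / 35)
  expect_lt(f, 1)
  expect_gte(f, 0.15)
  expect_lte(f, 0.45)
})

test_that("oral collapses to the IV limit without first pass and with fast absorption", {
  ind <- ref_individual()
  ind$gastric_emptying_time <- 0.01          # near-instant gastric emptying
  drug <- ref_drug()
  drug$intestinal_permeability <- 0.01       # ka ~ 576 /h
  # renal-only elimination: total clearance set equal to fu*GFR
  drug$total_body_clearance <- 0.45 * 120 / 70
  clr <- allocate_clearance(drug, ind)
  expect_equal(clr$hepatic_plasma_clearance, 0, tolerance = 1e-9)
  part <- calibrate_kp_scale(compute_partition_coefficients(drug, ind), ind, 11)
  sys <- assemble_model(ind, drug, part, clr)
  oral <- simulate_pbpk(sys, dose_event("oral", 35), t_end = 240, dt_out = 0.1)
  iv <- simulate_pbpk(sys, dose_event("iv_infusion", 35, infusion_duration = 0.01),
                      t_end = 240, dt_out = 0.1)
  n_oral <- nca_summary(as_profile(oral)); n_iv <- nca_summary(as_profile(iv))
  expect_equal(n_oral$auc_0_inf, n_iv$auc_0_inf, tolerance = 0.01)
  # profiles agree once the absorption transient has passed
  sel <- oral$time >= 2
  expect_equal(oral$plasma_concentration[sel],
               approx(iv$time, iv$plasma_concentration, oral$time[sel])$y,
               tolerance = 0.02)
})

test_that("clearance-free IV simulation eliminates nothing at any time", {
  setup <- zero_clearance_setup()
  sim <- simulate_pbpk(setup$system, dose_event("iv_infusion", 35, "absolute_mg"),
                       t_end = 24, dt_out = 0.5)
  expect_equal(max(sim$amounts[, "eliminated_hepatic"] + sim$amounts[, "eliminated_renal"]), 0)
  expect_lte(mass_balance(sim)$max_relative_error, 1e-3)
})
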