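test_that("cirrhosis modifier table is monotone in severity", {
  a <- cirrhosis_modifiers("CP-A")
  b <- cirrhosis_modifiers("CP-B")
  c <- cirrhosis_modifiers("CP-C")
  expect_lt(a$liver_volume_factor, 1)
  for (f in c("liver_volume_factor", "gfr", "hepatic_intrinsic_clearance_factor",
              "hematocrit", "protein_binding_factor")) {
    expect_lte(c[[f]], b[[f]])
    expect_lte(b[[f]], a[[f]])
  }
  expect_error(cirrhosis_modifiers("CP-D"), "cp_class")
})

test_that("a non-monotone user table triggers a warning", {
  tab <- cirrhosis_modifier_table()
  tab$value[tab$label == "CP-C" & tab$field == "gfr"] <- 150
  expect_warning(cirrhosis_modifiers("CP-A", table = tab), "monotone")
})

test_that("severe CKD returns the five published physiological values", {
  m <- renal_modifiers("severe")
  expect_equal(m$gastric_emptying_time, 24.375)
  expect_equal(m$small_intestine_transit_time, 2.94)
  expect_equal(m$hematocrit, 0.398)
  expect_equal(m$protein_binding_factor, 0.843)
  expect_equal(m$gfr, 11)
  expect_identical(m$gfr_unit, "mL/min")
  expect_error(renal_modifiers("mild"), "arg")
})

test_that("moderate CKD interpolates midway between healthy and severe", {
  m <- renal_modifiers("moderate")
  expect_equal(m$gastric_emptying_time, (15 + 24.375) / 2)    # 19.6875
  expect_equal(m$small_intestine_transit_time, (3.3 + 2.94) / 2)
  expect_equal(m$hematocrit, (0.45 + 0.398) / 2)
  expect_equal(m$protein_binding_factor, (1 + 0.843) / 2)
  expect_equal(m$gfr, (120 + 11) / 2)
})

test_that("healthy label is the exact identity", {
  out <- apply_modifiers(ref_individual(), healthy_modifiers(), ref_clearance(),
                         drug = ref_drug())
  expect_identical(out$individual, ref_individual())
  expect_identical(out$clearance, ref_clearance())
})

test_that("disease application transforms binding, GI physiology and clearances", {
  out <- apply_modifiers(ref_individual(), renal_modifiers("severe"),
                         ref_clearance(), drug = ref_drug())
  ind <- out$individual
  expect_equal(effective_fu(ref_drug(), ind), 1 - 0.843 * 0.55, tolerance = 1e-12)
  expect_equal(ind$gastric_emptying_time, 24.375)
  expect_equal(ind$hematocrit, 0.398)
  expect_identical(ind$disease_label, "CKD-severe")
  fu_dis <- 1 - 0.843 * 0.55
  expect_equal(out$clearance$renal_clearance, fu_dis * 11 * 0.06, tolerance = 1e-9)
})

test_that("both GFR unit readings are honored on an 80-kg subject", {
  ind80 <- build_reference_individual(50, 80, sex = "male")
  clr80 <- allocate_clearance(ref_drug(), ind80)
  fu_dis <- 1 - 0.843 * 0.55
  abs_read <- apply_modifiers(ind80, renal_modifiers("severe", gfr_unit = "mL/min"),
                              clr80, drug = ref_drug())
  expect_equal(abs_read$clearance$renal_clearance, fu_dis * 11 * 0.06, tolerance = 1e-9)
  perkg_read <- apply_modifiers(ind80, renal_modifiers("severe", gfr_unit = "mL/min/kg"),
                                clr80, drug = ref_drug())
  expect_equal(perkg_read$clearance$renal_clearance, fu_dis * 11 * 80 * 0.06,
               tolerance = 1e-9)
})

test_that("cirrhosis application shrinks the liver and its metabolic capacity", {
  out <- apply_modifiers(ref_individual(), cirrhosis_modifiers("CP-C"),
                         ref_clearance(), drug = ref_drug())
  expect_equal(out$individual$organ_volumes[["liver"]],
               0.7 * ref_individual()$organ_volumes[["liver"]])
  expect_lt(out$clearance$hepatic_plasma_clearance,
            ref_clearance()$hepatic_plasma_clearance)
  expect_lt(out$clearance$total_plasma_clearance,
            ref_clearance()$total_plasma_clearance)
})

test_that("applying modifiers twice is an error", {
  once <- apply_modifiers(ref_individual(), cirrhosis_modifiers("CP-A"),
                          ref_clearance(), drug = ref_drug())
  expect_error(apply_modifiers(once$individual, cirrhosis_modifiers("CP-B"),
                               once$clearance, drug = ref_drug()),
               "healthy baseline")
})

test_that("lowering the protein binding factor raises fu and the renal term", {
  # two-point sweep with everything else held fixed
  mk <- function(pbf) {
    labetapbpk:::new_disease_modifiers("CKD-moderate",
                                       protein_binding_factor = pbf,
                                       gfr = 120, gfr_unit = "mL/min")
  }
  hi <- apply_modifiers(ref_individual(), mk(1.0), ref_clearance(), drug = ref_drug())
  lo <- apply_modifiers(ref_individual(), mk(0.9), ref_clearance(), drug = ref_drug())
  expect_gt(lo$clearance$fu_effective, hi$clearance$fu_effective)
  expect_gt(lo$clearance$renal_clearance, hi$clearance$renal_clearance)
  # higher total clearance means lower AUC contribution (AUC = Dose/CL)
  expect_gt(lo$clearance$total_plasma_clearance, hi$clearance$total_plasma_clearance)
})
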