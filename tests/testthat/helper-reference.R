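# Shared fixtures, built once per test run. Everything is generated in code;
# the only files touched are the package's own plain-text data tables.

.ref_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.ref_cache[[key]])) .ref_cache[[key]] <- force(expr)
  .ref_cache[[key]]
}

ref_individual <- function() cached("ind", build_reference_individual(30, 70, sex = "male"))
ref_drug <- function() cached("drug", labetalol_parameters())

ref_partition <- function() cached("part", {
  calibrate_kp_scale(compute_partition_coefficients(ref_drug(), ref_individual()),
                     ref_individual(), 11)
})

ref_clearance <- function() cached("clr", allocate_clearance(ref_drug(), ref_individual()))

ref_system <- function() cached("sys", {
  assemble_model(ref_individual(), ref_drug(), ref_partition(), ref_clearance())
})

# long-horizon IV simulation used by several oracle tests (terminal half-life
# of the calibrated model is ~22 h, so 240 h covers > 10 half-lives)
ref_iv_sim_long <- function() cached("iv240", {
  simulate_pbpk(ref_system(), dose_event("iv_infusion", 0.5, "mg_per_kg"),
                t_end = 240, dt_out = 0.1)
})

# identity composition table: every organ identical to plasma
identity_composition <- function() {
  comp <- tissue_composition()
  plasma <- comp[comp$organ == "plasma", ]
  comp$f_water <- plasma$f_water
  comp$f_neutral_lipid <- plasma$f_neutral_lipid
  comp$f_phospholipid <- plasma$f_phospholipid
  comp
}

# reference individual with all clearances removed (GFR 0 + zero total CL)
zero_clearance_setup <- function() cached("zero_cl", {
  ind <- ref_individual()
  ind$gfr <- 0
  drug <- ref_drug()
  drug$total_body_clearance <- 0
  clr <- allocate_clearance(drug, ind)
  part <- compute_partition_coefficients(drug, ind,
                                         composition = identity_composition())
  list(individual = ind, drug = drug, clearance = clr, partition = part,
       system = assemble_model(ind, drug, part, clr))
})
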