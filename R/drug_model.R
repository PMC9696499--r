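# Drug parameters, tissue:plasma partition coefficients and clearance
# allocation.
#
# Partition coefficients come from a tissue-composition scheme in the style of
# Poulin & Theil (J Pharm Sci 2002): each tissue:plasma ratio is the ratio of
# drug-solubilizing capacity (neutral lipid, phospholipid, water) of tissue
# versus plasma, evaluated at the membrane-relevant lipophilicity
# (log D at pH 7.4 for a monoprotic base). Because composition-based schemes
# under-predict the very large distribution volume of lysosomally trapped
# bases such as labetalol, a single global multiplicative calibration factor
# (`kp_scale`) maps the implied steady-state volume of distribution onto the
# clinical 9-15.7 L/kg window (default target 11 L/kg).

#' Construct a drug parameter set
#'
#' @param molecular_weight g/mol.
#' @param pka Single basic pKa (monoprotic base convention).
#' @param logp Octanol:water log partition coefficient.
#' @param fraction_unbound Unbound fraction in plasma, in (0, 1].
#' @param intestinal_permeability Effective intestinal permeability, cm/min.
#' @param total_body_clearance Total body clearance, mL/min/kg.
#' @param specific_organ_permeability,specific_clearance Simulator-internal
#'   optimized quantities retained as metadata; they do not drive the engine.
#' @return An object of class `pbpk_drug`.
#' @export
drug_parameters <- function(molecular_weight, pka, logp, fraction_unbound,
                            intestinal_permeability, total_body_clearance,
                            specific_organ_permeability = NA_real_,
                            specific_clearance = NA_real_) {
  check_number(molecular_weight, "molecular_weight", lower = 0, strict_lower = TRUE)
  check_number(pka, "pka", lower = 0, upper = 14)
  check_number(logp, "logp", lower = -10, upper = 10)
  check_number(fraction_unbound, "fraction_unbound", lower = 0, upper = 1,
               strict_lower = TRUE)
  check_number(intestinal_permeability, "intestinal_permeability", lower = 0)
  check_number(total_body_clearance, "total_body_clearance", lower = 0)
  structure(list(
    molecular_weight = molecular_weight,
    pka = pka,
    logp = logp,
    fraction_unbound = fraction_unbound,
    intestinal_permeability = intestinal_permeability,
    total_body_clearance = total_body_clearance,
    specific_organ_permeability = specific_organ_permeability,
    specific_clearance = specific_clearance
  ), class = "pbpk_drug")
}

#' Labetalol parameter set
#'
#' Reads the packaged labetalol parameter file (molecular weight 328.412
#' g/mol, pKa 9.38, log P 2.79, fu 0.45, intestinal permeability
#' 4.67e-5 cm/min, total body clearance 15 mL/min/kg).
#'
#' @param path Optional alternative parameter CSV.
#' @return A `pbpk_drug` object.
#' @export
labetalol_parameters <- function(path = pbpk_extdata("labetalol_parameters.csv")) {
  tab <- read_pbpk_csv(path)
  val <- function(p) tab$value[match(p, tab$parameter)]
  drug_parameters(
    molecular_weight = val("molecular_weight"),
    pka = val("pka"),
    logp = val("logp"),
    fraction_unbound = val("fraction_unbound"),
    intestinal_permeability = val("intestinal_permeability"),
    total_body_clearance = val("total_body_clearance"),
    specific_organ_permeability = val("specific_organ_permeability"),
    specific_clearance = val("specific_clearance")
  )
}

#' Tissue composition table
#'
#' Fractional water, neutral lipid and phospholipid content per organ plus the
#' plasma reference phase, as shipped with the package.
#'
#' @param path Optional alternative composition CSV.
#' @return A data.frame with columns `organ`, `f_water`, `f_neutral_lipid`,
#'   `f_phospholipid`.
#' @export
tissue_composition <- function(path = pbpk_extdata("tissue_composition.csv")) {
  read_pbpk_csv(path)
}

#' Effective unbound fraction for an individual
#'
#' Disease states scale the bound fraction by the individual's
#' `protein_binding_scale` (healthy = 1):
#' `fu_eff = 1 - scale * (1 - fu_healthy)`.
#'
#' @param drug A `pbpk_drug`.
#' @param individual A `pbpk_individual`.
#' @return The effective unbound fraction.
#' @export
effective_fu <- function(drug, individual) {
  fu <- 1 - individual$protein_binding_scale * (1 - drug$fraction_unbound)
  if (fu <= 0 || fu > 1) {
    stop_field("fraction_unbound", sprintf(
      "effective unbound fraction %.4f outside (0, 1]", fu))
  }
  fu
}

# Solubilization capacity of a phase with the given composition at apparent
# membrane affinity P (phospholipid treated as 30% lipid-like, 70% water-like).
phase_capacity <- function(P, f_water, f_nl, f_ph) {
  P * (f_nl + 0.3 * f_ph) + (f_water + 0.7 * f_ph)
}

#' Compute tissue:plasma partition coefficients
#'
#' Tissue-composition scheme evaluated at log D(7.4) for a monoprotic base:
#' `Kp = capacity(tissue) / capacity(plasma)` with
#' `capacity = P*(f_nl + 0.3*f_ph) + (f_water + 0.7*f_ph)`.
#' Blood pools implicitly partition at 1. Returns the uncalibrated set
#' (`kp_scale = 1`); see [calibrate_kp_scale()].
#'
#' @param drug A `pbpk_drug`.
#' @param individual A `pbpk_individual` (supplies organ volumes for the
#'   implied Vss).
#' @param method Only `"standard"` (the composition scheme) is implemented.
#' @param composition Tissue composition table, see [tissue_composition()].
#' @return An object of class `pbpk_partition` with elements `kp` (named,
#'   one per perfused organ), `kp_scale`, and `vss_per_kg`.
#' @export
compute_partition_coefficients <- function(drug, individual,
                                           method = "standard",
                                           composition = tissue_composition()) {
  check_choice(method, "method", "standard")
  stopifnot(inherits(drug, "pbpk_drug"), inherits(individual, "pbpk_individual"))

  # neutral fraction of a monoprotic base at plasma pH, Henderson-Hasselbalch
  f_neutral <- 1 / (1 + 10^(drug$pka - 7.4))
  P <- 10^drug$logp * f_neutral  # apparent membrane affinity (log D scale)

  plasma <- composition[composition$organ == "plasma", , drop = FALSE]
  if (nrow(plasma) != 1L) stop("composition table must contain one plasma row", call. = FALSE)
  organs <- setdiff(names(individual$organ_blood_flows), character(0))
  kp <- vapply(organs, function(org) {
    row <- composition[composition$organ == org, , drop = FALSE]
    if (nrow(row) != 1L) {
      stop("no tissue composition for organ: ", org, call. = FALSE)
    }
    phase_capacity(P, row$f_water, row$f_neutral_lipid, row$f_phospholipid) /
      phase_capacity(P, plasma$f_water, plasma$f_neutral_lipid, plasma$f_phospholipid)
  }, numeric(1))
  if (any(kp <= 0)) stop("partition coefficients must be positive", call. = FALSE)

  new_partition(kp, kp_scale = 1, individual = individual)
}

new_partition <- function(kp, kp_scale, individual) {
  structure(list(
    kp = kp,
    kp_scale = kp_scale,
    vss_per_kg = implied_vss_per_kg(kp, individual)
  ), class = "pbpk_partition")
}

# Vss implied by the kp set: plasma/blood pools at unity plus kp-weighted
# perfused organ volumes, per kg body weight.
implied_vss_per_kg <- function(kp, individual) {
  v <- individual$organ_volumes
  blood <- sum(v[c("arterial_blood", "venous_blood")])
  (blood + sum(kp * v[names(kp)])) / individual$weight
}

#' Calibrate the global partition scale to a target Vss
#'
#' Applies one multiplicative factor to every tissue Kp so that the implied
#' steady-state volume of distribution matches `target_vss_per_kg` exactly
#' (closed form: Vss is affine in the scale).
#'
#' @param partition A `pbpk_partition`.
#' @param individual The `pbpk_individual` the set was computed for.
#' @param target_vss_per_kg Target Vss in L/kg, in (0, 50].
#' @return A recalibrated `pbpk_partition`.
#' @export
calibrate_kp_scale <- function(partition, individual, target_vss_per_kg) {
  stopifnot(inherits(partition, "pbpk_partition"))
  check_number(target_vss_per_kg, "target_vss_per_kg", lower = 0, upper = 50,
               strict_lower = TRUE)
  v <- individual$organ_volumes
  blood <- sum(v[c("arterial_blood", "venous_blood")])
  base_kp <- partition$kp / partition$kp_scale
  tissue_term <- sum(base_kp * v[names(base_kp)])
  scale <- (target_vss_per_kg * individual$weight - blood) / tissue_term
  if (!is.finite(scale) || scale <= 0) {
    stop("target Vss is below the blood volume floor; cannot calibrate",
         call. = FALSE)
  }
  new_partition(base_kp * scale, kp_scale = scale, individual = individual)
}

#' Allocate total clearance into renal and hepatic pathways
#'
#' Renal clearance of unchanged drug is glomerular filtration of unbound drug,
#' `CLr = fu_eff * GFR`; the remainder of the total body clearance input is
#' assigned to the liver and inverted through the well-stirred model,
#' `CLh = Qh * fu * CLint / (Qh + fu * CLint)`, to recover the unbound hepatic
#' intrinsic clearance. `Qh` is total hepatic blood flow (hepatic arterial +
#' portal).
#'
#' @param drug A `pbpk_drug` (supplies fu and total body clearance).
#' @param individual A healthy-baseline `pbpk_individual`.
#' @return An object of class `pbpk_clearance` with elements
#'   `hepatic_intrinsic_clearance` (unbound, L/h), `renal_clearance` (L/h),
#'   `total_plasma_clearance` (L/h), `hepatic_plasma_clearance` (L/h),
#'   `fu_effective`, and `liver_blood_flow` (L/h).
#' @export
allocate_clearance <- function(drug, individual) {
  stopifnot(inherits(drug, "pbpk_drug"), inherits(individual, "pbpk_individual"))
  if (!identical(individual$disease_label, "healthy")) {
    stop("allocate_clearance() requires a healthy-baseline individual; use ",
         "apply_modifiers() to derive diseased clearances", call. = FALSE)
  }
  fu <- effective_fu(drug, individual)
  cl_total <- ml_per_min_to_l_per_h(drug$total_body_clearance * individual$weight)
  cl_renal <- fu * ml_per_min_to_l_per_h(individual$gfr)
  q_h <- individual$organ_blood_flows[["liver"]] + individual$organ_blood_flows[["gut"]]
  cl_hep <- cl_total - cl_renal
  if (cl_hep < 0) {
    stop("renal filtration clearance exceeds the total body clearance input",
         call. = FALSE)
  }
  if (cl_hep >= q_h) {
    stop(sprintf(paste0(
      "infeasible clearance split: required hepatic plasma clearance ",
      "%.1f L/h meets or exceeds total liver blood flow %.1f L/h ",
      "(well-stirred flow limit)"), cl_hep, q_h), call. = FALSE)
  }
  fu_clint <- if (cl_hep == 0) 0 else q_h * cl_hep / (q_h - cl_hep)
  new_clearance(
    hepatic_intrinsic_clearance = fu_clint / fu,
    renal_clearance = cl_renal,
    fu_effective = fu,
    liver_blood_flow = q_h
  )
}

new_clearance <- function(hepatic_intrinsic_clearance, renal_clearance,
                          fu_effective, liver_blood_flow) {
  fu_clint <- fu_effective * hepatic_intrinsic_clearance
  cl_hep <- liver_blood_flow * fu_clint / (liver_blood_flow + fu_clint)
  structure(list(
    hepatic_intrinsic_clearance = hepatic_intrinsic_clearance,
    renal_clearance = renal_clearance,
    hepatic_plasma_clearance = cl_hep,
    total_plasma_clearance = cl_hep + renal_clearance,
    fu_effective = fu_effective,
    liver_blood_flow = liver_blood_flow
  ), class = "pbpk_clearance")
}

#' @export
print.pbpk_clearance <- function(x, ...) {
  cat(sprintf("<pbpk_clearance> total %.2f L/h = hepatic %.2f + renal %.2f (fu %.3f)\n",
              x$total_plasma_clearance, x$hepatic_plasma_clearance,
              x$renal_clearance, x$fu_effective))
  invisible(x)
}
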