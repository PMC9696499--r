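# Disease extrapolation: liver cirrhosis (Child-Pugh A/B/C) and chronic
# kidney disease (moderate/severe).
#
# A DiseaseModifiers object carries absolute replacement values (hematocrit,
# GFR, GI times) and dimensionless factors (liver volume, protein binding,
# hepatic intrinsic clearance, liver arterial flow) applied to a healthy
# baseline. The severe-CKD row is fully determined by the published
# physiological changes (gastric emptying 24.375 min, small-intestine transit
# 2.94 h, hematocrit 0.398, protein binding factor 0.843, GFR 11); moderate
# CKD interpolates midway between healthy and severe by default. The printed
# GFR unit (mL/min/kg) exceeds any healthy GFR and is treated as a
# typographical artifact: the default reading is 11 mL/min absolute, with the
# literal per-kg reading available via `gfr_unit = "mL/min/kg"`.

CKD_SEVERE <- list(
  gastric_emptying_time = 24.375,        # min
  small_intestine_transit_time = 2.94,   # h
  hematocrit = 0.398,
  protein_binding_factor = 0.843,
  gfr = 11                               # value; unit per `gfr_unit`
)

DISEASE_LABELS <- c("healthy", "CP-A", "CP-B", "CP-C", "CKD-moderate", "CKD-severe")

new_disease_modifiers <- function(label, liver_volume_factor = 1,
                                  hematocrit = NA_real_,
                                  protein_binding_factor = 1,
                                  gfr = NA_real_, gfr_unit = "mL/min",
                                  gfr_severity_fraction = 1,
                                  gastric_emptying_time = NA_real_,
                                  small_intestine_transit_time = NA_real_,
                                  hepatic_intrinsic_clearance_factor = 1,
                                  liver_flow_factor = 1) {
  check_choice(label, "label", DISEASE_LABELS)
  for (f in c(liver_volume_factor, protein_binding_factor,
              hepatic_intrinsic_clearance_factor, liver_flow_factor)) {
    if (!is.finite(f) || f <= 0 || f > 2) {
      stop_field("factors", "all factors must lie in (0, 2]")
    }
  }
  if (!is.na(hematocrit) && (hematocrit <= 0 || hematocrit >= 1)) {
    stop_field("hematocrit", "must be in (0, 1)")
  }
  if (!is.na(gfr) && gfr < 0) stop_field("gfr", "must be >= 0")
  check_choice(gfr_unit, "gfr_unit", c("mL/min", "mL/min/kg"))
  structure(list(
    label = label,
    liver_volume_factor = liver_volume_factor,
    hematocrit = hematocrit,
    protein_binding_factor = protein_binding_factor,
    gfr = gfr,
    gfr_unit = gfr_unit,
    gfr_severity_fraction = gfr_severity_fraction,
    gastric_emptying_time = gastric_emptying_time,
    small_intestine_transit_time = small_intestine_transit_time,
    hepatic_intrinsic_clearance_factor = hepatic_intrinsic_clearance_factor,
    liver_flow_factor = liver_flow_factor
  ), class = "pbpk_disease_modifiers")
}

#' Default Child-Pugh modifier table
#'
#' @param path Optional alternative CSV with columns
#'   `label, field, value, unit, provenance`.
#' @return The long-format modifier table as a data.frame.
#' @export
cirrhosis_modifier_table <- function(path = pbpk_extdata("cirrhosis_modifiers.csv")) {
  read_pbpk_csv(path)
}

#' Cirrhosis physiological modifiers for a Child-Pugh class
#'
#' Returns the modifier row for `cp_class` from `table`. If a user-supplied
#' table is not monotone in severity (liver volume, GFR and intrinsic
#' clearance factors non-increasing A -> C), a warning is raised.
#'
#' @param cp_class `"CP-A"`, `"CP-B"` or `"CP-C"`.
#' @param table Long-format modifier table, see [cirrhosis_modifier_table()].
#' @return A `pbpk_disease_modifiers` object.
#' @export
cirrhosis_modifiers <- function(cp_class, table = cirrhosis_modifier_table()) {
  check_choice(cp_class, "cp_class", c("CP-A", "CP-B", "CP-C"))
  get_val <- function(label, field) {
    v <- table$value[table$label == label & table$field == field]
    if (length(v) != 1L) {
      stop(sprintf("modifier table has no unique row for (%s, %s)", label, field),
           call. = FALSE)
    }
    v
  }
  for (f in c("liver_volume_factor", "gfr", "hepatic_intrinsic_clearance_factor")) {
    vals <- vapply(c("CP-A", "CP-B", "CP-C"), get_val, numeric(1), field = f)
    if (any(diff(vals) > 0)) {
      warning("modifier table is not monotone in severity for field: ", f,
              call. = FALSE)
    }
  }
  new_disease_modifiers(
    label = cp_class,
    liver_volume_factor = get_val(cp_class, "liver_volume_factor"),
    hematocrit = get_val(cp_class, "hematocrit"),
    protein_binding_factor = get_val(cp_class, "protein_binding_factor"),
    gfr = get_val(cp_class, "gfr"),
    gfr_unit = "mL/min",
    hepatic_intrinsic_clearance_factor = get_val(cp_class, "hepatic_intrinsic_clearance_factor"),
    liver_flow_factor = get_val(cp_class, "liver_flow_factor")
  )
}

#' Chronic kidney disease physiological modifiers
#'
#' `"severe"` returns the five published physiological changes exactly;
#' `"moderate"` interpolates between the healthy baseline and severe values
#' (default: midpoint).
#'
#' @param severity `"moderate"` or `"severe"`.
#' @param gfr_unit Interpretation of the GFR value: `"mL/min"` (default;
#'   treats the printed per-kg unit as a typographical artifact) or the
#'   literal `"mL/min/kg"` reading, resolved against body weight when the
#'   modifiers are applied.
#' @param interpolation Severity fraction for `"moderate"` (0 = healthy,
#'   1 = severe; default 0.5).
#' @param healthy Baseline list with elements `gastric_emptying_time` (min),
#'   `small_intestine_transit_time` (h), `hematocrit`, `protein_binding_factor`
#'   and `gfr` (mL/min); defaults to the package's healthy defaults.
#' @return A `pbpk_disease_modifiers` object.
#' @export
renal_modifiers <- function(severity = c("moderate", "severe"),
                            gfr_unit = c("mL/min", "mL/min/kg"),
                            interpolation = 0.5,
                            healthy = list(
                              gastric_emptying_time = HEALTHY_DEFAULTS$gastric_emptying_time,
                              small_intestine_transit_time = HEALTHY_DEFAULTS$small_intestine_transit_time,
                              hematocrit = HEALTHY_DEFAULTS$hematocrit,
                              protein_binding_factor = 1,
                              gfr = HEALTHY_DEFAULTS$gfr)) {
  severity <- match.arg(severity)
  gfr_unit <- match.arg(gfr_unit)
  check_number(interpolation, "interpolation", lower = 0, upper = 1)
  f <- if (severity == "severe") 1 else interpolation
  lerp <- function(a, b) (1 - f) * a + f * b
  gfr_val <- if (gfr_unit == "mL/min") lerp(healthy$gfr, CKD_SEVERE$gfr) else CKD_SEVERE$gfr
  new_disease_modifiers(
    label = paste0("CKD-", severity),
    hematocrit = lerp(healthy$hematocrit, CKD_SEVERE$hematocrit),
    protein_binding_factor = lerp(healthy$protein_binding_factor,
                                  CKD_SEVERE$protein_binding_factor),
    gfr = gfr_val,
    gfr_unit = gfr_unit,
    gfr_severity_fraction = f,
    gastric_emptying_time = lerp(healthy$gastric_emptying_time,
                                 CKD_SEVERE$gastric_emptying_time),
    small_intestine_transit_time = lerp(healthy$small_intestine_transit_time,
                                        CKD_SEVERE$small_intestine_transit_time)
  )
}

#' Healthy (identity) modifiers
#' @return A `pbpk_disease_modifiers` object that leaves its inputs unchanged.
#' @export
healthy_modifiers <- function() new_disease_modifiers("healthy")

modifiers_for_label <- function(label, gfr_unit = "mL/min") {
  switch(label,
         "healthy" = healthy_modifiers(),
         "CP-A" = , "CP-B" = , "CP-C" = cirrhosis_modifiers(label),
         "CKD-moderate" = renal_modifiers("moderate", gfr_unit = gfr_unit),
         "CKD-severe" = renal_modifiers("severe", gfr_unit = gfr_unit),
         stop("unknown disease label: ", label, call. = FALSE))
}

#' Apply disease modifiers to a healthy individual and clearance model
#'
#' Absolute fields are replaced, factor fields are multiplied. The effective
#' unbound fraction becomes `1 - PBF * (1 - fu_healthy)` (the protein binding
#' factor scales the bound fraction), the hepatic unbound intrinsic clearance
#' is scaled by its factor, and the renal clearance is recomputed as
#' `fu_disease * GFR_disease`. The `"healthy"` label is the identity. Applying
#' modifiers to an already-diseased individual is an error.
#'
#' @param individual A healthy-baseline `pbpk_individual`.
#' @param modifiers A `pbpk_disease_modifiers`.
#' @param clearance The healthy-baseline `pbpk_clearance` for the same
#'   individual.
#' @param drug The `pbpk_drug` (needed to recompute the unbound fraction).
#' @return A list with elements `individual` and `clearance`.
#' @export
apply_modifiers <- function(individual, modifiers, clearance,
                            drug = labetalol_parameters()) {
  stopifnot(inherits(individual, "pbpk_individual"),
            inherits(modifiers, "pbpk_disease_modifiers"),
            inherits(clearance, "pbpk_clearance"))
  if (!identical(individual$disease_label, "healthy")) {
    stop("modifiers must be applied to a healthy baseline; individual already has label: ",
         individual$disease_label, call. = FALSE)
  }
  if (identical(modifiers$label, "healthy")) {
    return(list(individual = individual, clearance = clearance))
  }

  ind <- individual
  ind$organ_volumes[["liver"]] <- ind$organ_volumes[["liver"]] * modifiers$liver_volume_factor
  if (!is.na(modifiers$hematocrit)) ind$hematocrit <- modifiers$hematocrit
  ind$protein_binding_scale <- ind$protein_binding_scale * modifiers$protein_binding_factor
  if (!is.na(modifiers$gastric_emptying_time)) {
    ind$gastric_emptying_time <- modifiers$gastric_emptying_time
  }
  if (!is.na(modifiers$small_intestine_transit_time)) {
    ind$small_intestine_transit_time <- modifiers$small_intestine_transit_time
  }
  if (modifiers$liver_flow_factor != 1) {
    old <- ind$organ_blood_flows[["liver"]]
    new <- old * modifiers$liver_flow_factor
    ind$organ_blood_flows[["liver"]] <- new
    # keep flow conservation: the difference is routed through 'rest'
    ind$organ_blood_flows[["rest"]] <- ind$organ_blood_flows[["rest"]] + (old - new)
  }
  if (!is.na(modifiers$gfr)) {
    if (modifiers$gfr_unit == "mL/min/kg") {
      severe_abs <- modifiers$gfr * ind$weight
      f <- modifiers$gfr_severity_fraction
      ind$gfr <- (1 - f) * individual$gfr + f * severe_abs
    } else {
      ind$gfr <- modifiers$gfr
    }
  }
  ind$disease_label <- modifiers$label

  fu_dis <- effective_fu(drug, ind)  # errors if outside (0, 1]
  clint_dis <- clearance$hepatic_intrinsic_clearance *
    modifiers$hepatic_intrinsic_clearance_factor
  q_h <- ind$organ_blood_flows[["liver"]] + ind$organ_blood_flows[["gut"]]
  clr_dis <- fu_dis * ml_per_min_to_l_per_h(ind$gfr)
  clr_new <- new_clearance(
    hepatic_intrinsic_clearance = clint_dis,
    renal_clearance = clr_dis,
    fu_effective = fu_dis,
    liver_blood_flow = q_h
  )
  validate_individual(ind)
  list(individual = ind, clearance = clr_new)
}
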