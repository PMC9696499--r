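# Reference adult physiology and virtual-population sampling.
#
# The reference anatomy is a single documented 70-kg adult table of organ
# volumes and regional blood flows (see inst/extdata/reference_physiology.csv).
# All organs and flows scale linearly with body weight relative to 70 kg;
# non-lung regional flows sum exactly to the cardiac output, and the lung
# carries the whole cardiac output in series.

HEALTHY_DEFAULTS <- list(
  hematocrit = 0.45,            # fraction
  gfr = 120,                    # mL/min
  protein_binding_scale = 1.0,  # multiplier on the bound fraction
  gastric_emptying_time = 15,   # min (half-emptying time)
  small_intestine_transit_time = 3.3  # h (total mean transit)
)

REFERENCE_WEIGHT_KG <- 70
REFERENCE_HEIGHT_CM <- c(male = 176, female = 163)

#' Reference adult physiology table
#'
#' Organ volumes (L) and regional blood flows (L/h) for the 70-kg reference
#' adult. The gut flow is the portal inflow to the liver and the liver flow is
#' the hepatic arterial flow; blood pools carry zero nominal regional flow.
#'
#' @param path Optional path to an alternative table with the same columns
#'   (`organ`, `volume_L_per_70kg`, `flow_L_per_h_per_70kg`).
#' @return A data.frame with one row per organ.
#' @export
reference_physiology <- function(path = pbpk_extdata("reference_physiology.csv")) {
  tab <- read_pbpk_csv(path)
  required <- c("organ", "volume_L_per_70kg", "flow_L_per_h_per_70kg")
  if (!all(required %in% names(tab))) {
    stop("reference physiology table must have columns: ",
         paste(required, collapse = ", "), call. = FALSE)
  }
  tab
}

#' Build a healthy reference individual
#'
#' Constructs a complete healthy adult physiology: organ volumes and blood
#' flows scaled linearly to body weight from the packaged 70-kg reference
#' table, plus conventional healthy defaults (hematocrit 0.45, GFR 120 mL/min,
#' gastric half-emptying time 15 min, small-intestine transit 3.3 h, protein
#' binding scale 1).
#'
#' @param age Age in years, within 18-80.
#' @param weight Body weight in kg, within 40-150.
#' @param height Height in cm; defaults to the sex-specific reference
#'   (176 cm male, 163 cm female).
#' @param sex `"male"` or `"female"`.
#' @param physiology Reference physiology table, see [reference_physiology()].
#' @return An object of class `pbpk_individual`.
#' @examples
#' ind <- build_reference_individual(30, 70, sex = "male")
#' ind$organ_volumes[["liver"]]
#' @export
build_reference_individual <- function(age, weight, height = NULL,
                                       sex = c("male", "female"),
                                       physiology = reference_physiology()) {
  sex <- match.arg(sex)
  check_number(age, "age", lower = 18, upper = 80)
  check_number(weight, "weight", lower = 40, upper = 150)
  if (is.null(height)) height <- REFERENCE_HEIGHT_CM[[sex]]
  check_number(height, "height", lower = 120, upper = 220)

  scale <- weight / REFERENCE_WEIGHT_KG
  volumes <- stats::setNames(physiology$volume_L_per_70kg * scale, physiology$organ)
  flows_all <- stats::setNames(physiology$flow_L_per_h_per_70kg * scale, physiology$organ)
  flows <- flows_all[flows_all > 0]  # perfused organs only (blood pools are conduits)
  cardiac_output <- flows[["lung"]]

  ind <- structure(list(
    age = age,
    weight = weight,
    height = height,
    sex = sex,
    hematocrit = HEALTHY_DEFAULTS$hematocrit,
    gfr = HEALTHY_DEFAULTS$gfr,
    protein_binding_scale = HEALTHY_DEFAULTS$protein_binding_scale,
    gastric_emptying_time = HEALTHY_DEFAULTS$gastric_emptying_time,
    small_intestine_transit_time = HEALTHY_DEFAULTS$small_intestine_transit_time,
    organ_volumes = volumes,
    organ_blood_flows = flows,
    cardiac_output = cardiac_output,
    disease_label = "healthy"
  ), class = "pbpk_individual")
  validate_individual(ind)
  ind
}

validate_individual <- function(ind) {
  stopifnot(inherits(ind, "pbpk_individual"))
  if (any(ind$organ_volumes <= 0)) stop_field("organ_volumes", "must be strictly positive")
  if (any(ind$organ_blood_flows <= 0)) stop_field("organ_blood_flows", "must be strictly positive")
  if (ind$hematocrit <= 0 || ind$hematocrit >= 1) {
    stop_field("hematocrit", "must be in (0, 1)")
  }
  if (ind$gfr < 0) stop_field("gfr", "must be non-negative")
  non_lung <- ind$organ_blood_flows[setdiff(names(ind$organ_blood_flows), "lung")]
  rel <- abs(sum(non_lung) - ind$cardiac_output) / ind$cardiac_output
  if (rel > 1e-6) {
    stop("flow conservation violated: non-lung flows differ from cardiac output by ",
         signif(rel, 3), " relative", call. = FALSE)
  }
  invisible(ind)
}

#' @export
print.pbpk_individual <- function(x, ...) {
  cat(sprintf("<pbpk_individual> %s, %g y, %g kg, %g cm [%s]\n",
              x$sex, x$age, x$weight, x$height, x$disease_label))
  cat(sprintf("  cardiac output %.1f L/h; hct %.3f; GFR %g mL/min; GET %g min; SITT %g h\n",
              x$cardiac_output, x$hematocrit, x$gfr,
              x$gastric_emptying_time, x$small_intestine_transit_time))
  invisible(x)
}

#' Specify a virtual population
#'
#' @param n Number of subjects (>= 1).
#' @param age_range Length-2 numeric `(min, max)` in years (may be degenerate).
#' @param weight_range Length-2 numeric `(min, max)` in kg, or `"unreported"`
#'   to apply the documented 70-kg reference default.
#' @param female_fraction Probability that a sampled subject is female.
#' @param seed Integer seed making the sampling reproducible.
#' @return An object of class `pbpk_population_spec`.
#' @export
population_spec <- function(n, age_range, weight_range = "unreported",
                            female_fraction = 0, seed = 1L) {
  check_number(n, "n", lower = 1)
  if (identical(weight_range, "unreported")) {
    weight_range <- c(REFERENCE_WEIGHT_KG, REFERENCE_WEIGHT_KG)
    weight_assumed <- TRUE
  } else {
    weight_assumed <- FALSE
  }
  if (length(age_range) != 2L || any(!is.finite(age_range)) || age_range[1] > age_range[2]) {
    stop_field("age_range", "must be a non-decreasing (min, max) pair")
  }
  if (length(weight_range) != 2L || any(!is.finite(weight_range)) ||
      weight_range[1] > weight_range[2]) {
    stop_field("weight_range", "must be a non-decreasing (min, max) pair or \"unreported\"")
  }
  check_number(female_fraction, "female_fraction", lower = 0, upper = 1)
  structure(list(
    n = as.integer(n),
    age_range = as.numeric(age_range),
    weight_range = as.numeric(weight_range),
    female_fraction = female_fraction,
    seed = as.integer(seed),
    weight_assumed = weight_assumed
  ), class = "pbpk_population_spec")
}

#' Sample a virtual population
#'
#' Draws `spec$n` healthy individuals: age and weight uniform over their
#' ranges, sex Bernoulli with the specified female fraction, height fixed at
#' the sex-specific reference. Sampling is bitwise reproducible for a given
#' seed and leaves the caller's RNG state untouched.
#'
#' @param spec A [population_spec()].
#' @param physiology Reference physiology table.
#' @return A list of `pbpk_individual` objects.
#' @export
sample_population <- function(spec, physiology = reference_physiology()) {
  stopifnot(inherits(spec, "pbpk_population_spec"))
  with_seed(spec$seed, {
    lapply(seq_len(spec$n), function(i) {
      age <- stats::runif(1, spec$age_range[1], spec$age_range[2])
      weight <- stats::runif(1, spec$weight_range[1], spec$weight_range[2])
      sex <- if (stats::runif(1) < spec$female_fraction) "female" else "male"
      build_reference_individual(age, weight, sex = sex, physiology = physiology)
    })
  })
}
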