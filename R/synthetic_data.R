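# Synthetic "observed" clinical data generation and the eight study-design
# fixtures driving every scenario.
#
# The generator emulates the structure of sparse clinical PK datasets: a
# sparse sampling grid (minutes-dense early, hourly later), multiplicative
# log-normal residual error around a known true profile, and small cohorts.
# It makes no attempt to recreate the digitized profiles of the source
# studies; observed data enter the qualification pipeline only through the
# printed PK-parameter tables.

#' Sparse clinical sampling grid
#'
#' 5, 10, 20, 30, 45, 60 and 90 minutes, then hourly to `t_end`.
#'
#' @param t_end Last sampling time, h.
#' @return Numeric vector of times in h.
#' @export
clinical_sampling_times <- function(t_end = 12) {
  check_number(t_end, "t_end", lower = 2)
  sort(unique(c(c(5, 10, 20, 30, 45, 60, 90) / 60, seq(2, floor(t_end), by = 1), t_end)))
}

#' Residual-error model for synthetic observations
#'
#' @param residual_cv Coefficient of variation of the multiplicative
#'   log-normal residual error, in `[0, 1)`.
#' @param sampling_times Strictly increasing sampling times, h.
#' @param seed Integer seed.
#' @return An object of class `pbpk_noise_model`.
#' @export
noise_model <- function(residual_cv = 0.2, sampling_times = clinical_sampling_times(),
                        seed = 1L) {
  check_number(residual_cv, "residual_cv", lower = 0, upper = 1, strict_upper = TRUE)
  if (any(diff(sampling_times) <= 0)) {
    stop_field("sampling_times", "must be strictly increasing")
  }
  structure(list(residual_cv = residual_cv,
                 sampling_times = as.numeric(sampling_times),
                 seed = as.integer(seed)),
            class = "pbpk_noise_model")
}

#' The eight study scenarios
#'
#' Loads the packaged study-design table (five healthy profiles, two chronic
#' liver disease profiles modeled as Child-Pugh A, one severe renal failure
#' profile) into scenario objects: dose event, cohort specification and the
#' matching observed PK records. Unreported weights resolve to the documented
#' 70-kg reference default, flagged via the cohort's `weight_assumed`.
#'
#' @param designs_path,observed_path Optional alternative fixture CSVs.
#' @return A list of `pbpk_scenario` objects, one per study.
#' @export
study_fixtures <- function(designs_path = pbpk_extdata("study_designs.csv"),
                           observed_path = pbpk_extdata("observed_pk.csv")) {
  designs <- read_pbpk_csv(designs_path)
  observed <- observed_table_reader(observed_path)
  lapply(seq_len(nrow(designs)), function(i) {
    row <- designs[i, ]
    route <- if (row$route == "iv") "iv_infusion" else "oral"
    basis <- if (row$dose_unit == "mg/kg") "mg_per_kg" else "absolute_mg"
    dose <- dose_event(route, amount = row$dose, amount_basis = basis)
    weight_range <- if (identical(row$weight_reported, "yes")) {
      c(row$weight_min, row$weight_max)
    } else {
      "unreported"
    }
    cohort <- population_spec(
      n = row$n_subjects,
      age_range = c(row$age_min, row$age_max),
      weight_range = weight_range,
      female_fraction = row$n_female / row$n_subjects,
      seed = row$study_id
    )
    structure(list(
      id = row$study_id,
      population = row$population,
      route = row$route,
      dose = dose,
      cohort = cohort,
      observed = observed[observed$study_id == row$study_id, , drop = FALSE]
    ), class = "pbpk_scenario")
  })
}

#' @export
print.pbpk_scenario <- function(x, ...) {
  cat(sprintf("<pbpk_scenario> study %d: %s, %s, %g %s, n=%d\n",
              x$id, x$population, x$route, x$dose$amount,
              ifelse(x$dose$amount_basis == "mg_per_kg", "mg/kg", "mg"),
              x$cohort$n))
  invisible(x)
}

#' Generate a synthetic observed profile
#'
#' Interpolates the true profile at the noise model's sampling times and
#' multiplies each point by a mean-one log-normal deviate with the requested
#' coefficient of variation. `residual_cv = 0` returns the interpolated truth
#' exactly; a fixed seed makes the dataset reproducible.
#'
#' @param true_profile A `pbpk_profile` spanning all sampling times.
#' @param noise A `pbpk_noise_model`.
#' @return A `pbpk_profile` with attribute `"provenance" = "synthetic"`.
#' @export
generate_observed <- function(true_profile, noise) {
  stopifnot(inherits(true_profile, "pbpk_profile"), inherits(noise, "pbpk_noise_model"))
  ts <- noise$sampling_times
  if (min(ts) < min(true_profile$time) || max(ts) > max(true_profile$time)) {
    stop_field("sampling_times", "must lie within the true profile's span")
  }
  truth <- stats::approx(true_profile$time, true_profile$concentration, xout = ts)$y
  if (noise$residual_cv > 0) {
    sdlog <- sqrt(log(1 + noise$residual_cv^2))
    eps <- with_seed(noise$seed,
                     stats::rlnorm(length(ts), meanlog = -sdlog^2 / 2, sdlog = sdlog))
    obs <- truth * eps
  } else {
    obs <- truth
  }
  out <- concentration_profile(ts, obs, dose = true_profile$dose,
                               weight = true_profile$weight)
  attr(out, "provenance") <- "synthetic"
  out
}

#' Parameter-recovery experiment
#'
#' Simulates the true profile for a scenario's mid-demographic reference
#' subject, then repeatedly generates synthetic cohorts with the given noise
#' model, runs NCA on every synthetic profile, and summarizes the bias and
#' RMSE of the cohort-mean clearance and Cmax against (a) the engine truth
#' and (b) the noise-free NCA estimate on the same sampling grid (which
#' isolates residual-error bias from sparse-sampling bias).
#'
#' @param scenario A `pbpk_scenario` (see [study_fixtures()]).
#' @param noise A `pbpk_noise_model`.
#' @param replicates Number of replicate synthetic cohorts (>= 1).
#' @param t_end Simulation and sampling horizon, h (default 48 h).
#' @param terminal_points Terminal samples for the lambda-z regression.
#'   The default 12 (an 11-h window on the hourly tail) is wider than the
#'   dense-profile NCA default of 3: with 20% residual error the decay over a
#'   2-h window is smaller than the noise, and a 3-point fit frequently has a
#'   non-negative slope, leaving clearance inestimable.
#' @param gfr_unit GFR unit interpretation for CKD scenarios.
#' @return A list with `truth` (engine clearance and dense-grid NCA),
#'   `noisefree` (NCA on the noise-free sampled profile), `replicates`
#'   (per-replicate cohort means over subjects with an estimable terminal
#'   phase, plus `n_estimable`) and `summary` (bias and RMSE).
#' @export
recovery_experiment <- function(scenario, noise, replicates = 20L, t_end = 48,
                                terminal_points = 12L, gfr_unit = "mL/min") {
  stopifnot(inherits(scenario, "pbpk_scenario"), inherits(noise, "pbpk_noise_model"))
  replicates <- as.integer(replicates)
  if (replicates < 1L) stop_field("replicates", "must be >= 1")

  subject <- scenario_reference_subject(scenario, gfr_unit = gfr_unit)
  sim <- simulate_pbpk(subject$system, scenario$dose, t_end = t_end)
  truth_profile <- as_profile(sim)
  truth_nca <- nca_summary(truth_profile)
  cl_true <- subject$clearance$total_plasma_clearance

  sample_noise <- noise_model(0, sampling_times = noise$sampling_times[
    noise$sampling_times <= t_end], seed = noise$seed)
  noisefree <- nca_summary(generate_observed(truth_profile, sample_noise),
                           terminal_points = terminal_points)

  n_sub <- scenario$cohort$n
  reps <- lapply(seq_len(replicates), function(r) {
    ests <- lapply(seq_len(n_sub), function(j) {
      nm <- noise_model(noise$residual_cv,
                        sampling_times = sample_noise$sampling_times,
                        seed = noise$seed + 1000L * r + j)
      nca_summary(generate_observed(truth_profile, nm),
                  terminal_points = terminal_points)
    })
    cls <- vapply(ests, function(e) e$clearance, numeric(1))
    data.frame(
      replicate = r,
      cl_mean = mean(cls, na.rm = TRUE),
      n_estimable = sum(is.finite(cls)),
      cmax_mean = mean(vapply(ests, function(e) e$cmax, numeric(1)))
    )
  })
  reps <- do.call(rbind, reps)

  summarize <- function(est, ref) {
    c(bias = mean(est - ref, na.rm = TRUE) / ref,
      rmse = sqrt(mean((est - ref)^2, na.rm = TRUE)) / ref)
  }
  list(
    truth = list(clearance = cl_true, nca = truth_nca),
    noisefree = noisefree,
    replicates = reps,
    summary = list(
      cl_vs_truth = summarize(reps$cl_mean, cl_true),
      cl_vs_noisefree = summarize(reps$cl_mean, noisefree$clearance),
      cmax_vs_noisefree = summarize(reps$cmax_mean, noisefree$cmax)
    )
  )
}

#' Assemble the model for a scenario's mid-demographic reference subject
#'
#' Builds one deterministic subject at the midpoint of the scenario's age and
#' weight ranges (male, reference height), applies the scenario's disease
#' modifiers, and returns the calibrated, assembled system. Useful for
#' engine-level checks that do not need population spread.
#'
#' @param scenario A `pbpk_scenario`.
#' @param target_vss Vss calibration target, L/kg.
#' @param gfr_unit GFR unit interpretation for CKD scenarios.
#' @param drug Drug parameter set.
#' @return A list with `individual`, `clearance`, `partition` and `system`.
#' @export
scenario_reference_subject <- function(scenario, target_vss = 11,
                                       gfr_unit = "mL/min",
                                       drug = labetalol_parameters()) {
  age <- mean(scenario$cohort$age_range)
  weight <- mean(scenario$cohort$weight_range)
  ind <- build_reference_individual(age, weight, sex = "male")
  clr <- allocate_clearance(drug, ind)
  if (!identical(scenario$population, "healthy")) {
    mods <- modifiers_for_label(scenario$population, gfr_unit = gfr_unit)
    out <- apply_modifiers(ind, mods, clr, drug = drug)
    ind <- out$individual; clr <- out$clearance
  }
  part <- calibrate_kp_scale(compute_partition_coefficients(drug, ind), ind, target_vss)
  list(individual = ind, clearance = clr, partition = part,
       system = assemble_model(ind, drug, part, clr))
}
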