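# Non-compartmental analysis of concentration-time profiles.

#' Construct a concentration-time profile
#'
#' @param time Strictly increasing sampling times, h (>= 3 points).
#' @param concentration Non-negative concentrations, ng/mL.
#' @param dose Optional `pbpk_dose` the profile arose from (enables CL).
#' @param weight Body weight in kg (used to resolve mg/kg doses).
#' @return An object of class `pbpk_profile`.
#' @export
concentration_profile <- function(time, concentration, dose = NULL, weight = NA_real_) {
  if (length(time) < 3L) stop_field("time", "profile needs at least 3 points")
  if (length(time) != length(concentration)) {
    stop_field("concentration", "must match `time` in length")
  }
  if (any(!is.finite(time)) || any(diff(time) <= 0)) {
    stop_field("time", "must be finite and strictly increasing")
  }
  if (any(!is.finite(concentration)) || any(concentration < 0)) {
    stop_field("concentration", "must be finite and non-negative")
  }
  if (!is.null(dose)) stopifnot(inherits(dose, "pbpk_dose"))
  structure(list(time = as.numeric(time),
                 concentration = as.numeric(concentration),
                 dose = dose, weight = weight),
            class = "pbpk_profile")
}

#' Extract the venous plasma profile of a simulation
#'
#' @param result A `pbpk_simulation`.
#' @return A `pbpk_profile` carrying the simulation's first dose and weight.
#' @export
as_profile <- function(result) {
  stopifnot(inherits(result, "pbpk_simulation"))
  concentration_profile(result$time, result$plasma_concentration,
                        dose = result$doses[[1L]],
                        weight = result$system$individual$weight)
}

trapezoid_auc <- function(t, c, method = "linear") {
  dt <- diff(t)
  c1 <- c[-length(c)]; c2 <- c[-1]
  seg <- (c1 + c2) / 2 * dt
  if (method == "linlog") {
    # log-trapezoid on strictly declining positive segments
    declining <- c2 < c1 & c2 > 0 & c1 > 0
    seg[declining] <- (c1[declining] - c2[declining]) /
      log(c1[declining] / c2[declining]) * dt[declining]
  }
  sum(seg)
}

#' Non-compartmental PK summary
#'
#' Linear-trapezoid AUC to the last sample, terminal slope by unweighted
#' log-linear regression on the last `terminal_points` positive
#' concentrations, `AUC(0-inf) = AUC(0-t) + C_last / lambda_z`, and clearance
#' from the dose and extrapolated AUC (IV: CL; oral: apparent CL/F). An
#' all-zero profile yields zero AUC and Cmax with the terminal phase flagged
#' undefined rather than an error.
#'
#' @param profile A `pbpk_profile`.
#' @param terminal_points Number of terminal samples for the regression
#'   (default 3).
#' @param auc_method `"linear"` (default) or `"linlog"`.
#' @return An object of class `pbpk_nca`: `cmax`, `tmax`, `auc_0_t`,
#'   `auc_0_inf`, `lambda_z` (1/h), `half_life` (h), `clearance` (L/h),
#'   `clearance_type` (`"CL"` or `"CL/F"`), `lambda_z_r_squared` and
#'   `lambda_z_flagged` (TRUE when undefined or adjusted R^2-free fit
#'   quality < 0.9).
#' @export
nca_summary <- function(profile, terminal_points = 3L,
                        auc_method = c("linear", "linlog")) {
  stopifnot(inherits(profile, "pbpk_profile"))
  auc_method <- match.arg(auc_method)
  terminal_points <- as.integer(terminal_points)
  if (terminal_points < 3L) stop_field("terminal_points", "must be >= 3")
  t <- profile$time; c <- profile$concentration

  cmax <- max(c)
  tmax <- t[which.max(c)]
  auc_t <- trapezoid_auc(t, c, auc_method)

  pos <- which(c > 0)
  lambda <- NA_real_; r2 <- NA_real_; flagged <- TRUE
  if (length(pos) >= terminal_points) {
    tail_idx <- utils::tail(pos, terminal_points)
    fit <- stats::lm(log(c[tail_idx]) ~ t[tail_idx])
    slope <- unname(stats::coef(fit)[2])
    y <- log(c[tail_idx])
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
    if (is.finite(slope) && slope < 0) {
      lambda <- -slope
      flagged <- !is.finite(r2) || r2 < 0.9
    }
  }
  auc_inf <- if (is.finite(lambda)) auc_t + c[length(c)] / lambda else NA_real_
  half_life <- if (is.finite(lambda)) log(2) / lambda else NA_real_

  clearance <- NA_real_; clearance_type <- NA_character_
  if (!is.null(profile$dose) && is.finite(auc_inf) && auc_inf > 0) {
    dose_ng <- resolve_dose_ng(profile$dose, profile$weight)
    clearance <- dose_ng / auc_inf / 1000  # ng / (ng.h/mL) = mL/h -> L/h
    clearance_type <- if (profile$dose$route == "oral") "CL/F" else "CL"
  }

  structure(list(cmax = cmax, tmax = tmax, auc_0_t = auc_t, auc_0_inf = auc_inf,
                 lambda_z = lambda, half_life = half_life,
                 clearance = clearance, clearance_type = clearance_type,
                 lambda_z_r_squared = r2, lambda_z_flagged = flagged),
            class = "pbpk_nca")
}

#' @export
print.pbpk_nca <- function(x, ...) {
  cat(sprintf("<pbpk_nca> Cmax %.2f ng/mL @ %.2f h; AUC0-t %.1f, AUC0-inf %.1f ng.h/mL; t1/2 %.2f h; %s %.2f L/h\n",
              x$cmax, x$tmax, x$auc_0_t, x$auc_0_inf, x$half_life,
              ifelse(is.na(x$clearance_type), "CL", x$clearance_type), x$clearance))
  invisible(x)
}

#' Read an observed PK parameter table
#'
#' Reads a CSV of observed (and optionally predicted) PK parameters in the
#' documented schema: columns `study_id`, `route` (iv/oral), `population`,
#' `parameter` (cmax/auc_0_t/cl), `observed`, `unit`, optionally `predicted`
#' and `ratio_printed`. Units are stored verbatim and never rescaled; ratios
#' are computed within rows, where units cancel.
#'
#' @param path CSV path; defaults to the packaged transcription of the
#'   observed/predicted tables for the eight study profiles.
#' @return A data.frame (possibly zero rows for a header-only file).
#' @export
observed_table_reader <- function(path = pbpk_extdata("observed_pk.csv")) {
  tab <- read_pbpk_csv(path)
  required <- c("study_id", "route", "population", "parameter", "observed", "unit")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols)) {
    stop("observed table missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(tab) == 0L) return(tab)
  bad <- which(!(tab$route %in% c("iv", "oral")))
  if (length(bad)) stop("invalid route in rows: ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!(tab$parameter %in% c("cmax", "auc_0_t", "cl")))
  if (length(bad)) stop("invalid parameter in rows: ", paste(bad, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(tab$observed) | tab$observed <= 0)
  if (length(bad)) stop("non-positive observed value in rows: ", paste(bad, collapse = ", "), call. = FALSE)
  tab
}
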