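# Internal validation and file helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Path to a packaged data file
#'
#' Locates one of the plain-text data files shipped under `extdata/`
#' (reference physiology, tissue composition, drug parameters, disease
#' modifier tables, study designs, observed PK tables).
#'
#' @param file File name within `extdata/`.
#' @return Absolute path to the file.
#' @export
pbpk_extdata <- function(file) {
  path <- system.file("extdata", file, package = "labetapbpk")
  if (!nzchar(path)) {
    stop("packaged data file not found: ", file, call. = FALSE)
  }
  path
}

read_pbpk_csv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_number <- function(x, field, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_field(field, "must be a single finite number")
  }
  if (strict_lower && x <= lower) {
    stop_field(field, sprintf("must be > %g (got %g)", lower, x))
  }
  if (!strict_lower && x < lower) {
    stop_field(field, sprintf("must be >= %g (got %g)", lower, x))
  }
  if (strict_upper && x >= upper) {
    stop_field(field, sprintf("must be < %g (got %g)", upper, x))
  }
  if (!strict_upper && x > upper) {
    stop_field(field, sprintf("must be <= %g (got %g)", upper, x))
  }
  invisible(x)
}

check_choice <- function(x, field, choices) {
  if (!is.character(x) || length(x) != 1L || !(x %in% choices)) {
    stop_field(field, sprintf("must be one of: %s", paste(choices, collapse = ", ")))
  }
  invisible(x)
}

# Evaluate `expr` under a local RNG stream seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions never disturb the global
# random sequence.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    check_number(seed, "seed")
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Unit conversions used throughout: clearances are carried in L/h, GFR in
# mL/min, gastric emptying in minutes, transit in hours.
ml_per_min_to_l_per_h <- function(x) x * 60 / 1000
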