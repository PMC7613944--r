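#' First-order elimination rate constant from a blockade half-life
#'
#' @param half_life Positive half-life in minutes of the central receptor
#'   blockade (110 min for IV naloxone, 4320 min = 72 h for oral naltrexone).
#' @return Elimination rate constant `k = ln(2) / half_life`, per minute.
#' @examples
#' elimination_rate(110) # ~0.0063, printed rounded as 0.006
#' @export
elimination_rate <- function(half_life) {
  check_number(half_life, "half_life", lower = 0, strict_lower = TRUE)
  log(2) / half_life
}

#' Pool blockade half-life estimates
#'
#' Arithmetic mean and standard error (sample SD / sqrt(n)) of half-life
#' estimates from independent studies, e.g. the 100 and 120 min naloxone
#' estimates pooling to 110 min (SE 10).
#'
#' @param values Half-life estimates in minutes (at least one).
#' @return Tibble with columns `mean`, `se` (`NA` for a single value), `n`.
#' @export
pool_half_lives <- function(values) {
  if (length(values) < 1L) {
    abort("At least one half-life value is required.",
          class = c("opioidblockr_insufficient_data", "opioidblockr_error"))
  }
  check_numeric_vec(values, "values", lower = 0)
  if (any(values == 0)) stop_domain("Half-lives must be positive.")
  tibble(
    mean = mean(values),
    se = if (length(values) > 1L) sd(values) / sqrt(length(values)) else NA_real_,
    n = length(values)
  )
}

#' Back-extrapolate blockade to the administration time point
#'
#' Removes the exponential elimination between administration and the
#' measurement time: multiplies a blockade measured at `t_measure` by
#' `exp(k * t_measure)`, assuming no absorption phase. The result is a
#' pseudo-percent amplitude and is deliberately not truncated at 100%:
#' central antagonist concentration can exceed the level needed for full
#' blockade, and keeping the excess avoids underestimating how long full
#' blockade lasts.
#'
#' @param blockade_at_measure Percent blockade at the measurement time.
#' @param k Elimination rate constant (1/min), >= 0.
#' @param t_measure Minutes between administration and measurement, >= 0.
#' @return Pseudo-percent blockade amplitude at administration time.
#' @export
back_extrapolate <- function(blockade_at_measure, k, t_measure) {
  check_numeric_vec(blockade_at_measure, "blockade_at_measure", lower = 0)
  check_number(k, "k", lower = 0)
  check_number(t_measure, "t_measure", lower = 0)
  blockade_at_measure * exp(k * t_measure)
}

#' Lower branch of the Lambert W function
#'
#' Solves `w * exp(w) = x` on the lower real branch (`w <= -1`) for
#' `x` in `(-1/e, 0)`, with the branch point `W(-1/e) = -1`. This is the
#' inversion needed to recover the absorption rate constant from the
#' one-compartment peak-time identity.
#'
#' @param x Value(s) in `[-1/e, 0)`.
#' @return `w <= -1` with `w * exp(w) = x` to better than 1e-12 absolute.
#' @export
lambert_w_m1 <- function(x) {
  check_numeric_vec(x, "x")
  if (any(x < -exp(-1) - 1e-15 | x >= 0)) {
    stop_domain("`x` must lie in [-1/e, 0) for the lower Lambert W branch.")
  }
  w <- vapply(x, function(xi) {
    if (abs(xi + exp(-1)) < 1e-15) return(-1)
    pracma::lambertWn(xi)
  }, 1.0)
  # Halley polish to the contracted 1e-12 residual; skip near the branch
  # point w = -1 where the update degenerates
  for (i in 1:3) {
    ew <- exp(w)
    f <- w * ew - x
    denom <- ew * (w + 1) - (w + 2) * f / (2 * w + 2)
    step <- ifelse(f == 0 | abs(w + 1) < 1e-9 | !is.finite(denom) | denom == 0,
                   0, f / denom)
    w <- w - step
  }
  w
}

#' Absorption rate constant from time-to-peak blockade
#'
#' In a one-compartment model with first-order absorption (rate `ka`) and
#' elimination (rate `k`), the profile peaks at
#' `t_max = ln(ka/k) / (ka - k)`. Given `k` and `t_max` this transcendental
#' identity is inverted in closed form on the lower Lambert W branch:
#' `ka = -W_{-1}(-k t_max exp(-k t_max)) / t_max`. A solution with `ka > k`
#' exists only when `k * t_max < 1` (a peak later than `1/k` is unattainable
#' with first-order absorption).
#'
#' @param k Elimination rate constant (1/min), > 0.
#' @param t_max Time-to-peak in minutes, > 0.
#' @return Absorption rate constant (1/min), strictly greater than `k`.
#' @examples
#' absorption_rate(elimination_rate(110), 25) # ~0.126
#' @export
absorption_rate <- function(k, t_max) {
  check_number(k, "k", lower = 0, strict_lower = TRUE)
  check_number(t_max, "t_max", lower = 0, strict_lower = TRUE)
  if (k * t_max >= 1) {
    abort(sprintf(
      "No absorption rate yields a peak at t_max = %g min with k = %g: requires k * t_max < 1.",
      t_max, k
    ), class = c("opioidblockr_no_solution", "opioidblockr_error"))
  }
  -lambert_w_m1(-k * t_max * exp(-k * t_max)) / t_max
}

#' Assemble the kinetic parameter set for a drug
#'
#' Combines half-life, elimination rate, measurement time, and (when
#' time-to-peak is known) the derived absorption rate constant. For oral
#' naltrexone the time-to-peak is not established (likely 1-2 h), so
#' absorption-phase modeling is disabled unless the user supplies `t_max`.
#'
#' @param drug `"iv_naloxone"` or `"oral_naltrexone"`, or `NULL` to build
#'   purely from the other arguments.
#' @param half_life,t_max,t_measure Optional overrides, minutes.
#' @return A list of class `kinetic_params`: `half_life_min`, `k_per_min`,
#'   `t_max_min`, `ka_per_min` (NA when `t_max` is absent), `t_measure_min`.
#' @examples
#' kinetic_params("iv_naloxone")
#' @export
kinetic_params <- function(drug = NULL, half_life = NULL, t_max = NULL,
                           t_measure = NULL) {
  if (!is.null(drug)) {
    d <- drug_defaults(drug)
    half_life <- half_life %||% d$half_life_min
    t_max <- t_max %||% d$t_max_min
    t_measure <- t_measure %||% d$t_measure_min
  }
  if (is.null(half_life)) stop_domain("`half_life` is required.")
  k <- elimination_rate(half_life)
  t_max <- t_max %||% NA_real_
  ka <- if (!is.na(t_max)) absorption_rate(k, t_max) else NA_real_
  structure(
    list(
      half_life_min = half_life,
      k_per_min = k,
      t_max_min = t_max,
      ka_per_min = ka,
      t_measure_min = t_measure %||% NA_real_,
      drug = drug
    ),
    class = "kinetic_params"
  )
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat("Central blockade kinetics", if (!is.null(x$drug)) paste0("(", x$drug, ")"), "\n")
  cat(sprintf("  half-life: %g min   k: %.4g /min\n", x$half_life_min, x$k_per_min))
  if (!is.na(x$t_max_min)) {
    cat(sprintf("  t_max: %g min   ka: %.4g /min\n", x$t_max_min, x$ka_per_min))
  } else {
    cat("  t_max: unknown (absorption-phase modeling disabled)\n")
  }
  if (!is.na(x$t_measure_min)) {
    cat(sprintf("  t_measure: %g min\n", x$t_measure_min))
  }
  invisible(x)
}

#' @export
tidy.kinetic_params <- function(x, ...) {
  tibble(
    half_life_min = x$half_life_min,
    k_per_min = x$k_per_min,
    t_max_min = x$t_max_min,
    ka_per_min = x$ka_per_min,
    t_measure_min = x$t_measure_min
  )
}
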