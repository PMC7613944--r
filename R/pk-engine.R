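#' Build a dosing-regimen table
#'
#' One row per administration event. `amount` is the blockade amplitude at
#' the administration time in pseudo-percent (the back-extrapolated blockade
#' standing in for dose in the unit-volume one-compartment model), not a drug
#' mass. A bolus may use first-order absorption; an infusion delivers its
#' amount at a constant zero-order rate over `infusion_duration`; the two are
#' mutually exclusive within an event.
#'
#' @param amount Non-negative amplitude(s), pseudo-percent.
#' @param time Administration start time(s), minutes >= 0 (default 0).
#' @param infusion_duration Minutes (0 = bolus).
#' @param use_absorption Logical; apply first-order absorption to the bolus.
#' @return Tibble with columns `time`, `amount`, `infusion_duration`,
#'   `use_absorption`.
#' @export
dose_events <- function(amount, time = 0, infusion_duration = 0,
                        use_absorption = FALSE) {
  ev <- tibble(
    time = time, amount = amount,
    infusion_duration = infusion_duration,
    use_absorption = use_absorption
  )
  check_numeric_vec(ev$time, "time", lower = 0)
  check_numeric_vec(ev$amount, "amount", lower = 0)
  check_numeric_vec(ev$infusion_duration, "infusion_duration", lower = 0)
  if (any(ev$use_absorption & ev$infusion_duration > 0)) {
    stop_domain("An event cannot use absorption and a nonzero infusion duration.")
  }
  ev
}

# closed-form single-event terms; all zero before the event start
term_bolus_absorbed <- function(tt, A, k, ka) {
  out <- numeric(length(tt))
  on <- tt >= 0
  t1 <- tt[on]
  if (abs(ka - k) < 1e-12 * k) {
    # ka -> k limit of the two-exponential form
    out[on] <- A * k * t1 * exp(-k * t1)
  } else {
    out[on] <- A * ka / (ka - k) * (exp(-k * t1) - exp(-ka * t1))
  }
  out
}

term_bolus_instant <- function(tt, A, k) {
  out <- numeric(length(tt))
  on <- tt >= 0
  out[on] <- A * exp(-k * tt[on])
  out
}

term_infusion <- function(tt, A, k, dur) {
  out <- numeric(length(tt))
  on <- tt >= 0
  t1 <- tt[on]
  rate <- A / dur
  out[on] <- rate / k * (1 - exp(-k * pmin(t1, dur))) * exp(-k * pmax(0, t1 - dur))
  out
}

#' Closed-form blockade-time profile of a dosing regimen
#'
#' Evaluates the one-compartment (volume 1, clearance = `k`) blockade-time
#' profile as the pointwise superposition of the closed-form contribution of
#' each event: the two-exponential absorbed-bolus curve, the single
#' exponential of an instantaneous bolus, or the rise-and-washout of a
#' zero-order infusion. No ODE solver is involved, so superposition is exact
#' to machine precision.
#'
#' Values are pseudo-percent blockade and may exceed 100 when the central
#' amplitude exceeds the level needed for full blockade; `truncate = TRUE`
#' (the default, matching how the curves are usually displayed) caps them at
#' 100, while planners work on the untruncated profile.
#'
#' @param events Regimen from [dose_events()] (or any data frame with those
#'   columns).
#' @param k Elimination rate constant (1/min), > 0.
#' @param ka Absorption rate constant (1/min); required if any event uses
#'   absorption.
#' @param times Evaluation grid, minutes >= 0; default 0 to 10 elimination
#'   half-lives at 1-min resolution.
#' @param truncate Cap values at 100%.
#' @param receptor Optional receptor label attached to the profile.
#' @return A tibble of class `blockade_profile` with columns `time`, `value`
#'   and attributes `truncated`, `receptor`.
#' @examples
#' kp <- kinetic_params("iv_naloxone")
#' pk_profile(dose_events(138), k = kp$k_per_min, ka = kp$ka_per_min)
#' @export
pk_profile <- function(events, k, ka = NULL, times = NULL, truncate = TRUE,
                       receptor = NULL) {
  check_number(k, "k", lower = 0, strict_lower = TRUE)
  ev <- dose_events(
    amount = events$amount,
    time = events$time %||% 0,
    infusion_duration = events$infusion_duration %||% 0,
    use_absorption = events$use_absorption %||% FALSE
  )
  if (is.null(times)) times <- seq(0, 10 * log(2) / k, by = 1)
  check_numeric_vec(times, "times", lower = 0)
  if (is.unsorted(times, strictly = TRUE)) {
    stop_domain("`times` must be strictly increasing.")
  }
  if (any(ev$use_absorption) && (is.null(ka) || is.na(ka))) {
    stop_domain("`ka` is required when an event uses first-order absorption.")
  }

  value <- numeric(length(times))
  for (i in seq_len(nrow(ev))) {
    tt <- times - ev$time[i]
    value <- value + if (ev$infusion_duration[i] > 0) {
      term_infusion(tt, ev$amount[i], k, ev$infusion_duration[i])
    } else if (ev$use_absorption[i]) {
      term_bolus_absorbed(tt, ev$amount[i], k, ka)
    } else {
      term_bolus_instant(tt, ev$amount[i], k)
    }
  }
  if (truncate) value <- pmin(value, 100)

  out <- tibble(time = times, value = value)
  class(out) <- c("blockade_profile", class(out))
  attr(out, "truncated") <- truncate
  attr(out, "receptor") <- receptor
  attr(out, "k") <- k
  attr(out, "ka") <- ka
  out
}

#' Peak of a blockade-time profile
#'
#' For a single absorbed bolus the peak time is analytic,
#' `t_peak = ln(ka/k)/(ka - k)`, and the value is the closed form there. For
#' any other regimen the peak is located by a grid scan followed by
#' golden-section refinement.
#'
#' @inheritParams pk_profile
#' @param resolution Scan resolution (minutes) for the multi-event fallback.
#' @return Tibble with columns `t_peak` (minutes) and `value`
#'   (untruncated pseudo-percent).
#' @export
pk_peak <- function(events, k, ka = NULL, resolution = 1) {
  check_number(k, "k", lower = 0, strict_lower = TRUE)
  ev <- dose_events(
    amount = events$amount,
    time = events$time %||% 0,
    infusion_duration = events$infusion_duration %||% 0,
    use_absorption = events$use_absorption %||% FALSE
  )
  single_abs <- nrow(ev) == 1L && ev$use_absorption[1] && ev$infusion_duration[1] == 0
  if (single_abs) {
    stopifnot(!is.null(ka), ka > 0, abs(ka - k) > 0)
    t_peak <- ev$time[1] + log(ka / k) / (ka - k)
    value <- term_bolus_absorbed(t_peak - ev$time[1], ev$amount[1], k, ka)
    return(tibble(t_peak = t_peak, value = value))
  }
  horizon <- max(ev$time + ev$infusion_duration) + 10 * log(2) / k
  grid <- seq(0, horizon, by = resolution)
  f <- function(t) pk_profile(ev, k = k, ka = ka, times = t, truncate = FALSE)$value[1]
  vals <- pk_profile(ev, k = k, ka = ka, times = grid, truncate = FALSE)$value
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  tibble(t_peak = opt$maximum, value = opt$objective)
}

#' Read or write dosing regimens and profiles as CSV
#'
#' Regimen CSVs use the header
#' `time_min,amount,infusion_duration_min,use_absorption`; profile CSVs use
#' `time_min,value` plus `receptor` when the profile carries one.
#'
#' @param path File path.
#' @return `read_regimen_csv()` returns a [dose_events()] tibble.
#' @export
read_regimen_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("time_min", "amount")
  if (!all(need %in% names(x))) {
    stop_domain("Regimen CSV must have columns `time_min` and `amount`.",
                class = "opioidblockr_parse_error")
  }
  dose_events(
    amount = x$amount, time = x$time_min,
    infusion_duration = x$infusion_duration_min %||% 0,
    use_absorption = as.logical(x$use_absorption %||% FALSE)
  )
}

#' @rdname read_regimen_csv
#' @param profile A `blockade_profile` tibble.
#' @export
write_profile_csv <- function(profile, path) {
  out <- tibble(time_min = profile$time, value = profile$value)
  if (!is.null(attr(profile, "receptor"))) out$receptor <- attr(profile, "receptor")
  readr::write_csv(out, path)
  invisible(path)
}

#' @export
autoplot.blockade_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 90, linetype = "dashed") +
    ggplot2::labs(x = "Time since first administration (min)",
                  y = "Blockade (%)",
                  title = attr(object, "receptor"))
}
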