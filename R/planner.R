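# Experiment-design calculations: full-blockade windows, washout intervals,
# minimum doses, bolus+infusion holds, and drug-cost estimates.

# amplitude of the absorbed-bolus profile per unit amplitude at t_admin
shape_fun <- function(t, k, ka, absorption = TRUE) {
  if (absorption) {
    ka / (ka - k) * (exp(-k * t) - exp(-ka * t))
  } else {
    exp(-k * t)
  }
}

# map a dose to the back-extrapolated profile amplitude, and back
dose_to_amplitude <- function(dose, model, receptor = "MOR") {
  b <- 100 * dose / (dose + panel_ed50(model$panel, receptor))
  t_meas <- model$kinetics$t_measure_min
  if (is.na(t_meas)) t_meas <- 0
  back_extrapolate(b, model$kinetics$k_per_min, t_meas)
}

amplitude_to_dose <- function(amp, model, receptor = "MOR") {
  t_meas <- model$kinetics$t_measure_min
  if (is.na(t_meas)) t_meas <- 0
  b <- amp * exp(-model$kinetics$k_per_min * t_meas)
  inverse_dose(b, panel_ed50(model$panel, receptor))
}

#' Window of full receptor blockade after a single bolus
#'
#' Finds the contiguous interval during which the untruncated absorbed-bolus
#' blockade profile stays above a threshold (default 90%, the conventional
#' definition of full blockade). Crossings are bracketed on a 1-min scan of
#' the closed-form profile and refined by bisection to 0.01 min. The window
#' is computed on the untruncated profile: truncating at 100% would flatten
#' the peak and hide the crossings.
#'
#' @param drug Drug identifier or [drug_model()] object.
#' @param dose Bolus dose in drug units.
#' @param receptor Receptor subtype (default `"MOR"`).
#' @param threshold Percent blockade defining "full" (default 90).
#' @param ... Passed to [drug_model()].
#' @return A list of class `blockade_window`: `onset`, `offset`, `duration`
#'   (minutes; `NA`/0 when not attained), `threshold`, `attained`,
#'   `peak_time`, `peak_value`. [tidy()] returns a one-row tibble.
#' @examples
#' full_blockade_window("iv_naloxone", 0.1)
#' @export
full_blockade_window <- function(drug, dose, receptor = "MOR", threshold = 90,
                                 ...) {
  model <- if (inherits(drug, "drug_model")) drug else drug_model(drug, ...)
  check_number(dose, "dose", lower = 0)
  check_receptor(receptor)
  check_number(threshold, "threshold", lower = 0)
  kin <- model$kinetics
  if (is.na(kin$ka_per_min)) {
    abort("Blockade windows need absorption kinetics; supply `t_max`.",
          class = c("opioidblockr_kinetics_unavailable", "opioidblockr_error"))
  }
  amp <- dose_to_amplitude(dose, model, receptor)
  k <- kin$k_per_min
  ka <- kin$ka_per_min
  value_at <- function(t) amp * shape_fun(t, k, ka)

  peak_time <- log(ka / k) / (ka - k)
  peak_value <- value_at(peak_time)
  if (peak_value < threshold) {
    out <- list(onset = NA_real_, offset = NA_real_, duration = 0,
                threshold = threshold, attained = FALSE,
                peak_time = peak_time, peak_value = peak_value,
                receptor = receptor, dose = dose)
    class(out) <- "blockade_window"
    return(out)
  }

  g <- function(t) value_at(t) - threshold
  horizon <- 10 * log(2) / k
  grid <- seq(0, horizon, by = 1)
  v <- g(grid)
  sign_change <- which(diff(sign(v)) != 0)
  roots <- vapply(sign_change, function(i) {
    uniroot(g, c(grid[i], grid[i + 1]), tol = 1e-4)$root
  }, 1.0)
  onset <- min(roots)
  offset <- max(roots)
  out <- list(onset = onset, offset = offset, duration = offset - onset,
              threshold = threshold, attained = TRUE,
              peak_time = peak_time, peak_value = peak_value,
              receptor = receptor, dose = dose)
  class(out) <- "blockade_window"
  out
}

#' @export
print.blockade_window <- function(x, ...) {
  if (!x$attained) {
    cat(sprintf(">%g%% %s blockade is not attained (peak %.1f%% at %.1f min)\n",
                x$threshold, x$receptor, x$peak_value, x$peak_time))
  } else {
    cat(sprintf(">%g%% %s blockade from %.1f to %.1f min (duration %.1f min, ~%g min)\n",
                x$threshold, x$receptor, x$onset, x$offset, x$duration,
                round(x$duration / 5) * 5))
  }
  invisible(x)
}

#' @export
tidy.blockade_window <- function(x, ...) {
  tibble(
    receptor = x$receptor, dose = x$dose, threshold = x$threshold,
    attained = x$attained, onset = x$onset, offset = x$offset,
    duration = x$duration, peak_time = x$peak_time, peak_value = x$peak_value
  )
}

#' Washout time as a multiple of the blockade half-life
#'
#' Exponential decay is conventionally considered complete after five to ten
#' half-lives; the default multiplier 5 is the minimum recommendation
#' (550 min ~ 9 h for naloxone's 110-min half-life; 360 h = 15 days for
#' naltrexone's 72-h half-life).
#'
#' @param half_life Blockade half-life, minutes.
#' @param n_half_lives Positive multiplier (default 5; use 10 for the
#'   conservative option).
#' @return Washout time in minutes.
#' @export
washout_time <- function(half_life, n_half_lives = 5) {
  check_number(half_life, "half_life", lower = 0, strict_lower = TRUE)
  check_number(n_half_lives, "n_half_lives", lower = 0, strict_lower = TRUE)
  n_half_lives * half_life
}

#' Minimum bolus dose reaching a target blockade at a given time
#'
#' Inverts the simulation chain analytically: the untruncated profile is
#' linear in the administration amplitude, so the required amplitude is
#' `target / S(at_time)` with `S` the unit-amplitude profile shape; the
#' amplitude is then mapped back through the elimination correction and the
#' inverse dose-blockade curve. The result is verified by forward simulation.
#'
#' @inheritParams full_blockade_window
#' @param target_blockade Percent in `[0, 100)`.
#' @param at_time Minutes post-administration at which the target must be
#'   met.
#' @param absorption Model the absorption phase (default `TRUE`).
#' @return The minimum dose, in drug units.
#' @examples
#' min_dose_for("iv_naloxone", target_blockade = 90, at_time = 30)
#' @export
min_dose_for <- function(drug, receptor = "MOR", target_blockade = 90,
                         at_time, absorption = TRUE, ...) {
  model <- if (inherits(drug, "drug_model")) drug else drug_model(drug, ...)
  check_receptor(receptor)
  check_number(target_blockade, "target_blockade", lower = 0)
  check_number(at_time, "at_time", lower = 0)
  if (target_blockade >= 100) {
    abort("100% blockade is unattainable under the model.",
          class = c("opioidblockr_unattainable", "opioidblockr_error"))
  }
  kin <- model$kinetics
  if (absorption && is.na(kin$ka_per_min)) {
    abort("Absorption kinetics unavailable; supply `t_max` or set `absorption = FALSE`.",
          class = c("opioidblockr_kinetics_unavailable", "opioidblockr_error"))
  }
  s <- shape_fun(at_time, kin$k_per_min, kin$ka_per_min, absorption)
  if (s <= 0) {
    abort("The profile is zero at `at_time`; no dose can attain the target.",
          class = c("opioidblockr_unattainable", "opioidblockr_error"))
  }
  amp <- target_blockade / s
  t_meas <- kin$t_measure_min
  if (is.na(t_meas)) t_meas <- 0
  b_measure <- amp * exp(-kin$k_per_min * t_meas)
  if (b_measure >= 100) {
    abort(sprintf(
      "%.1f%% %s blockade at %g min is unattainable with any single bolus (would require %.1f%% at the fit window).",
      target_blockade, receptor, at_time, b_measure
    ), class = c("opioidblockr_unattainable", "opioidblockr_error"))
  }
  dose <- inverse_dose(b_measure, panel_ed50(model$panel, receptor))
  # forward check of the inversion
  achieved <- dose_to_amplitude(dose, model, receptor) *
    shape_fun(at_time, kin$k_per_min, kin$ka_per_min, absorption)
  stopifnot(abs(achieved - target_blockade) <= 1e-6)
  dose
}

#' Drug cost of a dosing scheme
#'
#' Whole purchasable units (vials or tablets) needed to cover the total drug
#' amount, and the resulting price range. For per-kilogram dosing (IV
#' naloxone) the participant weight converts dose to a total amount.
#'
#' @param drug Drug identifier (for the packaged [cost_schedule()]) or a
#'   [drug_model()].
#' @param dose Dose in drug units (mg/kg for IV naloxone, total mg for oral
#'   naltrexone).
#' @param weight_kg Participant weight; required for per-kg dosing (the
#'   packaged summaries assume 70 kg).
#' @param schedule Optional [cost_schedule()]-style override.
#' @return List of class `cost_estimate`: `total_drug`, `units_needed`,
#'   `unit_label`, `cost_range` (USD low/high), `cost_mid`, `assumed_weight`.
#' @examples
#' cost_estimate("iv_naloxone", dose = 0.1, weight_kg = 70)
#' @export
cost_estimate <- function(drug, dose, weight_kg = NULL, schedule = NULL) {
  drug_id <- if (inherits(drug, "drug_model")) drug$drug else check_drug(drug)
  schedule <- schedule %||% cost_schedule(drug_id)
  check_number(dose, "dose", lower = 0, strict_lower = TRUE)
  per_kg <- grepl("/kg", drug_defaults(drug_id)$dose_unit, fixed = TRUE)
  if (per_kg) {
    if (is.null(weight_kg)) {
      abort("`weight_kg` is required for per-kilogram dosing.",
            class = c("opioidblockr_missing_parameter", "opioidblockr_error"))
    }
    check_number(weight_kg, "weight_kg", lower = 0, strict_lower = TRUE)
    total <- dose * weight_kg
  } else {
    total <- dose
  }
  # tolerate floating error when the dose divides the unit content exactly
  units <- ceiling(total / schedule$unit_content - 1e-9)
  rng <- units * schedule$unit_price_usd
  structure(
    list(
      total_drug = total, units_needed = units,
      unit_label = schedule$unit_label,
      cost_range = rng, cost_mid = mean(rng),
      assumed_weight = if (per_kg) weight_kg else NA_real_
    ),
    class = "cost_estimate"
  )
}

#' @export
print.cost_estimate <- function(x, ...) {
  cat(sprintf("Total drug: %g (%d x %s)\n", x$total_drug, x$units_needed,
              x$unit_label))
  cat(sprintf("Cost: %.2f-%.2f USD (midpoint ~%.0f USD)\n",
              x$cost_range[1], x$cost_range[2], x$cost_mid))
  invisible(x)
}

#' @export
tidy.cost_estimate <- function(x, ...) {
  tibble(
    total_drug = x$total_drug, units_needed = x$units_needed,
    cost_low = x$cost_range[1], cost_high = x$cost_range[2],
    cost_mid = x$cost_mid, assumed_weight = x$assumed_weight
  )
}

#' Bolus-plus-infusion regimen holding a blockade threshold
#'
#' Designs a low-bolus regimen that maintains at least `threshold` percent
#' blockade from the bolus's own onset until `hold_until`: the bolus is the
#' minimum dose first reaching the threshold at `onset` minutes, and, when the
#' bolus's own window ends before `hold_until`, a zero-order infusion running
#' from administration to `hold_until` at rate `k` times the back-extrapolated
#' threshold amplitude (the infusion's steady state then sits at that
#' amplitude, which keeps the superposed profile above the threshold as the
#' bolus washes out). The returned regimen is verified by forward simulation
#' on a 1-min grid.
#'
#' @inheritParams full_blockade_window
#' @param hold_until Minutes post-administration until which the threshold
#'   must hold.
#' @param onset Minutes at which the bolus first reaches the threshold
#'   (default 15, the minimum assessment delay recommended for low boluses).
#' @return List of class `hold_regimen`: `events` ([dose_events()] in
#'   amplitude units), `bolus_dose` (drug units), `infusion_amplitude`,
#'   `total_dose_equivalent` (drug units; the bolus dose plus the infusion's
#'   per-minute amplitude mapped through the inverse dose-blockade chain and
#'   scaled by duration), `threshold`, `hold_until`.
#' @examples
#' regimen_hold("iv_naloxone", hold_until = 180)
#' @export
regimen_hold <- function(drug, receptor = "MOR", threshold = 90, hold_until,
                         onset = 15, ...) {
  model <- if (inherits(drug, "drug_model")) drug else drug_model(drug, ...)
  check_number(hold_until, "hold_until", lower = 0, strict_lower = TRUE)
  check_number(onset, "onset", lower = 0, strict_lower = TRUE)
  kin <- model$kinetics

  bolus_dose <- min_dose_for(model, receptor, threshold, at_time = onset)
  bolus_amp <- dose_to_amplitude(bolus_dose, model, receptor)
  window <- full_blockade_window(model, bolus_dose, receptor, threshold)

  if (window$attained && hold_until <= window$offset + 1e-9) {
    events <- dose_events(amount = bolus_amp, use_absorption = TRUE)
    infusion_amp <- 0
  } else {
    t_meas <- kin$t_measure_min
    if (is.na(t_meas)) t_meas <- 0
    rate <- kin$k_per_min * back_extrapolate(threshold, kin$k_per_min, t_meas)
    infusion_amp <- rate * hold_until
    events <- dose_events(
      amount = c(bolus_amp, infusion_amp),
      time = c(0, 0),
      infusion_duration = c(0, hold_until),
      use_absorption = c(TRUE, FALSE)
    )
  }

  grid <- sort(unique(c(seq(onset, hold_until, by = 1), onset, hold_until)))
  prof <- pk_profile(events, k = kin$k_per_min, ka = kin$ka_per_min,
                     times = grid, truncate = FALSE)
  if (any(prof$value < threshold - 1e-6)) {
    abort("The designed regimen fails to hold the threshold; target unattainable.",
          class = c("opioidblockr_unattainable", "opioidblockr_error"))
  }

  # infusion drug-equivalent: per-minute amplitude mapped through the inverse
  # dose-blockade chain (near-linear well below saturation), times duration
  infusion_dose <- if (infusion_amp > 0) {
    amplitude_to_dose(infusion_amp / hold_until, model, receptor) * hold_until
  } else 0
  total <- bolus_dose + infusion_dose
  structure(
    list(
      events = events, bolus_dose = bolus_dose,
      infusion_amplitude = infusion_amp,
      total_dose_equivalent = total,
      threshold = threshold, hold_until = hold_until, onset = onset,
      receptor = receptor, drug = model$drug
    ),
    class = "hold_regimen"
  )
}

#' @export
print.hold_regimen <- function(x, ...) {
  cat(sprintf("Hold >=%g%% %s blockade from %g to %g min (%s)\n",
              x$threshold, x$receptor, x$onset, x$hold_until, x$drug))
  cat(sprintf("  bolus: %.4g (drug units); infusion amplitude: %.4g\n",
              x$bolus_dose, x$infusion_amplitude))
  cat(sprintf("  total dose equivalent: %.4g (drug units)\n",
              x$total_dose_equivalent))
  invisible(x)
}
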