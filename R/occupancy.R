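#' Per-receptor ED50 panel from affinity ratios
#'
#' Scales the fitted mu-opioid (MOR) ED50 to the delta (DOR) and kappa (KOR)
#' receptors by the antagonist's relative affinities: an antagonist binding
#' MOR `r` times more strongly than another receptor needs `r` times the dose
#' for the same occupancy of that receptor, so `ED50_DOR = ED50_MOR *
#' ratio_dor` and `ED50_KOR = ED50_MOR * ratio_kor`.
#'
#' @param ed50_mor Positive MOR ED50 in drug dose units.
#' @param ratio_dor,ratio_kor Positive MOR:DOR and MOR:KOR affinity ratios
#'   (41 and 8 for naloxone, 79 and 2 for naltrexone).
#' @param ratio_ranges Optional named list with elements `DOR` and/or `KOR`,
#'   each `c(min, max)` ratios bracketing the central value, used for
#'   uncertainty bands in [dose_response_curves()].
#' @return Tibble of class `receptor_panel` with columns `receptor`, `ratio`,
#'   `ed50`, and (when ranges are given) `ratio_min`, `ratio_max`.
#' @examples
#' receptor_panel(0.0023, ratio_dor = 41, ratio_kor = 8)
#' @export
receptor_panel <- function(ed50_mor, ratio_dor, ratio_kor, ratio_ranges = NULL) {
  check_number(ed50_mor, "ed50_mor", lower = 0, strict_lower = TRUE)
  check_number(ratio_dor, "ratio_dor", lower = 0, strict_lower = TRUE)
  check_number(ratio_kor, "ratio_kor", lower = 0, strict_lower = TRUE)
  out <- tibble(
    receptor = factor(receptor_levels(), levels = receptor_levels()),
    ratio = c(1, ratio_dor, ratio_kor),
    ed50 = ed50_mor * c(1, ratio_dor, ratio_kor)
  )
  if (!is.null(ratio_ranges)) {
    rng <- function(r, central) {
      v <- ratio_ranges[[r]]
      if (is.null(v)) return(c(NA_real_, NA_real_))
      stopifnot(length(v) == 2, v[1] <= central, central <= v[2])
      v
    }
    ranges <- rbind(c(1, 1), rng("DOR", ratio_dor), rng("KOR", ratio_kor))
    out$ratio_min <- ranges[, 1]
    out$ratio_max <- ranges[, 2]
  }
  class(out) <- c("receptor_panel", class(out))
  out
}

panel_ed50 <- function(panel, receptor) {
  panel$ed50[match(receptor, as.character(panel$receptor))]
}

#' Fit and assemble the full model for a packaged drug
#'
#' Convenience composition used by the planner and the command-line tool:
#' fits the dose-blockade model to the packaged observations, builds the
#' receptor panel from the default affinity ratios, and assembles the kinetic
#' parameters. Any component can be overridden.
#'
#' @param drug `"iv_naloxone"` or `"oral_naltrexone"`.
#' @param ed50,ratio_dor,ratio_kor,half_life,t_max,t_measure Optional
#'   overrides of the fitted/default values (times in minutes).
#' @param data Optional observations to fit instead of the packaged ones.
#' @return A list of class `drug_model`: `drug`, `fit` (`NULL` when `ed50`
#'   is overridden), `panel`, `kinetics`, `defaults`.
#' @examples
#' m <- drug_model("iv_naloxone")
#' m$panel
#' @export
drug_model <- function(drug, ed50 = NULL, ratio_dor = NULL, ratio_kor = NULL,
                       half_life = NULL, t_max = NULL, t_measure = NULL,
                       data = NULL) {
  check_drug(drug)
  defaults <- drug_defaults(drug)
  fit <- NULL
  if (is.null(ed50)) {
    fit <- fit_ed50(data %||% blockade_observations(drug), drug = drug)
    ed50 <- fit$ed50
  }
  panel <- receptor_panel(
    ed50,
    ratio_dor %||% defaults$affinity_ratio_dor,
    ratio_kor %||% defaults$affinity_ratio_kor
  )
  kin <- kinetic_params(drug, half_life = half_life, t_max = t_max,
                        t_measure = t_measure)
  structure(
    list(drug = drug, fit = fit, panel = panel, kinetics = kin,
         defaults = defaults),
    class = "drug_model"
  )
}

#' @export
print.drug_model <- function(x, ...) {
  cat("Opioid antagonist model:", x$drug, "\n")
  cat(sprintf("  MOR ED50: %.4g %s\n", panel_ed50(x$panel, "MOR"),
              x$defaults$dose_unit))
  cat(sprintf("  DOR/KOR ED50: %.4g / %.4g %s\n",
              panel_ed50(x$panel, "DOR"), panel_ed50(x$panel, "KOR"),
              x$defaults$dose_unit))
  print(x$kinetics)
  invisible(x)
}

#' Receptor blockade at the fit window
#'
#' Evaluates the dose-blockade curve with the receptor's scaled ED50 at the
#' time window the fit refers to (55 min post-administration for IV naloxone,
#' within 8 h for oral naltrexone), with no time correction. This is the
#' headline per-receptor estimate, e.g. 82% KOR and 10% DOR blockade with
#' 50 mg oral naltrexone.
#'
#' @param drug Drug identifier, or a [drug_model()] object.
#' @param dose Non-negative dose(s) in drug units.
#' @param receptor `"MOR"`, `"DOR"`, or `"KOR"` (any subset).
#' @return Tibble with columns `receptor`, `dose`, `value` (percent in
#'   `[0, 100)`).
#' @examples
#' blockade_at_fit_window("oral_naltrexone", 50, c("MOR", "DOR", "KOR"))
#' @export
blockade_at_fit_window <- function(drug, dose, receptor = "MOR") {
  model <- if (inherits(drug, "drug_model")) drug else drug_model(drug)
  check_numeric_vec(dose, "dose", lower = 0)
  receptor <- vapply(receptor, check_receptor, "")
  tidyr::expand_grid(receptor = receptor, dose = dose) |>
    dplyr::mutate(
      value = 100 * .data$dose /
        (.data$dose + panel_ed50(model$panel, .data$receptor))
    )
}

#' Per-receptor blockade-time curves for a bolus dose
#'
#' The forward simulation chain: evaluate the dose-blockade curve with the
#' receptor's ED50 at the measurement time, back-extrapolate to the
#' administration time with the elimination rate (no absorption assumed),
#' then simulate the absorbed-bolus time profile with the drug's `k` and
#' `ka`. DOR and KOR are assumed to share the absorption and elimination
#' kinetics of MOR blockade.
#'
#' Oral naltrexone has no established time-to-peak, so time curves require an
#' explicit `t_max` override (and its back-extrapolation step is skipped,
#' because the naltrexone fit carries no single measurement time).
#'
#' @inheritParams blockade_at_fit_window
#' @param receptors Receptors to simulate.
#' @param times Evaluation grid in minutes (default 0 to 10 half-lives, 1-min
#'   steps).
#' @param truncate Cap values at 100%.
#' @param ... Passed to [drug_model()] (e.g. `t_max` for naltrexone).
#' @return Long tibble of class `blockade_curves`: `time`, `receptor`,
#'   `value`.
#' @examples
#' blockade_time_curves("iv_naloxone", 0.1, times = seq(0, 120, 5))
#' @export
blockade_time_curves <- function(drug, dose, receptors = receptor_levels(),
                                 times = NULL, truncate = TRUE, ...) {
  model <- if (inherits(drug, "drug_model")) drug else drug_model(drug, ...)
  check_number(dose, "dose", lower = 0)
  receptors <- vapply(receptors, check_receptor, "")
  kin <- model$kinetics
  if (is.na(kin$t_max_min) || is.na(kin$ka_per_min)) {
    abort(sprintf(
      "Time-blockade profiles for %s need `t_max` (time-to-peak), which is not established for this drug; supply it explicitly.",
      model$drug
    ), class = c("opioidblockr_kinetics_unavailable", "opioidblockr_error"))
  }
  t_meas <- kin$t_measure_min
  if (is.na(t_meas)) t_meas <- 0

  curves <- purrr::map(receptors, function(r) {
    b <- 100 * dose / (dose + panel_ed50(model$panel, r))
    amp <- back_extrapolate(b, kin$k_per_min, t_meas)
    prof <- pk_profile(
      dose_events(amount = amp, use_absorption = TRUE),
      k = kin$k_per_min, ka = kin$ka_per_min,
      times = times, truncate = truncate, receptor = r
    )
    tibble(time = prof$time, receptor = r, value = prof$value)
  })
  out <- dplyr::bind_rows(curves)
  out$receptor <- factor(out$receptor, levels = receptor_levels())
  class(out) <- c("blockade_curves", class(out))
  attr(out, "truncated") <- truncate
  attr(out, "dose") <- dose
  attr(out, "drug") <- model$drug
  out
}

#' Per-receptor dose-blockade curves with optional uncertainty bands
#'
#' Evaluates the dose-blockade curve for each receptor across a dose grid.
#' For MOR the band is the delta-method 95% confidence band of the fit; for
#' DOR/KOR bands are recomputed from user-supplied minimum and maximum
#' affinity ratios (higher ratio means higher ED50, hence lower blockade).
#'
#' @inheritParams blockade_time_curves
#' @param doses Non-negative dose grid.
#' @param ratio_ranges Optional named list (`DOR`, `KOR`) of `c(min, max)`
#'   affinity ratios; default absent.
#' @param level Confidence level for the MOR band (only used when the model
#'   carries a fit).
#' @return Long tibble of class `blockade_curves`: `dose`, `receptor`,
#'   `value`, `lower`, `upper` (bands `NA` where unavailable).
#' @export
dose_response_curves <- function(drug, doses, receptors = receptor_levels(),
                                 ratio_ranges = NULL, level = 0.95, ...) {
  model <- if (inherits(drug, "drug_model")) drug else drug_model(drug, ...)
  check_numeric_vec(doses, "doses", lower = 0)
  receptors <- vapply(receptors, check_receptor, "")
  ed50_mor <- panel_ed50(model$panel, "MOR")

  curves <- purrr::map(receptors, function(r) {
    e <- panel_ed50(model$panel, r)
    val <- 100 * doses / (doses + e)
    lower <- rep(NA_real_, length(doses))
    upper <- lower
    if (r == "MOR" && !is.null(model$fit)) {
      band <- confidence_band(model$fit, doses, level = level)
      lower <- band$lower
      upper <- band$upper
    } else if (!is.null(ratio_ranges[[r]])) {
      v <- ratio_ranges[[r]]
      stopifnot(length(v) == 2, v[1] <= v[2])
      lower <- 100 * doses / (doses + ed50_mor * v[2])
      upper <- 100 * doses / (doses + ed50_mor * v[1])
    }
    tibble(dose = doses, receptor = r, value = val, lower = lower, upper = upper)
  })
  out <- dplyr::bind_rows(curves)
  out$receptor <- factor(out$receptor, levels = receptor_levels())
  class(out) <- c("blockade_curves", class(out))
  attr(out, "drug") <- model$drug
  out
}

#' @export
autoplot.blockade_curves <- function(object, ...) {
  xvar <- if ("time" %in% names(object)) "time" else "dose"
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data[[xvar]], y = .data$value, colour = .data$receptor
  ))
  if (all(c("lower", "upper") %in% names(object)) &&
      any(!is.na(object$lower))) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$lower, ymax = .data$upper,
                   fill = .data$receptor),
      alpha = 0.15, colour = NA
    )
  }
  p <- p + ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 90, linetype = "dashed") +
    ggplot2::labs(
      x = if (xvar == "time") "Time since administration (min)" else "Dose",
      y = "Blockade (%)", colour = "Receptor", fill = "Receptor"
    )
  if (xvar == "dose") p <- p + ggplot2::scale_x_log10()
  p
}

#' Write receptor curves as long-format CSV
#'
#' @param curves A `blockade_curves` tibble.
#' @param path Output path. Columns are `dose_or_time, receptor, value`
#'   plus `lower, upper` when bands are present.
#' @export
write_curves_csv <- function(curves, path) {
  xvar <- if ("time" %in% names(curves)) "time" else "dose"
  out <- tibble(
    dose_or_time = curves[[xvar]],
    receptor = as.character(curves$receptor),
    value = curves$value
  )
  if (all(c("lower", "upper") %in% names(curves))) {
    out$lower <- curves$lower
    out$upper <- curves$upper
  }
  readr::write_csv(out, path)
  invisible(path)
}
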