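#' Published dose-blockade observations for an opioid antagonist
#'
#' Loads the packaged mu-opioid receptor (MOR) blockade observations compiled
#' from PET and dual-detector studies with carfentanil-based radiotracers:
#' 16 observations for intravenous naloxone (including the 0 mg/kg control)
#' and 7 observations for oral naltrexone. These are the data behind the
#' packaged dose-blockade fits.
#'
#' Doses are in mg/kg body weight for intravenous naloxone and total mg for
#' oral naltrexone. Blockade is percent receptor occupancy in `[0, 100]`.
#' `method` distinguishes full PET imaging from the simpler two-probe
#' dual-detector systems used in the early studies.
#'
#' @param drug `"iv_naloxone"` or `"oral_naltrexone"`.
#' @return A tibble with columns `dose`, `blockade`, `method` (factor:
#'   `PET`, `dual_detector`), `study`.
#' @examples
#' blockade_observations("iv_naloxone")
#' @export
blockade_observations <- function(drug) {
  check_drug(drug)
  file <- switch(drug,
    iv_naloxone = "naloxone_blockade.csv",
    oral_naltrexone = "naltrexone_blockade.csv"
  )
  path <- system.file("extdata", file, package = "opioidblockr", mustWork = TRUE)
  read_blockade_csv(path)
}

#' Read dose-blockade observations from a CSV file
#'
#' Reads user-supplied observations in the same dialect as the packaged data:
#' header `dose,blockade,method,study` (the last two optional; `method`
#' defaults to `"PET"`, `study` to the file name).
#'
#' @param path Path to a CSV file.
#' @return A tibble with columns `dose`, `blockade`, `method`, `study`.
#' @export
read_blockade_csv <- function(path) {
  obs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("dose", "blockade") %in% names(obs))) {
    stop_domain("Observation CSV must have columns `dose` and `blockade`.",
                class = "opioidblockr_parse_error")
  }
  if (!"method" %in% names(obs)) obs$method <- "PET"
  if (!"study" %in% names(obs)) obs$study <- basename(path)
  obs <- dplyr::select(obs, "dose", "blockade", "method", "study")
  validate_observations(obs)
}

validate_observations <- function(obs) {
  check_numeric_vec(obs$dose, "dose", lower = 0)
  check_numeric_vec(obs$blockade, "blockade", lower = 0)
  if (any(obs$blockade > 100)) {
    stop_domain("Observed blockade must lie in [0, 100] percent.")
  }
  bad <- setdiff(unique(obs$method), c("PET", "dual_detector"))
  if (length(bad)) {
    stop_domain(sprintf("Unknown measurement method(s): %s.",
                        paste(bad, collapse = ", ")))
  }
  obs$method <- factor(obs$method, levels = c("PET", "dual_detector"))
  as_tibble(obs)
}

#' Default kinetic and affinity parameters for an antagonist
#'
#' Returns the packaged per-drug defaults: central blockade half-life
#' (110 min for IV naloxone, 72 h = 4320 min for oral naltrexone), the
#' measurement time the dose-blockade fit refers to (55 min for naloxone, the
#' midpoint of the 45-65 min recording window; absent for naltrexone, whose
#' fit applies to the whole <8 h window), time-to-peak blockade (25 min for
#' naloxone), and the MOR:DOR and MOR:KOR affinity ratios (41 and 8 for
#' naloxone, 79 and 2 for naltrexone). All times are carried in minutes.
#'
#' @param drug `"iv_naloxone"` or `"oral_naltrexone"`.
#' @return A list with elements `drug`, `dose_unit`, `half_life_min`,
#'   `half_life_sources_min`, `t_measure_min` (`NA` for naltrexone),
#'   `t_max_min` (`NA` for naltrexone), `affinity_ratio_dor`,
#'   `affinity_ratio_kor`, and `cost` (see [cost_schedule()]).
#' @examples
#' drug_defaults("iv_naloxone")$half_life_min
#' @export
drug_defaults <- function(drug) {
  check_drug(drug)
  path <- system.file("extdata", "defaults.json",
                      package = "opioidblockr", mustWork = TRUE)
  d <- jsonlite::read_json(path, simplifyVector = TRUE)[[drug]]
  d$t_measure_min <- d$t_measure_min %||% NA_real_
  d$t_max_min <- d$t_max_min %||% NA_real_
  stopifnot(d$half_life_min > 0,
            d$affinity_ratio_dor >= 1, d$affinity_ratio_kor >= 1)
  if (!is.na(d$t_max_min) && !is.na(d$t_measure_min)) {
    stopifnot(d$t_max_min < d$t_measure_min)
  }
  d
}

#' Purchasable-unit cost schedule for an antagonist
#'
#' @param drug `"iv_naloxone"` (0.4 mg vial, 4.58-7.07 USD) or
#'   `"oral_naltrexone"` (50 mg tablet, 4.28-9.72 USD).
#' @return A list with `unit_label`, `unit_content` (drug amount per vial or
#'   tablet, in the drug's dose unit), and `unit_price_usd` (`c(low, high)`).
#' @export
cost_schedule <- function(drug) {
  s <- drug_defaults(drug)$cost
  stopifnot(s$unit_content > 0, s$unit_price_usd[1] <= s$unit_price_usd[2])
  s
}
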