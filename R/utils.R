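# Internal argument checks. All stop with classed conditions so callers and the
# CLI can branch on error class rather than message text.

stop_domain <- function(msg, class = "opioidblockr_domain_error") {
  abort(msg, class = c(class, "opioidblockr_error"))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x))) {
    stop_domain(sprintf("`%s` must be a single number.", name))
  }
  if (is.na(x)) return(invisible(x))
  if (strict_lower && x <= lower) {
    stop_domain(sprintf("`%s` must be > %g (got %g).", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    stop_domain(sprintf("`%s` must be >= %g (got %g).", name, lower, x))
  }
  if (x > upper) {
    stop_domain(sprintf("`%s` must be <= %g (got %g).", name, upper, x))
  }
  invisible(x)
}

check_numeric_vec <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) == 0L || anyNA(x)) {
    stop_domain(sprintf("`%s` must be a non-empty numeric vector without NA.", name))
  }
  if (any(x < lower)) {
    stop_domain(sprintf("All values of `%s` must be >= %g.", name, lower))
  }
  invisible(x)
}

#' Supported antagonist drugs
#'
#' @return Character vector of the drug identifiers understood by the
#'   data-loading and modeling functions.
#' @export
supported_drugs <- function() c("iv_naloxone", "oral_naltrexone")

check_drug <- function(drug) {
  if (!is.character(drug) || length(drug) != 1L || !drug %in% supported_drugs()) {
    abort(
      sprintf(
        "Unsupported drug '%s'. Use one of: %s.",
        as.character(drug)[1], paste(supported_drugs(), collapse = ", ")
      ),
      class = c("opioidblockr_unsupported_drug", "opioidblockr_error")
    )
  }
  drug
}

receptor_levels <- function() c("MOR", "DOR", "KOR")

check_receptor <- function(receptor) {
  if (!is.character(receptor) || length(receptor) != 1L ||
      !receptor %in% receptor_levels()) {
    stop_domain(sprintf(
      "Unknown receptor '%s'. Use one of: %s.",
      as.character(receptor)[1], paste(receptor_levels(), collapse = ", ")
    ))
  }
  receptor
}
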