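#' Residual diagnostics for a dose-blockade fit
#'
#' Shapiro-Wilk normality test on the fit residuals, and Levene's test for
#' homogeneity of the residual variance across a grouping factor (by default
#' the measurement method, PET vs dual detector, giving the (1, n - 2) df
#' structure of a two-group split). Levene's test uses group-mean centering by
#' default; median centering (Brown-Forsythe) is available via `center`.
#'
#' @param fit An [ed50_fit][fit_ed50] object.
#' @param groups Optional vector of per-observation group labels; defaults to
#'   the `method` column of the fitted data.
#' @param center `"mean"` (default) or `"median"` centering for Levene's test.
#' @return A list of class `blockade_diagnostics` with elements `shapiro_w`,
#'   `shapiro_p`, `levene_f`, `levene_df` (integer pair), `levene_p`,
#'   `grouping`. [tidy()] returns it as a two-row tibble.
#' @examples
#' fit <- fit_ed50(blockade_observations("iv_naloxone"))
#' fit_diagnostics(fit)
#' @export
fit_diagnostics <- function(fit, groups = NULL, center = c("mean", "median")) {
  stopifnot(inherits(fit, "ed50_fit"))
  center <- match.arg(center)
  res <- fit$residuals
  if (length(res) < 3L) {
    abort("At least 3 residuals are required for the Shapiro-Wilk test.",
          class = c("opioidblockr_insufficient_data", "opioidblockr_error"))
  }
  grouping <- "method"
  if (is.null(groups)) {
    if (!"method" %in% names(fit$data)) {
      stop_domain("No `groups` given and the fitted data have no `method` column.")
    }
    groups <- fit$data$method
  } else {
    grouping <- deparse(substitute(groups))[1]
  }
  if (length(groups) != length(res)) {
    stop_domain("`groups` must have one label per residual.")
  }
  g <- droplevels(factor(groups))
  if (nlevels(g) < 2L) {
    stop_domain("Levene's test needs at least 2 distinct group labels.")
  }

  sw <- shapiro.test(res)
  centre <- if (center == "mean") mean else stats::median
  lev <- car::leveneTest(res ~ g, center = centre)

  structure(
    list(
      shapiro_w = unname(sw$statistic),
      shapiro_p = sw$p.value,
      levene_f = lev[1, "F value"],
      levene_df = c(lev[1, "Df"], lev[2, "Df"]),
      levene_p = lev[1, "Pr(>F)"],
      grouping = grouping,
      center = center
    ),
    class = "blockade_diagnostics"
  )
}

#' @export
print.blockade_diagnostics <- function(x, ...) {
  cat(sprintf("Shapiro-Wilk: W = %.3f, p = %.3f\n", x$shapiro_w, x$shapiro_p))
  cat(sprintf("Levene (%s-centered, by %s): F(%d, %d) = %.3f, p = %.3f\n",
              x$center, x$grouping, x$levene_df[1], x$levene_df[2],
              x$levene_f, x$levene_p))
  invisible(x)
}

#' @export
tidy.blockade_diagnostics <- function(x, ...) {
  tibble(
    test = c("shapiro_wilk", "levene"),
    statistic = c(x$shapiro_w, x$levene_f),
    p.value = c(x$shapiro_p, x$levene_p),
    df1 = c(NA_integer_, x$levene_df[1]),
    df2 = c(NA_integer_, x$levene_df[2])
  )
}

#' Test the ED50 difference between measurement methods
#'
#' Joint least-squares fit of the constrained log-logistic model with a
#' method-specific ED50, `ed50(method) = ed50_PET - delta * I(dual_detector)`
#' equivalently parameterized as two group ED50s. Because the groups are
#' disjoint the joint optimum decouples into two one-dimensional fits; the
#' standard error of the difference comes from the two-parameter linearized
#' (Gauss-Newton) covariance with residual variance `RSS_total / (n - 2)`.
#' `delta_ed50` is reported as PET minus dual detector.
#'
#' @param data Observations with columns `dose`, `blockade`, `method`
#'   containing both methods.
#' @return A list of class `method_contrast`: `delta_ed50`, `se`, `t_stat`,
#'   `df`, `p_value`, plus the per-method ED50s (`ed50_pet`, `ed50_dual`).
#' @examples
#' method_difference_test(blockade_observations("iv_naloxone"))
#' @export
method_difference_test <- function(data) {
  obs <- validate_observations(as_tibble(data))
  split_obs <- split(obs, obs$method)
  if (any(vapply(split_obs, nrow, 1L) == 0L)) {
    abort("Both methods (PET and dual_detector) must be present.",
          class = c("opioidblockr_missing_group", "opioidblockr_error"))
  }
  fits <- lapply(split_obs, fit_ed50)
  e <- vapply(fits, function(f) f$ed50, 1.0)
  rss <- sum(vapply(fits, function(f) f$rss, 1.0))
  n <- nrow(obs)
  df <- n - 2L
  s2 <- rss / df
  # block-diagonal Gauss-Newton covariance: groups share no parameters
  var_g <- vapply(fits, function(f) {
    grad <- 100 * f$data$dose / (f$data$dose + f$ed50)^2
    s2 / sum(grad^2)
  }, 1.0)
  delta <- e[["PET"]] - e[["dual_detector"]]
  se <- sqrt(sum(var_g))
  t_stat <- delta / se
  structure(
    list(
      delta_ed50 = delta, se = se, t_stat = t_stat, df = df,
      p_value = 2 * pt(-abs(t_stat), df = df),
      ed50_pet = e[["PET"]], ed50_dual = e[["dual_detector"]]
    ),
    class = "method_contrast"
  )
}

#' @export
print.method_contrast <- function(x, ...) {
  cat(sprintf("ED50 difference (PET - dual detector): %.4g (SE %.2g)\n",
              x$delta_ed50, x$se))
  cat(sprintf("t(%d) = %.2f, p = %.3f\n", x$df, x$t_stat, x$p_value))
  invisible(x)
}

#' @export
tidy.method_contrast <- function(x, ...) {
  tibble(
    term = "delta_ed50",
    estimate = x$delta_ed50,
    std.error = x$se,
    statistic = x$t_stat,
    df = x$df,
    p.value = x$p_value
  )
}
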