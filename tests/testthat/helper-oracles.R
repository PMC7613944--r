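# Independent oracles used across the suite.

# Lower-branch Lambert W by bisection: w * exp(w) = x is strictly decreasing
# on (-Inf, -1], so the root is bracketed in [-750, -1].
lambert_oracle <- function(x) {
  vapply(x, function(xi) {
    lo <- -750
    hi <- -1
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (mid * exp(mid) > xi) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, 1.0)
}

# Known published observations, inlined independently of the packaged CSVs
# so data-loading bugs cannot hide.
naloxone_rows <- function() {
  tibble::tribble(
    ~dose, ~blockade, ~method, ~study,
    1, 83, "PET", "Frost 1985",
    1, 90, "PET", "Frost 1985",
    0.001, 19, "PET", "Mayberg 1990",
    0.01, 65, "PET", "Mayberg 1990",
    0.1, 97, "PET", "Mayberg 1990",
    1.0, 98, "PET", "Mayberg 1990",
    0.002, 43, "dual_detector", "Kim 1997",
    0.03, 81, "dual_detector", "Kim 1997",
    0, 0, "dual_detector", "Villemagne 1994",
    0.0005, 20, "dual_detector", "Villemagne 1994",
    0.001, 40, "dual_detector", "Villemagne 1994",
    0.005, 75, "dual_detector", "Villemagne 1994",
    0.01, 100, "dual_detector", "Villemagne 1994",
    0.1, 100, "dual_detector", "Villemagne 1994",
    0.5, 100, "dual_detector", "Villemagne 1994",
    1.0, 100, "dual_detector", "Villemagne 1994"
  )
}

naltrexone_rows <- function() {
  tibble::tibble(
    dose = c(2, 5, 5, 5, 15, 50, 50),
    blockade = c(27, 43, 46, 58, 61, 92, 98)
  )
}

# noise-free observations on the model curve
exact_obs <- function(ed50, doses) {
  tibble::tibble(dose = doses, blockade = 100 * doses / (doses + ed50))
}
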