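k_nx <- log(2) / 110
ka_nx <- absorption_rate(k_nx, 25)

test_that("single-event profiles match their closed forms", {
  # instantaneous bolus decays to half at one half-life
  p <- pk_profile(dose_events(100), k = k_nx, times = c(0, 110, 220),
                  truncate = FALSE)
  expect_equal(p$value, c(100, 50, 25))

  # absorbed bolus peaks at the constructed t_max
  pk <- pk_peak(dose_events(138.3, use_absorption = TRUE), k = k_nx, ka = ka_nx)
  expect_equal(pk$t_peak, 25, tolerance = 1e-9)

  # infusion reaches its closed-form level at end of infusion, then decays
  amt <- 60; dur <- 120
  pi <- pk_profile(dose_events(amt, infusion_duration = dur), k = k_nx,
                   times = c(dur, dur + 110), truncate = FALSE)
  expect_equal(pi$value[1], (amt / dur) / k_nx * (1 - exp(-k_nx * dur)))
  expect_equal(pi$value[2], pi$value[1] / 2)
})

test_that("superposition holds to machine precision before truncation", {
  times <- seq(0, 800, by = 1)
  e1 <- dose_events(c(120, 40), time = c(0, 60),
                    use_absorption = c(TRUE, FALSE))
  e2 <- dose_events(50, time = 30, infusion_duration = 90)
  both <- dplyr::bind_rows(e1, e2)
  v1 <- pk_profile(e1, k_nx, ka_nx, times, truncate = FALSE)$value
  v2 <- pk_profile(e2, k_nx, ka_nx, times, truncate = FALSE)$value
  v12 <- pk_profile(both, k_nx, ka_nx, times, truncate = FALSE)$value
  expect_equal(v12, v1 + v2, tolerance = 1e-14)

  # two identical co-timed events equal one event of doubled amount
  vd <- pk_profile(dose_events(c(70, 70), use_absorption = TRUE),
                   k_nx, ka_nx, times, truncate = FALSE)$value
  v2x <- pk_profile(dose_events(140, use_absorption = TRUE),
                    k_nx, ka_nx, times, truncate = FALSE)$value
  expect_equal(vd, v2x, tolerance = 1e-14)
})

test_that("profiles are non-negative and decrease monotonically after the last peak", {
  set.seed(7)
  times <- seq(0, 1200, by = 1)
  for (i in 1:10) {
    n_ev <- sample(1:3, 1)
    ev <- dose_events(
      amount = runif(n_ev, 10, 150),
      time = sort(runif(n_ev, 0, 200)),
      infusion_duration = 0,
      use_absorption = sample(c(TRUE, FALSE), n_ev, replace = TRUE)
    )
    v <- pk_profile(ev, k_nx, ka_nx, times, truncate = FALSE)$value
    expect_true(all(v >= 0))
    pk <- pk_peak(ev, k_nx, ka_nx)
    expect_gte(pk$value, max(v) - 1e-8)
    # every per-event term declines once past the latest single-event peak
    after <- v[times > max(ev$time) + 30]
    expect_true(all(diff(after) < 0))
  }
})

test_that("absorption conserves total exposure (area = amount / k)", {
  A <- 115
  area_inst <- integrate(function(t) A * exp(-k_nx * t), 0, Inf,
                         rel.tol = 1e-10)$value
  f_abs <- function(t) {
    pk_profile(dose_events(A, use_absorption = TRUE), k_nx, ka_nx,
               times = t, truncate = FALSE)$value
  }
  # integrate() may pass unsorted abscissae, so evaluate pointwise
  area_abs <- integrate(function(t) vapply(t, f_abs, 1.0), 0, Inf,
                        rel.tol = 1e-10)$value
  expect_equal(area_inst, A / k_nx, tolerance = 1e-8)
  expect_equal(area_abs, A / k_nx, tolerance = 1e-6)
  # infusion too
  f_inf <- function(t) {
    pk_profile(dose_events(A, infusion_duration = 90), k_nx,
               times = t, truncate = FALSE)$value
  }
  area_inf <- integrate(function(t) vapply(t, f_inf, 1.0), 0, 1e5,
                        rel.tol = 1e-9)$value
  expect_equal(area_inf, A / k_nx, tolerance = 1e-6)
})

test_that("profile at the measurement time round-trips with back-extrapolation", {
  b <- 81.3
  amp <- back_extrapolate(b, k_nx, 55)
  v <- pk_profile(dose_events(amp), k = k_nx, times = c(0, 55),
                  truncate = FALSE)$value
  expect_equal(v[2], b)
})

test_that("the ka = k limit is continuous", {
  times <- seq(0, 600, by = 5)
  v_lim <- pk_profile(dose_events(100, use_absorption = TRUE),
                      k = 0.01, ka = 0.01, times = times, truncate = FALSE)$value
  expect_equal(v_lim, 100 * 0.01 * times * exp(-0.01 * times), tolerance = 1e-12)
  v_near <- pk_profile(dose_events(100, use_absorption = TRUE),
                       k = 0.01, ka = 0.01 * (1 + 1e-9), times = times,
                       truncate = FALSE)$value
  expect_equal(v_near, v_lim, tolerance = 1e-6)
})

test_that("truncation caps at 100 and agrees elsewhere", {
  times <- seq(0, 400, by = 1)
  raw <- pk_profile(dose_events(138.3, use_absorption = TRUE),
                    k_nx, ka_nx, times, truncate = FALSE)
  cap <- pk_profile(dose_events(138.3, use_absorption = TRUE),
                    k_nx, ka_nx, times, truncate = TRUE)
  expect_gt(max(raw$value), 100)
  expect_lte(max(cap$value), 100)
  same <- raw$value <= 100
  expect_equal(cap$value[same], raw$value[same])
})

test_that("event validation enforces the regimen contract", {
  expect_error(dose_events(10, use_absorption = TRUE, infusion_duration = 30),
               class = "opioidblockr_domain_error")
  expect_error(dose_events(-5), class = "opioidblockr_domain_error")
  expect_error(pk_profile(dose_events(10, use_absorption = TRUE), k = k_nx),
               class = "opioidblockr_domain_error")
  expect_error(pk_profile(dose_events(10), k = k_nx, times = c(-5, 0)),
               class = "opioidblockr_domain_error")
})

test_that("regimen and profile CSVs round-trip", {
  ev <- dose_events(c(120, 45), time = c(0, 30),
                    infusion_duration = c(0, 60),
                    use_absorption = c(TRUE, FALSE))
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(
    tibble::tibble(time_min = ev$time, amount = ev$amount,
                   infusion_duration_min = ev$infusion_duration,
                   use_absorption = ev$use_absorption),
    path
  )
  again <- read_regimen_csv(path)
  expect_equal(as.data.frame(again), as.data.frame(ev))

  prof <- pk_profile(ev, k_nx, ka_nx, times = seq(0, 100, 10), receptor = "MOR")
  out <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, out)
  back <- readr::read_csv(out, show_col_types = FALSE)
  expect_equal(back$value, prof$value)
  expect_equal(unique(back$receptor), "MOR")
})
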