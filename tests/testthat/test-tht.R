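test_that("moving average matches the brute-force window mean", {
  expect_equal(smooth_ma(rep(7, 100)), rep(7, 100))
  y_lin <- 3 * (1:100) + 2
  expect_equal(smooth_ma(y_lin)[6:95], y_lin[6:95])
  impulse <- rep(0, 101); impulse[51] <- 1
  sm <- smooth_ma(impulse, 11)
  expect_equal(sm, smooth_brute(impulse, 11))
  expect_equal(sm[46:56], rep(1 / 11, 11))
  expect_equal(sum(sm[45:57] > 0), 11L)
  set.seed(1)
  y <- rnorm(80)
  for (w in c(3, 5, 11)) expect_equal(smooth_ma(y, w), smooth_brute(y, w))
  expect_error(smooth_ma(y, 4), "odd")
  expect_error(smooth_ma(rnorm(9), 11), "smaller than the series length")
})

test_that("symmetric difference quotient is exact on linear and quadratic data", {
  t <- seq(0, 10, by = 0.1)
  expect_equal(sym_derivative(t, 2 * t), rep(2, length(t)))
  d <- sym_derivative(t, t^2)
  interior <- 2:(length(t) - 1)  # symmetric stencil everywhere but endpoints
  expect_equal(d[interior], 2 * t[interior], tolerance = 1e-10)
  t2 <- seq(0, 2 * pi, by = 0.01)
  err <- abs(sym_derivative(t2, sin(t2)) - cos(t2))
  expect_lt(max(err[3:(length(t2) - 2)]), 1e-3)
  expect_error(sym_derivative(c(1, 1, 2, 3, 4), 1:5), "strictly increasing")
})

test_that("second derivative from the first recovers curvature", {
  t <- seq(0, 10, by = 0.1)
  d1 <- sym_derivative(t, t^3)
  d2 <- sym_derivative(t, d1)
  interior <- 5:(length(t) - 4)
  expect_equal(d2[interior], 6 * t[interior], tolerance = 1e-6)
})

test_that("segmentation matches closed-form logistic crossings and the scan oracle", {
  # linear ramp: threshold met at the very first point
  t <- seq(0, 10, by = 0.1)
  seg <- segment_growth(t, rep(5, length(t)))
  expect_identical(seg$start, 1L)
  expect_equal(seg$lag_time, t[1])

  lc <- logistic_curve(A = 1000, k = 1, t0 = 25)
  d1 <- sym_derivative(lc$t, lc$y)
  seg <- segment_growth(lc$t, d1)
  cross <- logistic_crossings(lc$k, lc$t0)
  dt <- lc$t[2] - lc$t[1]
  expect_lt(abs(lc$t[seg$start] - cross["start"]), dt + 1e-9)
  expect_lt(abs(lc$t[seg$end] - cross["end"]), dt + 1e-9)

  # injected pre-max spike: the FIRST crossing wins
  d_spike <- d1
  spike_at <- which(lc$t == 10)
  d_spike[spike_at] <- 0.07 * max(d1)
  seg_s <- segment_growth(lc$t, d_spike)
  expect_identical(seg_s$start, spike_at)
  oracle <- segment_brute(lc$t, d_spike)
  expect_identical(seg_s$start, oracle$start)
  expect_identical(seg_s$end, oracle$end)
})

test_that("flat and decreasing curves yield an undefined-growth signal", {
  t <- seq(0, 20, length.out = 100)
  seg <- segment_growth(t, rep(0, 100))
  expect_false(seg$defined)
  kp <- extract_parameters(list(t = t, y = rep(50, 100)))
  expect_false(kp$defined)
  expect_true(is.na(kp$lag_time) && is.na(kp$max_growth_rate))
})

test_that("logistic kinetic parameters match their closed forms within 1%", {
  lc <- logistic_curve(A = 1000, k = 1, t0 = 20, t = seq(0, 60, by = 0.05))
  kp <- extract_parameters(list(t = lc$t, y = lc$y))
  expect_equal(kp$max_growth_rate, lc$A * lc$k / 4, tolerance = 0.01)
  expect_equal(kp$plateau_height, lc$A, tolerance = 0.01)
  expect_equal(kp$lag_time, logistic_crossings(lc$k, lc$t0)[["start"]],
               tolerance = 0.01)
  expect_equal(kp$acceleration_max, lc$A * lc$k^2 / (6 * sqrt(3)),
               tolerance = 0.02)
  expect_lte(kp$growth_start, lc$t[kp$provenance$argmax_index + 1])
  expect_gte(kp$growth_end, lc$t[kp$provenance$argmax_index + 1])
})

test_that("rates transform dimensionally under axis scalings", {
  lc <- logistic_curve(A = 500, k = 0.8, t0 = 20, t = seq(0, 50, by = 0.05))
  kp <- extract_parameters(list(t = lc$t, y = lc$y))
  kp_y <- extract_parameters(list(t = lc$t, y = 3 * lc$y))
  expect_equal(kp_y$max_growth_rate, 3 * kp$max_growth_rate, tolerance = 1e-8)
  expect_equal(kp_y$plateau_height, 3 * kp$plateau_height, tolerance = 1e-8)
  expect_equal(kp_y$lag_time, kp$lag_time, tolerance = 1e-8)
  kp_t <- extract_parameters(list(t = 2 * lc$t, y = lc$y))
  expect_equal(kp_t$max_growth_rate, kp$max_growth_rate / 2, tolerance = 1e-8)
  expect_equal(kp_t$lag_time, 2 * kp$lag_time, tolerance = 1e-8)
})

test_that("replicate alignment recovers constructed shifts and preserves the mean lag", {
  lc <- logistic_curve(A = 1000, k = 1, t0 = 25, t = seq(0, 60, by = 0.1))
  mk <- function(shift) list(t = lc$t, y = lc$A /
                               (1 + exp(-lc$k * (lc$t - shift - lc$t0))))
  curves <- list(mk(-1), mk(0), mk(1))
  al <- align_replicates(curves)
  expect_true(al$aligned)
  expect_equal(al$shifts, c(1, 0, -1), tolerance = 0.05)
  expect_equal(sum(al$shifts), 0, tolerance = 1e-9)
  lags_after <- vapply(al$curves,
                       function(cv) extract_parameters(cv)$lag_time,
                       numeric(1))
  expect_equal(lags_after, rep(mean(al$lags), 3), tolerance = 0.02)

  ident <- align_replicates(list(mk(0), mk(0)))
  expect_equal(ident$shifts, c(0, 0), tolerance = 1e-9)

  flat <- list(t = lc$t, y = rep(1, length(lc$t)))
  expect_warning(al2 <- align_replicates(list(mk(0), flat)), "skipped")
  expect_false(al2$aligned)
})

test_that("dose series is geometric with exact endpoints", {
  expect_equal(build_dose_series(n = 2), c(1 / 5000, 1))
  r <- build_dose_series()
  expect_length(r, 10L)
  expect_identical(r[1], 1 / 5000)
  expect_identical(r[10], 1)
  expect_equal(diff(log(r)), rep(log(5000) / 9, 9))
  expect_identical(build_dose_series(include_control = TRUE)[1], 0)
  expect_error(build_dose_series(n = 1), ">= 2")
})

test_that("raw and max-normalized extraction agree on trends", {
  # dose range kept low enough that every curve plateaus inside the window
  design <- assay_design(n_ratios = 4, ratio_max = 0.01, n_replicates = 2,
                         noise_sd = 0.5, lag_jitter_sd = 0,
                         t_grid = seq(0, 50, by = 0.25), rng_seed = 3L)
  set <- generate_tht_assay(aggregation_model(), design)
  cmp <- suppressWarnings(compare_normalization(set))
  raw_c <- cmp$raw[cmp$raw$stat == "curve" & cmp$raw$defined, ]
  nrm_c <- cmp$normalized[cmp$normalized$stat == "curve" &
                            cmp$normalized$defined, ]
  expect_equal(nrm_c$lag_time, raw_c$lag_time, tolerance = 1e-8)
  expect_equal(nrm_c$growth_duration, raw_c$growth_duration, tolerance = 1e-8)
  expect_true(all(abs(nrm_c$plateau_height - 1) < 0.05))
  expect_equal(cmp$rank_correlation[["max_growth_rate"]], 1)
})
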