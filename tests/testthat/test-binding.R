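test_that("CSP formula and above-average flag behave as defined", {
  apo <- peaks3()
  expect_equal(compute_csp(apo, apo)$csp, c(0, 0, 0))
  holo_h <- peaks3(); holo_h$shift_H <- holo_h$shift_H + 0.1
  expect_equal(compute_csp(apo, holo_h)$csp, rep(0.1, 3))
  holo_x <- peaks3(); holo_x$shift_X[2] <- holo_x$shift_X[2] + 1
  prof <- compute_csp(apo, holo_x)
  expect_equal(prof$csp[2], sqrt(0.14), tolerance = 1e-12)
  expect_identical(prof$csp_above_avg, c(FALSE, TRUE, FALSE))
  # invariance under a global reference offset applied to both lists
  off <- function(p) { p$shift_H <- p$shift_H + 0.37
                       p$shift_X <- p$shift_X - 2.1; p }
  expect_equal(compute_csp(off(apo), off(holo_x))$csp, prof$csp)
  dup <- rbind(apo, apo[1, ])
  expect_error(compute_csp(dup, holo_x), "duplicate")
  expect_message(compute_csp(apo, holo_x[-2, ]), "unmatched")
})

test_that("broadening ratios respect the threshold and its overrides", {
  apo <- peaks3()
  holo <- peaks3(I = c(100, 20, 30))
  br <- broadening_ratios(apo, holo)
  expect_equal(br$intensity_ratio, c(1, 0.2, 0.3))
  expect_identical(br$broadened, c(FALSE, TRUE, FALSE))
  br2 <- broadening_ratios(apo, holo, threshold = 0.5)
  expect_identical(br2$broadened, c(FALSE, TRUE, TRUE))
  apo0 <- peaks3(I = c(0, 100, 100))
  br3 <- broadening_ratios(apo0, holo)
  expect_true(br3$ratio_undefined[1] && is.na(br3$intensity_ratio[1]))
})

test_that("PRE classification is the 50%-loss rule and round-trips the simulator", {
  dia <- peaks3(I = c(100, 100, 100))
  para <- peaks3(I = c(40, 100, 60))
  cl <- classify_pre(dia, para)
  expect_identical(cl$pre_active, c(TRUE, FALSE, FALSE))  # 0.6 / 0 / 0.4 loss
  truth <- pre_ground_truth(list(A = c(3, 7, 11), B = c(2, 5)),
                            loss_active = 0.8, loss_inactive = 0.1)
  sim <- simulate_pre_profile(truth, list(A = 1:20, B = 1:15))
  expect_equal(sim$para$intensity[sim$dia$chain == "A"][3] /
                 sim$dia$intensity[1], 0.2)
  cl2 <- classify_pre(sim$dia, sim$para)
  expect_identical(cl2$residue[cl2$chain == "A" & cl2$pre_active],
                   c(3L, 7L, 11L))
  expect_identical(cl2$residue[cl2$chain == "B" & cl2$pre_active], c(2L, 5L))
  # empty active set: every ratio above 0.5
  none <- simulate_pre_profile(pre_ground_truth(list(A = integer()),
                                                0.8, 0.1), list(A = 1:10))
  expect_true(all(none$para$intensity / none$dia$intensity > 0.5))
  expect_warning(classify_pre(dia, rbind(para, peaks3()[1, ] |>
                                           transform(residue = 9))),
                 "without diamagnetic partner")
  expect_error(pre_ground_truth(list(A = 1), loss_active = 0.4),
               "exceed 0.5")
})

test_that("classification functions equal brute-force threshold scans", {
  set.seed(11)
  for (i in 1:20) {
    n <- 30
    dia <- data.frame(residue = 1:n, shift_H = rnorm(n, 8),
                      shift_X = rnorm(n, 118), intensity = runif(n, 50, 150))
    para <- dia
    para$intensity <- dia$intensity * runif(n, 0, 1)
    thr <- runif(1, 0.2, 0.8)
    cl <- classify_pre(dia, para, loss_threshold = thr)
    brute <- (1 - para$intensity / dia$intensity) > thr
    expect_identical(cl$pre_active, brute)
  }
})

test_that("the bound fraction obeys the quadratic isotherm", {
  kd <- 5
  pb <- bound_fraction(kd, P0 = kd, L0 = kd)
  expect_equal(pb, (3 - sqrt(5)) / 2, tolerance = 1e-12)
  expect_equal(bound_fraction(61, 0, 29), 0)
  expect_equal(bound_fraction(61, 1e9, 29), 1, tolerance = 1e-6)
  # strictly decreasing in KD at fixed concentrations
  pbs <- vapply(c(1, 5, 20, 61, 200, 1000),
                function(k) bound_fraction(k, 29, 29), numeric(1))
  expect_true(all(diff(pbs) < 0))
  expect_true(all(pbs >= 0 & pbs <= 1))
})

test_that("titration peaks interpolate free and bound states affinely", {
  ex <- exchange_model(KD = 61, L0 = 29)
  ser <- simulate_titration(ex, c(0, 0.5, 1, 2, 1e6))
  expect_equal(ser$peaks[[1]]$shift_H, ex$shifts$H_free)
  expect_equal(ser$peaks[[5]]$shift_H, ex$shifts$H_bound, tolerance = 1e-3)
  # affine in p_b: shift difference proportional to p_b
  d2 <- ser$peaks[[2]]$shift_H - ex$shifts$H_free
  d3 <- ser$peaks[[3]]$shift_H - ex$shifts$H_free
  expect_equal(d3 / d2, rep(ser$points$p_b[3] / ser$points$p_b[2], 37),
               tolerance = 1e-9)
  intens <- vapply(ser$peaks, function(p) p$intensity[1], numeric(1))
  expect_true(all(diff(intens) < 0))
  expect_error(simulate_titration(ex, c(-1, 0)), ">= 0")
})

test_that("K_D is recovered from titrations across regimes", {
  ratios <- c(0, 0.4, 0.75, 1.25, 2, 3, 5, 8)
  ex <- exchange_model(KD = 61, L0 = 29)
  fit <- fit_kd_titration(simulate_titration(ex, ratios), n_boot = 200)
  expect_equal(fit$KD, 61, tolerance = 0.02)
  # stoichiometric limit: fitted KD below 1% of L0
  ex0 <- exchange_model(KD = 0.01, L0 = 29)
  fit0 <- fit_kd_titration(simulate_titration(ex0, ratios), n_boot = 50,
                           interval = c(-4, 4))
  expect_lt(fit0$KD, 0.01 * 29)
  # bootstrap SD shrinks monotonically with the injected noise
  sds <- vapply(c(0.02, 0.005, 0.001), function(ns) {
    s <- simulate_titration(ex, ratios, noise_sd = ns, rng_seed = 5)
    fit_kd_titration(s, n_boot = 200, rng_seed = 5)$KD_err
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
  # weak-saturation series triggers an identifiability warning
  ex_weak <- exchange_model(KD = 5000, L0 = 29)
  expect_warning(
    fit_kd_titration(simulate_titration(ex_weak, ratios), n_boot = 10,
                     min_csp = 0),
    "identifiable")
})

test_that("K_D recovery holds across a KD x noise grid", {
  ratios <- c(0, 0.4, 0.75, 1.25, 2, 3, 5, 8)
  # recovery under noise is stochastic: assert the median error over
  # replicate simulations; residue noise floor sits an order of magnitude
  # above the position noise, as when selecting reporters for lineshape
  # fitting
  for (kd in c(20, 61, 150))
    for (ns in c(0, 0.002, 0.005)) {
      errs <- vapply(1:5, function(sd) {
        ex <- exchange_model(KD = kd, L0 = 29)
        ser <- simulate_titration(ex, ratios, noise_sd = ns, rng_seed = sd)
        fit <- fit_kd_titration(ser, n_boot = 10, rng_seed = sd,
                                min_csp = max(0.02, 10 * ns))
        abs(fit$KD - kd) / kd
      }, numeric(1))
      tol <- if (ns == 0) 0.02 else 0.15
      expect_lt(stats::median(errs), tol)
    }
})

test_that("two-site lineshape reduces to the fast and slow exchange limits", {
  grid <- seq(6700, 7400, by = 0.25)
  fast <- exchange_model(KD = 61, koff = 1e7, P0 = 29, L0 = 29,
                         R2_free = 15, R2_bound = 40)
  sp_f <- lineshape_two_site(fast, grid, residue = 6)
  pb <- bound_fraction(61, 29, 29)
  sh <- fast$shifts[6, ]
  nu_avg <- ((1 - pb) * sh$H_free + pb * sh$H_bound) * 850
  expect_lt(abs(sp_f$freq[which.max(sp_f$intensity)] - nu_avg), 1)
  slow <- exchange_model(KD = 61, koff = 1, P0 = 29, L0 = 29,
                         R2_free = 15, R2_bound = 15)
  sp_s <- lineshape_two_site(slow, grid, residue = 6)
  # two maxima at the site frequencies with area ratio p_f : p_b
  nu_f <- sh$H_free * 850; nu_b <- sh$H_bound * 850
  i_f <- which.min(abs(sp_s$freq - nu_f))
  i_b <- which.min(abs(sp_s$freq - nu_b))
  expect_gt(sp_s$intensity[i_f], max(sp_s$intensity) * 0.9)
  mid <- which.min(abs(sp_s$freq - (nu_f + nu_b) / 2))
  expect_lt(sp_s$intensity[mid], sp_s$intensity[i_b])
  half <- sp_s$freq < (nu_f + nu_b) / 2
  area_lo <- sum(sp_s$intensity[half])
  area_hi <- sum(sp_s$intensity[!half])
  lo_is_free <- nu_f < nu_b
  ratio <- if (lo_is_free) area_lo / area_hi else area_hi / area_lo
  expect_equal(ratio, (1 - pb) / pb, tolerance = 0.05)
})

test_that("lineshape area is conserved across exchange rates", {
  grid <- seq(5000, 9000, by = 0.5)
  areas <- vapply(c(10, 100, 1e3, 6e3, 1e5), function(k) {
    ex <- exchange_model(KD = 61, koff = k, P0 = 29, L0 = 29,
                         R2_free = 20, R2_bound = 80)
    sum(lineshape_two_site(ex, grid)$intensity)
  }, numeric(1))
  expect_lt(diff(range(areas)) / mean(areas), 0.005)
})

test_that("a shared off-rate is recovered from a lineshape titration", {
  ex <- exchange_model(KD = 61, koff = 6000, L0 = 29)
  ser <- lineshape_series(ex, c(0.4, 1.25, 3, 8), residues = c(1, 2, 3))
  fit <- fit_koff_lineshape(ser)
  expect_equal(fit$koff, 6000, tolerance = 0.2)
})

test_that("BLI steady-state fitting recovers the Langmuir parameters", {
  tab <- simulate_bli(11, 1, c(0.5, 1.5, 5, 15, 50, 150))
  expect_equal(simulate_bli(11, 1, 11)$response, 0.5)  # [A] = KD midpoint
  expect_lt(simulate_bli(11, 1, 1e-6)$response, 1e-7)  # [A] -> 0 limit
  fit <- fit_bli_steady_state(tab$conc, tab$response, n_boot = 100)
  expect_equal(fit$KD, 11, tolerance = 1e-4)
  expect_equal(fit$Rmax, 1, tolerance = 1e-4)
  expect_error(fit_bli_steady_state(c(1, 2), c(0.1, 0.2)), "3 distinct")
  expect_error(fit_bli_steady_state(c(1, 2, 5), c(0.1, 0.2, 0.4)),
               "10-fold")
  expect_error(fit_bli_steady_state(c(1, 10, 100), c(0.5, 0.5, 0.5)),
               "zero variance")
})
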