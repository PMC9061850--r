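mk_profile <- function(above) {
  data.frame(residue = seq_along(above), csp = as.numeric(above),
             csp_above_avg = above)
}

test_that("ligand selection applies the strict-majority rule", {
  # residue 1 above-average at 4 of 7 ratios -> active; residue 2 never
  profs <- lapply(1:7, function(i)
    mk_profile(c(i <= 4, FALSE, TRUE)))
  rs <- select_ligand_actives(profs)
  expect_identical(rs$chains$A, c(1L, 3L))
  # exactly half (2 of 4) is NOT a strict majority
  profs2 <- lapply(1:4, function(i) mk_profile(c(i <= 2, TRUE)))
  expect_identical(select_ligand_actives(profs2)$chains$A, 2L)
})

test_that("a titration built around the two binding segments yields the 12-residue set", {
  truth_set <- c(6, 10:13, 17:19, 24, 26:28)
  ex <- exchange_model(KD = 61, L0 = 29)
  ser <- simulate_titration(ex, c(0, 0.4, 0.75, 1.25, 2, 3, 5, 8))
  apo <- ser$peaks[[1]]
  profs <- lapply(ser$peaks[-1], function(pk) compute_csp(apo, pk))
  rs <- select_ligand_actives(profs)
  expect_length(rs$chains$A, 12L)
  expect_identical(rs$chains$A, as.integer(truth_set))
})

test_that("receptor selection recovers noiseless PRE ground truth per chain", {
  actives <- list(alpha = c(8, 9, 12, 118), beta = c(4, 12, 15),
                  betap = c(4, 61, 107))
  truth <- pre_ground_truth(actives, loss_active = 0.8, loss_inactive = 0.1)
  sim <- simulate_pre_profile(truth, list(alpha = 1:150, beta = 1:120,
                                          betap = 1:120))
  prof <- classify_pre(sim$dia, sim$para)
  rs <- select_receptor_actives(prof)
  expect_identical(rs$chains[order(names(rs$chains))],
                   lapply(actives, as.integer)[order(names(actives))])
  # impossible threshold empties every chain
  rs_none <- select_receptor_actives(prof, loss_threshold = 1.0)
  expect_true(all(vapply(rs_none$chains, length, 1L) == 0L))
  bad <- prof
  bad <- rbind(bad, bad[1, ])
  expect_error(select_receptor_actives(bad), "duplicate")
})

test_that("selection is monotone in its thresholds", {
  set.seed(4)
  prof <- data.frame(chain = "A", residue = 1:50,
                     pre_ratio = runif(50), pre_active = NA)
  prev <- NULL
  for (thr in seq(0.1, 0.9, by = 0.2)) {
    cur <- select_receptor_actives(prof, loss_threshold = thr)$chains$A
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  profs <- lapply(1:6, function(i)
    mk_profile(runif(20) < 0.5))
  prev <- NULL
  for (mf in c(0.2, 0.4, 0.6, 0.8)) {
    cur <- select_ligand_actives(profs, majority_frac = mf)$chains$A
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("plain export round-trips and AIR export has one stanza per active", {
  rs <- restraint_set(list(A = c(6, 10), alpha = c(8, 9, 12)))
  f <- withr::local_tempfile(fileext = ".txt")
  export_restraints(rs, f, "plain")
  back <- read_restraints(f)
  expect_identical(back$chains, rs$chains)
  # empty chain omitted from output
  rs2 <- restraint_set(list(A = c(3), B = integer()))
  lines <- export_restraints(rs2, style = "plain")
  expect_length(lines, 1L)
  air <- export_restraints(rs, style = "air")
  expect_identical(sum(grepl("^assign", air)),
                   length(rs$chains$A) + length(rs$chains$alpha))
  expect_identical(export_restraints(rs, style = "air"), air)  # deterministic
  expect_error(export_restraints(rs, style = "xplor"), "arg")
  expect_error(export_restraints(restraint_set(list(A = integer()))),
               "non-empty")
})
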