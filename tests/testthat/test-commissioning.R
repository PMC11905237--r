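test_that("plan-count-weighted mean reproduces the published averages", {
  expect_equal(weighted_mean_diff(dlg_trial(0.01, 1.43, 1.61)), 1.51)
  expect_equal(weighted_mean_diff(dlg_trial(1.00, 9.81, 9.76)), 9.79)
  expect_equal(weighted_mean_diff(dlg_trial(0.1, 2.5, 2.5)), 2.5)
  expect_equal(weighted_mean_diff(dlg_trial(0.1, 1.43, 1.61), digits = NA),
               (12 * 1.43 + 10 * 1.61) / 22)
})

test_that("DLG grid search selects the published optimum", {
  trials <- published_dlg_trials()
  expect_identical(optimize_dlg(trials), 0.01)
})

test_that("DLG ties break toward the smaller candidate", {
  trials <- list(dlg_trial(0.05, 1.5, 1.5), dlg_trial(0.02, 1.5, 1.5))
  expect_identical(optimize_dlg(trials), 0.02)
  expect_error(optimize_dlg(list()), class = "seccheck_input_error")
  expect_error(optimize_dlg(list(dlg_trial(0.01, 1, 1))),
               class = "seccheck_input_error")
})

test_that("DLG search equals exhaustive argmin on random trial sets", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(3:8, 1)
    dlgs <- sort(runif(n, 0, 1))
    trials <- lapply(dlgs, function(d) {
      dlg_trial(d, runif(1, 0.5, 5), runif(1, 0.5, 5),
                n_primary = sample(5:15, 1), n_adaptive = sample(5:15, 1))
    })
    means <- vapply(trials, weighted_mean_diff, numeric(1), digits = NA)
    expect_identical(optimize_dlg(trials), dlgs[which.min(means)])
  }
})

test_that("DLG optimizer recovers a known optimum over 100 synthetic draws", {
  candidates <- c(0, 0.01, 0.02, 0.1, 0.15, 0.2, 1.0)
  hits <- 0L
  for (seed in 1:100) {
    true_dlg <- candidates[(seed %% length(candidates)) + 1L]
    trials <- make_dlg_trials(seed = seed, true_dlg = true_dlg,
                              candidates = candidates)
    if (identical(optimize_dlg(trials), true_dlg)) hits <- hits + 1L
  }
  expect_identical(hits, 100L)
})

test_that("MLC transmission derivation averages the closed-bank readings", {
  expect_equal(derive_transmission(10.0, 0.054, 0.056), 0.0055)
  expect_identical(derive_transmission(1, 0, 0), 0)
  expect_identical(derive_transmission(8, 0.02, 0.07),
                   derive_transmission(8, 0.07, 0.02))
  expect_error(derive_transmission(1, 1.2, 0.1),
               class = "seccheck_measurement_error")
})

test_that("cryostat normalization anchors CF(0) and sorts by angle", {
  eq <- data.frame(gantry_angle = c(0, 90, 180, 270), charge = rep(5, 4))
  tab <- normalize_cryostat(eq)
  expect_identical(tab$correction_factors, rep(1, 4))
  # synthetic readings with a 1.4% dip reproduce the dip in CF
  rd <- make_cryostat_readings(seed = 2, dip = 0.014)
  tab2 <- normalize_cryostat(rd)
  expect_identical(tab2$correction_factors[tab2$gantry_angles == 0], 1)
  expect_equal(max(abs(tab2$correction_factors - 1)), 0.014,
               tolerance = 1e-9)
  # permuted input order gives the identical table
  perm <- rd[sample(nrow(rd)), ]
  expect_identical(normalize_cryostat(perm), tab2)
  expect_error(normalize_cryostat(data.frame(gantry_angle = 10, charge = 1)),
               class = "seccheck_normalization_error")
})

test_that("PDD comparison uses the measured denominator and sign convention", {
  meas <- pdd_table(c(20, 30), c(13, 50), rbind(c(1, 0.835), c(1, 0.850)), 1335)
  mod <- pdd_table(c(20, 30), c(13, 50), rbind(c(1, 0.830), c(1, 0.839)), 1335)
  rows <- compare_pdd(meas, mod, depths = 50, sides = c(20, 30))
  expect_equal(rows$percent_diff[rows$side == 30],
               100 * (0.850 - 0.839) / 0.850, tolerance = 1e-12)
  expect_equal(rows$percent_diff[rows$side == 30], 1.29, tolerance = 1e-2)
  same <- compare_pdd(meas, meas, depths = 50, sides = c(20, 30))
  expect_true(all(same$percent_diff == 0))
  # model above measurement -> negative difference
  rows2 <- compare_pdd(mod, meas, depths = 50, sides = 20)
  expect_lt(rows2$percent_diff, 0)
  expect_error(compare_pdd(meas, mod, depths = 200, sides = 20),
               class = "seccheck_range_error")
})
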