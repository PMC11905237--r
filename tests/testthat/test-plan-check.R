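test_that("field comparison applies the percent-OR-absolute rule inclusively", {
  tol <- tolerance_spec()
  expect_true(compare_field(100, 104.9, tol)$pass)   # 4.9% < 5%
  expect_false(compare_field(100, 106, tol)$pass)    # 6% and 6 MU both out
  expect_true(compare_field(40, 44, tol)$pass)       # 10% fails, 4 MU passes
  expect_true(compare_field(100, 105, tol)$pass)     # boundary is inclusive
  cmp0 <- compare_field(0, 3, tol)
  expect_true(is.na(cmp0$percent_diff))
  expect_true(cmp0$pass)                             # absolute still applies
  expect_false(compare_field(0, 7, tol)$pass)
  expect_equal(compare_field(100, 95, tol)$percent_diff, -5)
})

test_that("loosening any tolerance never converts a pass into a fail", {
  set.seed(11)
  for (i in 1:200) {
    tps <- runif(1, 10, 300)
    engine <- tps * runif(1, 0.85, 1.15)
    base <- tolerance_spec(runif(1, 1, 8), runif(1, 1, 8),
                           runif(1, 1, 8), runif(1, 1, 8))
    loose <- tolerance_spec(base$field_percent * 1.5, base$field_mu * 2,
                            base$point_percent, base$point_dose)
    if (compare_field(tps, engine, base)$pass) {
      expect_true(compare_field(tps, engine, loose)$pass)
    }
  }
})

test_that("POI selection short-circuits on valid predefined candidates", {
  m <- test_model()
  ph <- water_phantom(c(100, 100, 100), 5)
  f <- field_spec(c(-40, 40), c(-40, 40), mu = 100, ssd = 1335)
  dose <- array(100, dim = dim(ph$density))
  res <- select_poi(m, dose, ph, list(f),
                    predefined = list(reference_point = dose_point(0, 0, 50)),
                    prescription = 100)
  expect_identical(res$provenance, "reference_point")
  expect_equal(as.numeric(res$point), c(0, 0, 50))
})

test_that("a candidate too close to an interface yields to the next one", {
  m <- test_model()
  d <- array(1, dim = c(20, 20, 20))
  d[, , 10:20] <- 0.25  # interface plane at z = 50 mm (5 mm voxels)
  ph <- phantom_model(d, 5)
  f <- field_spec(c(-40, 40), c(-40, 40), mu = 100, ssd = 1335)
  dose <- array(100, dim = dim(ph$density))
  # clearance distances are taken to interface voxel centers, so place the
  # candidate in line with a center column: (2.5, 2.5, 48) is 0.5 mm from
  # the interface voxel center at z = 47.5
  res <- select_poi(
    m, dose, ph, list(f),
    predefined = list(reference_point = dose_point(2.5, 2.5, 48),
                      isocenter = dose_point(2.5, 2.5, 25)),
    prescription = 100
  )
  expect_identical(res$provenance, "isocenter")
})

test_that("grid search equals the exhaustive brute-force oracle", {
  m <- test_model()
  set.seed(23)
  d <- array(1, dim = c(12, 12, 12))
  d[, , 7:12] <- 0.25
  ph <- phantom_model(d, 10)
  fields <- list(
    field_spec(c(-40, 40), c(-40, 40), mu = 120, ssd = 1335),
    field_spec(c(-20, 50), c(-30, 30), mu = 80, ssd = 1335)
  )
  dose <- array(runif(12^3, 60, 100), dim = dim(d))
  rule <- poi_rule()
  res <- select_poi(m, dose, ph, fields, predefined = list(), rule = rule,
                    prescription = 100)
  oracle <- brute_force_poi(m, dose, ph, fields, rule, res$floor_used, 100)
  expect_equal(as.numeric(res$point), as.numeric(oracle))
})

test_that("no-valid-point is reported even after loosening to 70%", {
  m <- test_model()
  ph <- water_phantom(c(60, 60, 60), 10)
  f <- field_spec(c(-5, 5), c(-5, 5), mu = 100, ssd = 1335)  # tiny field
  dose <- array(100, dim = dim(ph$density))
  expect_error(select_poi(m, dose, ph, list(f), prescription = 100),
               class = "seccheck_no_valid_point")
})

test_that("self-check plans pass with zero differences and perturbations fail", {
  m <- test_model()
  plan <- make_step_and_shoot_plan(m, n_segments = 3, seed = 5)
  plan <- plan_with_engine_tps(m, plan)
  rep0 <- check_plan(m, plan)
  expect_true(rep0$overall)
  expect_equal(max(abs(rep0$fields$percent_diff)), 0, tolerance = 1e-9)
  expect_equal(rep0$point$percent_diff, 0, tolerance = 1e-9)
  # +7% MU on one field fails exactly that row
  plan_bad <- perturb_plan_mu(plan, 2, 1.07)
  rep1 <- check_plan(m, plan_bad)
  expect_false(rep1$overall)
  expect_identical(which(!rep1$fields$verdict), 2L)
})

test_that("plan reports carry one row per field", {
  m <- test_model()
  plan <- make_step_and_shoot_plan(m, n_segments = 11, seed = 9)
  plan <- plan_with_engine_tps(m, plan)
  rep <- check_plan(m, plan)
  expect_identical(nrow(rep$fields), 11L)
  expect_true(rep$overall)
})

test_that("an unresolvable field is annotated unverifiable and fails the plan", {
  m <- test_model()
  plan <- make_step_and_shoot_plan(m, n_segments = 2, seed = 3)
  plan <- plan_with_engine_tps(m, plan)
  # shrink the aperture below the table hull so the lookup fails
  plan$fields[[2]]$jaw_x <- c(-5, 5)
  plan$fields[[2]]$jaw_y <- c(-5, 5)
  plan$fields[[2]]$mlc_aperture <- NULL
  rep <- check_plan(m, plan)
  expect_false(rep$overall)
  expect_match(rep$fields$note[2], "unverifiable")
  expect_true(rep$fields$verdict[1])
})
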