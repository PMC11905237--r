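test_that("Sterling equivalent square matches the closed form", {
  expect_equal(equivalent_square(100, 100), 100)
  expect_equal(equivalent_square(50, 200), 80)
  # hand evaluation of 2XY/(X+Y) for the maximum jaw opening
  expect_equal(equivalent_square(500, 220), 305.56, tolerance = 0.01 / 305)
  expect_error(equivalent_square(-10, 100), class = "seccheck_domain_error")
  expect_error(equivalent_square(0, 100), class = "seccheck_domain_error")
})

test_that("PDD lookup is bit-exact at every printed grid node", {
  m <- test_model()
  nodes <- printed_pdd_nodes()
  for (i in seq_len(nrow(nodes))) {
    expect_identical(pdd_lookup(m, nodes$side[i], nodes$depth[i]),
                     nodes$value[i])
  }
})

test_that("PDD lookup interpolates bilinearly and enforces its hull", {
  m <- test_model()
  # midpoint in field side at a depth node
  expect_equal(pdd_lookup(m, 25, 50), (0.830 + 0.839) / 2)
  # midpoint in depth at a side node
  expect_equal(pdd_lookup(m, 100, 115), (0.708 + 0.602) / 2)
  expect_error(pdd_lookup(m, 100, 200), class = "seccheck_range_error")
  expect_error(pdd_lookup(m, 5, 50), class = "seccheck_range_error")
  # log-linear extrapolation from the last two depth nodes, opt-in only
  v <- pdd_lookup(m, 100, 150, extrapolate = TRUE)
  slope <- (log(0.602) - log(0.708)) / 30
  expect_equal(v, exp(log(0.602) + slope * 20), tolerance = 1e-12)
})

test_that("output factor is exactly 1 at the reference side and exact at nodes", {
  m <- test_model()
  expect_identical(scp_lookup(m, 100), 1)
  tab <- m$output_factors
  for (i in seq_along(tab$equivalent_square_sides)) {
    expect_identical(scp_lookup(m, tab$equivalent_square_sides[i]),
                     tab$scp_values[i])
  }
})

test_that("cryostat correction is anchored, periodic and bridges gaps", {
  m <- test_model()
  expect_identical(cryostat_cf(m, 0), 1)
  expect_identical(cryostat_cf(m, 360), 1)
  set.seed(42)
  theta <- runif(1000, -720, 720)
  for (t in theta[1:50]) {
    expect_equal(cryostat_cf(m, t), cryostat_cf(m, t + 360), tolerance = 1e-12)
  }
  expect_equal(vapply(theta, function(t) cryostat_cf(m, t), numeric(1)),
               vapply(theta + 360, function(t) cryostat_cf(m, t), numeric(1)),
               tolerance = 1e-12)
  # the unmeasured 8-18 degree span is bridged linearly between its ends
  tab <- cryostat_table(c(0, 8, 18, 30), c(1, 0.996, 0.992, 0.99))
  expect_equal(cryostat_cf(tab, 13), (0.996 + 0.992) / 2)
  expect_equal(cryostat_cf(tab, 10), 0.996 + (0.992 - 0.996) * 2 / 10)
  # wrap segment between the last node and 360
  expect_equal(cryostat_cf(tab, 195), (0.99 + 1) / 2)
})

test_that("table validators reject malformed models", {
  expect_error(cryostat_table(c(0, 10), c(0.99, 1)),
               class = "seccheck_validation_error")  # CF(0) != 1
  expect_error(cryostat_table(numeric(0), numeric(0)),
               class = "seccheck_config_error")
  expect_error(pdd_table(c(20, 10), c(10, 50), matrix(0.5, 2, 2), 1335),
               class = "seccheck_validation_error")  # non-ascending sides
  expect_error(pdd_table(c(10, 20), c(50, 10), matrix(0.5, 2, 2), 1335),
               class = "seccheck_validation_error")  # non-monotone depth grid
  # rising beyond the depth of maximum
  expect_error(pdd_table(20, c(10, 50, 100), matrix(c(1, 0.8, 0.9), 1), 1335),
               class = "seccheck_validation_error")
  expect_error(output_factor_table(c(20, 50), c(0.9, 0.95)),
               class = "seccheck_validation_error")  # no 100 mm anchor
  expect_error(mlc_model(transmission = 0.2),
               class = "seccheck_validation_error")
  expect_error(mlc_model(dosimetric_leaf_gap = 1.5),
               class = "seccheck_validation_error")
})

test_that("the packaged model carries the commissioned MLC settings", {
  m <- test_model()
  expect_identical(m$mlc$transmission, 0.0055)
  expect_identical(m$mlc$dosimetric_leaf_gap, 0.010)
  expect_identical(m$energy_label, "7X-FFF")
  expect_identical(m$calibration$reference_dose, 1)
  expect_identical(m$calibration$reference_mu, 100)
})

test_that("beam-model serialization round trip is lossless", {
  m <- test_model()
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  save_beam_model(m, tf)
  expect_identical(load_beam_model(tf), m)
})

test_that("loader rejects unknown keys and missing tables by name", {
  m <- test_model()
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  save_beam_model(m, tf)
  doc <- jsonlite::fromJSON(tf)
  doc$surprise <- 1
  tf2 <- tempfile(fileext = ".json")
  on.exit(unlink(tf2), add = TRUE)
  jsonlite::write_json(doc, tf2, auto_unbox = TRUE, digits = I(17))
  expect_error(load_beam_model(tf2), "surprise",
               class = "seccheck_schema_error")
  doc$surprise <- NULL
  doc$cryostat <- NULL
  jsonlite::write_json(doc, tf2, auto_unbox = TRUE, digits = I(17))
  expect_error(load_beam_model(tf2), "cryostat",
               class = "seccheck_schema_error")
})

test_that("cm-declared model files are converted at load", {
  m <- test_model()
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  save_beam_model(m, tf)
  doc <- jsonlite::fromJSON(tf, simplifyVector = TRUE)
  doc$length_unit <- "cm"
  scale10 <- function(x) x / 10
  doc$calibration[] <- lapply(doc$calibration, scale10)
  doc$calibration$reference_dose <- m$calibration$reference_dose
  doc$calibration$reference_mu <- m$calibration$reference_mu
  doc$pdd$equivalent_square_sides <- doc$pdd$equivalent_square_sides / 10
  doc$pdd$depths <- doc$pdd$depths / 10
  doc$pdd$nominal_ssd <- doc$pdd$nominal_ssd / 10
  doc$output_factors$equivalent_square_sides <-
    doc$output_factors$equivalent_square_sides / 10
  doc$output_factors$reference_depth <- doc$output_factors$reference_depth / 10
  doc$output_factors$reference_ssd <- doc$output_factors$reference_ssd / 10
  doc$mlc$leaf_width <- doc$mlc$leaf_width / 10
  doc$profiles$sides <- doc$profiles$sides / 10
  doc$dmax <- doc$dmax / 10
  tf2 <- tempfile(fileext = ".json")
  on.exit(unlink(tf2), add = TRUE)
  jsonlite::write_json(doc, tf2, auto_unbox = TRUE, digits = I(17))
  m2 <- load_beam_model(tf2)
  expect_equal(m2$calibration, m$calibration, tolerance = 1e-12)
  expect_equal(m2$pdd$depths, m$pdd$depths, tolerance = 1e-12)
})
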