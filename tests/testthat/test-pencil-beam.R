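test_that("open rectangular apertures reproduce the factor chain within 1%", {
  m <- test_model()
  cases <- list(
    list(jx = c(-50, 50), jy = c(-50, 50),
         pts = list(c(0, 0, 50), c(0, 0, 100), c(20, 10, 50))),
    list(jx = c(-25, 25), jy = c(-100, 100),
         pts = list(c(0, 0, 50), c(0, 40, 50), c(0, -60, 80)))
  )
  for (cs in cases) {
    mlc <- open_mlc_aperture(m, cs$jx, cs$jy)
    f_mlc <- field_spec(cs$jx, cs$jy, mlc_aperture = mlc, mu = 100, ssd = 1335)
    f_open <- field_spec(cs$jx, cs$jy, mu = 100, ssd = 1335)
    for (p in cs$pts) {
      a <- pencil_beam_dose(m, f_mlc, NULL, p)$dose
      b <- point_dose(m, f_open, NULL, p)$dose
      expect_lt(abs(a / b - 1), 0.01)
    }
  }
})

test_that("a fully blocked aperture falls to the transmission floor", {
  m <- test_model()
  mlc_closed <- matrix(0, m$mlc$leaf_count / 2, 2)
  f_closed <- field_spec(c(-50, 50), c(-50, 50), mlc_aperture = mlc_closed,
                         mu = 100, ssd = 1335)
  f_open <- field_spec(c(-50, 50), c(-50, 50), mu = 100, ssd = 1335)
  d_closed <- point_dose(m, f_closed, NULL, c(0, 0, 50))$dose
  d_open <- point_dose(m, f_open, NULL, c(0, 0, 50))$dose
  expect_lt(abs(d_closed / (m$mlc$transmission * d_open) - 1), 0.1)
})

test_that("translating the aperture translates the dose profile", {
  # horn-free model isolates the fluence term, making the equivariance exact
  m <- model_with_profiles(horn_slope = 0)
  mlc1 <- open_mlc_aperture(m, c(-30, 30), c(-40, 20))
  mlc2 <- mlc1
  open1 <- mlc1[, 2] > mlc1[, 1]
  mlc2[open1, ] <- mlc1[open1, ] + 10  # shift +10 mm in-plane
  f1 <- field_spec(c(-30, 30), c(-60, 60), mlc_aperture = mlc1,
                   mu = 100, ssd = 1335)
  f2 <- field_spec(c(-30, 30), c(-60, 60), mlc_aperture = mlc2,
                   mu = 100, ssd = 1335)
  scale_pt <- (1335 + 50) / test_model()$calibration$source_axis_distance
  for (v in c(-20, 0, 15)) {
    r1 <- pencil_beam_dose(m, f1, NULL, c(0, v, 50))
    r2 <- pencil_beam_dose(m, f2, NULL, c(0, v + 10 * scale_pt, 50))
    # the aperture (fluence) factor translates exactly; the full dose also
    # moves with it up to the slant-depth change of the shifted point
    expect_equal(unname(r2$factors["oar"]), unname(r1$factors["oar"]),
                 tolerance = 1e-9)
    expect_equal(r2$dose, r1$dose, tolerance = 1e-4)
  }
})

test_that("a beamlet grid coarser than the smallest opening is rejected", {
  m <- test_model()
  mlc <- matrix(0, m$mlc$leaf_count / 2, 2)
  mlc[40, ] <- c(-1, 1)  # 2 mm opening (plus DLG widening)
  f <- field_spec(c(-50, 50), c(-50, 50), mlc_aperture = mlc,
                  mu = 100, ssd = 1335)
  expect_error(pencil_beam_dose(m, f, NULL, c(0, 0, 50), beamlet_mm = 5),
               class = "seccheck_resolution_error")
})

test_that("pencil beam requires an MLC aperture", {
  m <- test_model()
  f <- field_spec(c(-50, 50), c(-50, 50), mu = 100, ssd = 1335)
  expect_error(pencil_beam_dose(m, f, NULL, c(0, 0, 50)),
               class = "seccheck_validation_error")
})

test_that("heterogeneity scales beamlet weights through radiological path", {
  m <- test_model()
  ph <- make_slab_phantom()
  mlc <- open_mlc_aperture(m, c(-40, 40), c(-40, 40))
  f <- field_spec(c(-40, 40), c(-40, 40), mlc_aperture = mlc,
                  mu = 100, ssd = 1335)
  p_lung <- c(-50, 0, 50)   # behind lung: shorter radiological path
  p_water <- c(-50, 0, 20)  # above the slab
  d_lung <- pencil_beam_dose(m, f, ph, p_lung, beamlet_mm = 2)
  d_water <- pencil_beam_dose(m, f, ph, p_water, beamlet_mm = 2)
  expect_lt(d_lung$rad_depth, 50)
  expect_equal(d_water$rad_depth, 20, tolerance = 1e-3)  # slant vs vertical
  expect_gt(d_lung$dose, 0)
})
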