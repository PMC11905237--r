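#' Calibration settings of a beam model
#'
#' Describes the absolute-dose calibration geometry of the machine: a
#' reference square field at a stated source-to-plane distance and depth
#' delivers `reference_dose` Gy for `reference_mu` monitor units. The
#' calibration-point source distance is
#' `source_to_plane_distance + calibration_depth`.
#'
#' @param reference_field_side Side of the square reference field, mm.
#' @param source_to_plane_distance Source to phantom-surface distance, mm.
#' @param calibration_depth Depth of the calibration point, mm.
#' @param reference_dose Dose delivered at calibration, Gy.
#' @param reference_mu Monitor units delivered at calibration.
#' @param source_axis_distance Source-isocenter distance, mm.
#' @return An object of class `calibration_spec`.
#' @export
calibration_spec <- function(reference_field_side = 100,
                             source_to_plane_distance = 1385,
                             calibration_depth = 50,
                             reference_dose = 1,
                             reference_mu = 100,
                             source_axis_distance = 1435) {
  check_number(reference_field_side, "reference_field_side", positive = TRUE)
  check_number(source_to_plane_distance, "source_to_plane_distance", positive = TRUE)
  check_number(calibration_depth, "calibration_depth", positive = TRUE)
  check_number(reference_dose, "reference_dose", positive = TRUE)
  check_number(reference_mu, "reference_mu", positive = TRUE)
  check_number(source_axis_distance, "source_axis_distance", positive = TRUE)
  structure(
    list(
      reference_field_side = as.numeric(reference_field_side),
      source_to_plane_distance = as.numeric(source_to_plane_distance),
      calibration_depth = as.numeric(calibration_depth),
      reference_dose = as.numeric(reference_dose),
      reference_mu = as.numeric(reference_mu),
      source_axis_distance = as.numeric(source_axis_distance)
    ),
    class = "calibration_spec"
  )
}

#' Percent depth-dose table
#'
#' Rectangular grid of fractional depth dose (relative to the depth of
#' maximum) indexed by equivalent-square field side and depth, both mm,
#' measured/modelled at a fixed nominal SSD. Values must be positive and,
#' for each field size, monotonically non-increasing beyond the depth of
#' maximum.
#'
#' @param equivalent_square_sides Ascending vector of field sides, mm.
#' @param depths Ascending vector of depths, mm.
#' @param values Matrix `length(sides) x length(depths)` of fractions.
#' @param nominal_ssd SSD at which the table applies, mm.
#' @return An object of class `pdd_table`.
#' @export
pdd_table <- function(equivalent_square_sides, depths, values, nominal_ssd) {
  values <- as.matrix(values)
  if (!is_ascending(equivalent_square_sides)) {
    stop_seccheck("equivalent_square_sides must be strictly ascending",
                  "seccheck_validation_error")
  }
  if (!is_ascending(depths)) {
    stop_seccheck("depth grid must be strictly ascending",
                  "seccheck_validation_error")
  }
  if (nrow(values) != length(equivalent_square_sides) ||
      ncol(values) != length(depths)) {
    stop_seccheck("PDD value matrix does not match the side x depth grid",
                  "seccheck_validation_error")
  }
  if (any(!is.finite(values)) || any(values <= 0) || any(values > 1.2)) {
    stop_seccheck("PDD values must lie in (0, 1.2]", "seccheck_validation_error")
  }
  for (i in seq_len(nrow(values))) {
    row <- values[i, ]
    j <- which.max(row)
    if (j < length(row) && any(diff(row[j:length(row)]) > 1e-12)) {
      stop_seccheck(
        sprintf("PDD for side %g mm is not non-increasing beyond its maximum",
                equivalent_square_sides[i]),
        "seccheck_validation_error"
      )
    }
  }
  check_number(nominal_ssd, "nominal_ssd", positive = TRUE)
  structure(
    list(
      equivalent_square_sides = as.numeric(equivalent_square_sides),
      depths = as.numeric(depths),
      values = unname(values),
      nominal_ssd = nominal_ssd
    ),
    class = "pdd_table"
  )
}

#' Total scatter factor (S\[c,p\]) table
#'
#' Relative output versus equivalent-square field side at a stated reference
#' depth and SSD. The factor at the 100 mm reference field side must be
#' exactly 1 and factors must be non-decreasing with field side.
#'
#' @param equivalent_square_sides Ascending field sides, mm.
#' @param scp_values Dimensionless factors, one per side.
#' @param reference_depth Measurement depth, mm.
#' @param reference_ssd Measurement SSD, mm.
#' @return An object of class `output_factor_table`.
#' @export
output_factor_table <- function(equivalent_square_sides, scp_values,
                                reference_depth = 100, reference_ssd = 1335) {
  if (!is_ascending(equivalent_square_sides)) {
    stop_seccheck("equivalent_square_sides must be strictly ascending",
                  "seccheck_validation_error")
  }
  if (length(scp_values) != length(equivalent_square_sides)) {
    stop_seccheck("scp_values and sides differ in length",
                  "seccheck_validation_error")
  }
  i_ref <- match(100, equivalent_square_sides)
  if (is.na(i_ref) || scp_values[i_ref] != 1) {
    stop_seccheck(
      "output-factor table must contain the 100 mm reference side with factor exactly 1",
      "seccheck_validation_error"
    )
  }
  if (any(diff(scp_values) < 0)) {
    stop_seccheck("output factors must be non-decreasing with field side",
                  "seccheck_validation_error")
  }
  structure(
    list(
      equivalent_square_sides = as.numeric(equivalent_square_sides),
      scp_values = as.numeric(scp_values),
      reference_depth = reference_depth,
      reference_ssd = reference_ssd
    ),
    class = "output_factor_table"
  )
}

#' Cryostat gantry-angle correction table
#'
#' Output correction factor CF(theta) for attenuation by the MR cryostat,
#' normalized so CF(0 deg) = 1 exactly. The table is treated as periodic in
#' gantry angle.
#'
#' @param gantry_angles Strictly increasing angles in `[0, 360)` degrees.
#' @param correction_factors Dimensionless factors, one per angle.
#' @return An object of class `cryostat_table`.
#' @export
cryostat_table <- function(gantry_angles, correction_factors) {
  if (length(gantry_angles) == 0L) {
    stop_seccheck("cryostat table is empty", "seccheck_config_error")
  }
  if (!is_ascending(gantry_angles) ||
      any(gantry_angles < 0) || any(gantry_angles >= 360)) {
    stop_seccheck("gantry angles must be strictly increasing within [0, 360)",
                  "seccheck_validation_error")
  }
  if (length(correction_factors) != length(gantry_angles)) {
    stop_seccheck("angles and correction factors differ in length",
                  "seccheck_validation_error")
  }
  i0 <- match(0, gantry_angles)
  if (is.na(i0) || correction_factors[i0] != 1) {
    stop_seccheck("CF at gantry 0 deg must be present and exactly 1",
                  "seccheck_validation_error")
  }
  structure(
    list(
      gantry_angles = as.numeric(gantry_angles),
      correction_factors = as.numeric(correction_factors)
    ),
    class = "cryostat_table"
  )
}

#' Multi-leaf collimator model
#'
#' @param transmission Fractional dose transmitted through closed leaves
#'   (must satisfy `0 <= transmission < 0.1`).
#' @param dosimetric_leaf_gap Effective rounded-leaf-end gap, cm, in
#'   `[0, 1]` (the range the configuration accepts).
#' @param leaf_count Total number of leaves (two banks).
#' @param leaf_width Single leaf width projected to isocenter, mm. Leaf
#'   pairs stack along the cross-plane (x) axis and travel in-plane (y).
#' @return An object of class `mlc_model`.
#' @export
mlc_model <- function(transmission = 0.0055, dosimetric_leaf_gap = 0.010,
                      leaf_count = 160, leaf_width = 7.175) {
  check_number(transmission, "transmission")
  if (transmission < 0 || transmission >= 0.1) {
    stop_seccheck("transmission must lie in [0, 0.1)", "seccheck_validation_error")
  }
  check_number(dosimetric_leaf_gap, "dosimetric_leaf_gap")
  if (dosimetric_leaf_gap < 0 || dosimetric_leaf_gap > 1) {
    stop_seccheck("dosimetric_leaf_gap (cm) must lie in [0, 1]",
                  "seccheck_validation_error")
  }
  if (leaf_count %% 2 != 0 || leaf_count <= 0) {
    stop_seccheck("leaf_count must be a positive even number",
                  "seccheck_validation_error")
  }
  structure(
    list(
      transmission = transmission,
      dosimetric_leaf_gap = dosimetric_leaf_gap,
      leaf_count = as.integer(leaf_count),
      leaf_width = leaf_width
    ),
    class = "mlc_model"
  )
}

#' Off-axis profile parameterization
#'
#' Declared functional form for off-axis ratios: an erf-shaped penumbra per
#' axis multiplied by a linear FFF off-axis envelope, with the cross-plane
#' profile translated by a Lorentz lateral shift and floored at the MLC
#' transmission far outside the aperture. Parameters are tabulated per
#' equivalent-square field side and interpolated linearly between sides.
#'
#' @param sides Ascending equivalent-square sides, mm.
#' @param penumbra_width 80--20 penumbra width at dmax, mm.
#' @param asymmetry_shift Lorentz lateral displacement of the cross-plane
#'   profile, mm (positive x direction).
#' @param horn_slope FFF envelope slope, fractional decrease per mm off axis.
#' @param depth_broadening Penumbra growth with depth, mm per mm.
#' @return An object of class `profile_model`.
#' @export
profile_model <- function(sides, penumbra_width, asymmetry_shift,
                          horn_slope, depth_broadening) {
  n <- length(sides)
  if (!is_ascending(sides)) {
    stop_seccheck("profile sides must be strictly ascending",
                  "seccheck_validation_error")
  }
  lens <- c(length(penumbra_width), length(asymmetry_shift),
            length(horn_slope), length(depth_broadening))
  if (any(lens != n)) {
    stop_seccheck("profile parameter vectors must match length(sides)",
                  "seccheck_validation_error")
  }
  if (any(penumbra_width <= 0) || any(horn_slope < 0) ||
      any(depth_broadening < 0)) {
    stop_seccheck("profile parameters out of range", "seccheck_validation_error")
  }
  structure(
    list(
      sides = as.numeric(sides),
      penumbra_width = as.numeric(penumbra_width),
      asymmetry_shift = as.numeric(asymmetry_shift),
      horn_slope = as.numeric(horn_slope),
      depth_broadening = as.numeric(depth_broadening)
    ),
    class = "profile_model"
  )
}

#' Full beam model of one machine/energy
#'
#' Aggregates the calibration settings and every dosimetric table needed by
#' the dose engine. Internal units are millimetres, Gray and monitor units.
#'
#' @param energy_label Text label, e.g. `"7X-FFF"`.
#' @param calibration A [calibration_spec()].
#' @param pdd A [pdd_table()].
#' @param output_factors An [output_factor_table()].
#' @param cryostat A [cryostat_table()].
#' @param mlc An [mlc_model()].
#' @param profiles A [profile_model()].
#' @param dmax Depth of maximum dose used by SSD conversion, mm.
#' @return An object of class `beam_model`.
#' @export
beam_model <- function(energy_label, calibration, pdd, output_factors,
                       cryostat, mlc, profiles, dmax = 13) {
  stopifnot(
    inherits(calibration, "calibration_spec"),
    inherits(pdd, "pdd_table"),
    inherits(output_factors, "output_factor_table"),
    inherits(cryostat, "cryostat_table"),
    inherits(mlc, "mlc_model"),
    inherits(profiles, "profile_model")
  )
  check_number(dmax, "dmax", positive = TRUE)
  structure(
    list(
      energy_label = as.character(energy_label),
      calibration = calibration,
      pdd = pdd,
      output_factors = output_factors,
      cryostat = cryostat,
      mlc = mlc,
      profiles = profiles,
      dmax = dmax
    ),
    class = "beam_model"
  )
}

#' @export
print.beam_model <- function(x, ...) {
  cal <- x$calibration
  cat("<beam_model> ", x$energy_label, "\n", sep = "")
  cat(sprintf("  calibration: %g Gy / %g MU, %g mm field, STD %g mm, depth %g mm\n",
              cal$reference_dose, cal$reference_mu, cal$reference_field_side,
              cal$source_to_plane_distance, cal$calibration_depth))
  cat(sprintf("  PDD grid: %d sides x %d depths (SSD %g mm), dmax %g mm\n",
              length(x$pdd$equivalent_square_sides), length(x$pdd$depths),
              x$pdd$nominal_ssd, x$dmax))
  cat(sprintf("  output factors: %d sides; cryostat: %d angles\n",
              length(x$output_factors$equivalent_square_sides),
              length(x$cryostat$gantry_angles)))
  cat(sprintf("  MLC: transmission %.4g, DLG %.3g cm, %d leaves\n",
              x$mlc$transmission, x$mlc$dosimetric_leaf_gap, x$mlc$leaf_count))
  invisible(x)
}

#' Sterling equivalent square of a rectangular field
#'
#' `2 X Y / (X + Y)`: side of the square field dosimetrically equivalent to
#' an `X x Y` rectangle (TG-71 practice).
#'
#' @param x_extent,y_extent Field extents, mm, both > 0.
#' @return Equivalent square side, mm.
#' @examples
#' equivalent_square(100, 100) # 100
#' equivalent_square(50, 200)  # 80
#' @export
equivalent_square <- function(x_extent, y_extent) {
  check_number(x_extent, "x_extent", positive = TRUE)
  check_number(y_extent, "y_extent", positive = TRUE)
  2 * x_extent * y_extent / (x_extent + y_extent)
}

#' Percent depth-dose lookup
#'
#' Exact table value at grid nodes; bilinear interpolation between nodes
#' (linear in equivalent-square side, linear in depth). Depths beyond the
#' last measured node may optionally be extrapolated with the log-linear
#' slope of the last two nodes; this is off by default.
#'
#' @param model A [beam_model()] or a bare [pdd_table()].
#' @param eq_square Equivalent-square side, mm.
#' @param depth Depth, mm.
#' @param extrapolate Allow log-linear extrapolation beyond the deepest node.
#' @return Fraction of maximum dose.
#' @export
pdd_lookup <- function(model, eq_square, depth, extrapolate = FALSE) {
  tab <- if (inherits(model, "beam_model")) model$pdd else model
  stopifnot(inherits(tab, "pdd_table"))
  check_number(eq_square, "eq_square", positive = TRUE)
  check_number(depth, "depth", positive = TRUE)
  sides <- tab$equivalent_square_sides
  depths <- tab$depths
  dmax_tab <- depths[length(depths)]
  if (depth > dmax_tab && extrapolate) {
    n <- length(depths)
    at_depth <- function(d) {
      vapply(seq_along(sides), function(i) {
        slope <- (log(tab$values[i, n]) - log(tab$values[i, n - 1L])) /
          (depths[n] - depths[n - 1L])
        exp(log(tab$values[i, n]) + slope * (d - depths[n]))
      }, numeric(1))
    }
    return(lin_interp(sides, at_depth(depth), eq_square))
  }
  if (eq_square < sides[1L] || eq_square > sides[length(sides)] ||
      depth < depths[1L] || depth > dmax_tab) {
    stop_seccheck(
      sprintf("PDD query (side %g mm, depth %g mm) outside table hull",
              eq_square, depth),
      "seccheck_range_error"
    )
  }
  by_side <- vapply(seq_along(sides), function(i) {
    lin_interp(depths, tab$values[i, ], depth)
  }, numeric(1))
  lin_interp(sides, by_side, eq_square)
}

#' Total scatter factor lookup
#'
#' Linear interpolation of S\[c,p\] in equivalent-square side; exact at nodes.
#'
#' @inheritParams pdd_lookup
#' @return Dimensionless output factor.
#' @export
scp_lookup <- function(model, eq_square) {
  tab <- if (inherits(model, "beam_model")) model$output_factors else model
  stopifnot(inherits(tab, "output_factor_table"))
  check_number(eq_square, "eq_square", positive = TRUE)
  lin_interp(tab$equivalent_square_sides, tab$scp_values, eq_square)
}

#' Cryostat correction factor at a gantry angle
#'
#' Periodic linear interpolation between tabulated angles: any real angle is
#' wrapped modulo 360 and bridged linearly across gaps (including the span
#' skipped during measurement to avoid the cryostat pipe) and across the
#' 358->360 wrap.
#'
#' @param model A [beam_model()] or a bare [cryostat_table()].
#' @param gantry_angle Angle in degrees (any real number).
#' @return Dimensionless correction factor; exactly 1 at 0 degrees.
#' @export
cryostat_cf <- function(model, gantry_angle) {
  tab <- if (inherits(model, "beam_model")) model$cryostat else model
  stopifnot(inherits(tab, "cryostat_table"))
  check_number(gantry_angle, "gantry_angle", finite = TRUE)
  a <- gantry_angle %% 360
  ang <- tab$gantry_angles
  cf <- tab$correction_factors
  # close the circle: repeat the first node at +360
  lin_interp(c(ang, ang[1L] + 360), c(cf, cf[1L]), a)
}

# Interpolate the per-field-size profile parameters at an equivalent square,
# clamped to the tabulated side range.
profile_params <- function(model, eq_square) {
  p <- model$profiles
  s <- min(max(eq_square, p$sides[1L]), p$sides[length(p$sides)])
  list(
    penumbra_width = lin_interp(p$sides, p$penumbra_width, s),
    asymmetry_shift = lin_interp(p$sides, p$asymmetry_shift, s),
    horn_slope = lin_interp(p$sides, p$horn_slope, s),
    depth_broadening = lin_interp(p$sides, p$depth_broadening, s)
  )
}
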