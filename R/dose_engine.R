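#' Inverse-square factor relative to the calibration point
#'
#' `(calibration source distance / source_to_point)^2`, where the
#' calibration source distance is the calibration source-to-plane distance
#' plus the calibration depth (1385 + 50 = 1435 mm for the packaged model).
#'
#' @param model A [beam_model()].
#' @param source_to_point Source-to-point distance, mm (> 0).
#' @return Dimensionless factor; 1 at the calibration distance.
#' @export
inverse_square_factor <- function(model, source_to_point) {
  stopifnot(inherits(model, "beam_model"))
  check_number(source_to_point, "source_to_point", positive = TRUE)
  cal_dist <- model$calibration$source_to_plane_distance +
    model$calibration$calibration_depth
  (cal_dist / source_to_point)^2
}

#' Mayneord F factor: convert a PDD between SSDs
#'
#' `[(ssd_to+dmax)/(ssd_to+depth)]^2 * [(ssd_from+depth)/(ssd_from+dmax)]^2`.
#' Needed because the PDD table is commissioned at one SSD while treatment
#' fields and the calibration geometry use others.
#'
#' @param ssd_from SSD at which the PDD was measured, mm.
#' @param ssd_to SSD at which the PDD is wanted, mm.
#' @param depth Depth, mm.
#' @param dmax Depth of maximum dose, mm.
#' @return Dimensionless factor; 1 when `ssd_from == ssd_to`.
#' @export
mayneord_factor <- function(ssd_from, ssd_to, depth, dmax) {
  check_number(ssd_from, "ssd_from", positive = TRUE)
  check_number(ssd_to, "ssd_to", positive = TRUE)
  check_number(depth, "depth", positive = TRUE)
  check_number(dmax, "dmax", positive = TRUE)
  ((ssd_to + dmax) / (ssd_to + depth))^2 *
    ((ssd_from + depth) / (ssd_from + dmax))^2
}

# ---- aperture geometry ------------------------------------------------------

# x span of MLC leaf pair i at the isocenter plane
leaf_pair_span <- function(model, i) {
  n_pairs <- model$mlc$leaf_count / 2
  w <- model$mlc$leaf_width
  x0 <- -n_pairs * w / 2
  c(x0 + (i - 1) * w, x0 + i * w)
}

# Effective open aperture of a field at the isocenter plane: the MLC pair
# openings widened by DLG/2 per leaf end and clipped by the jaws. Returns
# the equivalent square of the opening and, per pair, the clipped open
# interval used for point-in-aperture tests.
effective_aperture <- function(model, field) {
  jaw_x <- field$jaw_x; jaw_y <- field$jaw_y
  if (is.null(field$mlc_aperture)) {
    return(list(
      eq_square = equivalent_square(diff(jaw_x), diff(jaw_y)),
      fully_blocked = FALSE, has_mlc = FALSE,
      x_range = jaw_x, y_center = mean(jaw_y)
    ))
  }
  widen <- model$mlc$dosimetric_leaf_gap * 10 / 2  # cm -> mm, per side
  n_pairs <- nrow(field$mlc_aperture)
  open_int <- matrix(NA_real_, n_pairs, 2L)
  wx <- numeric(n_pairs)
  for (i in seq_len(n_pairs)) {
    span <- leaf_pair_span(model, i)
    w_clip <- min(span[2L], jaw_x[2L]) - max(span[1L], jaw_x[1L])
    if (w_clip <= 0) next
    e <- field$mlc_aperture[i, ]
    if (e[1L] >= e[2L]) next  # closed pair
    lo <- max(e[1L] - widen, jaw_y[1L])
    hi <- min(e[2L] + widen, jaw_y[2L])
    if (hi <= lo) next
    open_int[i, ] <- c(lo, hi)
    wx[i] <- w_clip
  }
  is_open <- !is.na(open_int[, 1L])
  if (!any(is_open)) {
    return(list(
      eq_square = equivalent_square(diff(jaw_x), diff(jaw_y)),
      fully_blocked = TRUE, has_mlc = TRUE, open_int = open_int,
      x_range = jaw_x, y_center = mean(jaw_y)
    ))
  }
  area <- sum(wx[is_open] * (open_int[is_open, 2L] - open_int[is_open, 1L]))
  x_open <- sum(wx[is_open])
  y_mean <- area / x_open
  spans <- t(vapply(which(is_open), function(i) leaf_pair_span(model, i),
                    numeric(2)))
  x_range <- c(max(min(spans[, 1L]), jaw_x[1L]),
               min(max(spans[, 2L]), jaw_x[2L]))
  list(
    eq_square = equivalent_square(x_open, y_mean),
    fully_blocked = FALSE, has_mlc = TRUE, open_int = open_int,
    x_range = x_range,
    y_center = mean(range(open_int[is_open, ], na.rm = TRUE))
  )
}

# Project beam coordinates (x, y at depth z for a given SSD) to the
# isocenter plane.
project_to_iso <- function(model, field, point) {
  sad <- model$calibration$source_axis_distance
  s <- sad / (field$ssd + point[3L])
  c(point[1L] * s, point[2L] * s)
}

# Is the projected point inside the open aperture? A point exactly on an
# edge counts as inside (documented tie-break).
point_open <- function(model, field, point, aperture = NULL) {
  ap <- aperture %||% effective_aperture(model, field)
  uv <- project_to_iso(model, field, point)
  u <- uv[1L]; v <- uv[2L]
  if (u < field$jaw_x[1L] || u > field$jaw_x[2L] ||
      v < field$jaw_y[1L] || v > field$jaw_y[2L]) return(FALSE)
  if (!ap$has_mlc) return(TRUE)
  if (ap$fully_blocked) return(FALSE)
  n_pairs <- nrow(ap$open_int)
  w <- model$mlc$leaf_width
  x0 <- -n_pairs * w / 2
  i <- floor((u - x0) / w) + 1L
  i <- min(max(i, 1L), n_pairs)
  !is.na(ap$open_int[i, 1L]) &&
    v >= ap$open_int[i, 1L] && v <= ap$open_int[i, 2L]
}

# erf via pnorm (base R has no erf)
.erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# one-axis penumbra term: ~1 deep inside [a, b], 0.5 at the edges, -> 0 outside
.pen <- function(u, a, b, sigma) {
  0.5 * (.erf((b - u) / (sqrt(2) * sigma)) + .erf((u - a) / (sqrt(2) * sigma)))
}

#' Off-axis ratio of a field at a point
#'
#' Product of cross-plane and in-plane profile values from the declared
#' profile parameterization: an erf-shaped penumbra over the aperture edges
#' multiplied by a linear FFF off-axis envelope, with the cross-plane
#' profile translated by the Lorentz `asymmetry_shift`. The ratio is
#' exactly 1 on the central axis whenever the axis lies inside the
#' aperture, and falls to the MLC transmission floor far outside it. A
#' point under a closed MLC region receives the transmission floor
#' directly.
#'
#' @param model A [beam_model()].
#' @param field A [field_spec()].
#' @param point A [dose_point()] or numeric `c(x, y, z)` mm.
#' @return A list with `oar` (the ratio) and `blocked` (TRUE when the MLC
#'   shields the point).
#' @export
off_axis_ratio <- function(model, field, point) {
  stopifnot(inherits(model, "beam_model"), inherits(field, "field_spec"))
  point <- as.numeric(point)
  ap <- effective_aperture(model, field)
  trans <- model$mlc$transmission
  uv <- project_to_iso(model, field, point)
  u <- uv[1L]; v <- uv[2L]

  open_here <- point_open(model, field, point, ap)
  if (ap$has_mlc && !open_here &&
      u >= field$jaw_x[1L] && u <= field$jaw_x[2L] &&
      v >= field$jaw_y[1L] && v <= field$jaw_y[2L]) {
    # under the leaves but inside the jaws: pure transmission
    return(list(oar = trans, blocked = TRUE))
  }

  pp <- profile_params(model, ap$eq_square)
  sigma <- pp$penumbra_width / 1.683 +
    pp$depth_broadening * max(0, point[3L] - model$dmax)
  env <- function(t) pmax(1 - pp$horn_slope * abs(t), 0.5)

  # cross-plane: jaw edges, Lorentz-shifted
  ax <- ap$x_range
  raw_x <- function(t) env(t) * .pen(t - pp$asymmetry_shift, ax[1L], ax[2L], sigma)
  nx <- if (.pen(-pp$asymmetry_shift, ax[1L], ax[2L], sigma) >= 0.5) {
    raw_x(0)
  } else {
    env(mean(ax))
  }

  # in-plane: the open interval of the point's leaf pair (or the jaws)
  ay <- field$jaw_y
  if (ap$has_mlc && open_here) {
    n_pairs <- nrow(ap$open_int)
    w <- model$mlc$leaf_width
    x0 <- -n_pairs * w / 2
    i <- min(max(floor((u - x0) / w) + 1L, 1L), n_pairs)
    if (!is.na(ap$open_int[i, 1L])) ay <- ap$open_int[i, ]
  }
  raw_y <- function(t) env(t) * .pen(t, ay[1L], ay[2L], sigma)
  ny <- if (.pen(0, ay[1L], ay[2L], sigma) >= 0.5) raw_y(0) else env(mean(ay))

  val <- (raw_x(u) / nx) * (raw_y(v) / ny)
  list(oar = max(val, trans), blocked = FALSE)
}

# ---- the point-dose chain ---------------------------------------------------

#' Point dose for a field
#'
#' TG-71-style factorization relative to the calibration point:
#' \deqn{D = MU \cdot \frac{D_{ref}}{MU_{ref}} \cdot S_{c,p}(s) \cdot
#'   \frac{PDD(s, d_{rad})\,F_{May}}{PDD(s_{cal}, d_{cal})\,F_{May,cal}}
#'   \cdot ISF \cdot OAR \cdot CF(\theta)}
#' where `s` is the equivalent square of the DLG-widened open aperture,
#' `d_rad` the radiological depth of the point, `F_May` converts the PDD
#' table's nominal SSD to the field's SSD, `ISF` the dmax-plane
#' inverse-square ratio, `OAR` the off-axis ratio and `CF` the cryostat
#' gantry-angle correction. A point shielded by closed leaves receives the
#' MLC transmission in place of the open-aperture term. The reported dose
#' equals the product of the reported factor breakdown by construction.
#'
#' @param model A [beam_model()].
#' @param field A [field_spec()].
#' @param phantom A [phantom_model()], or `NULL` for homogeneous water.
#' @param point A [dose_point()] or numeric `c(x, y, z)` mm.
#' @param extrapolate Allow PDD extrapolation beyond the deepest table node.
#' @return An object of class `dose_result` with elements `dose` (Gy),
#'   `mu`, `factors` (named breakdown), `transmission_applied`,
#'   `eq_square` and `rad_depth`.
#' @export
point_dose <- function(model, field, phantom = NULL, point,
                       extrapolate = FALSE) {
  stopifnot(inherits(model, "beam_model"), inherits(field, "field_spec"))
  point <- as.numeric(point)
  if (length(point) != 3L) {
    stop_seccheck("point must be c(x, y, z)", "seccheck_validation_error")
  }
  cal <- model$calibration
  ssd0 <- model$pdd$nominal_ssd
  dmax <- model$dmax

  ap <- effective_aperture(model, field)
  d_rad <- beam_rad_depth(phantom, point, field$ssd)
  if (d_rad <= 0) {
    stop_seccheck("point has zero radiological depth (surface or outside beam)",
                  "seccheck_geometry_error")
  }

  scp <- scp_lookup(model, ap$eq_square)
  pdd_pt <- pdd_lookup(model, ap$eq_square, d_rad, extrapolate = extrapolate)
  pdd_cal <- pdd_lookup(model, cal$reference_field_side, cal$calibration_depth)
  may_pt <- mayneord_factor(ssd0, field$ssd, d_rad, dmax)
  may_cal <- mayneord_factor(ssd0, cal$source_to_plane_distance,
                             cal$calibration_depth, dmax)
  isf <- ((cal$source_to_plane_distance + dmax) / (field$ssd + dmax))^2

  oar <- off_axis_ratio(model, field, point)
  oar_val <- if (ap$fully_blocked) model$mlc$transmission else oar$oar
  blocked <- ap$fully_blocked || oar$blocked
  cf <- cryostat_cf(model, field$gantry_angle)

  factors <- c(
    scp = scp,
    pdd = pdd_pt / pdd_cal,
    isf = isf,
    mayneord = may_pt / may_cal,
    oar = oar_val,
    cryostat = cf
  )
  dose <- (field$mu / cal$reference_mu) * cal$reference_dose * prod(factors)
  structure(
    list(dose = dose, mu = field$mu,
         dose_per_mu_ref = cal$reference_dose / cal$reference_mu,
         factors = factors, transmission_applied = blocked,
         eq_square = ap$eq_square, rad_depth = d_rad),
    class = "dose_result"
  )
}

#' @export
print.dose_result <- function(x, ...) {
  cat(sprintf("<dose_result> %.6g Gy for %g MU%s\n", x$dose, x$mu,
              if (x$transmission_applied) " (MLC transmission applied)" else ""))
  cat(sprintf("  eq. square %.4g mm, radiological depth %.4g mm\n",
              x$eq_square, x$rad_depth))
  f <- x$factors
  cat("  factors: ",
      paste(sprintf("%s=%.5g", names(f), f), collapse = "  "), "\n", sep = "")
  invisible(x)
}

#' Monitor units needed for a target dose
#'
#' Inverts [point_dose()]: `target_dose / (dose per single MU)`. The round
#' trip `mu_for_dose(point_dose(mu))` recovers `mu` exactly because the
#' dose chain is linear in MU.
#'
#' @inheritParams point_dose
#' @param target_dose Target dose at the point, Gy.
#' @return Monitor units.
#' @export
mu_for_dose <- function(model, field, phantom = NULL, point, target_dose,
                        extrapolate = FALSE) {
  check_number(target_dose, "target_dose")
  if (target_dose < 0) {
    stop_seccheck("target_dose must be >= 0", "seccheck_domain_error")
  }
  if (target_dose == 0) return(0)
  f1 <- field
  f1$mu <- 1
  dpm <- point_dose(model, f1, phantom, point, extrapolate = extrapolate)$dose
  if (dpm <= 0) {
    stop_seccheck("zero dose rate at the point: unverifiable point",
                  "seccheck_unverifiable_point")
  }
  target_dose / dpm
}
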