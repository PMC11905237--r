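#' Gamma analysis criteria
#'
#' @param dose_percent Dose-difference criterion, % of the global maximum
#'   of the reference distribution.
#' @param dta Distance-to-agreement criterion, mm.
#' @param low_dose_threshold Reference points below this % of the reference
#'   maximum are excluded from the analysis.
#' @return An object of class `gamma_criteria`.
#' @export
gamma_criteria <- function(dose_percent = 5, dta = 5, low_dose_threshold = 10) {
  check_number(dose_percent, "dose_percent", positive = TRUE)
  check_number(dta, "dta", positive = TRUE)
  check_number(low_dose_threshold, "low_dose_threshold", positive = TRUE)
  structure(
    list(dose_percent = dose_percent, dta = dta,
         low_dose_threshold = low_dose_threshold),
    class = "gamma_criteria"
  )
}

.gamma_result <- function(gamma, n_total) {
  structure(
    list(gamma = gamma,
         pass_rate = if (length(gamma)) 100 * mean(gamma <= 1) else NA_real_,
         evaluated_count = length(gamma),
         total_count = n_total),
    class = "gamma_result"
  )
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("<gamma_result> pass rate %.1f%% (%d of %d points evaluated, %d excluded)\n",
              x$pass_rate, sum(x$gamma <= 1), x$evaluated_count,
              x$total_count - x$evaluated_count))
  cat(sprintf("  gamma: mean %.3f, max %.3f\n", mean(x$gamma), max(x$gamma)))
  invisible(x)
}

#' 1-D global gamma comparison of two profiles
#'
#' Standard gamma index: for each reference sample above the low-dose
#' threshold,
#' \deqn{\gamma(r) = \min_{r'} \sqrt{ (\Delta d(r, r')/\Delta D)^2 +
#'   (|r - r'|/\delta)^2 }}
#' with \eqn{\Delta D} the dose criterion as a fraction of the global
#' reference maximum and \eqn{\delta} the DTA. The evaluated curve is
#' linearly interpolated on a search grid of step `dta/10` over a window of
#' `±3 dta` around each reference position.
#'
#' @param reference,evaluated Data frames (or lists) with `position_mm` and
#'   `dose` columns; at least two samples each, overlapping support.
#' @param criteria A [gamma_criteria()].
#' @return A `gamma_result` with per-point gamma values, pass rate (% of
#'   evaluated points with gamma <= 1) and the evaluated count.
#' @export
gamma_profile <- function(reference, evaluated, criteria = gamma_criteria()) {
  stopifnot(inherits(criteria, "gamma_criteria"))
  rx <- as.numeric(reference$position_mm); rd <- as.numeric(reference$dose)
  ex <- as.numeric(evaluated$position_mm); ed <- as.numeric(evaluated$dose)
  if (length(rx) < 2L || length(ex) < 2L) {
    stop_seccheck("both curves need at least two samples", "seccheck_validation_error")
  }
  if (max(ex) < min(rx) || min(ex) > max(rx)) {
    stop_seccheck("curves have disjoint supports", "seccheck_geometry_error")
  }
  ref_max <- max(rd)
  dd_abs <- criteria$dose_percent / 100 * ref_max
  dta <- criteria$dta
  keep <- rd >= criteria$low_dose_threshold / 100 * ref_max
  step <- dta / 10
  gamma <- vapply(which(keep), function(i) {
    xs <- seq(rx[i] - 3 * dta, rx[i] + 3 * dta, by = step)
    xs <- xs[xs >= min(ex) & xs <= max(ex)]
    if (!length(xs)) return(Inf)
    ev <- stats::approx(ex, ed, xout = xs, method = "linear", ties = "ordered")$y
    sqrt(min(((ev - rd[i]) / dd_abs)^2 + ((xs - rx[i]) / dta)^2))
  }, numeric(1))
  .gamma_result(gamma, length(rd))
}

#' 2-D global gamma comparison of two planar dose maps
#'
#' Same definition as [gamma_profile()] on a planar grid: the evaluated
#' distribution is bilinearly interpolated on a search grid of step
#' `dta/10` within a disk of radius `3 dta` around each reference point.
#'
#' @param reference,evaluated Lists with `x`, `y` (ascending axes, mm) and
#'   `dose` (matrix `length(x) x length(y)`).
#' @param criteria A [gamma_criteria()].
#' @return A `gamma_result`.
#' @export
gamma_2d <- function(reference, evaluated, criteria = gamma_criteria()) {
  stopifnot(inherits(criteria, "gamma_criteria"))
  ref_max <- max(reference$dose)
  dd_abs <- criteria$dose_percent / 100 * ref_max
  dta <- criteria$dta
  step <- dta / 10
  offs <- as.matrix(expand.grid(dx = seq(-3 * dta, 3 * dta, by = step),
                                dy = seq(-3 * dta, 3 * dta, by = step)))
  offs <- offs[sqrt(offs[, 1L]^2 + offs[, 2L]^2) <= 3 * dta, , drop = FALSE]

  interp2 <- function(xq, yq) {
    ex <- evaluated$x; ey <- evaluated$y; ed <- evaluated$dose
    ok <- xq >= ex[1L] & xq <= ex[length(ex)] &
      yq >= ey[1L] & yq <= ey[length(ey)]
    out <- rep(NA_real_, length(xq))
    if (!any(ok)) return(out)
    ix <- pmin(pmax(findInterval(xq[ok], ex), 1L), length(ex) - 1L)
    iy <- pmin(pmax(findInterval(yq[ok], ey), 1L), length(ey) - 1L)
    tx <- (xq[ok] - ex[ix]) / (ex[ix + 1L] - ex[ix])
    ty <- (yq[ok] - ey[iy]) / (ey[iy + 1L] - ey[iy])
    out[ok] <- (1 - tx) * (1 - ty) * ed[cbind(ix, iy)] +
      tx * (1 - ty) * ed[cbind(ix + 1L, iy)] +
      (1 - tx) * ty * ed[cbind(ix, iy + 1L)] +
      tx * ty * ed[cbind(ix + 1L, iy + 1L)]
    out
  }

  thr <- criteria$low_dose_threshold / 100 * ref_max
  gammas <- c()
  for (j in seq_along(reference$y)) {
    for (i in seq_along(reference$x)) {
      d0 <- reference$dose[i, j]
      if (d0 < thr) next
      xs <- reference$x[i] + offs[, 1L]
      ys <- reference$y[j] + offs[, 2L]
      ev <- interp2(xs, ys)
      ok <- !is.na(ev)
      if (!any(ok)) { gammas <- c(gammas, Inf); next }
      g2 <- ((ev[ok] - d0) / dd_abs)^2 +
        (offs[ok, 1L]^2 + offs[ok, 2L]^2) / dta^2
      gammas <- c(gammas, sqrt(min(g2)))
    }
  }
  .gamma_result(gammas, length(reference$dose))
}
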