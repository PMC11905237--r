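# Beam-model commissioning procedures: DLG optimization, MLC transmission
# derivation, cryostat normalization, PDD comparison.

#' One dosimetric-leaf-gap trial
#'
#' Mean absolute plan-dose differences between the secondary engine and the
#' TPS for one candidate DLG, split into primary (CT-based) and adaptive
#' (MR-based) plan groups.
#'
#' @param candidate_dlg Candidate DLG, cm.
#' @param primary_mean_diff,adaptive_mean_diff Mean absolute dose
#'   differences, %.
#' @param n_primary,n_adaptive Plan counts (> 0).
#' @return An object of class `dlg_trial`.
#' @export
dlg_trial <- function(candidate_dlg, primary_mean_diff, adaptive_mean_diff,
                      n_primary = 12, n_adaptive = 10) {
  check_number(candidate_dlg, "candidate_dlg")
  if (primary_mean_diff < 0 || adaptive_mean_diff < 0) {
    stop_seccheck("mean absolute differences must be >= 0",
                  "seccheck_validation_error")
  }
  if (n_primary <= 0 || n_adaptive <= 0) {
    stop_seccheck("plan counts must be > 0", "seccheck_validation_error")
  }
  structure(
    list(candidate_dlg = candidate_dlg,
         primary_mean_diff = primary_mean_diff,
         adaptive_mean_diff = adaptive_mean_diff,
         n_primary = n_primary, n_adaptive = n_adaptive),
    class = "dlg_trial"
  )
}

#' Plan-count-weighted mean dose difference of a DLG trial
#'
#' `(n_primary * primary + n_adaptive * adaptive) / (n_primary + n_adaptive)`,
#' rounded to `digits` decimals for reporting (`digits = NA` returns the
#' unrounded value, which the optimizer uses).
#'
#' @param trial A [dlg_trial()].
#' @param digits Decimals for reporting (default 2).
#' @return Weighted mean difference, %.
#' @export
weighted_mean_diff <- function(trial, digits = 2) {
  stopifnot(inherits(trial, "dlg_trial"))
  w <- (trial$n_primary * trial$primary_mean_diff +
          trial$n_adaptive * trial$adaptive_mean_diff) /
    (trial$n_primary + trial$n_adaptive)
  if (is.na(digits)) w else round(w, digits)
}

#' Pick the DLG with the smallest weighted mean difference
#'
#' Grid search over candidate trials: the candidate minimizing the
#' (unrounded) plan-count-weighted mean dose difference is selected; exact
#' ties break toward the smaller DLG.
#'
#' @param trials List of [dlg_trial()] objects (>= 2).
#' @return The selected `candidate_dlg`, cm.
#' @export
optimize_dlg <- function(trials) {
  if (length(trials) < 2L || !all(vapply(trials, inherits, TRUE, "dlg_trial"))) {
    stop_seccheck("optimize_dlg needs at least two dlg_trial objects",
                  "seccheck_input_error")
  }
  means <- vapply(trials, weighted_mean_diff, numeric(1), digits = NA)
  dlgs <- vapply(trials, `[[`, numeric(1), "candidate_dlg")
  best <- which(means == min(means))
  dlgs[best][which.min(dlgs[best])]
}

#' Derive MLC transmission from closed-bank readings
#'
#' Average of the two closed-bank chamber readings divided by the open-field
#' reading.
#'
#' @param open_reading Open-field charge reading (> 0).
#' @param y1_closed,y2_closed Readings with each bank driven closed; must
#'   not exceed the open reading.
#' @return Transmission fraction.
#' @export
derive_transmission <- function(open_reading, y1_closed, y2_closed) {
  check_number(open_reading, "open_reading", positive = TRUE)
  if (y1_closed > open_reading || y2_closed > open_reading) {
    stop_seccheck("closed reading exceeds open reading: check measurement order",
                  "seccheck_measurement_error")
  }
  if (y1_closed < 0 || y2_closed < 0) {
    stop_seccheck("readings must be >= 0", "seccheck_validation_error")
  }
  mean(c(y1_closed, y2_closed)) / open_reading
}

#' Normalize cryostat readings into a correction table
#'
#' Divides every gantry-angle reading by the reading at 0 degrees
#' (CF(0) = 1 exactly) and returns a sorted [cryostat_table()].
#'
#' @param readings Data frame (or list) with `gantry_angle` (degrees) and
#'   `charge` columns; must include a reading at 0.
#' @return A [cryostat_table()].
#' @export
normalize_cryostat <- function(readings) {
  ang <- as.numeric(readings$gantry_angle)
  chg <- as.numeric(readings$charge)
  if (length(ang) == 0L || length(ang) != length(chg)) {
    stop_seccheck("readings need matching gantry_angle and charge columns",
                  "seccheck_validation_error")
  }
  i0 <- match(0, ang)
  if (is.na(i0)) {
    stop_seccheck("no reading at gantry angle 0: cannot normalize",
                  "seccheck_normalization_error")
  }
  o <- order(ang)
  cryostat_table(ang[o], chg[o] / chg[i0])
}

#' Compare a measured PDD table against the model's
#'
#' Percent differences use the measured value as denominator; a model value
#' above the measurement gives a negative difference.
#'
#' @param measured,model [pdd_table()] objects covering the requested nodes.
#' @param depths,sides Depth and side nodes, mm, at which to compare.
#' @return Data frame with side, depth, measured, model and percent
#'   difference columns.
#' @export
compare_pdd <- function(measured, model, depths, sides) {
  stopifnot(inherits(measured, "pdd_table"), inherits(model, "pdd_table"))
  rows <- expand.grid(side = sides, depth = depths)
  rows$measured <- mapply(function(s, d) pdd_lookup(measured, s, d),
                          rows$side, rows$depth)
  rows$model <- mapply(function(s, d) pdd_lookup(model, s, d),
                       rows$side, rows$depth)
  rows$percent_diff <- 100 * (rows$measured - rows$model) / rows$measured
  rows
}
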