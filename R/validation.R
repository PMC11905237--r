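#' Parse a jaw-specification string
#'
#' `"10,10"` means symmetric X and Y widths in cm (edges at half-width);
#' `"[−10,20],10"` means asymmetric X edges at -10 and +20 cm (sorted) with
#' a centered Y width of 10 cm.
#'
#' @param spec Jaw string.
#' @return List with `jaw_x` and `jaw_y` edge pairs, mm.
#' @export
parse_jaw_spec <- function(spec) {
  s <- gsub("−|‐|‑|–", "-", trimws(spec))  # unicode minus
  parse_one <- function(part) {
    if (grepl("^\\[", part)) {
      nums <- as.numeric(strsplit(gsub("\\[|\\]", "", part), ",")[[1L]])
      if (length(nums) != 2L || any(is.na(nums))) {
        stop_seccheck(sprintf("cannot parse jaw edges '%s'", part),
                      "seccheck_parse_error")
      }
      # "[a,b]" with a < b lists the edges directly; reversed order denotes
      # the mirrored field (e.g. "[20,-10]" is "[-10,20]" flipped about the
      # axis), matching the off-axis validation geometries
      if (nums[1L] > nums[2L]) nums <- -nums
      sort(nums * 10)  # cm -> mm, edges
    } else {
      w <- as.numeric(part)
      if (is.na(w) || w <= 0) {
        stop_seccheck(sprintf("cannot parse jaw width '%s'", part),
                      "seccheck_parse_error")
      }
      c(-w * 10 / 2, w * 10 / 2)  # centered width
    }
  }
  # split on the top-level comma (not inside brackets)
  chars <- strsplit(s, "")[[1L]]
  depth <- 0L; cut <- NA_integer_
  for (i in seq_along(chars)) {
    if (chars[i] == "[") depth <- depth + 1L
    else if (chars[i] == "]") depth <- depth - 1L
    else if (chars[i] == "," && depth == 0L) { cut <- i; break }
  }
  if (is.na(cut)) {
    stop_seccheck(sprintf("jaw spec '%s' needs an X and a Y part", spec),
                  "seccheck_parse_error")
  }
  list(jaw_x = parse_one(substr(s, 1L, cut - 1L)),
       jaw_y = parse_one(substr(s, cut + 1L, nchar(s))))
}

#' Packaged point-dose validation fixture
#'
#' The 27 point-dose verification geometries used to benchmark the beam
#' model in a homogeneous water phantom: SSD, jaw setting, measurement
#' point, and the ion-chamber, TPS and secondary-calculation doses (cGy).
#'
#' @return Data frame of class `validation_points` with columns `ssd_cm`,
#'   `jaws`, `x_cm`, `y_cm`, `z_cm`, `measured_cgy`, `tps_cgy`,
#'   `clearcalc_cgy`.
#' @export
load_validation_points <- function() {
  path <- system.file("extdata", "validation_points.csv",
                      package = "seccheck", mustWork = TRUE)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (any(df$measured_cgy <= 0) || any(df$tps_cgy <= 0) ||
      any(df$clearcalc_cgy <= 0)) {
    stop_seccheck("validation fixture contains non-positive doses",
                  "seccheck_validation_error")
  }
  class(df) <- c("validation_points", class(df))
  df
}

#' Turn a validation-fixture row into engine inputs
#'
#' @param row One row of [load_validation_points()].
#' @param mu Monitor units (the validation deliveries used 100 MU).
#' @return List with `field` ([field_spec()]) and `point` ([dose_point()]).
#' @export
validation_geometry <- function(row, mu = 100) {
  jaws <- parse_jaw_spec(row$jaws)
  list(
    field = field_spec(jaw_x = jaws$jaw_x, jaw_y = jaws$jaw_y,
                       gantry_angle = 0, mu = mu, ssd = row$ssd_cm * 10),
    point = dose_point(row$x_cm * 10, row$y_cm * 10, row$z_cm * 10)
  )
}
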