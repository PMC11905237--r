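# Machine aperture limits at isocenter, mm: jaw travel covering the
# 57.4 x 22 cm maximum field.
MACHINE_X_LIMIT <- 287
MACHINE_Y_LIMIT <- 110

#' One treatment beam
#'
#' Jaw edge positions are given at the isocenter plane and support
#' asymmetric settings. The optional MLC aperture is a matrix of per-leaf-
#' pair in-plane (y) edge positions; leaf pairs stack along x with the
#' width given by the machine's MLC model.
#'
#' @param jaw_x,jaw_y Edge position pairs `c(lo, hi)`, mm at isocenter.
#' @param mlc_aperture Optional `n_pairs x 2` matrix of y edges, mm; a pair
#'   with `lo == hi` is closed.
#' @param gantry_angle Gantry angle, degrees.
#' @param mu Monitor units (>= 0).
#' @param ssd Source-surface distance along the central axis, mm.
#' @param id Optional field identifier.
#' @return An object of class `field_spec`.
#' @export
field_spec <- function(jaw_x, jaw_y, mlc_aperture = NULL, gantry_angle = 0,
                       mu = 100, ssd = 1335, id = NULL) {
  jaw_x <- sort(as.numeric(jaw_x))
  jaw_y <- sort(as.numeric(jaw_y))
  if (length(jaw_x) != 2L || length(jaw_y) != 2L) {
    stop_seccheck("jaw_x and jaw_y must each be a pair of edge positions",
                  "seccheck_validation_error")
  }
  if (jaw_x[1L] >= jaw_x[2L] || jaw_y[1L] >= jaw_y[2L]) {
    stop_seccheck("jaw edges must be distinct (zero-area field)",
                  "seccheck_validation_error")
  }
  if (any(abs(jaw_x) > MACHINE_X_LIMIT) || any(abs(jaw_y) > MACHINE_Y_LIMIT)) {
    stop_seccheck(
      sprintf("jaw setting outside machine limits (|x| <= %g, |y| <= %g mm)",
              MACHINE_X_LIMIT, MACHINE_Y_LIMIT),
      "seccheck_validation_error"
    )
  }
  if (!is.null(mlc_aperture)) {
    mlc_aperture <- as.matrix(mlc_aperture)
    if (ncol(mlc_aperture) != 2L) {
      stop_seccheck("mlc_aperture must have two columns (y1, y2 edges)",
                    "seccheck_validation_error")
    }
    if (any(mlc_aperture[, 1L] > mlc_aperture[, 2L])) {
      stop_seccheck("MLC pair edges must satisfy y1 <= y2",
                    "seccheck_validation_error")
    }
  }
  check_number(mu, "mu")
  if (mu < 0) stop_seccheck("mu must be >= 0", "seccheck_validation_error")
  check_number(ssd, "ssd", positive = TRUE)
  structure(
    list(jaw_x = jaw_x, jaw_y = jaw_y, mlc_aperture = mlc_aperture,
         gantry_angle = as.numeric(gantry_angle), mu = mu, ssd = ssd,
         id = id),
    class = "field_spec"
  )
}

#' @export
print.field_spec <- function(x, ...) {
  cat(sprintf("<field_spec>%s jaws x [%g, %g] y [%g, %g] mm, gantry %g, %g MU, SSD %g mm%s\n",
              if (is.null(x$id)) "" else paste0(" ", x$id),
              x$jaw_x[1L], x$jaw_x[2L], x$jaw_y[1L], x$jaw_y[2L],
              x$gantry_angle, x$mu, x$ssd,
              if (is.null(x$mlc_aperture)) "" else
                sprintf(", MLC %d pairs", nrow(x$mlc_aperture))))
  invisible(x)
}

#' A calculation point in beam coordinates
#'
#' @param x Cross-plane off-axis distance, mm.
#' @param y In-plane off-axis distance, mm.
#' @param z Depth below the surface along the beam axis, mm (>= 0).
#' @return An object of class `dose_point` (named numeric of length 3).
#' @export
dose_point <- function(x, y, z) {
  check_number(x, "x"); check_number(y, "y"); check_number(z, "z")
  if (z < 0) stop_seccheck("depth z must be >= 0", "seccheck_validation_error")
  structure(c(x = x, y = y, z = z), class = "dose_point")
}

#' A treatment plan for verification
#'
#' Bundles the fields with the TPS quantities the secondary check compares
#' against: per-field MU, per-field dose contribution at the reference
#' point, and the plan point dose.
#'
#' @param fields List of [field_spec()] objects.
#' @param ref_point Primary reference/calculation point, [dose_point()].
#' @param tps_point_dose TPS plan dose at `ref_point`, cGy.
#' @param tps_field_dose Numeric vector, per-field TPS dose at `ref_point`,
#'   cGy.
#' @param prescription_dose Prescription (per-fraction) dose, cGy; used by
#'   the isodose floor of automatic point selection.
#' @param id Plan identifier.
#' @return An object of class `rt_plan`.
#' @export
rt_plan <- function(fields, ref_point = NULL, tps_point_dose = NULL,
                    tps_field_dose = NULL, prescription_dose = NULL,
                    id = "plan") {
  if (length(fields) < 1L || !all(vapply(fields, inherits, TRUE, "field_spec"))) {
    stop_seccheck("a plan needs at least one field_spec",
                  "seccheck_validation_error")
  }
  if (!is.null(tps_field_dose) && length(tps_field_dose) != length(fields)) {
    stop_seccheck("tps_field_dose must have one entry per field",
                  "seccheck_validation_error")
  }
  structure(
    list(fields = fields, ref_point = ref_point,
         tps_point_dose = tps_point_dose,
         tps_field_dose = tps_field_dose,
         prescription_dose = prescription_dose, id = id),
    class = "rt_plan"
  )
}

#' @export
print.rt_plan <- function(x, ...) {
  cat(sprintf("<rt_plan> %s: %d field(s), total %g MU\n", x$id,
              length(x$fields), sum(vapply(x$fields, `[[`, 0, "mu"))))
  invisible(x)
}

#' Read / write the JSON plan dialect
#'
#' The JSON plan dialect mirrors [field_spec()]: a document with `fields`
#' (jaw edges mm, optional MLC matrix, gantry, mu, ssd), an optional
#' reference point and the TPS comparison values.
#'
#' @param path File path.
#' @return `read_plan_json()` returns an [rt_plan()];
#'   `write_plan_json()` returns `path` invisibly.
#' @export
read_plan_json <- function(path) {
  if (!file.exists(path)) {
    stop_seccheck(sprintf("no such plan file: %s", path), "seccheck_io_error")
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  fields <- lapply(doc$fields, function(f) {
    mlc <- f$mlc_aperture
    if (!is.null(mlc) && !is.matrix(mlc)) {
      mlc <- do.call(rbind, lapply(mlc, as.numeric))
    }
    field_spec(
      jaw_x = f$jaw_x, jaw_y = f$jaw_y,
      mlc_aperture = mlc,
      gantry_angle = f$gantry_angle %||% 0,
      mu = f$mu, ssd = f$ssd, id = f$id
    )
  })
  rt_plan(
    fields = fields,
    ref_point = if (!is.null(doc$ref_point))
      dose_point(doc$ref_point[[1L]], doc$ref_point[[2L]], doc$ref_point[[3L]]),
    tps_point_dose = doc$tps_point_dose,
    tps_field_dose = if (!is.null(doc$tps_field_dose))
      as.numeric(unlist(doc$tps_field_dose)),
    prescription_dose = doc$prescription_dose,
    id = doc$id %||% "plan"
  )
}

#' @param plan An [rt_plan()].
#' @rdname read_plan_json
#' @export
write_plan_json <- function(plan, path) {
  stopifnot(inherits(plan, "rt_plan"))
  doc <- list(
    id = plan$id,
    fields = lapply(plan$fields, function(f) {
      out <- list(jaw_x = f$jaw_x, jaw_y = f$jaw_y,
                  gantry_angle = f$gantry_angle, mu = f$mu, ssd = f$ssd)
      if (!is.null(f$id)) out$id <- f$id
      if (!is.null(f$mlc_aperture)) {
        out$mlc_aperture <- lapply(seq_len(nrow(f$mlc_aperture)),
                                   function(i) f$mlc_aperture[i, ])
      }
      out
    }),
    ref_point = if (!is.null(plan$ref_point)) unclass(plan$ref_point),
    tps_point_dose = plan$tps_point_dose,
    tps_field_dose = plan$tps_field_dose,
    prescription_dose = plan$prescription_dose
  )
  doc <- doc[!vapply(doc, is.null, TRUE)]
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}
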