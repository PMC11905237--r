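#' Tolerance specification for plan checks
#'
#' A comparison passes if EITHER the percent criterion OR the absolute
#' criterion is met (both inclusive): 5% or 5 MU per field, 5% or 5 cGy for
#' the plan point dose by default.
#'
#' @param field_percent,field_mu Field MU tolerances (% and MU).
#' @param point_percent,point_dose Plan point tolerances (% and cGy).
#' @return An object of class `tolerance_spec`.
#' @export
tolerance_spec <- function(field_percent = 5, field_mu = 5,
                           point_percent = 5, point_dose = 5) {
  for (v in c(field_percent, field_mu, point_percent, point_dose)) {
    check_number(v, "tolerance", positive = TRUE)
  }
  structure(
    list(field_percent = field_percent, field_mu = field_mu,
         point_percent = point_percent, point_dose = point_dose),
    class = "tolerance_spec"
  )
}

#' Rules for automatic point-of-interest selection
#'
#' @param interface_clearance Minimum distance from tissue interfaces, mm.
#' @param field_edge_clearance Minimum distance from all field edges, mm.
#' @param isodose_floor Minimum dose as % of prescription (loosenable to 70
#'   when no point satisfies the default 90).
#' @return An object of class `poi_rule`.
#' @export
poi_rule <- function(interface_clearance = 3, field_edge_clearance = 10,
                     isodose_floor = 90) {
  if (interface_clearance < 0 || field_edge_clearance < 0) {
    stop_seccheck("clearances must be >= 0", "seccheck_validation_error")
  }
  if (isodose_floor <= 0 || isodose_floor > 100) {
    stop_seccheck("isodose_floor must be in (0, 100]", "seccheck_validation_error")
  }
  structure(
    list(interface_clearance = interface_clearance,
         field_edge_clearance = field_edge_clearance,
         isodose_floor = isodose_floor),
    class = "poi_rule"
  )
}

#' Compare one field's MU against the TPS
#'
#' @param tps_mu TPS monitor units (> 0 for a percent difference; at 0 the
#'   percent criterion is undefined and only the absolute one applies).
#' @param engine_mu Independently computed monitor units.
#' @param tol A [tolerance_spec()].
#' @return List with `percent_diff` (TPS denominator), `mu_diff`
#'   (engine - TPS) and logical `pass`.
#' @export
compare_field <- function(tps_mu, engine_mu, tol = tolerance_spec()) {
  stopifnot(inherits(tol, "tolerance_spec"))
  check_number(engine_mu, "engine_mu")
  check_number(tps_mu, "tps_mu")
  mu_diff <- engine_mu - tps_mu
  if (tps_mu == 0) {
    return(list(percent_diff = NA_real_, mu_diff = mu_diff,
                pass = abs(mu_diff) <= tol$field_mu))
  }
  pct <- 100 * mu_diff / tps_mu
  list(percent_diff = pct, mu_diff = mu_diff,
       pass = abs(pct) <= tol$field_percent || abs(mu_diff) <= tol$field_mu)
}

# ---- automatic POI selection ------------------------------------------------

# voxels whose density differs from a 6-neighbour by > 0.1: tissue interfaces
interface_mask <- function(density) {
  d <- dim(density)
  m <- array(FALSE, d)
  shift_diff <- function(ax, by) {
    idx_a <- vector("list", 3L); idx_b <- idx_a
    for (k in 1:3) { idx_a[[k]] <- seq_len(d[k]); idx_b[[k]] <- seq_len(d[k]) }
    idx_a[[ax]] <- seq_len(d[ax] - by)
    idx_b[[ax]] <- seq_len(d[ax] - by) + by
    a <- do.call(`[`, c(list(density), idx_a, drop = FALSE))
    b <- do.call(`[`, c(list(density), idx_b, drop = FALSE))
    hit <- abs(a - b) > 0.1
    ma <- array(FALSE, d)
    ma <- do.call(`[<-`, c(list(ma), idx_a, list(hit)))
    mb <- array(FALSE, d)
    mb <- do.call(`[<-`, c(list(mb), idx_b, list(hit)))
    ma | mb
  }
  for (ax in 1:3) m <- m | shift_diff(ax, 1L)
  m
}

# minimum distance (mm) from a point to any interface voxel center
dist_to_interface <- function(point, phantom, iface_idx) {
  if (nrow(iface_idx) == 0L) return(Inf)
  ctr <- sweep(sweep(iface_idx - 0.5, 2L, phantom$voxel_mm, `*`),
               2L, phantom$origin, `+`)
  sqrt(min(rowSums(sweep(ctr, 2L, as.numeric(point), `-`)^2)))
}

# minimum distance (mm, at the point's plane) from an in-aperture point to
# the field edges; -Inf when the point is not open in the field
edge_clearance <- function(model, field, point) {
  if (!point_open(model, field, point)) return(-Inf)
  sad <- model$calibration$source_axis_distance
  s <- (field$ssd + point[3L]) / sad  # iso-plane -> point-plane scale
  ap <- effective_aperture(model, field)
  x_edges <- ap$x_range * s
  y_edges <- field$jaw_y
  if (ap$has_mlc) {
    uv <- project_to_iso(model, field, point)
    n_pairs <- nrow(ap$open_int)
    w <- model$mlc$leaf_width
    x0 <- -n_pairs * w / 2
    i <- min(max(floor((uv[1L] - x0) / w) + 1L, 1L), n_pairs)
    if (!is.na(ap$open_int[i, 1L])) y_edges <- ap$open_int[i, ]
  }
  y_edges <- y_edges * s
  min(point[1L] - x_edges[1L], x_edges[2L] - point[1L],
      point[2L] - y_edges[1L], y_edges[2L] - point[2L])
}

# MU-weighted open-aperture exposure of a point
field_exposure <- function(model, fields, point) {
  sum(vapply(fields, function(f) f$mu * point_open(model, f, point), numeric(1)))
}

poi_valid <- function(model, point, dose_value, phantom, iface_idx, fields,
                      rule, floor_pct, prescription) {
  if (dose_value < floor_pct / 100 * prescription) return(FALSE)
  if (dist_to_interface(point, phantom, iface_idx) <= rule$interface_clearance) {
    return(FALSE)
  }
  all(vapply(fields, function(f) {
    edge_clearance(model, f, point) > rule$field_edge_clearance
  }, logical(1)))
}

#' Automatic point-of-interest selection
#'
#' Checks the predefined candidates in order (primary reference point,
#' isocenter, target centroids); the first one lying away from tissue
#' interfaces, clear of all field edges and inside the isodose floor wins.
#' If none qualifies the dose grid is searched exhaustively for voxels
#' satisfying all clearances, and the one maximizing the MU-weighted field
#' exposure is returned (ties broken toward the lowest linear voxel index).
#' If the default isodose floor admits no point it is loosened to 70%; if
#' that still fails, a `seccheck_no_valid_point` error is raised.
#'
#' @param model A [beam_model()].
#' @param dose 3-D dose array on the phantom grid, cGy.
#' @param phantom A [phantom_model()] on the same grid.
#' @param fields List of [field_spec()] objects.
#' @param predefined Named ordered list of candidate [dose_point()]s.
#' @param rule A [poi_rule()].
#' @param prescription Prescription dose, cGy (defaults to the grid
#'   maximum).
#' @return List with `point`, `provenance` (which rule selected it) and
#'   `floor_used`.
#' @export
select_poi <- function(model, dose, phantom, fields, predefined = list(),
                       rule = poi_rule(), prescription = NULL) {
  stopifnot(inherits(phantom, "phantom_model"))
  if (length(dose) == 0L || !identical(dim(dose), dim(phantom$density))) {
    stop_seccheck("dose grid must be non-empty and match the phantom grid",
                  "seccheck_validation_error")
  }
  prescription <- prescription %||% max(dose)
  iface_idx <- which(interface_mask(phantom$density), arr.ind = TRUE)

  dose_at <- function(p) {
    v <- voxel_of(phantom, as.numeric(p))
    if (is.null(v)) return(-Inf)
    dose[v[1L], v[2L], v[3L]]
  }

  try_floor <- function(floor_pct) {
    for (nm in names(predefined)) {
      p <- as.numeric(predefined[[nm]])
      if (poi_valid(model, p, dose_at(p), phantom, iface_idx, fields,
                    rule, floor_pct, prescription)) {
        return(list(point = dose_point(p[1L], p[2L], p[3L]),
                    provenance = nm, floor_used = floor_pct))
      }
    }
    d <- dim(phantom$density)
    best <- NULL; best_score <- -Inf
    for (k in seq_len(d[3L])) for (j in seq_len(d[2L])) for (i in seq_len(d[1L])) {
      if (!phantom$mask[i, j, k]) next
      p <- phantom$origin + (c(i, j, k) - 0.5) * phantom$voxel_mm
      if (!poi_valid(model, p, dose[i, j, k], phantom, iface_idx, fields,
                     rule, floor_pct, prescription)) next
      score <- field_exposure(model, fields, p)
      if (score > best_score) {  # strict: earliest (lowest index) wins ties
        best_score <- score
        best <- p
      }
    }
    if (!is.null(best)) {
      return(list(point = dose_point(best[1L], best[2L], best[3L]),
                  provenance = "search", floor_used = floor_pct))
    }
    NULL
  }

  res <- try_floor(rule$isodose_floor)
  if (is.null(res) && rule$isodose_floor > 70) res <- try_floor(70)
  if (is.null(res)) {
    stop_seccheck("no point satisfies the POI rule even at the 70% isodose floor",
                  "seccheck_no_valid_point")
  }
  res
}

# note: the triple loop above runs i fastest, matching R's linear (column-
# major) index order, so "earliest wins" is the lowest linear voxel index.

#' Verify a plan against its TPS values
#'
#' For each field, the MUs necessary to achieve the field's TPS dose at the
#' calculation point are computed with [mu_for_dose()] and compared to the
#' TPS MU under the field tolerance; the plan point dose is the sum of
#' [point_dose()] over fields at the same point, compared under the point
#' tolerance. A field whose geometry cannot be resolved is annotated
#' unverifiable and fails the overall verdict.
#'
#' @param model A [beam_model()].
#' @param plan An [rt_plan()] carrying TPS MU, per-field dose and point
#'   dose (cGy).
#' @param phantom A [phantom_model()] or `NULL` for water.
#' @param tol A [tolerance_spec()].
#' @param poi A [dose_point()], or `NULL` to use the plan's reference point.
#' @param extrapolate Passed to the dose engine.
#' @return An object of class `plan_check_report`: per-field data frame,
#'   plan-point row and overall verdict.
#' @export
check_plan <- function(model, plan, phantom = NULL, tol = tolerance_spec(),
                       poi = NULL, extrapolate = FALSE) {
  stopifnot(inherits(plan, "rt_plan"), inherits(tol, "tolerance_spec"))
  poi <- poi %||% plan$ref_point
  if (is.null(poi)) {
    stop_seccheck("no calculation point: supply poi or a plan reference point",
                  "seccheck_validation_error")
  }
  nf <- length(plan$fields)
  if (is.null(plan$tps_field_dose)) {
    stop_seccheck("plan lacks per-field TPS doses at the reference point",
                  "seccheck_validation_error")
  }
  rows <- vector("list", nf)
  engine_point_cgy <- 0
  point_ok <- TRUE
  for (i in seq_len(nf)) {
    f <- plan$fields[[i]]
    fid <- f$id %||% sprintf("field_%02d", i)
    res <- tryCatch({
      emu <- mu_for_dose(model, f, phantom, poi,
                         plan$tps_field_dose[i] / 100,  # cGy -> Gy
                         extrapolate = extrapolate)
      cmp <- compare_field(f$mu, emu, tol)
      # the tryCatch expression runs in this frame, so plain assignment
      engine_point_cgy <- engine_point_cgy +
        100 * point_dose(model, f, phantom, poi, extrapolate = extrapolate)$dose
      data.frame(field = fid, tps_mu = f$mu, engine_mu = emu,
                 percent_diff = cmp$percent_diff, mu_diff = cmp$mu_diff,
                 verdict = cmp$pass, note = "", stringsAsFactors = FALSE)
    }, seccheck_error = function(e) {
      point_ok <<- FALSE
      data.frame(field = fid, tps_mu = f$mu, engine_mu = NA_real_,
                 percent_diff = NA_real_, mu_diff = NA_real_,
                 verdict = FALSE, note = paste("unverifiable:", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    rows[[i]] <- res
  }
  fields_df <- do.call(rbind, rows)

  point_row <- NULL
  if (!is.null(plan$tps_point_dose)) {
    if (point_ok) {
      dd <- engine_point_cgy - plan$tps_point_dose
      pct <- 100 * dd / plan$tps_point_dose
      point_row <- list(location = as.numeric(poi),
                        tps_dose = plan$tps_point_dose,
                        engine_dose = engine_point_cgy,
                        percent_diff = pct, dose_diff = dd,
                        verdict = abs(pct) <= tol$point_percent ||
                          abs(dd) <= tol$point_dose)
    } else {
      point_row <- list(location = as.numeric(poi),
                        tps_dose = plan$tps_point_dose,
                        engine_dose = NA_real_, percent_diff = NA_real_,
                        dose_diff = NA_real_, verdict = FALSE)
    }
  }
  overall <- all(fields_df$verdict) && (is.null(point_row) || point_row$verdict)
  structure(
    list(plan_id = plan$id, fields = fields_df, point = point_row,
         tolerance = tol, overall = overall),
    class = "plan_check_report"
  )
}

#' @export
print.plan_check_report <- function(x, ...) {
  cat(sprintf("<plan_check_report> %s — %s\n", x$plan_id,
              if (x$overall) "PASS" else "FAIL"))
  df <- x$fields
  df$percent_diff <- round(df$percent_diff, 2)
  df$engine_mu <- round(df$engine_mu, 2)
  df$mu_diff <- round(df$mu_diff, 2)
  df$verdict <- ifelse(df$verdict, "pass", "FAIL")
  print(df, row.names = FALSE)
  if (!is.null(x$point)) {
    p <- x$point
    cat(sprintf("plan point (%g, %g, %g) mm: TPS %.2f cGy, engine %.2f cGy (%.2f%%) — %s\n",
                p$location[1L], p$location[2L], p$location[3L],
                p$tps_dose, p$engine_dose, p$percent_diff,
                if (isTRUE(p$verdict)) "pass" else "FAIL"))
  }
  invisible(x)
}
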