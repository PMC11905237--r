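#' Voxel phantom of relative electron density
#'
#' A rectilinear grid of relative electron density (water = 1) with an
#' external-boundary mask. Coordinates follow the beam system used
#' throughout the package: x cross-plane, y in-plane, z depth below the
#' surface, all mm; the voxel `[1,1,1]` has its lower corner at `origin`.
#'
#' @param density 3-D numeric array `[nx, ny, nz]` of relative electron
#'   densities (>= 0).
#' @param voxel_mm Voxel edge lengths, mm (length 1 or 3).
#' @param origin Lower corner of the grid, mm (default centers x/y on the
#'   beam axis with the surface at z = 0).
#' @param mask Logical array of the same dimension marking the patient /
#'   phantom exterior boundary; defaults to `density > 0`. Must be
#'   non-empty.
#' @param kind Optional label; `"uniform_water"` enables an analytic
#'   fast path in which radiological depth equals geometric path length.
#' @return An object of class `phantom_model`.
#' @export
phantom_model <- function(density, voxel_mm, origin = NULL, mask = NULL,
                          kind = "grid") {
  if (length(dim(density)) != 3L) {
    stop_seccheck("density must be a 3-D array", "seccheck_validation_error")
  }
  if (any(density < 0) || any(!is.finite(density))) {
    stop_seccheck("densities must be finite and >= 0", "seccheck_validation_error")
  }
  voxel_mm <- rep_len(as.numeric(voxel_mm), 3L)
  if (any(voxel_mm <= 0)) {
    stop_seccheck("voxel_mm must be positive", "seccheck_validation_error")
  }
  d <- dim(density)
  if (is.null(origin)) {
    origin <- c(-d[1L] * voxel_mm[1L] / 2, -d[2L] * voxel_mm[2L] / 2, 0)
  }
  if (is.null(mask)) mask <- density > 0
  if (!any(mask)) {
    stop_seccheck("external boundary mask is empty", "seccheck_validation_error")
  }
  structure(
    list(density = density, voxel_mm = voxel_mm, origin = as.numeric(origin),
         mask = mask, kind = kind),
    class = "phantom_model"
  )
}

#' @export
print.phantom_model <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("<phantom_model> %s, %d x %d x %d voxels @ %g x %g x %g mm\n",
              x$kind, d[1L], d[2L], d[3L],
              x$voxel_mm[1L], x$voxel_mm[2L], x$voxel_mm[3L]))
  cat(sprintf("  density range [%.3g, %.3g], origin (%g, %g, %g) mm\n",
              min(x$density), max(x$density),
              x$origin[1L], x$origin[2L], x$origin[3L]))
  invisible(x)
}

#' Uniform water phantom
#'
#' @param size_mm Extents in x, y, z, mm.
#' @param voxel_mm Voxel size, mm.
#' @return A [phantom_model()] with `kind = "uniform_water"`.
#' @export
water_phantom <- function(size_mm = c(400, 400, 400), voxel_mm = 10) {
  size_mm <- rep_len(size_mm, 3L)
  voxel_mm <- rep_len(voxel_mm, 3L)
  d <- pmax(1L, as.integer(round(size_mm / voxel_mm)))
  phantom_model(array(1, dim = d), voxel_mm, kind = "uniform_water")
}

voxel_of <- function(phantom, p) {
  i <- floor((p - phantom$origin) / phantom$voxel_mm) + 1L
  d <- dim(phantom$density)
  if (any(i < 1L) || any(i > d)) return(NULL)
  as.integer(i)
}

#' Radiological depth along a ray
#'
#' Line integral of relative electron density (restricted to the external
#' boundary mask) along the straight segment from `entry` to `point`, using
#' an incremental Siddon-style traversal of the voxel grid. In uniform
#' water this equals the geometric path length.
#'
#' @param phantom A [phantom_model()].
#' @param entry Surface entry point `c(x, y, z)` mm.
#' @param point Calculation point `c(x, y, z)` mm; must lie inside the
#'   external boundary.
#' @return Water-equivalent path length, mm.
#' @export
radiological_depth <- function(phantom, entry, point) {
  stopifnot(inherits(phantom, "phantom_model"))
  entry <- as.numeric(entry); point <- as.numeric(point)
  v <- voxel_of(phantom, point)
  if (is.null(v) || !phantom$mask[v[1L], v[2L], v[3L]]) {
    stop_seccheck("calculation point lies outside the external boundary",
                  "seccheck_geometry_error")
  }
  L <- sqrt(sum((point - entry)^2))
  if (L == 0) return(0)
  if (identical(phantom$kind, "uniform_water")) return(L)

  d <- dim(phantom$density)
  o <- phantom$origin
  vox <- phantom$voxel_mm
  dir <- point - entry

  # clip the segment parameter to the grid bounding box
  t0 <- 0; t1 <- 1
  for (ax in 1:3) {
    lo <- o[ax]; hi <- o[ax] + d[ax] * vox[ax]
    if (dir[ax] == 0) {
      if (entry[ax] < lo || entry[ax] > hi) return(0)
    } else {
      ta <- (lo - entry[ax]) / dir[ax]
      tb <- (hi - entry[ax]) / dir[ax]
      t0 <- max(t0, min(ta, tb))
      t1 <- min(t1, max(ta, tb))
    }
  }
  if (t0 >= t1) return(0)

  # parametric positions of every voxel-boundary crossing
  alphas <- c(t0, t1)
  for (ax in 1:3) {
    if (dir[ax] != 0) {
      planes <- o[ax] + (0:d[ax]) * vox[ax]
      ta <- (planes - entry[ax]) / dir[ax]
      alphas <- c(alphas, ta[ta > t0 & ta < t1])
    }
  }
  alphas <- sort(unique(alphas))
  mids <- (alphas[-1L] + alphas[-length(alphas)]) / 2
  lens <- diff(alphas) * L
  total <- 0
  for (k in seq_along(mids)) {
    p <- entry + mids[k] * dir
    i <- floor((p - o) / vox) + 1L
    if (all(i >= 1L) && all(i <= d) && phantom$mask[i[1L], i[2L], i[3L]]) {
      total <- total + phantom$density[i[1L], i[2L], i[3L]] * lens[k]
    }
  }
  total
}

# Radiological depth of a beam point: ray from the source through the point,
# entering the phantom surface plane z = 0. `point` is c(x, y, z) beam
# coordinates, `ssd` the central-axis source-surface distance.
beam_rad_depth <- function(phantom, point, ssd) {
  if (is.null(phantom)) {
    # no phantom: water-equivalent slant depth
    t <- ssd / (ssd + point[3L])
    entry <- c(point[1L] * t, point[2L] * t, 0)
    return(sqrt(sum((point - entry)^2)))
  }
  t <- ssd / (ssd + point[3L])
  entry <- c(point[1L] * t, point[2L] * t, 0)
  radiological_depth(phantom, entry, point)
}
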