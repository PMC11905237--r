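# Independent brute-force oracles, written directly from the definitions
# and kept free of the package's internal code paths they check.

# exhaustive POI search: triple loop over voxels, literal rule evaluation
brute_force_poi <- function(model, dose, phantom, fields, rule, floor_pct,
                            prescription) {
  d <- dim(phantom$density)
  iface <- array(FALSE, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    for (nb in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                    c(0, 0, 1), c(0, 0, -1))) {
      ii <- i + nb[1]; jj <- j + nb[2]; kk <- k + nb[3]
      if (ii >= 1 && ii <= d[1] && jj >= 1 && jj <= d[2] &&
          kk >= 1 && kk <= d[3] &&
          abs(phantom$density[i, j, k] - phantom$density[ii, jj, kk]) > 0.1) {
        iface[i, j, k] <- TRUE
      }
    }
  }
  iface_pts <- NULL
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (iface[i, j, k]) {
      iface_pts <- rbind(iface_pts,
                         phantom$origin + (c(i, j, k) - 0.5) * phantom$voxel_mm)
    }
  }
  best <- NULL; best_score <- -Inf
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    p <- phantom$origin + (c(i, j, k) - 0.5) * phantom$voxel_mm
    if (dose[i, j, k] < floor_pct / 100 * prescription) next
    if (!is.null(iface_pts)) {
      dmin <- sqrt(min(rowSums(sweep(iface_pts, 2, p)^2)))
      if (dmin <= rule$interface_clearance) next
    }
    ok <- TRUE
    for (f in fields) {
      clr <- seccheck:::edge_clearance(model, f, p)
      if (clr <= rule$field_edge_clearance) { ok <- FALSE; break }
    }
    if (!ok) next
    score <- sum(vapply(fields, function(f) {
      f$mu * seccheck:::point_open(model, f, p)
    }, numeric(1)))
    if (score > best_score) { best_score <- score; best <- p }
  }
  best
}

# dense brute-force 1-D gamma from the definition
brute_gamma_1d <- function(ref, ev, crit, step = 0.02) {
  ref_max <- max(ref$dose)
  dd <- crit$dose_percent / 100 * ref_max
  keep <- ref$dose >= crit$low_dose_threshold / 100 * ref_max
  xs <- seq(min(ev$position_mm), max(ev$position_mm), by = step)
  es <- approx(ev$position_mm, ev$dose, xout = xs)$y
  vapply(which(keep), function(i) {
    r0 <- ref$position_mm[i]
    win <- abs(xs - r0) <= 3 * crit$dta
    if (!any(win)) return(Inf)
    sqrt(min(((es[win] - ref$dose[i]) / dd)^2 +
               ((xs[win] - r0) / crit$dta)^2))
  }, numeric(1))
}
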