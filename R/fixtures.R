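# Synthetic input generators: slab phantoms, step-and-shoot plans, cryostat
# readings, DLG trial sets and perturbed plans for tolerance testing. All
# generators are seed-deterministic: the same seed reproduces bit-identical
# output.

#' Layered slab phantom with labeled probe points
#'
#' Water body with a lung slab (relative electron density 0.25) and a bone
#' slab (1.6) in separate lateral halves, so that each probe class sees
#' only its own heterogeneity: lung occupies x < 0 at depths 30--70 mm,
#' bone occupies x > 0 at depths 100--130 mm, water elsewhere. Probe
#' points covering the heterogeneous point classes (tissue, superficial
#' tissue, tissue--lung interface, lung, bone; uniform and gradient
#' locations) are attached as the `probes` attribute.
#'
#' @param size_mm Phantom extents, mm.
#' @param voxel_mm Voxel size, mm.
#' @param lung_density,bone_density Relative electron densities of the
#'   slabs (conventional surrogates 0.25 and 1.6).
#' @return A [phantom_model()] with a `probes` attribute (named list of
#'   [dose_point()]s).
#' @export
make_slab_phantom <- function(size_mm = c(200, 200, 200), voxel_mm = 5,
                              lung_density = 0.25, bone_density = 1.6) {
  size_mm <- rep_len(size_mm, 3L)
  voxel_mm <- rep_len(voxel_mm, 3L)
  d <- as.integer(round(size_mm / voxel_mm))
  dens <- array(1, dim = d)
  x_centers <- -size_mm[1L] / 2 + (seq_len(d[1L]) - 0.5) * voxel_mm[1L]
  z_centers <- (seq_len(d[3L]) - 0.5) * voxel_mm[3L]
  dens[x_centers < 0, , z_centers > 30 & z_centers < 70] <- lung_density
  dens[x_centers > 0, , z_centers > 100 & z_centers < 130] <- bone_density
  ph <- phantom_model(dens, voxel_mm, kind = "slab_lung_bone")
  attr(ph, "probes") <- list(
    tissue_superficial = dose_point(0, 0, 5),
    tissue_uniform = dose_point(0, 0, 20),
    tissue_lung_interface = dose_point(-50, 0, 32),
    lung_uniform = dose_point(-50, 0, 50),
    lung_gradient = dose_point(-80, 0, 60),
    bone = dose_point(50, 0, 115),
    deep_tissue = dose_point(-50, 0, 160)
  )
  ph
}

#' Synthetic step-and-shoot plan
#'
#' `n_segments` rectangular-plus-MLC segments inside a 10 x 10 cm jaw
#' setting with randomized (seed-deterministic) segment openings and known
#' MU. With `n_segments = 1` the single segment is fully open to the jaws,
#' so the plan reproduces the open-field calibration identity at the
#' calibration geometry.
#'
#' @param model A [beam_model()] (for the leaf geometry).
#' @param n_segments Number of segments (>= 1); each becomes one field.
#' @param seed Integer seed.
#' @param ssd Source-surface distance, mm.
#' @param mu_per_segment Monitor units per segment.
#' @return An [rt_plan()] (TPS comparison values unset).
#' @export
make_step_and_shoot_plan <- function(model, n_segments = 7, seed = 1,
                                     ssd = 1335, mu_per_segment = 100) {
  stopifnot(n_segments >= 1)
  set.seed(seed)
  jaw_x <- c(-50, 50); jaw_y <- c(-50, 50)
  fields <- lapply(seq_len(n_segments), function(i) {
    if (i == 1L) {
      mlc <- open_mlc_aperture(model, jaw_x, jaw_y)
    } else {
      # random sub-aperture: contiguous open pairs, jittered edges
      mlc <- open_mlc_aperture(model, jaw_x, jaw_y)
      open_pairs <- which(mlc[, 2L] > mlc[, 1L])
      n_open <- length(open_pairs)
      keep <- sort(sample(open_pairs, max(2L, round(n_open * stats::runif(1, 0.5, 1)))))
      closed <- setdiff(open_pairs, keep)
      mlc[closed, ] <- 0
      for (p in keep) {
        lo <- stats::runif(1, jaw_y[1L], -5)
        hi <- stats::runif(1, 5, jaw_y[2L])
        mlc[p, ] <- c(lo, hi)
      }
    }
    field_spec(jaw_x, jaw_y, mlc_aperture = mlc,
               gantry_angle = (i - 1) * 360 / n_segments,
               mu = mu_per_segment, ssd = ssd,
               id = sprintf("seg_%02d", i))
  })
  rt_plan(fields, ref_point = dose_point(0, 0, 50),
          id = sprintf("step_and_shoot_%d", n_segments))
}

#' Fill a plan's TPS values from the engine itself
#'
#' Self-check helper: sets the per-field TPS doses, MU-consistent point
#' dose and prescription from the engine's own output, so that
#' [check_plan()] on the unperturbed plan reports zero differences.
#'
#' @param model A [beam_model()].
#' @param plan An [rt_plan()].
#' @param phantom A [phantom_model()] or `NULL`.
#' @param poi Calculation point (defaults to the plan reference point).
#' @return The plan with TPS fields populated (doses in cGy).
#' @export
plan_with_engine_tps <- function(model, plan, phantom = NULL, poi = NULL) {
  poi <- poi %||% plan$ref_point
  fd <- vapply(plan$fields, function(f) {
    100 * point_dose(model, f, phantom, poi)$dose
  }, numeric(1))
  plan$tps_field_dose <- fd
  plan$tps_point_dose <- sum(fd)
  plan$prescription_dose <- plan$prescription_dose %||% sum(fd)
  plan
}

#' Perturb one field's MU
#'
#' @param plan An [rt_plan()].
#' @param field_index Field to perturb.
#' @param factor Multiplicative MU perturbation (e.g. 1.06 for +6%).
#' @return The perturbed plan.
#' @export
perturb_plan_mu <- function(plan, field_index, factor) {
  stopifnot(inherits(plan, "rt_plan"))
  plan$fields[[field_index]]$mu <- plan$fields[[field_index]]$mu * factor
  plan
}

#' Synthetic cryostat readings
#'
#' Chamber readings every 2 degrees (skipping the 10--16 degree span where
#' the beam would penetrate the cryostat pipe) following a smooth
#' gantry-angle attenuation shape with a stated maximum dip below unity,
#' plus optional multiplicative noise.
#'
#' @param seed Integer seed.
#' @param dip Maximum fractional dip below the 0-degree reading.
#' @param base Open-field reading scale (arbitrary charge units).
#' @param noise_sd Relative standard deviation of reading noise (applied to
#'   every angle except 0, which stays the normalization anchor).
#' @return Data frame with `gantry_angle` and `charge` columns.
#' @export
make_cryostat_readings <- function(seed = 1, dip = 0.014, base = 20,
                                   noise_sd = 0) {
  set.seed(seed)
  angles <- setdiff(seq(0, 358, by = 2), c(10, 12, 14, 16))
  shape <- 1 - dip * sin(pi * angles / 360)^2  # dip at 180 degrees
  charge <- base * shape
  if (noise_sd > 0) {
    jitter <- stats::rnorm(length(angles), 0, noise_sd)
    jitter[angles == 0] <- 0
    charge <- charge * (1 + jitter)
  }
  data.frame(gantry_angle = angles, charge = charge)
}

#' Synthetic DLG trial set with a known optimum
#'
#' Per-plan dose differences for each candidate DLG are drawn around a
#' V-shaped response centred on `true_dlg`, with per-plan noise at the
#' calculation-reproducibility level, then summarized into [dlg_trial()]
#' rows (12 primary / 10 adaptive plans by default).
#'
#' @param seed Integer seed.
#' @param true_dlg The DLG at which the response is minimal, cm; must be
#'   one of `candidates`.
#' @param candidates Candidate DLG grid, cm.
#' @param n_primary,n_adaptive Plan counts.
#' @param base Baseline mean difference at the optimum, %.
#' @param slope Response slope, % per cm of DLG error.
#' @param plan_sd Per-plan noise standard deviation, %.
#' @return List of [dlg_trial()] objects.
#' @export
make_dlg_trials <- function(seed = 1, true_dlg = 0.01,
                            candidates = c(0, 0.01, 0.02, 0.1, 0.15, 0.2, 1.0),
                            n_primary = 12, n_adaptive = 10,
                            base = 1.5, slope = 8, plan_sd = 0.05) {
  stopifnot(true_dlg %in% candidates)
  set.seed(seed)
  lapply(candidates, function(dlg) {
    mu <- base + slope * abs(dlg - true_dlg)
    dlg_trial(
      candidate_dlg = dlg,
      primary_mean_diff = mean(abs(stats::rnorm(n_primary, mu, plan_sd))),
      adaptive_mean_diff = mean(abs(stats::rnorm(n_adaptive, mu, plan_sd))),
      n_primary = n_primary, n_adaptive = n_adaptive
    )
  })
}

#' Write a directory of example fixtures
#'
#' Emits the packaged beam model, a step-and-shoot plan (JSON and DICOM),
#' cryostat readings and a slab-phantom description under `out_dir`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @return `out_dir`, invisibly.
#' @export
make_fixture_set <- function(out_dir, seed = 7) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  model <- unity_beam_model()
  save_beam_model(model, file.path(out_dir, "beam_model.json"))
  plan <- make_step_and_shoot_plan(model, n_segments = 7, seed = seed)
  write_plan_json(plan, file.path(out_dir, "plan_7seg.json"))
  write_rtplan(plan, file.path(out_dir, "plan_7seg.dcm"))
  utils::write.csv(make_cryostat_readings(seed = seed),
                   file.path(out_dir, "cryostat_readings.csv"),
                   row.names = FALSE)
  invisible(out_dir)
}
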