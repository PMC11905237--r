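# Beam-model file dialect.
#
# A beam model is stored either as one JSON document with embedded tables or
# as a directory holding `model.json` (scalars) plus CSV tables:
#   pdd.csv            header row of depths (mm), first column the
#                      equivalent-square side (mm)
#   output_factors.csv columns side,scp
#   cryostat.csv       columns gantry_angle,correction_factor
#   profiles.csv       columns side,penumbra_width,asymmetry_shift,
#                      horn_slope,depth_broadening
# Every file carries a "format_version" key (currently 1). Lengths may be
# declared in cm via "length_unit"; they are converted to mm at load.
# Unknown top-level keys are rejected so that typos cannot silently drop a
# table.

MODEL_FORMAT_VERSION <- 1L

.model_keys <- c("format_version", "length_unit", "energy_label", "dmax",
                 "calibration", "pdd", "output_factors", "cryostat",
                 "mlc", "profiles")

.len_scale <- function(unit) {
  switch(unit,
    mm = 1,
    cm = 10,
    stop_seccheck(sprintf("unknown length_unit '%s' (use mm or cm)", unit),
                  "seccheck_schema_error")
  )
}

.require_keys <- function(x, keys, where, optional = character()) {
  missing <- setdiff(keys, names(x))
  if (length(missing)) {
    stop_seccheck(
      sprintf("beam-model file is missing required %s: %s",
              if (length(missing) > 1) "entries" else "entry",
              paste(missing, collapse = ", ")),
      "seccheck_schema_error"
    )
  }
  unknown <- setdiff(names(x), c(keys, optional))
  if (length(unknown)) {
    stop_seccheck(
      sprintf("unknown key(s) in %s: %s", where,
              paste(unknown, collapse = ", ")),
      "seccheck_schema_error"
    )
  }
  invisible(x)
}

#' Load a beam model from file
#'
#' Reads either a single JSON beam-model document or a directory of CSV
#' tables plus `model.json`, validates every table invariant and returns a
#' [beam_model()]. Unknown keys and malformed tables are rejected with a
#' named error rather than silently coerced.
#'
#' @param path Path to a `.json` file or a model directory.
#' @return A validated [beam_model()].
#' @seealso [save_beam_model()], [unity_beam_model()]
#' @export
load_beam_model <- function(path) {
  if (dir.exists(path)) return(.load_model_dir(path))
  if (!file.exists(path)) {
    stop_seccheck(sprintf("no such beam-model file: %s", path),
                  "seccheck_io_error")
  }
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  .model_from_doc(doc)
}

.model_from_doc <- function(doc) {
  .require_keys(doc, setdiff(.model_keys, c("length_unit", "dmax")),
                "beam-model document", optional = c("length_unit", "dmax"))
  if (!identical(as.integer(doc$format_version), MODEL_FORMAT_VERSION)) {
    stop_seccheck(sprintf("unsupported format_version %s", doc$format_version),
                  "seccheck_schema_error")
  }
  k <- .len_scale(doc$length_unit %||% "mm")
  cal <- doc$calibration
  .require_keys(cal, c("reference_field_side", "source_to_plane_distance",
                       "calibration_depth", "reference_dose", "reference_mu",
                       "source_axis_distance"), "calibration")
  pdd <- doc$pdd
  .require_keys(pdd, c("equivalent_square_sides", "depths", "values",
                       "nominal_ssd"), "pdd")
  ofs <- doc$output_factors
  .require_keys(ofs, c("equivalent_square_sides", "scp_values",
                       "reference_depth", "reference_ssd"), "output_factors")
  cryo <- doc$cryostat
  .require_keys(cryo, c("gantry_angles", "correction_factors"), "cryostat")
  mlc <- doc$mlc
  .require_keys(mlc, c("transmission", "dosimetric_leaf_gap", "leaf_count",
                       "leaf_width"), "mlc")
  prof <- doc$profiles
  .require_keys(prof, c("sides", "penumbra_width", "asymmetry_shift",
                        "horn_slope", "depth_broadening"), "profiles")
  beam_model(
    energy_label = doc$energy_label,
    calibration = calibration_spec(
      reference_field_side = cal$reference_field_side * k,
      source_to_plane_distance = cal$source_to_plane_distance * k,
      calibration_depth = cal$calibration_depth * k,
      reference_dose = cal$reference_dose,
      reference_mu = cal$reference_mu,
      source_axis_distance = cal$source_axis_distance * k
    ),
    pdd = pdd_table(
      equivalent_square_sides = pdd$equivalent_square_sides * k,
      depths = pdd$depths * k,
      values = matrix(unlist(pdd$values), nrow = length(pdd$equivalent_square_sides),
                      byrow = FALSE),
      nominal_ssd = pdd$nominal_ssd * k
    ),
    output_factors = output_factor_table(
      equivalent_square_sides = ofs$equivalent_square_sides * k,
      scp_values = ofs$scp_values,
      reference_depth = ofs$reference_depth * k,
      reference_ssd = ofs$reference_ssd * k
    ),
    cryostat = cryostat_table(cryo$gantry_angles, cryo$correction_factors),
    mlc = mlc_model(
      transmission = mlc$transmission,
      dosimetric_leaf_gap = mlc$dosimetric_leaf_gap,  # stays in cm
      leaf_count = mlc$leaf_count,
      leaf_width = mlc$leaf_width * k
    ),
    profiles = profile_model(
      sides = prof$sides * k,
      penumbra_width = prof$penumbra_width,
      asymmetry_shift = prof$asymmetry_shift,
      horn_slope = prof$horn_slope,
      depth_broadening = prof$depth_broadening
    ),
    dmax = (doc$dmax %||% 13) * k
  )
}

.load_model_dir <- function(path) {
  scalars_path <- file.path(path, "model.json")
  if (!file.exists(scalars_path)) {
    stop_seccheck("model directory lacks model.json", "seccheck_schema_error")
  }
  doc <- jsonlite::fromJSON(scalars_path, simplifyVector = TRUE)
  read_tab <- function(name) {
    f <- file.path(path, name)
    if (!file.exists(f)) {
      stop_seccheck(sprintf("model directory is missing table %s", name),
                    "seccheck_schema_error")
    }
    utils::read.csv(f, comment.char = "#", check.names = FALSE)
  }
  pdd_csv <- read_tab("pdd.csv")
  of_csv <- read_tab("output_factors.csv")
  cr_csv <- read_tab("cryostat.csv")
  pr_csv <- read_tab("profiles.csv")
  doc$pdd <- list(
    equivalent_square_sides = as.numeric(pdd_csv[[1L]]),
    depths = as.numeric(names(pdd_csv)[-1L]),
    values = as.matrix(pdd_csv[, -1L, drop = FALSE]),
    nominal_ssd = doc$pdd_nominal_ssd
  )
  doc$pdd_nominal_ssd <- NULL
  doc$output_factors <- list(
    equivalent_square_sides = of_csv$side,
    scp_values = of_csv$scp,
    reference_depth = doc$output_factor_reference_depth,
    reference_ssd = doc$output_factor_reference_ssd
  )
  doc$output_factor_reference_depth <- NULL
  doc$output_factor_reference_ssd <- NULL
  doc$cryostat <- list(gantry_angles = cr_csv$gantry_angle,
                       correction_factors = cr_csv$correction_factor)
  doc$profiles <- list(
    sides = pr_csv$side,
    penumbra_width = pr_csv$penumbra_width,
    asymmetry_shift = pr_csv$asymmetry_shift,
    horn_slope = pr_csv$horn_slope,
    depth_broadening = pr_csv$depth_broadening
  )
  .model_from_doc(doc)
}

#' Save a beam model to a JSON file
#'
#' Serializes with 17 significant digits so that a save/load round trip
#' preserves every numeric field exactly.
#'
#' @param model A [beam_model()].
#' @param path Output path (`.json`).
#' @return `path`, invisibly.
#' @export
save_beam_model <- function(model, path) {
  stopifnot(inherits(model, "beam_model"))
  doc <- list(
    format_version = MODEL_FORMAT_VERSION,
    length_unit = "mm",
    energy_label = model$energy_label,
    dmax = model$dmax,
    calibration = unclass(model$calibration),
    pdd = unclass(model$pdd),
    output_factors = unclass(model$output_factors),
    cryostat = unclass(model$cryostat),
    mlc = list(
      transmission = model$mlc$transmission,
      dosimetric_leaf_gap = model$mlc$dosimetric_leaf_gap,
      leaf_count = model$mlc$leaf_count,
      leaf_width = model$mlc$leaf_width
    ),
    profiles = unclass(model$profiles)
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' The packaged Unity 7X-FFF example beam model
#'
#' Loads the beam model shipped with the package
#' (`inst/extdata/unity_7fff.json`): the machine-specific calibration
#' settings of an Elekta Unity class MR-linac (1 Gy per 100 MU at a 10 x 10
#' cm field, source-to-plane 1385 mm, depth 50 mm), the commissioning PDD
#' grid at SSD 1335 mm, MLC transmission 0.0055 and DLG 0.010 cm, a
#' synthetic monotone output-factor curve anchored at 1.000 for the 100 mm
#' side, a synthetic smooth cryostat correction with CF(0) = 1, and the
#' declared profile parameterization. Table entries that the commissioning
#' report does not print (shallow-depth PDD nodes, output factors, the
#' cryostat curve shape, profile parameters) are synthetic but physically
#' plausible; printed nodes are carried verbatim.
#'
#' @return A [beam_model()].
#' @export
unity_beam_model <- function() {
  load_beam_model(system.file("extdata", "unity_7fff.json",
                              package = "seccheck", mustWork = TRUE))
}
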