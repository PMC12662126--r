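#' Read and validate a pipeline configuration
#'
#' YAML schema mirrors [phantom_spec()] plus analysis settings.  Top-level
#' keys: `phantom` (phantom parameters; or `volumes` with paths to
#' `iodine`, `mask` NIfTI files), `hematocrit`, `blood_iodine`, optional
#' `atlas` (`kernel`, `thresholds`), optional `classify` (fields of
#' [classify_config()]), optional `reference_calls` (CSV path for
#' agreement statistics), optional `seed`.
#'
#' @param path YAML file path, or a list already parsed.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg$phantom) && is.null(cfg$volumes))
    stop("config must contain either a 'phantom' block or a 'volumes' block")
  if (!is.null(cfg$volumes)) {
    for (f in c("iodine", "mask")) {
      if (is.null(cfg$volumes[[f]]))
        stop(sprintf("config field missing: volumes.%s", f))
    }
    if (is.null(cfg$hematocrit)) stop("config field missing: hematocrit")
    if (is.null(cfg$blood_iodine)) stop("config field missing: blood_iodine")
  }
  if (!is.null(cfg$hematocrit) &&
      (cfg$hematocrit <= 0 || cfg$hematocrit >= 1))
    stop("config field hematocrit must be in (0, 1)")
  cfg
}

config_lesions <- function(lst) {
  lapply(lst, function(l) do.call(lesion_spec, l))
}

#' Run the full phantom-to-calls pipeline
#'
#' Stages: phantom simulation (or volume loading), ECV computation,
#' compartment collection (3-depth-band 34 x 72 grid), atlas-map
#' construction, AHA-16 polar aggregation, pathologic-segment
#' classification, and (if reference calls are supplied) agreement
#' statistics.  All stage parameters and outputs are written to `out_dir`:
#' `ecv.nii.gz`, `myocardium.nii.gz`, `compartments.csv`, `atlas.pdf`,
#' `polar.pdf`, `calls.csv`, `agreement.json` (optional), and
#' `pipeline_log.json` (parameter echo).  Outputs are deterministic under
#' a fixed seed.
#'
#' @param config Path to a YAML config or a config list (see
#'   [read_config()]).
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed overriding the config seed.
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- read_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1L
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- list(seed = cfg$seed, stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    res
  }

  if (!is.null(cfg$phantom)) {
    ph_args <- cfg$phantom
    if (!is.null(ph_args$lesions)) ph_args$lesions <- config_lesions(ph_args$lesions)
    if (!is.null(cfg$hematocrit)) ph_args$hematocrit <- cfg$hematocrit
    if (!is.null(cfg$blood_iodine)) ph_args$blood_iodine <- cfg$blood_iodine
    ph_args$seed <- cfg$seed
    spec <- stage("phantom", do.call(phantom_spec, ph_args))
    ph <- stage("phantom", generate_phantom(spec))
    iodine <- ph$iodine
    mask <- ph$truth$myocardium_mask
    geometry <- ph$truth$geometry
    hct <- spec$hematocrit
    blood <- spec$blood_iodine
    log$stages$phantom <- ph_args["seed" != names(ph_args)]
    log$stages$phantom$n_myocardial_voxels <- sum(mask$values != 0)
  } else {
    iodine <- stage("load", read_volume(cfg$volumes$iodine))
    mask <- stage("load", read_volume(cfg$volumes$mask))
    geometry <- stage("load", geometry_from_mask(mask))
    hct <- cfg$hematocrit
    blood <- cfg$blood_iodine
    log$stages$load <- cfg$volumes
  }

  ecv <- stage("ecv", compute_ecv(iodine_study(iodine, blood, hct)))
  write_volume(ecv$volume, file.path(out_dir, "ecv.nii.gz"))
  write_volume(mask, file.path(out_dir, "myocardium.nii.gz"), datatype = "uint8")
  log$stages$ecv <- list(hematocrit = hct, blood_iodine = blood,
                         n_below_0 = ecv$n_below_0, n_above_1 = ecv$n_above_1)

  grid <- stage("compartments", build_compartments(ecv, mask, geometry))
  compartments_to_csv(grid, file.path(out_dir, "compartments.csv"))
  log$stages$compartments <- list(n_layers = grid$n_layers,
                                  n_sectors = grid$n_sectors,
                                  depth_bands = grid$depth_bands,
                                  band_limits = grid$band_limits,
                                  voxels_in_band = sum(grid$voxel_count),
                                  near_axis_discarded = grid$n_discarded_axis)

  at_args <- cfg$atlas
  kernel <- if (is.null(at_args$kernel)) 5L else at_args$kernel
  thresholds <- if (is.null(at_args$thresholds)) c(35, 40, 45) else at_args$thresholds
  atlas <- stage("atlas", build_atlas(grid, kernel = kernel, thresholds = thresholds))
  render_atlas(atlas, file.path(out_dir, "atlas.pdf"))
  log$stages$atlas <- list(kernel = kernel, thresholds = thresholds,
                           volume_percent = lapply(atlas$layers, `[[`, "volume_percent"))

  polar <- stage("polar", aha16_aggregate(ecv, mask, geometry))
  render_polar(polar, file.path(out_dir, "polar.pdf"))

  cls_cfg <- if (is.null(cfg$classify)) classify_config()
             else do.call(classify_config, cfg$classify)
  calls <- stage("classify", classify_segments(ecv, mask, geometry,
                                               grid = grid, atlas = atlas,
                                               config = cls_cfg))
  calls_to_csv(calls, file.path(out_dir, "calls.csv"))
  log$stages$classify <- list(config = unclass(cls_cfg),
                              n_pathologic = sum(calls$pathologic))

  agreement <- NULL
  if (!is.null(cfg$reference_calls)) {
    ref <- stage("agree", read_reference_calls(cfg$reference_calls))
    aff <- segments_affected(calls)
    ref_aff <- vapply(1:16, function(s)
      any(ref$positive[ref$segment == s] != 0), logical(1))
    agreement <- stage("agree",
                       agreement_summary(list(as.integer(aff)),
                                         list(as.integer(ref_aff))))
    jsonlite::write_json(list(kappa = agreement$kappa$kappa,
                              interpretation = agreement$kappa$interpretation,
                              concordance = agreement$concordance),
                         file.path(out_dir, "agreement.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  jsonlite::write_json(log, file.path(out_dir, "pipeline_log.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  invisible(list(ecv = ecv, mask = mask, geometry = geometry, grid = grid,
                 atlas = atlas, polar = polar, calls = calls,
                 agreement = agreement, log = log))
}
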