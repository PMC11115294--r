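#' Serialize a pipeline configuration to YAML
#'
#' The written file, read back with [read_pipeline_config()], reproduces the
#' configuration exactly, so a run is fully determined by the YAML file plus
#' any input data.
#'
#' @param config a [pipeline_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  yaml::write_yaml(strip(config), path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file written by [write_pipeline_config()] (or edited by
#'   hand with the same fields).
#' @return A `pipeline_config` object.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  reclass <- function(x, cls) {
    if (is.null(x)) return(NULL)
    structure(x, class = cls)
  }
  cohort <- raw$cohort
  if (!is.null(cohort)) {
    cohort$paralyzed_params <- reclass(cohort$paralyzed_params,
                                       "sided_motion_params")
    cohort$nonparalyzed_params <- reclass(cohort$nonparalyzed_params,
                                          "sided_motion_params")
    cohort$geometry <- reclass(cohort$geometry, "arm_geometry")
    cohort <- reclass(cohort, "cohort_spec")
    cohort$n_participants <- as.integer(cohort$n_participants)
    cohort$trials_per_side <- as.integer(cohort$trials_per_side)
  }
  pipeline_config(
    cohort = cohort %||% cohort_spec(),
    input_paths = raw$input_paths,
    covariates_path = raw$covariates_path,
    features = reclass(raw$features, "feature_config") %||% feature_config(),
    forest = {
      fc <- reclass(raw$forest, "forest_config") %||% forest_config()
      fc$n_trees <- as.integer(fc$n_trees)
      fc
    },
    k_max = raw$k_max %||% 8,
    row_unit = raw$row_unit %||% "trial",
    frame_stride = raw$frame_stride %||% 10,
    alpha = raw$alpha %||% 0.05,
    output_dir = raw$output_dir,
    seed = if (is.null(raw$seed)) NULL else as.integer(raw$seed))
}
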