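# Run configuration: one serializable document of paths, thresholds and
# hyperparameters with the package defaults, read/written as YAML. An
# executed pipeline run writes its resolved configuration next to its
# outputs for reproducibility.

#' Default run configuration
#'
#' All thresholds mirror the package defaults: 1024-bit radius-2
#' fingerprints, activity class boundaries 5/7, hit threshold 0.8, 80/20
#' split, 5 CV folds, the tuned model hyperparameters, and the default
#' fusion configuration.
#'
#' @param ... Named overrides, nested lists allowed.
#' @return List of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    paths = list(ligand_table = NULL, candidate_library = NULL,
                 output_dir = "ligscreen_out", checkpoint = NULL),
    ic50_unit = "nM",
    thresholds = list(activity_low = 5, activity_high = 7, hit = 0.8,
                      lipinski = list(logp = 5, mw = 500, hbd = 5, hba = 10)),
    featurization = list(fp_dim = 1024L, radius = 2L),
    split = list(test_fraction = 0.2, n_folds = 5L),
    models = names(default_model_specs()),
    fusion = unclass(fusion_config()),
    synthetic = list(n_ligands = 400L, n_candidates = 150L,
                     analog_fraction = 0.3),
    diversity = list(target_count = 100L),
    seed = 1L,
    verbosity = 1L
  )
  overrides <- list(...)
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Unknown keys are kept; missing keys fall back to [run_config()]
#' defaults.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(unclass(run_config()), user)
  structure(cfg, class = "run_config")
}

#' Write a resolved run configuration
#'
#' @param cfg A `run_config`.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
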