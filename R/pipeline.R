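#' Run the full margin-assessment pipeline
#'
#' Chains simulate -> reduce -> fit -> evaluate (-> significance) and writes
#' every stage product plus a run manifest under `out_dir`:
#' \describe{
#'   \item{cohort/}{per-margin CSV + JSON files and `cohort.json`
#'     ([write_cohort]).}
#'   \item{features_full.csv}{the 105-variable table (+ threshold sidecar).}
#'   \item{features_final.csv}{the 15-variable table (+ selected-threshold
#'     report).}
#'   \item{model.json}{the fitted CIT ([write_cit_model]).}
#'   \item{selected_variables.json}{per-stratum split variables (the
#'     "which descriptor won" report).}
#'   \item{performance.csv}{Se/Sp/PPV/NPV/A overall, per MBD group and per
#'     orientation group ([performance_report]).}
#'   \item{significance.json}{F_obs and permutation p (when `n_perm > 0`).}
#'   \item{manifest.json}{config echo, seeds, versions, stage paths, file
#'     checksums, timestamps - written last; a run is re-executable from it.}
#' }
#'
#' @param config A [cohort_config] describing the synthetic cohort.
#' @param out_dir Output directory (created).
#' @param n_perm Label permutations for model significance; 0 skips the stage.
#' @param alpha,min_leaf CIT settings, see [fit_cit].
#' @param significance_seed Seed for the permutation stage (defaults to
#'   `config$seed + 1`).
#' @return The run manifest (list), invisibly; it is also written as JSON.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir,
                         n_perm = 0L, alpha = 0.05, min_leaf = 7L,
                         significance_seed = NULL) {
  if (!inherits(config, "cohort_config")) config <- do.call(cohort_config, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_ms("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }
  paths <- list()

  cohort <- stage("simulate", generate_cohort(config))
  paths$cohort <- file.path(out_dir, "cohort")
  stage("simulate", write_cohort(cohort, paths$cohort))

  full <- stage("reduce", reduce_cohort(cohort))
  paths$features_full <- file.path(out_dir, "features_full.csv")
  write_feature_table(full, paths$features_full)
  final <- stage("reduce", select_optimal_thresholds(full))
  paths$features_final <- file.path(out_dir, "features_final.csv")
  write_feature_table(final, paths$features_final)

  model <- stage("fit", fit_cit(final, alpha = alpha, min_leaf = min_leaf))
  paths$model <- file.path(out_dir, "model.json")
  write_cit_model(model, paths$model)
  paths$selected_variables <- file.path(out_dir, "selected_variables.json")
  jsonlite::write_json(
    list(selected_variables = selected_variables(model),
         selected_thresholds = attr(final, "selected_thresholds")),
    paths$selected_variables, auto_unbox = TRUE, digits = NA, dataframe = "rows")

  pred <- stage("evaluate", predict(model, final))
  report <- performance_report(pred, final$label, final$mbd, final$orientation)
  paths$performance <- file.path(out_dir, "performance.csv")
  write.csv(report, paths$performance, row.names = FALSE)

  sig <- NULL
  if (n_perm > 0L) {
    if (is.null(significance_seed)) significance_seed <- config$seed + 1L
    sig <- stage("significance",
                 model_significance(full, n_perm = n_perm,
                                    seed = significance_seed,
                                    alpha = alpha, min_leaf = min_leaf))
    paths$significance <- file.path(out_dir, "significance.json")
    jsonlite::write_json(
      list(F_obs = sig$F_obs, p = sig$p, p_strict = sig$p_strict,
           n_perm = sig$n_perm,
           Se = sig$perf_obs$Se, Sp = sig$perf_obs$Sp),
      paths$significance, auto_unbox = TRUE, digits = NA)
  }

  files <- unlist(paths[names(paths) != "cohort"])
  manifest <- list(
    package_version = as.character(packageVersion("marginsense")),
    r_version = as.character(getRversion()),
    created = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config_to_list(config),
    seeds = list(cohort = config$seed,
                 margin_seeds = attr(cohort, "margin_seeds"),
                 significance = if (n_perm > 0L) significance_seed else NULL),
    settings = list(n_perm = as.integer(n_perm), alpha = alpha,
                    min_leaf = as.integer(min_leaf)),
    paths = paths,
    checksums = as.list(tools::md5sum(files)))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  manifest$manifest_path <- manifest_path
  invisible(manifest)
}

#' Re-execute a pipeline run from its manifest
#'
#' Reads the configuration and seeds echoed in a `manifest.json` and reruns
#' [run_pipeline] into `out_dir`. Because every stochastic stage is seeded
#' from the manifest, the regenerated feature tables and model are
#' bit-identical to the original run.
#'
#' @param manifest_path Path to a `manifest.json`.
#' @param out_dir Output directory for the re-run.
#' @return The new manifest, invisibly.
#' @export
run_from_manifest <- function(manifest_path, out_dir) {
  m <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  config <- config_from_list(m$config)
  run_pipeline(config, out_dir,
               n_perm = m$settings$n_perm %||% 0L,
               alpha = m$settings$alpha %||% 0.05,
               min_leaf = m$settings$min_leaf %||% 7L,
               significance_seed = m$seeds$significance)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# JSON-safe round trip of a cohort_config (matrices lose dimnames in JSON)
config_to_list <- function(config) {
  cfg <- unclass(config)
  med <- cfg$class_params$medians
  cfg$class_params$medians <- lapply(
    setNames(nm = rownames(med)), function(r) as.list(med[r, ]))
  # JSON drops names of atomic vectors; store named vectors as objects
  cfg$class_params$sdlog <- as.list(cfg$class_params$sdlog)
  cfg$mbd_bc_multiplier <- as.list(cfg$mbd_bc_multiplier)
  cfg$class_proportions <- lapply(cfg$class_proportions, as.list)
  cfg
}

config_from_list <- function(cfg) {
  med_l <- cfg$class_params$medians
  med <- do.call(rbind, lapply(med_l, unlist))
  rownames(med) <- names(med_l)
  cfg$class_params$medians <- med
  cfg$class_params$sdlog <- unlist(cfg$class_params$sdlog)
  cfg$map_shape <- as.integer(unlist(cfg$map_shape))
  cfg$mbd_bc_multiplier <- unlist(cfg$mbd_bc_multiplier)
  cfg$class_proportions <- lapply(cfg$class_proportions, unlist)
  cfg$malignant_patch_fraction_range <-
    as.numeric(unlist(cfg$malignant_patch_fraction_range))
  do.call(cohort_config, cfg)
}
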