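#' Run the full phenotyping pipeline on a synthetic campaign
#'
#' Orchestrates simulate -> process -> QC -> link -> model as one
#' reproducible run: generates the campaign bundle, extracts fluorescence
#' parameters and spectral indices, applies the quality filters, assembles
#' the observation table, and fits the genotype-by-environment models
#' (Lasso with half-days validation and per-genotype accuracy, variance
#' partitions for both response types, temperature response curves per
#' genotype). All tables are written as CSV under `out_dir` together with
#' a `manifest.json` recording the seed, per-stage row counts and MD5
#' digests of every output file; re-running with the same config and seed
#' reproduces the digests.
#'
#' @param config A [campaign_config()].
#' @param out_dir Output directory.
#' @param seed Optional override of `config$seed`.
#' @param rules QC rules, see [qc_rules()].
#' @return Invisibly, a list with the observation table, QC logs, model
#'   fits, accuracy and partition tables, and the manifest.
#' @export
run_pipeline <- function(config = campaign_config(), out_dir,
                         seed = NULL, rules = qc_rules()) {
  if (!inherits(config, "campaign_config")) {
    stop("pipeline error [config]: expected a campaign_config", call. = FALSE)
  }
  if (!is.null(seed)) config$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline error [", name, "]: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  campaign <- run_stage("simulate", generate_campaign(config))
  write_campaign(campaign, file.path(out_dir, "raw"))
  stages$simulate <- list(transients = nrow(campaign$transients),
                          spectra = nrow(campaign$spectra),
                          env_minutes = nrow(campaign$env))

  params <- run_stage("process_transients",
                      process_transients(campaign$transients,
                                         campaign$schedule))
  indices <- run_stage("process_spectra",
                       process_spectra(campaign$spectra, campaign$references,
                                       campaign$transients))
  indices <- dplyr::left_join(
    indices, campaign$metadata[, c("plot_id", "species")], by = "plot_id")
  stages$process <- list(fluor_params = nrow(params),
                         spectral_indices = nrow(indices))

  params <- drop_repeated_position(params)
  indices <- drop_repeated_position(indices)
  fq <- run_stage("qc_fluorescence", qc_fluorescence(params, rules))
  qs <- run_stage("qc_spectral", qc_spectral(indices, rules))
  stages$qc <- list(
    fluor_in = nrow(params), fluor_kept = nrow(fq$kept),
    fluor_rejected = nrow(params) - nrow(fq$kept),
    spectral_in = nrow(indices), spectral_kept = nrow(qs$kept),
    spectral_rejected = nrow(indices) - nrow(qs$kept))

  obs <- run_stage("linkage",
                   assemble_observations(fq$kept, qs$kept, campaign$env,
                                         campaign$metadata))
  stages$linkage <- list(observations = nrow(obs),
                         env_unlinked = sum(!obs$env_linked))

  models <- run_stage("modeling", pipeline_models(obs, config))
  stages$modeling <- list(
    lasso_fits = length(models$lasso),
    partition_responses = length(models$partitions))

  # outputs
  out <- function(f) file.path(out_dir, f)
  readr::write_csv(flatten_for_csv(params), out("fluor_params.csv"))
  readr::write_csv(flatten_for_csv(indices), out("spectral_indices.csv"))
  readr::write_csv(fq$log, out("qc_fluor_log.csv"))
  readr::write_csv(qs$log, out("qc_spectral_log.csv"))
  readr::write_csv(flatten_for_csv(obs), out("observations.csv"))
  for (resp in names(models$lasso)) {
    fit <- models$lasso[[resp]]$fit
    readr::write_csv(
      tibble::tibble(term = names(fit$u), coefficient = fit$u,
                     lambda = fit$lambda, mu = fit$mu),
      out(paste0("lasso_coefficients_", resp, ".csv")))
    readr::write_csv(models$lasso[[resp]]$accuracy,
                     out(paste0("accuracy_", resp, ".csv")))
  }
  for (resp in names(models$partitions)) {
    readr::write_csv(models$partitions[[resp]],
                     out(paste0("variance_partition_", resp, ".csv")))
  }
  if (!is.null(models$response_curves)) {
    readr::write_csv(models$response_curves, out("response_curves.csv"))
  }

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    seed = config$seed,
    n_days = config$n_days,
    plots = campaign$metadata$plot_id,
    stages = stages,
    files = as.list(tools::md5sum(files))
  )
  names(manifest$files) <- sub(paste0("^", out_dir, "/?"), "",
                               names(manifest$files))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(campaign = campaign, params = params, indices = indices,
                 qc = list(fluor = fq, spectral = qs), observations = obs,
                 models = models, manifest = manifest))
}

flatten_for_csv <- function(tbl) {
  tbl[vapply(tbl, is.list, logical(1))] <- NULL
  tbl
}

pipeline_models <- function(obs, config) {
  models <- list(lasso = list(), partitions = list())
  n_days <- length(unique(obs$date))

  if (n_days >= 2) {
    parts <- split_train_validation(obs, "half-days")
    for (resp in c("fvfm", "fr2")) {
      design <- suppressWarnings(build_design_matrix(parts$train, resp))
      fit <- fit_lasso_cv(design, folds = 10,
                          seed = derive_seed(config$seed, 5L))
      pred <- predict(fit, parts$validation)
      val <- parts$validation[pred$rows_used, , drop = FALSE]
      acc <- validate_accuracy(pred$predicted, pred$observed,
                               val$genotype, val$date, val$hour_of_day)
      models$lasso[[resp]] <- list(fit = fit, accuracy = acc)
    }
  }

  models$partitions$fr2 <- partition_variance(obs, "fr2")
  models$partitions$fvfm <- partition_variance(
    obs, "fvfm",
    factors = c("ppfd", "sqrt_ppfd", "pri", "pndvi_ii", "date", "pndvi",
                "temperature", "rh"))

  models$response_curves <- tryCatch(
    fit_response_curve(obs, "fr2", "temperature",
                       terms = c("sqrt", "linear"), group = "genotype"),
    error = function(e) NULL)
  models
}
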