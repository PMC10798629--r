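#' Read and write trial-table CSV files
#'
#' The trial-table dialect has one row per trial with columns
#' `participant_id`, `experiment`, `group`, `phase`, `novelty`, `trial_index`,
#' `prior_label`, `likelihood_label`, `sigma_P`, `sigma_L`, `coin_x`,
#' `dot_x1..dot_x5`, `response_x`, `hit`. Positions are decimal screen units;
#' a header is required. The derived centroid column `mu_L` is not stored and
#' is recomputed on read.
#'
#' @param trials A trial-table tibble.
#' @param path File path.
#' @return `read_trial_table()` returns the tibble (with `mu_L` recomputed);
#'   `write_trial_table()` returns `path` invisibly.
#' @export
write_trial_table <- function(trials, path) {
  out <- trials[setdiff(names(trials), "mu_L")]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  ensure_mu_L(tibble::as_tibble(utils::read.csv(path)))
}

#' Run the full simulate / estimate / score / compare pipeline
#'
#' Simulates a cohort, runs [transfer_analysis()] and (optionally)
#' [compare_models()], and writes all artifacts to `out_dir`: `trials.csv`,
#' `participants.csv` (ground-truth sidecar), `estimates.csv`, `scores.csv`,
#' `summary.json`, `model_comparison.csv` and a `manifest.json` recording the
#' configuration, seed and exclusion tally. Identical configuration and seed
#' reproduce byte-identical outputs.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips writing.
#' @param models Model ids for [compare_models()], or `NULL` to skip the
#'   comparison stage.
#' @param mad_k,pooling Passed to [transfer_analysis()].
#' @return Invisibly, a list with `cohort`, `analysis`, `model_fits` (or
#'   `NULL`) and `manifest`.
#' @export
#' @examples
#' \donttest{
#' res <- run_pipeline(cohort_config(n_participants = 6, seed = 1), out_dir = NULL)
#' res$analysis$summary
#' }
run_pipeline <- function(config, out_dir = NULL, models = NULL,
                         mad_k = 3, pooling = "mean_ts") {
  stopifnot(inherits(config, "cohort_config"))
  cohort <- simulate_cohort(config)
  analysis <- transfer_analysis(cohort$trials, mad_k = mad_k, pooling = pooling)
  model_fits <- if (!is.null(models)) {
    compare_models(cohort$trials, models = models)
  }
  manifest <- list(
    package = "cointransfer",
    version = as.character(utils::packageVersion("cointransfer")),
    config = unclass(config),
    n_participants_included = sum(!analysis$scores$excluded),
    exclusions = as.list(analysis$exclusions)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trial_table(cohort$trials, file.path(out_dir, "trials.csv"))
    utils::write.csv(cohort$participants,
                     file.path(out_dir, "participants.csv"), row.names = FALSE)
    utils::write.csv(analysis$estimates,
                     file.path(out_dir, "estimates.csv"), row.names = FALSE)
    utils::write.csv(analysis$scores,
                     file.path(out_dir, "scores.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(summary = analysis$summary, exclusions = as.list(analysis$exclusions)),
      file.path(out_dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    if (!is.null(model_fits)) {
      utils::write.csv(model_fits,
                       file.path(out_dir, "model_comparison.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(list(cohort = cohort, analysis = analysis,
                 model_fits = model_fits, manifest = manifest))
}
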