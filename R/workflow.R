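#' Run the full semi-correlation workflow
#'
#' Wires the stages end to end: class balancing, Las Vegas split selection,
#' Monte Carlo weight optimization, per-subset evaluation, applicability
#' domain, and (optionally) a multi-probe promoter report. All stages consume
#' explicit seeds derived from `seed`, so a rerun with the same inputs is
#' byte-identical. When `out_dir` is given, the model (JSON), the per-subset
#' metric table, the optimization history, the domain verdicts, the promoter
#' report and a run manifest are written there; outputs are written only
#' after every stage has succeeded.
#'
#' @param data Data frame with `id`, `smiles`, `activity` (a `subset` column,
#'   if present, is replayed and balancing/splitting are skipped).
#' @param threshold_T,epochs_N Descriptor parameters T and N.
#' @param variant Target function, `"TF1"` or `"TF0"`.
#' @param seed Master integer seed.
#' @param n_attempts Las Vegas attempts (default 10).
#' @param n_probes Optimization runs for the promoter report; 0 skips it.
#' @param out_dir Optional output directory.
#' @return List with `data` (split dataset), `model`, `history`, `metrics`,
#'   `domain`, `stats`, `promoters` (or NULL) and `manifest`.
#' @export
run_workflow <- function(data, threshold_T = 3L, epochs_N = 15L,
                         variant = c("TF1", "TF0"), seed = 1L,
                         n_attempts = 10L, n_probes = 5L, out_dir = NULL) {
  variant <- match.arg(variant)
  if (!"subset" %in% names(data)) {
    balanced <- balance_dataset(data, seed = child_seed(seed, 11L))
    plan <- las_vegas_split(balanced, n_attempts = n_attempts,
                            seed = child_seed(seed, 12L))
    data <- apply_split(balanced, plan)
  }
  fit <- optimize_weights(data, threshold_T = threshold_T,
                          epochs_N = epochs_N, seed = child_seed(seed, 13L),
                          variant = variant)
  metrics <- evaluate_split(fit$model, data)
  stats <- attribute_statistics(data)
  domain <- applicability_domain(data, fit$model$weight_table, stats)
  promoters <- NULL
  if (n_probes > 0L) {
    runs <- lapply(seq_len(n_probes), function(k)
      optimize_weights(data, threshold_T = threshold_T, epochs_N = epochs_N,
                       seed = child_seed(seed, 100L + k), variant = variant,
                       warm_start = TRUE, step_max = 0.1))
    promoters <- promoter_report(runs, stats)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("semicorr")),
    variant = variant, threshold_T = threshold_T, epochs_N = epochs_N,
    seed = seed, n_attempts = n_attempts, n_probes = n_probes,
    n_compounds = nrow(data),
    subset_sizes = as.list(table(data$subset)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  result <- list(data = data, model = fit$model, history = fit$history,
                 metrics = metrics, domain = domain, stats = stats,
                 promoters = promoters, manifest = manifest)
  if (!is.null(out_dir)) write_workflow(result, out_dir)
  result
}

#' Write workflow outputs to a directory
#'
#' @param result A [run_workflow()] result.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_workflow <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  write_dataset(result$data, p("dataset.tsv"))
  write_model(result$model, p("model.json"))
  write_history(result$history, p("history.tsv"))
  utils::write.table(result$metrics, p("metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(result$domain, p("domain.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(result$promoters))
    utils::write.table(result$promoters, p("promoters.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  manifest <- result$manifest
  manifest$output_digests <- as.list(tools::md5sum(
    list.files(out_dir, full.names = TRUE, pattern = "\\.(tsv|json)$")))
  names(manifest$output_digests) <- basename(names(manifest$output_digests))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}

#' Published benchmark confusion matrices
#'
#' Loads the bundled per-subset confusion matrices (with their printed
#' sensitivity, specificity, accuracy and MCC) reported for ten balanced
#' splits of an acute dermal toxicity dataset under both target functions.
#' They serve as an oracle: [classification_metrics()] recomputed from the
#' TN/TP/FP/FN counts must agree with the printed accuracy and MCC to the
#' 4-decimal printing precision.
#'
#' @return Data frame with columns tf, split, set, sens, spec, acc, mcc, tn,
#'   tp, fp, fn, all.
#' @export
reference_confusion_tables <- function() {
  path <- system.file("extdata", "reference_confusion_tables.tsv",
                      package = "semicorr", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE)
}
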