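#' Balance a dataset by down-sampling inactives
#'
#' Binary semi-correlation modelling prefers balanced classes. All active
#' compounds are kept and an equally sized random subset of inactives is
#' drawn without replacement, deterministically per seed.
#'
#' @param data Data frame with columns `id`, `smiles`, `activity`.
#' @param seed Integer seed for the inactive sample.
#' @return Balanced data frame (rows in original order).
#' @export
balance_dataset <- function(data, seed = 1L) {
  act <- which(data$activity == 1L)
  inact <- which(data$activity == 0L)
  if (length(inact) < length(act))
    stopf("fewer inactive (%d) than active (%d) compounds",
          length(inact), length(act))
  keep_inact <- with_seed(seed, sample(inact, length(act)))
  out <- data[sort(c(act, keep_inact)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# One stratified random split: within each activity class, shuffled compounds
# are dealt round-robin to A, P, C, V, so per-subset class counts differ by
# at most one.
stratified_split <- function(data, seed) {
  letters4 <- c("A", "P", "C", "V")
  assignment <- character(nrow(data))
  with_seed(seed, {
    for (cls in c(1L, 0L)) {
      rows <- which(data$activity == cls)
      rows <- sample(rows)
      assignment[rows] <- rep_len(letters4, length(rows))
    }
  })
  stats::setNames(assignment, data$id)
}

#' Las Vegas selection of a four-way split
#'
#' Generates `n_attempts` random stratified splits into active training (A),
#' passive training (P), calibration (C) and validation (V) subsets of about
#' 25% each, scores every attempt by a cheap probe — the calibration-set MCC
#' of a short TF0 optimization run with a fixed probe seed — and returns the
#' split most favourable for the calibration set. Pairwise split
#' dissimilarity (fraction of compounds whose subset letter differs) is
#' recorded for inspection but no minimum is enforced.
#'
#' @param data Balanced data frame with `id`, `smiles`, `activity`.
#' @param n_attempts Number of random attempts (default 10).
#' @param seed Integer seed; attempt k uses a child seed derived from it.
#' @param probe List of probe-run settings: `threshold_T`, `epochs_N`,
#'   `seed`. The probe seed is fixed across attempts so that scores differ
#'   only through the splits.
#' @return An object of class `split_plan`: `assignment` (named letter
#'   vector), `seed`, `attempt_index`, `calibration_score`, per-attempt
#'   `scores` and the `dissimilarity` matrix.
#' @export
las_vegas_split <- function(data, n_attempts = 10L, seed = 1L,
                            probe = list(threshold_T = 3L, epochs_N = 2L,
                                         seed = 101L)) {
  if (n_attempts < 1L) stopf("n_attempts must be >= 1")
  if (nrow(data) < 8L) stopf("dataset too small to fill four subsets")
  assignments <- vector("list", n_attempts)
  scores <- numeric(n_attempts)
  for (k in seq_len(n_attempts)) {
    a <- stratified_split(data, child_seed(seed, k))
    assignments[[k]] <- a
    d <- data
    d$subset <- unname(a[d$id])
    fit <- optimize_weights(d, threshold_T = probe$threshold_T,
                            epochs_N = probe$epochs_N, seed = probe$seed,
                            variant = "TF0")
    cal <- d[d$subset == "C", , drop = FALSE]
    cm <- confusion_matrix(cal$activity, predict(fit$model, cal$smiles))
    scores[k] <- classification_metrics(cm)$mcc
  }
  dis <- matrix(0, n_attempts, n_attempts)
  for (a in seq_len(n_attempts)) for (b in seq_len(n_attempts))
    dis[a, b] <- mean(assignments[[a]] != assignments[[b]][names(assignments[[a]])])
  best <- which.max(scores)
  structure(list(assignment = assignments[[best]], seed = seed,
                 attempt_index = best, calibration_score = scores[best],
                 scores = scores, dissimilarity = dis),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("split plan: attempt %d of %d (calibration MCC %.4f, seed %d)\n",
              x$attempt_index, length(x$scores), x$calibration_score, x$seed))
  cat("subset sizes:", paste(names(table(x$assignment)),
                             table(x$assignment), collapse = "  "), "\n")
  invisible(x)
}

#' Attach a split plan to a dataset
#'
#' @param data Data frame with an `id` column.
#' @param plan A [las_vegas_split()] plan, or a named letter vector.
#' @return `data` with a `subset` column of letters A/P/C/V.
#' @export
apply_split <- function(data, plan) {
  a <- if (inherits(plan, "split_plan")) plan$assignment else plan
  if (!all(data$id %in% names(a)))
    stopf("split plan does not cover every compound id")
  data$subset <- unname(a[data$id])
  data
}

# -- dataset I/O ------------------------------------------------------------

#' Read a dataset from TSV
#'
#' Expected columns: `id`, `smiles`, `activity` (0/1) and optionally
#' `subset` (letters A/P/C/V), tab-separated with a header line. Malformed
#' activity values are reported with their line numbers.
#'
#' @param path Input file.
#' @return Data frame with columns id, smiles, activity and (if present)
#'   subset.
#' @export
read_dataset <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character", quote = "",
                         comment.char = "")
  need <- c("id", "smiles", "activity")
  if (!all(need %in% names(d)))
    stopf("dataset must have columns %s", paste(need, collapse = ", "))
  bad <- which(!d$activity %in% c("0", "1"))
  if (length(bad))
    stopf("activity must be 0/1; offending lines: %s",
          paste(bad + 1L, collapse = ", "))
  d$activity <- as.integer(d$activity)
  if (anyDuplicated(d$id)) stopf("compound ids must be unique")
  if ("subset" %in% names(d)) {
    bad <- which(!d$subset %in% c("A", "P", "C", "V"))
    if (length(bad))
      stopf("subset letters must be A/P/C/V; offending lines: %s",
            paste(bad + 1L, collapse = ", "))
  }
  d[, intersect(c("id", "smiles", "activity", "subset"), names(d))]
}

#' Write a dataset as TSV
#'
#' @param data Data frame with id, smiles, activity and optionally subset.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.table(data, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
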