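#' Per-attribute statistics over the three training-phase sets
#'
#' For every attribute seen in the active training (A), passive training (P)
#' or calibration (C) set, counts the compounds containing it (frequencies
#' N, N', N''), the corresponding probabilities P, P', P'' (frequency divided
#' by set size) and the statistical defect
#' \deqn{d_k = \frac{|P - P'|}{N + N'} + \frac{|P - P''|}{N + N''} +
#'       \frac{|P' - P''|}{N' + N''}}
#' where a term with zero denominator contributes 0. Equal probabilities
#' across the three sets give a defect of exactly 0.
#'
#' @param data Data frame with `smiles`, `subset` (A/P/C at least).
#' @return Data frame with columns code, n_a, n_p, n_c, p_a, p_p, p_c, d_k,
#'   sorted by code.
#' @export
attribute_statistics <- function(data) {
  sets <- list(A = data$smiles[data$subset == "A"],
               P = data$smiles[data$subset == "P"],
               C = data$smiles[data$subset == "C"])
  if (any(lengths(sets) == 0L))
    stopf("active, passive and calibration sets must all be non-empty")
  per_set <- lapply(sets, function(sm)
    table(unlist(lapply(sm, function(s) unique(smiles_attributes(s))))))
  codes <- lex_sort(unique(unlist(lapply(per_set, names))))
  count_in <- function(tab) {
    n <- as.integer(tab[codes])
    n[is.na(n)] <- 0L
    n
  }
  n_a <- count_in(per_set$A); n_p <- count_in(per_set$P)
  n_c <- count_in(per_set$C)
  p_a <- n_a / length(sets$A); p_p <- n_p / length(sets$P)
  p_c <- n_c / length(sets$C)
  term <- function(pi, pj, ni, nj) ifelse(ni + nj > 0, abs(pi - pj) / (ni + nj), 0)
  d_k <- term(p_a, p_p, n_a, n_p) + term(p_a, p_c, n_a, n_c) +
    term(p_p, p_c, n_p, n_c)
  data.frame(code = codes, n_a = n_a, n_p = n_p, n_c = n_c,
             p_a = p_a, p_p = p_p, p_c = p_c, d_k = d_k)
}

#' Statistical defect of one attribute
#'
#' Convenience wrapper around the three pairwise defect terms for explicitly
#' given probabilities and frequencies (ordered A, P, C).
#'
#' @param p Numeric length-3 vector of probabilities.
#' @param n Integer length-3 vector of frequencies.
#' @return The defect d_k, a non-negative number.
#' @export
statistical_defect <- function(p, n) {
  stopifnot(length(p) == 3L, length(n) == 3L)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  sum(vapply(pairs, function(ij) {
    den <- n[ij[1L]] + n[ij[2L]]
    if (den > 0) abs(p[ij[1L]] - p[ij[2L]]) / den else 0
  }, numeric(1L)))
}

#' Applicability-domain verdicts by statistical SMILES-defects
#'
#' The defect of a compound, D_j, sums the attribute defects d_k over the
#' distinct non-blocked attributes present in its SMILES. A compound is in
#' the applicability domain when D_j < multiplier x mean(D_j over the active
#' training set).
#'
#' @param data Data frame with `id`, `smiles`, `subset`.
#' @param wt The fitted [weight_table()] (defines the non-blocked set).
#' @param stats Attribute statistics from [attribute_statistics()]; computed
#'   from `data` when omitted.
#' @param multiplier Domain width multiplier (default 2).
#' @return Data frame with columns id, subset, D_j, d_bar, in_domain.
#' @export
applicability_domain <- function(data, wt, stats = NULL, multiplier = 2) {
  stopifnot(inherits(wt, "weight_table"))
  if (is.null(stats)) stats <- attribute_statistics(data)
  dk <- stats::setNames(stats$d_k, stats$code)
  non_blocked <- names(wt$weights)
  d_j <- vapply(data$smiles, function(s) {
    codes <- intersect(unique(smiles_attributes(s)), non_blocked)
    sum(dk[codes], na.rm = TRUE)
  }, numeric(1L), USE.NAMES = FALSE)
  d_bar <- mean(d_j[data$subset == "A"])
  data.frame(id = data$id, subset = data$subset, D_j = d_j, d_bar = d_bar,
             in_domain = d_j < multiplier * d_bar)
}

#' Promoter classification across repeated optimization runs
#'
#' An attribute whose correlation weight is positive in every run is a
#' promoter of endpoint increase; negative in every run, a promoter of
#' decrease; mixed signs leave its role unclear. Only attributes shared by
#' all runs are classified. The report is sorted by active-training
#' frequency (descending), then code.
#'
#' @param runs List of [weight_table()]s (or of `optimize_weights()` results)
#'   from repeated runs on the same split.
#' @param stats Attribute statistics from [attribute_statistics()], used to
#'   attach frequencies and defects; optional.
#' @return Data frame with columns code, role, one `cw_<k>` column per run,
#'   and (when `stats` is given) n_a, n_p, n_c, d_k.
#' @export
promoter_report <- function(runs, stats = NULL) {
  wts <- lapply(runs, function(r) {
    if (inherits(r, "weight_table")) r
    else if (inherits(r, "semicorr_model")) r$weight_table
    else r$model$weight_table
  })
  if (length(wts) < 2L) stopf("need >= 2 runs to classify promoters")
  shared <- Reduce(intersect, lapply(wts, function(w) names(w$weights)))
  cw <- vapply(wts, function(w) w$weights[shared],
               numeric(length(shared)))
  cw <- matrix(cw, nrow = length(shared),
               dimnames = list(shared, paste0("cw_", seq_along(wts))))
  role <- apply(cw, 1L, function(v)
    if (all(v > 0)) "promoter_increase"
    else if (all(v < 0)) "promoter_decrease"
    else "unclear")
  out <- data.frame(code = shared, role = role, cw,
                    row.names = NULL, check.names = FALSE)
  if (!is.null(stats)) {
    m <- match(out$code, stats$code)
    out$n_a <- stats$n_a[m]; out$n_p <- stats$n_p[m]
    out$n_c <- stats$n_c[m]; out$d_k <- stats$d_k[m]
    out <- out[order(-out$n_a, out$code, method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- out[order(out$code, method = "radix"), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}
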