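#' Blocked (rare) attributes of an active training set
#'
#' An attribute is blocked when the number of active-training compounds whose
#' SMILES contains it falls below the rarity threshold T. Blocked attributes
#' keep a correlation weight of 0 and are excluded from optimization.
#'
#' @param smiles Character vector: SMILES of the active training set.
#' @param threshold_T Positive integer rarity threshold.
#' @return Character vector of blocked canonical codes.
#' @export
blocked_attributes <- function(smiles, threshold_T = 3L) {
  if (length(smiles) == 0L) stopf("empty active training set")
  if (threshold_T < 1L) stopf("threshold_T must be >= 1")
  per_compound <- lapply(smiles, function(s) unique(smiles_attributes(s)))
  counts <- table(unlist(per_compound))
  lex_sort(names(counts)[counts < threshold_T])
}

#' Index of ideality of correlation
#'
#' The IIC of a calibration set is the Pearson correlation r between observed
#' and calculated values, scaled by the balance of negative and positive
#' residual magnitudes:
#' \deqn{IIC = r \cdot \frac{\min(MAE^-, MAE^+)}{\max(MAE^-, MAE^+)}}
#' with residuals \eqn{\Delta_k = observed_k - calculated_k}; \eqn{MAE^-}
#' averages \eqn{|\Delta_k|} over \eqn{\Delta_k < 0} and \eqn{MAE^+} over
#' \eqn{\Delta_k \ge 0}. If either side is empty (all residuals on one sign)
#' the ratio is undefined and the IIC is defined as 0, which simply removes
#' the calibration bonus. Symmetric residual magnitudes give IIC = r exactly.
#'
#' @param observed Numeric vector of observed endpoint values (0/1 here).
#' @param calculated Numeric vector of fitted model values.
#' @return A single number with |IIC| <= |r|.
#' @export
iic <- function(observed, calculated) {
  if (length(observed) < 2L || length(observed) != length(calculated))
    stopf("need >= 2 paired observed/calculated values")
  delta <- observed - calculated
  neg <- delta < 0
  n_minus <- sum(neg)
  n_plus <- sum(!neg)
  if (n_minus == 0L || n_plus == 0L) return(0)
  mae_minus <- mean(abs(delta[neg]))
  mae_plus <- mean(abs(delta[!neg]))
  hi <- max(mae_minus, mae_plus)
  if (hi == 0) return(0)
  safe_cor(observed, calculated) * min(mae_minus, mae_plus) / hi
}

#' Target function of the Monte Carlo optimization
#'
#' `TF0 = r_at + r_pt - |r_at - r_pt| * penalty_coeff` rewards high and
#' balanced determination coefficients on the active and passive training
#' sets. `TF1 = TF0 + iic_c * iic_coeff` adds the calibration-set index of
#' ideality of correlation, steering the optimization towards calibration
#' quality.
#'
#' @param r_at,r_pt Determination coefficients (squared Pearson correlations
#'   between observed 0/1 and calculated values) on the active and passive
#'   training sets.
#' @param iic_c Calibration-set IIC (used by TF1 only).
#' @param variant `"TF0"` or `"TF1"`.
#' @param penalty_coeff Weight of the |r_at - r_pt| dispersion penalty
#'   (default 0.1).
#' @param iic_coeff Weight of the IIC bonus (default 0.3).
#' @return A single number.
#' @export
target_function <- function(r_at, r_pt, iic_c = 0, variant = c("TF1", "TF0"),
                            penalty_coeff = 0.1, iic_coeff = 0.3) {
  variant <- match.arg(variant)
  tf0 <- r_at + r_pt - abs(r_at - r_pt) * penalty_coeff
  if (variant == "TF0") tf0 else tf0 + iic_c * iic_coeff
}

# Precompute everything the proposal loop needs: subset index vectors and,
# per non-blocked attribute, the rows and multiplicities it touches.
build_design <- function(data, threshold_T) {
  idx <- split(seq_len(nrow(data)), factor(data$subset, c("A", "P", "C", "V")))
  if (length(idx$A) == 0L || length(idx$P) == 0L || length(idx$C) == 0L)
    stopf("active, passive and calibration subsets must all be non-empty")
  attrs <- lapply(data$smiles, smiles_attributes)
  seen_A <- unique(unlist(lapply(attrs[idx$A], unique)))
  blocked <- blocked_attributes(data$smiles[idx$A], threshold_T)
  universe <- lex_sort(setdiff(seen_A, blocked))
  if (length(universe) == 0L)
    stopf("no non-blocked attributes at threshold T = %d", threshold_T)
  p <- length(universe)
  ii <- rep(seq_along(attrs), lengths(attrs))
  jj <- match(unlist(attrs), universe)
  keep <- !is.na(jj)
  # run-length encode (compound, attribute) pairs into per-column rows/counts
  key <- sort((ii[keep] - 1) * p + jj[keep])
  r <- rle(key)
  pair_j <- ((r$values - 1) %% p) + 1L
  pair_i <- ((r$values - 1) %/% p) + 1L
  by_col <- split(seq_along(pair_j), factor(pair_j, levels = seq_len(p)))
  # per column: global rows/counts plus positions local to each subset vector
  local_pos <- integer(nrow(data))
  for (s in c("A", "P", "C")) local_pos[idx[[s]]] <- seq_along(idx[[s]])
  in_set <- character(nrow(data))
  for (s in c("A", "P", "C", "V")) in_set[idx[[s]]] <- s
  cols <- lapply(by_col, function(k) {
    gi <- pair_i[k]; gx <- r$lengths[k]
    sel <- function(s) {
      m <- in_set[gi] == s
      list(i = local_pos[gi[m]], x = gx[m])
    }
    list(i = gi, x = gx, A = sel("A"), P = sel("P"), C = sel("C"))
  })
  list(universe = universe, blocked = blocked, cols = cols,
       idx = idx, y = as.numeric(data$activity))
}

# Precomputed response statistics per subset, for the tight proposal loop.
response_stats <- function(y) {
  n <- length(y)
  my <- mean(y)
  list(y = y, n = n, my = my, ssy = sum((y - my)^2))
}

# State evaluation from the three subset descriptor vectors. r_at / r_pt are
# squared Pearson correlations ("determination coefficients"); the line is
# fitted on the active training set only and the IIC on the calibration set
# only. Correlations involving a constant vector are taken as 0.
eval_state <- function(dA, dP, dC, ys, variant, penalty_coeff, iic_coeff,
                       need_c = TRUE) {
  r2 <- function(d, s) {
    sd_ <- sum(d)
    num <- sum(d * s$y) - sd_ * s$my
    den <- (sum(d * d) - sd_ * sd_ / s$n) * s$ssy
    if (den <= 0) 0 else num * num / den
  }
  r_at <- r2(dA, ys$A)
  r_pt <- r2(dP, ys$P)
  r_c <- NA_real_; iic_c <- 0; c0 <- NA_real_; c1 <- NA_real_
  if (need_c || variant == "TF1") {
    sdA <- sum(dA)
    ss <- sum(dA * dA) - sdA * sdA / ys$A$n
    if (ss > 0) {
      c1 <- (sum(dA * ys$A$y) - sdA * ys$A$my) / ss
      c0 <- ys$A$my - c1 * sdA / ys$A$n
      calcC <- c0 + c1 * dC
      yC <- ys$C$y
      r_c <- safe_cor(yC, calcC)
      delta <- yC - calcC
      neg <- delta < 0
      n_minus <- sum(neg)
      if (n_minus > 0L && n_minus < ys$C$n) {
        mae_minus <- -sum(delta[neg]) / n_minus
        mae_plus <- sum(delta[!neg]) / (ys$C$n - n_minus)
        hi <- max(mae_minus, mae_plus)
        if (hi > 0) iic_c <- r_c * min(mae_minus, mae_plus) / hi
      }
    } else {
      r_c <- 0
    }
  }
  tf <- target_function(r_at, r_pt, iic_c, variant, penalty_coeff, iic_coeff)
  list(r_at = r_at, r_pt = r_pt, r_c = r_c, iic_c = iic_c, tf = tf,
       c0 = c0, c1 = c1)
}

#' Monte Carlo optimization of correlation weights
#'
#' Seeded hill climbing over correlation weights. One epoch is one pass over
#' all non-blocked attributes in sorted code order; for each attribute a
#' uniform perturbation `u ~ U(-step_max, step_max)` of its weight is
#' proposed, the semi-correlation line is refitted on the active training set
#' and the proposal is accepted only if the target function strictly
#' increases. Identical seed and inputs give bit-identical results. The
#' returned model is put in the canonical orientation with a positive slope
#' (the target function cannot tell `(c1, CW)` from `(-c1, -CW)`, so the
#' orientation is fixed by convention to make weight signs meaningful).
#'
#' @param data Data frame with columns `id`, `smiles`, `activity` and
#'   `subset` (letters A/P/C/V from [las_vegas_split()] or a replayed split).
#' @param threshold_T Rarity threshold T of the descriptor DCW(T, N).
#' @param epochs_N Number of optimization epochs N.
#' @param seed Integer seed for initialization and proposals.
#' @param variant Target function, `"TF1"` (with IIC) or `"TF0"`.
#' @param step_max Half-width of the uniform proposal step.
#' @param init Length-2 numeric: initialization range of the weights
#'   (ignored when `warm_start = TRUE`).
#' @param warm_start Initialization mode. The default `FALSE` draws every
#'   weight uniformly from `init`; predictions are unaffected by where in the
#'   space of equivalent weight configurations the search lands, so this is
#'   the mode for model building. For promoter interpretation the individual
#'   weight signs must be meaningful: the target function is invariant under
#'   redistributions of weight among collinear attributes (and under jointly
#'   negating slope and weights), so with a random start each weight's final
#'   sign partly reflects where the random walk wandered. `warm_start = TRUE`
#'   anchors the start of each weight at `warm_scale` times the Pearson
#'   correlation between the attribute's count and the 0/1 activity on the
#'   active training set (plus a seeded uniform jitter from `warm_jitter`),
#'   selecting the representative in which each weight carries its own
#'   attribute's association with activity. [promoter_report()] probes and
#'   the workflow's interpretation stage use this mode.
#' @param warm_scale Scale of the warm-start direction (default 1).
#' @param warm_jitter Length-2 jitter range around the warm start.
#' @param penalty_coeff,iic_coeff Target-function coefficients, see
#'   [target_function()].
#' @param max_reinit Re-initialization attempts when the starting weights
#'   give a constant descriptor on the active training set.
#' @return List with `model` (a [semicorr_model()]) and `history`, a data
#'   frame of r_at, r_pt, r_c, iic and the target function per epoch.
#' @export
optimize_weights <- function(data, threshold_T = 3L, epochs_N = 15L,
                             seed = 1L, variant = c("TF1", "TF0"),
                             step_max = 0.3, init = c(-1, 1),
                             warm_start = FALSE, warm_scale = 1,
                             warm_jitter = c(-0.1, 0.1),
                             penalty_coeff = 0.1, iic_coeff = 0.3,
                             max_reinit = 25L) {
  variant <- match.arg(variant)
  if (epochs_N < 1L) stopf("epochs_N must be >= 1")
  if (init[1L] >= init[2L]) stopf("init range must satisfy low < high")
  design <- build_design(data, threshold_T)
  p <- length(design$universe)
  n <- length(design$y)
  ys <- list(A = response_stats(design$y[design$idx$A]),
             P = response_stats(design$y[design$idx$P]),
             C = response_stats(design$y[design$idx$C]))
  warm <- if (warm_start) {
    yA <- ys$A$y
    warm_scale * vapply(seq_len(p), function(j) {
      col <- design$cols[[j]]$A
      cnt <- numeric(ys$A$n)
      if (length(col$i)) cnt[col$i] <- col$x
      safe_cor(cnt, yA)
    }, numeric(1L))
  } else {
    numeric(p)
  }

  jit <- if (warm_start) warm_jitter else init
  with_seed(seed, {
    cw <- NULL
    for (attempt in seq_len(max_reinit)) {
      cand <- warm + stats::runif(p, jit[1L], jit[2L])
      d <- numeric(n)
      for (j in seq_len(p)) {
        col <- design$cols[[j]]
        d[col$i] <- d[col$i] + cand[j] * col$x
      }
      if (stats::var(d[design$idx$A]) > 0) {
        cw <- cand
        dA <- d[design$idx$A]; dP <- d[design$idx$P]; dC <- d[design$idx$C]
        break
      }
    }
    if (is.null(cw))
      stopf("degenerate initialization: constant descriptor after %d attempts",
            max_reinit)

    need_c <- variant == "TF1"
    state <- eval_state(dA, dP, dC, ys, variant, penalty_coeff, iic_coeff)
    history <- vector("list", epochs_N)
    for (epoch in seq_len(epochs_N)) {
      for (j in seq_len(p)) {
        u <- stats::runif(1L, -step_max, step_max)
        col <- design$cols[[j]]
        a <- col$A; pp <- col$P; cc <- col$C
        dA2 <- dA; if (length(a$i)) dA2[a$i] <- dA2[a$i] + u * a$x
        dP2 <- dP; if (length(pp$i)) dP2[pp$i] <- dP2[pp$i] + u * pp$x
        dC2 <- dC; if (length(cc$i)) dC2[cc$i] <- dC2[cc$i] + u * cc$x
        cand_state <- eval_state(dA2, dP2, dC2, ys, variant, penalty_coeff,
                                 iic_coeff, need_c = need_c)
        if (cand_state$tf > state$tf) {
          cw[j] <- cw[j] + u
          dA <- dA2; dP <- dP2; dC <- dC2
          state <- cand_state
        }
      }
      full <- eval_state(dA, dP, dC, ys, variant, penalty_coeff, iic_coeff)
      history[[epoch]] <- data.frame(epoch = epoch, r_at = full$r_at,
                                     r_pt = full$r_pt, r_c = full$r_c,
                                     iic = full$iic_c, tf = full$tf)
    }
    final <- eval_state(dA, dP, dC, ys, variant, penalty_coeff, iic_coeff)
    # The target function is invariant under (c1, CW) -> (-c1, -CW); fix the
    # orientation to c1 > 0 so correlation-weight signs are interpretable.
    c0 <- final$c0; c1 <- final$c1
    if (is.finite(c1) && c1 < 0) {
      cw <- -cw
      dA <- -dA; yA <- ys$A
      c1 <- (sum(dA * yA$y) - sum(dA) * yA$my) /
        (sum(dA * dA) - sum(dA)^2 / yA$n)
      c0 <- yA$my - c1 * sum(dA) / yA$n
    }
    wt <- weight_table(weights = stats::setNames(cw, design$universe),
                       blocked = design$blocked,
                       threshold_T = threshold_T, epochs_N = epochs_N)
    list(model = semicorr_model(c0, c1, wt),
         history = do.call(rbind, history))
  })
}

#' Evaluate a model on every subset of a split dataset
#'
#' @param model A [semicorr_model()].
#' @param data Data frame with `smiles`, `activity`, `subset`.
#' @return Data frame with one row per subset (A, P, C, V when present) and
#'   columns Set, Sens, Spec, Acc, MCC, TN, TP, FP, FN, All.
#' @export
evaluate_split <- function(model, data) {
  sets <- intersect(c("A", "P", "C", "V"), unique(data$subset))
  rows <- lapply(sets, function(s) {
    d <- data[data$subset == s, , drop = FALSE]
    cm <- confusion_matrix(d$activity, predict(model, d$smiles))
    m <- classification_metrics(cm)
    data.frame(Set = s, Sens = m$sens, Spec = m$spec, Acc = m$acc,
               MCC = m$mcc, TN = cm$tn, TP = cm$tp, FP = cm$fp, FN = cm$fn,
               All = cm$tp + cm$tn + cm$fp + cm$fn)
  })
  do.call(rbind, rows)
}

#' Write an optimization history as TSV
#'
#' @param history History data frame from [optimize_weights()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  utils::write.table(history, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
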