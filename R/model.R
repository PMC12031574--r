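#' Construct a correlation-weight table
#'
#' Holds the correlation weight CW of every non-blocked attribute seen in the
#' active training set, the set of blocked (rare) attributes, and the two
#' Monte Carlo parameters: the rarity threshold T and the number of epochs N.
#'
#' @param weights Named numeric vector, names are canonical 12-character codes.
#' @param blocked Character vector of blocked codes (CW fixed at 0).
#' @param threshold_T Positive integer rarity threshold.
#' @param epochs_N Positive integer number of optimization epochs.
#' @return An object of class `weight_table`.
#' @export
weight_table <- function(weights = numeric(0), blocked = character(0),
                         threshold_T = 3L, epochs_N = 15L) {
  if (is.null(names(weights)) && length(weights) > 0L)
    stopf("'weights' must be named by attribute code")
  if (any(blocked %in% names(weights)))
    stopf("blocked attributes must not carry weights")
  if (threshold_T < 1L || epochs_N < 1L)
    stopf("threshold_T and epochs_N must be positive integers")
  structure(list(weights = weights[lex_sort(names(weights))],
                 blocked = lex_sort(unique(blocked)),
                 threshold_T = as.integer(threshold_T),
                 epochs_N = as.integer(epochs_N)),
            class = "weight_table")
}

#' Optimal descriptor DCW(T, N) of a SMILES string
#'
#' Sums the correlation weights of every attribute instance (with
#' multiplicity) extracted from the SMILES: single tokens, adjacent pairs and
#' adjacent triples. Blocked attributes and attributes absent from the weight
#' table contribute 0.
#'
#' @param smiles Character vector of SMILES strings.
#' @param wt A [weight_table()].
#' @return Numeric vector of descriptor values.
#' @export
dcw <- function(smiles, wt) {
  stopifnot(inherits(wt, "weight_table"))
  vapply(smiles, function(s) {
    codes <- smiles_attributes(s)
    idx <- match(codes, names(wt$weights))
    sum(wt$weights[idx[!is.na(idx)]])
  }, numeric(1L), USE.NAMES = FALSE)
}

#' Least-squares semi-correlation line
#'
#' Ordinary least squares of the 0/1 activity on the descriptor, fitted on the
#' active training set only. The semi-correlation is a regression whose
#' response takes exactly the two values 0 (inactive) and 1 (active).
#'
#' @param descriptor Numeric vector of DCW values.
#' @param activity Integer vector of observed 0/1 activities.
#' @return Named numeric vector `c(c0 = ..., c1 = ...)`.
#' @export
semicorr_line <- function(descriptor, activity) {
  if (length(descriptor) < 2L)
    stopf("at least two records are required to fit the line")
  if (length(descriptor) != length(activity))
    stopf("descriptor and activity lengths differ")
  v <- stats::var(descriptor)
  if (!is.finite(v) || v == 0)
    stopf("degenerate fit: all descriptor values are identical")
  c1 <- stats::cov(descriptor, activity) / v
  c0 <- mean(activity) - c1 * mean(descriptor)
  c(c0 = c0, c1 = c1)
}

#' Classify a model value as active or inactive
#'
#' Thresholds the fitted semi-correlation value midway between the inactive
#' (0) and active (1) codes: active if `MODEL >= threshold`, inactive
#' otherwise. The comparison is inclusive at the threshold.
#'
#' @param model_value Numeric vector of fitted model values.
#' @param threshold Decision threshold, strictly between 0 and 1.
#' @return Integer vector of 0/1 categories.
#' @export
classify_activity <- function(model_value, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stopf("decision threshold must lie strictly between 0 and 1")
  if (any(is.na(model_value)) || any(is.nan(model_value)))
    stopf("model values must be finite numbers")
  as.integer(model_value >= threshold)
}

#' Confusion matrix with the active-as-positive convention
#'
#' @param observed Integer vector of observed 0/1 activities.
#' @param predicted Integer vector of predicted 0/1 categories.
#' @return An object of class `confusion_matrix` with fields tp, tn, fp, fn.
#' @export
confusion_matrix <- function(observed, predicted) {
  if (length(observed) != length(predicted))
    stopf("observed and predicted lengths differ")
  if (!all(observed %in% c(0L, 1L)) || !all(predicted %in% c(0L, 1L)))
    stopf("observed and predicted must be 0/1")
  structure(list(tp = sum(observed == 1L & predicted == 1L),
                 tn = sum(observed == 0L & predicted == 0L),
                 fp = sum(observed == 0L & predicted == 1L),
                 fn = sum(observed == 1L & predicted == 0L)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("confusion matrix (n = %d): TP %d  TN %d  FP %d  FN %d\n",
              x$tp + x$tn + x$fp + x$fn, x$tp, x$tn, x$fp, x$fn))
  invisible(x)
}

#' Classification statistics of a confusion matrix
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), accuracy and the Matthews
#' correlation coefficient
#' \deqn{MCC = \frac{TP\,TN - FP\,FN}{\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}.}
#' When any factor of the MCC denominator is zero the MCC is reported as 0
#' and the result is flagged degenerate rather than failing, so whole-split
#' evaluation never aborts; an undefined sensitivity or specificity (empty
#' class) is reported as `NaN` with the same flag.
#'
#' @param cm A [confusion_matrix()].
#' @return List with `sens`, `spec`, `acc`, `mcc` and logical `degenerate`.
#' @export
classification_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  tp <- cm$tp; tn <- cm$tn; fp <- cm$fp; fn <- cm$fn
  n <- tp + tn + fp + fn
  if (n == 0L) stopf("empty confusion matrix")
  sens <- if (tp + fn > 0L) tp / (tp + fn) else NaN
  spec <- if (tn + fp > 0L) tn / (tn + fp) else NaN
  acc <- (tp + tn) / n
  denom <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  degenerate <- denom == 0 || is.nan(sens) || is.nan(spec)
  mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / sqrt(denom)
  list(sens = sens, spec = spec, acc = acc, mcc = mcc, degenerate = degenerate)
}

#' Construct a semi-correlation model
#'
#' @param c0,c1 Intercept and slope of the semi-correlation line
#'   `MODEL = c0 + c1 * DCW(T, N)`.
#' @param wt The [weight_table()] behind the descriptor.
#' @param decision_threshold Classification threshold (default 0.5).
#' @return An object of class `semicorr_model`.
#' @export
semicorr_model <- function(c0, c1, wt, decision_threshold = 0.5) {
  stopifnot(inherits(wt, "weight_table"))
  if (decision_threshold <= 0 || decision_threshold >= 1)
    stopf("decision threshold must lie strictly between 0 and 1")
  structure(list(c0 = c0, c1 = c1, weight_table = wt,
                 decision_threshold = decision_threshold),
            class = "semicorr_model")
}

#' @export
print.semicorr_model <- function(x, ...) {
  wt <- x$weight_table
  cat(sprintf("MODEL = %.4f + %.5f x DCW(%d, %d)\n",
              x$c0, x$c1, wt$threshold_T, wt$epochs_N))
  cat(sprintf("  %d weighted attributes, %d blocked, threshold %.2f\n",
              length(wt$weights), length(wt$blocked), x$decision_threshold))
  invisible(x)
}

#' Predict activity for new SMILES
#'
#' @param object A [semicorr_model()].
#' @param smiles Character vector of SMILES strings.
#' @param type `"class"` for 0/1 categories, `"response"` for the raw fitted
#'   model values.
#' @param ... Unused.
#' @return Integer (class) or numeric (response) vector.
#' @export
predict.semicorr_model <- function(object, smiles,
                                   type = c("class", "response"), ...) {
  type <- match.arg(type)
  value <- object$c0 + object$c1 * dcw(smiles, object$weight_table)
  if (type == "response") value
  else classify_activity(value, object$decision_threshold)
}

# -- model serialization ----------------------------------------------------

#' Write a semi-correlation model to JSON
#'
#' The file holds c0, c1, T, N, the decision threshold, the blocked-attribute
#' list and the weight map keyed by 12-character codes, at full double
#' precision so a read/write round trip is bit-exact.
#'
#' @param model A [semicorr_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "semicorr_model"))
  wt <- model$weight_table
  obj <- list(c0 = model$c0, c1 = model$c1,
              threshold_T = wt$threshold_T, epochs_N = wt$epochs_N,
              decision_threshold = model$decision_threshold,
              blocked = as.list(wt$blocked),
              weights = as.list(wt$weights))
  # I(17) significant digits: doubles survive the write/read round trip
  # bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a semi-correlation model from JSON
#'
#' @param path File written by [write_model()].
#' @return A [semicorr_model()].
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path)
  w <- vapply(obj$weights, as.numeric, numeric(1L))
  semicorr_model(c0 = as.numeric(obj$c0), c1 = as.numeric(obj$c1),
                 wt = weight_table(weights = w,
                                   blocked = unlist(obj$blocked) %||% character(0),
                                   threshold_T = obj$threshold_T,
                                   epochs_N = obj$epochs_N),
                 decision_threshold = as.numeric(obj$decision_threshold))
}
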