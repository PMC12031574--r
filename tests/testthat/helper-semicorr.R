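# Shared fixtures built in code.

# A reduced synthetic scenario for module-level tests: same grammar and rules
# as the default study conditions, smaller pool so each test stays fast.
small_scenario <- function(seed = 1L, n_pool = 600L) {
  synthetic_scenario(seed = seed, n_pool = n_pool, base_rate = 0.3)
}

# A split dataset ready for optimization, bypassing Las Vegas selection.
small_split_data <- function(seed = 1L, n_pool = 600L) {
  sc <- small_scenario(seed, n_pool)
  apply_split(sc$data, semicorr:::stratified_split(sc$data, seed + 1L))
}

# Independent Matthews correlation oracle: the MCC of a confusion matrix is
# the Pearson correlation of the underlying paired 0/1 vectors.
mcc_by_correlation <- function(tp, tn, fp, fn) {
  obs <- c(rep(1, tp), rep(0, tn), rep(0, fp), rep(1, fn))
  pred <- c(rep(1, tp), rep(0, tn), rep(1, fp), rep(0, fn))
  suppressWarnings(stats::cor(obs, pred))
}

random_confusion <- function() {
  as.list(stats::setNames(sample(0:80, 4, replace = TRUE),
                          c("tp", "tn", "fp", "fn")))
}
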