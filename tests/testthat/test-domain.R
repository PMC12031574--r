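test_that("the statistical defect follows the three pairwise terms", {
  # equal probabilities: defect vanishes
  expect_equal(statistical_defect(c(0.3, 0.3, 0.3), c(30L, 30L, 30L)), 0)
  # direct substitution
  expect_equal(statistical_defect(c(0.5, 0.4, 0.4), c(50L, 40L, 40L)),
               0.1 / 90 + 0.1 / 90)
  # zero-denominator terms contribute nothing
  expect_equal(statistical_defect(c(0.5, 0, 0.4), c(50L, 0L, 40L)),
               0.5 / 50 + 0.1 / 90 + 0.4 / 40)
  # symmetric under permutation of the three sets
  p <- c(0.47, 0.12, 0.30); n <- c(19L, 4L, 11L)
  for (perm in list(c(2L, 1L, 3L), c(3L, 2L, 1L), c(2L, 3L, 1L))) {
    expect_equal(statistical_defect(p[perm], n[perm]),
                 statistical_defect(p, n))
  }
})

test_that("attribute statistics count compounds, not occurrences", {
  d <- data.frame(id = as.character(1:6),
                  smiles = c("CC", "CCC", "NN", "CN", "CC", "NN"),
                  activity = rep(0:1, 3),
                  subset = c("A", "A", "P", "P", "C", "C"))
  st <- attribute_statistics(d)
  row <- st[st$code == "C...C.......", ]
  # "CCC" contains C-C twice but counts once per compound
  expect_equal(row$n_a, 2L)
  expect_equal(row$p_a, 1)
  expect_equal(row$n_p, 0L)
  expect_equal(row$n_c, 1L)
  expect_equal(row$d_k, statistical_defect(c(1, 0, 0.5), c(2L, 0L, 1L)))
})

test_that("compound defects are additive over distinct attribute codes", {
  d <- small_split_data(seed = 7L, n_pool = 200L)
  fit <- optimize_weights(d, epochs_N = 1L, seed = 1L)
  st <- attribute_statistics(d)
  dom <- applicability_domain(d, fit$model$weight_table, st)
  dk <- stats::setNames(st$d_k, st$code)
  for (i in sample(nrow(d), 10L)) {
    codes <- intersect(unique(smiles_attributes(d$smiles[i])),
                       names(fit$model$weight_table$weights))
    expect_equal(dom$D_j[i], sum(dk[codes]))
  }
})

test_that("domain verdicts apply the 2 x mean rule on the active set", {
  d <- small_split_data(seed = 8L, n_pool = 200L)
  fit <- optimize_weights(d, epochs_N = 1L, seed = 1L)
  dom <- applicability_domain(d, fit$model$weight_table)
  a <- dom[dom$subset == "A", ]
  expect_equal(unique(dom$d_bar), mean(a$D_j))
  expect_identical(dom$in_domain, dom$D_j < 2 * dom$d_bar)
  # Markov: at least half of the active training set is inside its own domain
  expect_gte(mean(a$in_domain), 0.5)
})

test_that("a compound with only blocked attributes is trivially in domain", {
  wt <- weight_table(c("C..........." = 1), blocked = "N...........",
                     threshold_T = 3L, epochs_N = 1L)
  d <- data.frame(id = c("a", "b", "c", "d"),
                  smiles = c("CC", "CC", "CC", "N"),
                  activity = c(1L, 0L, 1L, 0L),
                  subset = c("A", "P", "C", "V"))
  dom <- applicability_domain(d, wt)
  expect_equal(dom$D_j[4L], 0)
  expect_true(dom$in_domain[4L] || dom$d_bar[4L] == 0)
})

test_that("promoter roles depend only on sign stability, not run order", {
  mk <- function(w) weight_table(w, threshold_T = 1L, epochs_N = 1L)
  runs <- list(
    mk(c("Cl.........." = 0.4, "N...#......." = -1.6, "C..........." = -0.2)),
    mk(c("Cl.........." = 1.1, "N...#......." = -1.7, "C..........." = 0.3)),
    mk(c("Cl.........." = 0.6, "N...#......." = -1.4, "C..........." = -0.1)))
  rep1 <- promoter_report(runs)
  roles <- stats::setNames(rep1$role, rep1$code)
  expect_identical(roles[["Cl.........."]], "promoter_increase")
  expect_identical(roles[["N...#......."]], "promoter_decrease")
  expect_identical(roles[["C..........."]], "unclear")
  rep2 <- promoter_report(rev(runs))
  expect_identical(rep1$role, rep2$role[match(rep1$code, rep2$code)])
  expect_error(promoter_report(runs[1L]), ">= 2 runs")
})

test_that("only attributes shared by all runs are classified", {
  mk <- function(w) weight_table(w, threshold_T = 1L, epochs_N = 1L)
  runs <- list(mk(c("Cl.........." = 0.4, "O...C......." = 0.2)),
               mk(c("Cl.........." = 0.6)))
  rep <- promoter_report(runs)
  expect_identical(rep$code, "Cl..........")
})
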