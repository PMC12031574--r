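test_that("rare attributes are blocked by the threshold T", {
  sm <- c("CCN", "CCO", "CC")
  # T = 1: nothing seen is rare
  expect_length(blocked_attributes(sm, threshold_T = 1L), 0L)
  # T = 3: anything in fewer than 3 compounds is blocked
  blocked <- blocked_attributes(sm, threshold_T = 3L)
  expect_true("N..........." %in% blocked)   # one compound
  expect_true("O..........." %in% blocked)
  expect_false("C..........." %in% blocked)  # all three
  expect_false("C...C......." %in% blocked)
  expect_error(blocked_attributes(character(0)), "empty")
})

test_that("the IIC scales the calibration correlation by residual balance", {
  # residual magnitudes balanced on both sides: IIC equals r exactly
  obs <- c(0, 0, 1, 1); calc <- c(0.2, -0.2, 0.8, 1.2)
  expect_equal(iic(obs, calc), stats::cor(obs, calc))
  # a perfect fit has one-sided (all-zero) residuals: defined as 0
  expect_identical(iic(obs, obs), 0)
  # one-sided residuals: defined as 0
  expect_identical(iic(c(0, 1, 1), c(0.5, 1.5, 1.2)), 0)
  # asymmetric residuals shrink the correlation
  obs2 <- c(0, 0, 1, 1); calc2 <- c(0.4, -0.1, 0.9, 1.05)
  r <- stats::cor(obs2, calc2)
  expect_lt(abs(iic(obs2, calc2)), abs(r))
})

test_that("|IIC| never exceeds |r| on random residual vectors", {
  set.seed(41)
  for (i in 1:1000) {
    n <- sample(3:30, 1L)
    obs <- rbinom(n, 1, 0.5)
    calc <- obs + rnorm(n, sd = runif(1, 0.01, 2)) + runif(1, -1, 1)
    r <- semicorr:::safe_cor(obs, calc)
    expect_lte(abs(iic(obs, calc)), abs(r) + 1e-12)
  }
})

test_that("target functions follow their stated forms", {
  expect_equal(target_function(0.8, 0.8, variant = "TF0"), 1.6)
  expect_equal(target_function(0.9, 0.7, variant = "TF0"), 1.6 - 0.02)
  expect_equal(target_function(0.9, 0.7, iic_c = 0.5, variant = "TF1"),
               1.58 + 0.15)
  expect_equal(target_function(0.5, 0.9, iic_c = -0.2, variant = "TF1",
                               penalty_coeff = 0.2, iic_coeff = 0.5),
               0.5 + 0.9 - 0.4 * 0.2 - 0.2 * 0.5)
})

test_that("optimization is deterministic and never worsens the target", {
  d <- small_split_data(seed = 3L)
  fit1 <- optimize_weights(d, epochs_N = 2L, seed = 9L, variant = "TF1")
  fit2 <- optimize_weights(d, epochs_N = 2L, seed = 9L, variant = "TF1")
  expect_identical(fit1$model$weight_table$weights,
                   fit2$model$weight_table$weights)
  expect_identical(fit1$history, fit2$history)
  fit3 <- optimize_weights(d, epochs_N = 2L, seed = 10L, variant = "TF1")
  expect_false(identical(fit1$model$weight_table$weights,
                         fit3$model$weight_table$weights))
  # best-so-far target value is non-decreasing across epochs
  expect_true(all(diff(fit1$history$tf) >= 0))
  expect_error(optimize_weights(d, epochs_N = 0L), "epochs_N")
})

test_that("history entries agree with the exported metric functions", {
  d <- small_split_data(seed = 5L)
  fit <- optimize_weights(d, epochs_N = 2L, seed = 4L, variant = "TF1")
  pred <- predict(fit$model, d$smiles, type = "response")
  y <- d$activity
  last <- fit$history[nrow(fit$history), ]
  r_at <- stats::cor(y[d$subset == "A"], pred[d$subset == "A"])^2
  r_pt <- stats::cor(y[d$subset == "P"], pred[d$subset == "P"])^2
  iic_c <- iic(y[d$subset == "C"], pred[d$subset == "C"])
  expect_equal(last$r_at, r_at, tolerance = 1e-10)
  expect_equal(last$r_pt, r_pt, tolerance = 1e-10)
  expect_equal(last$iic, iic_c, tolerance = 1e-10)
  expect_equal(last$tf, target_function(r_at, r_pt, iic_c, "TF1"),
               tolerance = 1e-10)
})

test_that("every non-blocked active-training attribute carries a weight", {
  d <- small_split_data(seed = 6L)
  fit <- optimize_weights(d, threshold_T = 3L, epochs_N = 1L, seed = 2L)
  wt <- fit$model$weight_table
  seen <- unique(unlist(lapply(d$smiles[d$subset == "A"],
                               function(s) unique(smiles_attributes(s)))))
  expect_setequal(names(wt$weights), setdiff(seen, wt$blocked))
  expect_length(intersect(wt$blocked, names(wt$weights)), 0L)
})
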