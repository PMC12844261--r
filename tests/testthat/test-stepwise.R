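test_that("tolerance screen flags collinear pairs and keeps independent ones", {
  # duplicated column: tolerance 0
  set.seed(3)
  x <- rnorm(50)
  comp <- data.frame(id = paste0("c", 1:50), logP = x, MLOGP = x,
                     logS = rnorm(50))
  d <- qsar_data(comp, rnorm(50) + x, rep("train", 50), "logKoc")
  scr <- tolerance_screen(d, c("logP", "MLOGP", "logS"))
  expect_equal(nrow(scr$flagged_pairs), 1L)
  expect_equal(scr$flagged_pairs$tolerance, 0)
  expect_setequal(scr$retained, c(setdiff(c("logP", "MLOGP"),
                                          scr$flagged_pairs$dropped), "logS"))

  # r = 0.96 -> tolerance 1 - 0.96^2 = 0.0784 < 0.1
  blk <- gen_collinear_block(2000, 0.96, seed = 8)
  comp2 <- data.frame(id = paste0("c", 1:2000),
                      logP = blk$x1, logD = blk$x2)
  d2 <- qsar_data(comp2, blk$x1 + rnorm(2000, 0, 0.1),
                  rep("train", 2000), "logKoc")
  scr2 <- tolerance_screen(d2, c("logP", "logD"))
  expect_equal(nrow(scr2$flagged_pairs), 1L)
  expect_equal(scr2$flagged_pairs$tolerance, 1 - cor(blk$x1, blk$x2)^2,
               tolerance = 1e-12)
  # the member more correlated with the response (logP) is kept
  expect_equal(scr2$retained, "logP")

  # independent columns at n = 500: both retained
  set.seed(5)
  comp3 <- data.frame(id = paste0("c", 1:500), logP = rnorm(500),
                      logS = rnorm(500))
  d3 <- qsar_data(comp3, rnorm(500), rep("train", 500), "logKoc")
  scr3 <- tolerance_screen(d3, c("logP", "logS"))
  expect_equal(nrow(scr3$flagged_pairs), 0L)
  expect_setequal(scr3$retained, c("logP", "logS"))
})

test_that("tolerance screen is symmetric and invariant to row order", {
  blk <- gen_collinear_block(300, 0.97, seed = 2)
  comp <- data.frame(id = paste0("c", 1:300), logP = blk$x1, logD = blk$x2,
                     logS = rnorm(300))
  y <- blk$x1 + rnorm(300, 0, 0.5)
  d <- qsar_data(comp, y, rep("train", 300), "logKoc")
  a <- tolerance_screen(d, c("logP", "logD", "logS"))
  b <- tolerance_screen(d, c("logD", "logP", "logS"))
  expect_setequal(a$retained, b$retained)
  perm <- sample(300)
  d2 <- qsar_data(comp[perm, ], y[perm], rep("train", 300), "logKoc")
  c_ <- tolerance_screen(d2, c("logP", "logD", "logS"))
  expect_setequal(a$retained, c_$retained)
  expect_equal(a$flagged_pairs$tolerance, c_$flagged_pairs$tolerance,
               tolerance = 1e-12)
})

test_that("zero-variance candidates are dropped as degenerate with a warning", {
  comp <- data.frame(id = paste0("c", 1:20), logP = rnorm(20), nRot = 5)
  d <- qsar_data(comp, rnorm(20), rep("train", 20), "logKoc")
  expect_warning(scr <- tolerance_screen(d, c("logP", "nRot")), "nRot")
  expect_equal(scr$degenerate, "nRot")
  expect_equal(scr$retained, "logP")
})

test_that("noiseless single-predictor data is recovered exactly", {
  set.seed(11)
  comp <- data.frame(id = paste0("c", 1:40), logP = runif(40, -2, 5),
                     logS = rnorm(40))
  d <- qsar_data(comp, 2 * comp$logP, rep("train", 40), "logKoc")
  fit <- qsar_stepwise(d, c("logP", "logS"))
  expect_equal(names(fit$coefficients), "logP")
  expect_equal(unname(fit$coefficients), 2, tolerance = 1e-10)
  expect_equal(unname(fit$metrics["R2"]), 1, tolerance = 1e-12)
  expect_equal(unname(fit$metrics["Q2"]), 1, tolerance = 1e-10)
})

test_that("stepwise on pure noise stays intercept-only at roughly (1-p)^k", {
  # with 5 independent null candidates at p_enter = 0.05 the chance of
  # entering none is bounded near 0.95^5 ~ 0.77; check >= 0.70 at 200 seeds
  hits <- vapply(1:200, function(s) {
    set.seed(s)
    comp <- data.frame(id = paste0("c", 1:30),
                       nRot = rnorm(30), nHet = rnorm(30), nRing = rnorm(30),
                       logS = rnorm(30), logP = rnorm(30))
    d <- qsar_data(comp, rnorm(30), rep("train", 30), "logKoc")
    fit <- qsar_stepwise(d, c("nRot", "nHet", "nRing", "logS", "logP"))
    length(fit$coefficients) == 0L
  }, logical(1))
  expect_gte(mean(hits), 0.70)
})

test_that("cumulative R2 in the step trace is non-decreasing, R2adj <= R2", {
  d <- gen_reference_dataset(synthetic_config("logBCF", n_train = 200,
                                              n_test = 50, seed = 4))
  fit <- qsar_stepwise(d, default_candidates("logBCF"))
  expect_true(all(diff(fit$step_trace$cum_R2) >= 0))
  expect_lte(fit$metrics[["R2adj"]], fit$metrics[["R2"]])
  expect_gte(fit$metrics[["RMSE_pred"]], 0)
})

test_that("LOO Q2 equals the naive n-refit oracle", {
  for (seed in c(1, 2, 3)) {
    d <- tiny_data(n = 10, seed = seed, noise = 0.3)
    fit <- qsar_stepwise(d, c("MDCK", "TPSA"))
    expect_equal(loo_q2(fit, d), naive_loo_q2(fit, d), tolerance = 1e-10)
  }
  # also on a larger fixture and with an irrelevant candidate available
  d <- tiny_data(n = 50, seed = 7, noise = 1)
  fit <- qsar_stepwise(d, c("MDCK", "TPSA", "nHet"))
  expect_equal(loo_q2(fit, d), naive_loo_q2(fit, d), tolerance = 1e-10)
})

test_that("Q2 is at most slightly below 1 for near-noiseless data and <= 0 for noise", {
  d <- tiny_data(n = 20, seed = 5, noise = 0)
  fit <- qsar_stepwise(d, c("MDCK", "TPSA"))
  expect_equal(unname(fit$metrics["Q2"]), 1, tolerance = 1e-8)
  # response independent of predictors: PRESS >= TSS in expectation
  q2s <- vapply(1:20, function(s) {
    set.seed(s + 100)
    comp <- data.frame(id = paste0("c", 1:25), MDCK = rnorm(25),
                       TPSA = rnorm(25))
    d0 <- qsar_data(comp, rnorm(25), rep("train", 25), "logKpuu")
    m <- qsar_model("logKpuu", 0, c(MDCK = 1, TPSA = 1))
    loo_q2(m, d0)
  }, numeric(1))
  expect_lte(mean(q2s), 0)
})

test_that("RMSE_pred matches hand arithmetic", {
  comp <- data.frame(id = paste0("c", 1:10), MDCK = 1:10 / 2, TPSA = 0)
  y <- 1 + 2 * comp$MDCK
  split <- rep(c("train", "test"), each = 5)
  d <- qsar_data(comp, y, split, "logKpuu")
  m <- qsar_model("logKpuu", 1, c(MDCK = 2))
  expect_equal(rmse_pred(m, d), 0)
  # constant offset of +1 -> RMSE exactly 1
  m_off <- qsar_model("logKpuu", 2, c(MDCK = 2))
  expect_equal(rmse_pred(m_off, d), 1)
  # 5-row hand fixture: errors 0.1, -0.2, 0.3, 0, 0.1
  err <- c(0.1, -0.2, 0.3, 0, 0.1)
  d2 <- qsar_data(comp, y + c(rep(0, 5), err), split, "logKpuu")
  expect_equal(rmse_pred(m, d2), sqrt(mean(err^2)), tolerance = 1e-12)
})

test_that("rank-deficient designs abort with a diagnostic", {
  comp <- data.frame(id = paste0("c", 1:20), logP = rnorm(20))
  comp$MLOGP <- comp$logP          # exact copy
  d <- qsar_data(comp, comp$logP + rnorm(20, 0, 0.01),
                 rep("train", 20), "logKoc")
  expect_error(qsar_stepwise(d, c("logP", "MLOGP")), "rank-deficient")
})
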