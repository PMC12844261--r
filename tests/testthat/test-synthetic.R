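test_that("generated datasets are reproducible and honour configured sizes", {
  cfg <- synthetic_config("logBCF", n_train = 50, n_test = 20,
                          n_validation = 10, seed = 77)
  d1 <- gen_reference_dataset(cfg)
  d2 <- gen_reference_dataset(cfg)
  expect_identical(d1$compounds, d2$compounds)
  expect_identical(d1$response, d2$response)
  expect_identical(d1$split, d2$split)
  expect_equal(as.integer(table(d1$split)[c("train", "test", "validation")]),
               c(50L, 20L, 10L))
  # byte-identical CSV under the same seed
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_compound_table(d1$compounds, p1)
  write_compound_table(d2$compounds, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("noiseless data is exactly identifiable by OLS on the true terms", {
  cfg <- synthetic_config("logKoc", n_train = 100, n_test = 0,
                          noise_sd = 0, seed = 5)
  d <- gen_reference_dataset(cfg)
  fit <- qsar_stepwise(d, names(model_koc()$coefficients))
  expect_equal(fit$coefficients[names(model_koc()$coefficients)],
               model_koc()$coefficients, tolerance = 1e-8)
  expect_equal(fit$intercept, model_koc()$intercept, tolerance = 1e-8)
})

test_that("the realized noise level matches the configured one", {
  cfg <- synthetic_config("logKoc", n_train = 5000, n_test = 0,
                          noise_sd = 0.4, seed = 99)
  d <- gen_reference_dataset(cfg)
  resid <- d$response - predict(model_koc(), d$compounds)
  expect_lt(abs(sd(resid) - 0.4) / 0.4, 0.05)
})

test_that("descriptor marginals stay inside the configured ranges", {
  cfg <- synthetic_config("logKpuu", n_train = 500, n_test = 0, seed = 8)
  d <- gen_reference_dataset(cfg)
  for (nm in names(cfg$ranges)) {
    r <- cfg$ranges[[nm]]
    expect_true(all(d$compounds[[nm]] >= r[1] & d$compounds[[nm]] <= r[2]),
                label = paste("range of", nm))
  }
  # counts are integers
  expect_true(all(d$compounds$nHet == round(d$compounds$nHet)))
  # every generated table validates cleanly
  v <- validate_table(d$compounds, required = names(cfg$ranges))
  expect_true(v$pass)
})

test_that("collinear blocks hit their target correlation", {
  blk <- gen_collinear_block(1000, 0.96, seed = 44)
  expect_lt(abs(cor(blk$x1, blk$x2) - 0.96), 0.03)
  blk0 <- gen_collinear_block(1000, 0, seed = 44)
  expect_lt(abs(cor(blk0$x1, blk0$x2)), 0.1)
  expect_error(gen_collinear_block(1000, 1, seed = 1), "< 1")
  expect_error(gen_collinear_block(5, 0.5, seed = 1), ">= 10")
})

test_that("an injected collinear pair is caught by the tolerance screen", {
  cfg <- synthetic_config("logKoc", n_train = 600, n_test = 0, seed = 21,
                          collinear_spec = list(list(pair = c("logS", "logP"),
                                                     r = 0.985)))
  d <- gen_reference_dataset(cfg)
  scr <- tolerance_screen(d, c("logS", "logP", "nRot"))
  expect_true(nrow(scr$flagged_pairs) >= 1)
  expect_true(all(sort(unlist(scr$flagged_pairs[1, c("a", "b")])) ==
                    c("logP", "logS")))
  # marginals still inside the configured ranges (copula, no clipping)
  expect_true(all(d$compounds$logP >= -2.2 & d$compounds$logP <= 9.9))
  expect_error(synthetic_config("logKoc",
                                collinear_spec = list(list(pair = c("logS", "logP"),
                                                           r = 1))),
               "infeasible")
})

test_that("the synthetic drug panel covers all families and model inputs", {
  panel <- gen_drug_panel(n = 86, seed = 1)
  expect_equal(nrow(panel), 86)
  expect_true(all(table(panel$family) >= 1))
  expect_setequal(unique(panel$family), family_levels())
  needed <- unique(c(names(model_koc()$coefficients),
                     names(model_bcf()$coefficients),
                     names(model_kpuu()$coefficients),
                     names(model_kpuu_lit()$coefficients),
                     "HIA", "caco2", "MW", "MLOGP", "nHA", "nHD"))
  expect_true(all(needed %in% names(panel)))
  expect_true(validate_table(panel, required = needed)$pass)
  expect_identical(panel, gen_drug_panel(n = 86, seed = 1))
  expect_false(identical(panel, gen_drug_panel(n = 86, seed = 2)))
})

test_that("a family logP offset raises that family's predicted log Koc", {
  spec <- list(
    base = list(fraction = 0.5, offsets = c()),
    shifted = list(fraction = 0.5, offsets = c(logP = 2)))
  # family names outside the controlled vocabulary are rejected by
  # validate_table but allowed in the raw generator; use family_summary
  panel <- gen_drug_panel(n = 40, family_spec = spec, seed = 6)
  pred <- predict(model_koc(), panel)
  fs <- family_summary(panel, pred)
  means <- setNames(fs$summary$mean, fs$summary$family)
  expect_gt(means["shifted"], means["base"])
})

test_that("generator functions never disturb the global RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(gen_drug_panel(n = 10, seed = 9))
  invisible(gen_reference_dataset(synthetic_config("logKoc", n_train = 10,
                                                   n_test = 0, seed = 9)))
  expect_identical(.Random.seed, before)
})
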