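test_that("built-in models carry the published coefficients", {
  koc <- model_koc()
  expect_identical(koc$intercept, 0.921)
  expect_identical(koc$coefficients,
                   c(nRot = -0.0441, nHet = 0.0309, nRing = 0.152,
                     PAMPA = -0.272, logS = -0.201, logP = 0.356))
  expect_identical(koc$se,
                   c(nRot = 0.0091, nHet = 0.0109, nRing = 0.029,
                     PAMPA = 0.074, logS = 0.033, logP = 0.034))
  bcf <- model_bcf()
  expect_identical(bcf$intercept, 0.668)
  expect_identical(bcf$coefficients,
                   c(nRot = -0.130, MaxRing = -0.0901, PAMPA = -0.543,
                     logS = -0.251, logD = 0.493))
  kpuu <- model_kpuu()
  expect_identical(kpuu$intercept, 6.81)
  expect_identical(kpuu$coefficients,
                   c(TPSA = -0.0118, nHet = -0.0971, Fsp3 = 0.670,
                     MDCK = 1.31))
  lit <- model_kpuu_lit()
  expect_identical(lit$intercept, 0.866)
  expect_identical(lit$coefficients,
                   c(HeavyAtoms = -0.211, HBD = -0.250, MR = 0.0272,
                     iLOGP = 0.483))
})

test_that("model evaluation is intercept + sum(coef * descriptor)", {
  zeros <- function(vars) as.data.frame(as.list(setNames(rep(0, length(vars)),
                                                         vars)))
  expect_equal(unname(predict(model_koc(),
                              zeros(names(model_koc()$coefficients)))),
               0.921)
  expect_equal(unname(predict(model_kpuu_lit(),
                              zeros(names(model_kpuu_lit()$coefficients)))),
               0.866)
  # term-by-term spreadsheet evaluation:
  # 0.921 - 0.0441*5 + 0.0309*4 + 0.152*2 - 0.272*0.5 - 0.201*(-3) + 0.356*2.5
  d <- data.frame(nRot = 5, nHet = 4, nRing = 2, PAMPA = 0.5,
                  logS = -3, logP = 2.5)
  expect_equal(unname(predict(model_koc(), d)), 2.4851, tolerance = 1e-10)
})

test_that("model evaluation is linear in the descriptors", {
  m <- model_bcf()
  vars <- names(m$coefficients)
  set.seed(1)
  d1 <- setNames(runif(length(vars), -3, 3), vars)
  d2 <- setNames(runif(length(vars), -3, 3), vars)
  at <- function(d) unname(predict(m, as.data.frame(as.list(d))))
  f0 <- at(setNames(rep(0, length(vars)), vars))
  expect_equal(at(d1 + d2) - f0, (at(d1) - f0) + (at(d2) - f0),
               tolerance = 1e-12)
})

test_that("a missing term errors naming the descriptor", {
  d <- data.frame(nRot = 1, nHet = 1, nRing = 1, PAMPA = 0.2, logS = -2)
  expect_error(predict(model_koc(), d), "logP")
  d2 <- data.frame(nRot = 1, nHet = NA, nRing = 1, PAMPA = 0.2,
                   logS = -2, logP = 3, id = "x")
  expect_error(predict(model_koc(), d2), "nHet")
})

test_that("built-in models round-trip through JSON bit-exactly", {
  for (m in list(model_koc(), model_bcf(), model_kpuu(),
                 model_kpuu_lit())) {
    back <- model_from_json(model_to_json(m))
    expect_identical(back$intercept, m$intercept)
    expect_identical(back$coefficients, m$coefficients)
    expect_identical(back$se, m$se)
    expect_identical(back$property, m$property)
  }
  # and through a file
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(model_koc(), path)
  expect_identical(model_from_json(path)$coefficients,
                   model_koc()$coefficients)
})

test_that("apparent permeability follows Papp = (dQ/dt)/(C0*A)", {
  expect_equal(apparent_permeability(0, 0.01, 1), 0)
  expect_equal(apparent_permeability(1e-6, 0.01, 1), 1e-4)
  expect_equal(apparent_permeability(1e-6, 0.01, 2),
               apparent_permeability(1e-6, 0.01, 1) / 2)
  expect_error(apparent_permeability(1e-6, 0, 1), "C0")
  expect_error(apparent_permeability(1e-6, 0.01, -1), "area")
})

test_that("effective permeability follows the PAMPA cell-constant formula", {
  expect_equal(effective_permeability(3e-4, 3e-4, 0.3, 14400, 0), 0)
  # symmetric volumes: C = V / (2 * area * time)
  C_sym <- 3e-4 / (2 * 0.3 * 14400)
  expect_equal(effective_permeability(3e-4, 3e-4, 0.3, 14400, 0.5),
               -C_sym * log(0.5))
  # direct arithmetic oracle: C = 1.5e-4 / (0.3 * 14400)
  expect_equal(effective_permeability(3e-4, 3e-4, 0.3, 14400, 0.5),
               -(1.5e-4 / (0.3 * 14400)) * log(0.5), tolerance = 1e-12)
  expect_error(effective_permeability(3e-4, 3e-4, 0.3, 14400, 1),
               "equilibrium")
  expect_error(effective_permeability(0, 3e-4, 0.3, 14400, 0.5), "positive")
})

test_that("effective permeability is increasing in the acceptor fraction", {
  fr <- seq(0, 0.99, by = 0.01)
  pe <- effective_permeability(3e-4, 3e-4, 0.3, 14400, fr)
  expect_true(all(diff(pe) > 0))
  expect_true(all(pe >= 0))
  # divergence towards equilibrium
  expect_gt(effective_permeability(3e-4, 3e-4, 0.3, 14400, 1 - 1e-12),
            30 * effective_permeability(3e-4, 3e-4, 0.3, 14400, 0.5))
})

test_that("simulate() adds Gaussian noise around the model prediction", {
  d <- gen_drug_panel(n = 20, seed = 2)
  mu <- predict(model_koc(), d)
  sims <- simulate(model_koc(), nsim = 3, seed = 7, newdata = d,
                   noise_sd = 0.4)
  expect_equal(dim(sims), c(20L, 3L))
  expect_false(identical(sims$sim_1, sims$sim_2))
  again <- simulate(model_koc(), nsim = 3, seed = 7, newdata = d,
                    noise_sd = 0.4)
  expect_identical(sims, again)
})
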