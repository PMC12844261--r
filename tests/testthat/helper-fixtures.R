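# Small in-code fixtures shared across the suite.

# A tiny hand-buildable dataset: y = b0 + b1*x1 + b2*x2 (+ noise), all rows
# in the training split unless n_test > 0.
tiny_data <- function(n = 10, seed = 42, b = c(1, 2, -0.5), noise = 0,
                      n_test = 0, property = "logKpuu") {
  set.seed(seed)
  x1 <- runif(n, -2, 2)
  x2 <- runif(n, 0, 5)
  y <- b[1] + b[2] * x1 + b[3] * x2 + rnorm(n, 0, noise)
  compounds <- data.frame(id = paste0("c", seq_len(n)),
                          TPSA = x2 * 40, MDCK = x1 - 5,
                          nHet = sample(0:10, n, TRUE),
                          stringsAsFactors = FALSE)
  # regression is run on MDCK/TPSA; recompute y on those columns
  y <- b[1] + b[2] * compounds$MDCK + b[3] * compounds$TPSA +
    rnorm(n, 0, noise)
  split <- rep("train", n)
  if (n_test > 0) split[sample(n, n_test)] <- "test"
  qsar_data(compounds, y, split, property)
}

# Descriptor vector satisfying every built-in model and classifier input.
full_descriptors <- function() {
  c(nRot = 5, nHet = 4, nRing = 2, MaxRing = 6, PAMPA = 0.5,
    logS = -3, logP = 2.5, logD = 2, TPSA = 80, Fsp3 = 0.4,
    MDCK = -5, caco2 = -4.8, HIA = 95, MW = 350, MLOGP = 2.1,
    nHA = 5, nHD = 2, HeavyAtoms = 25, HBD = 2, MR = 90, iLOGP = 2.2,
    logVDss = 0.5)
}

# Naive leave-one-out Q2: literal n-refit loop, independent of loo_q2().
naive_loo_q2 <- function(model, data) {
  idx <- which(data$split == "train")
  X <- data$compounds[idx, , drop = FALSE]
  y <- unname(data$response[idx])
  vars <- names(model$coefficients)
  press <- 0
  for (i in seq_along(idx)) {
    df <- data.frame(.y = y[-i], X[-i, vars, drop = FALSE],
                     check.names = FALSE)
    form <- if (length(vars))
      as.formula(paste(".y ~", paste(sprintf("`%s`", vars),
                                     collapse = " + ")))
    else as.formula(".y ~ 1")
    f <- lm(form, data = df)
    pred <- unname(predict(f, newdata = X[i, , drop = FALSE]))
    press <- press + (y[i] - pred)^2
  }
  1 - press / sum((y - mean(y))^2)
}
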