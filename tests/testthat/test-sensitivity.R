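test_that("Latin hypercube samples are stratified, log-uniform and reproducible", {
  # one draw per stratum of a log-uniform range
  plan <- mp_plan("p", c(p = 4), lo = c(p = 1), hi = c(p = 16),
                  n_samples = 4, seed = 5)
  x <- sort(lhs_sample(plan)[, 1])
  expect_true(x[1] >= 1 && x[1] < 2)
  expect_true(x[2] >= 2 && x[2] < 4)
  expect_true(x[3] >= 4 && x[3] < 8)
  expect_true(x[4] >= 8 && x[4] <= 16)

  # determinism from the seed
  expect_identical(lhs_sample(plan), lhs_sample(plan))

  # marginal distribution matches log-uniform (KS distance < 0.05 at 5000)
  plan2 <- mp_plan("p", c(p = 1), span = 10, n_samples = 5000, seed = 11)
  draws <- lhs_sample(plan2)[, 1]
  u <- (log(draws) - log(0.1)) / (log(10) - log(0.1))
  ks <- max(abs(sort(u) - (seq_along(u) - 0.5) / length(u)))
  expect_lt(ks, 0.05)

  expect_error(mp_plan("p", c(p = 1), lo = c(p = 2), hi = c(p = 2)),
               "degenerate")
  expect_error(mp_plan(c("a", "b"), c(a = 1, b = 1), n_samples = 3),
               "n_samples")
})

test_that("PRCC matches brute-force residualization and recovers monotone signs", {
  # brute-force oracle: explicit lm() residualization on ranks
  prcc_oracle <- function(X, y) {
    Xr <- apply(X, 2, rank); yr <- rank(y)
    vapply(seq_len(ncol(X)), function(j) {
      df <- data.frame(Xr[, -j, drop = FALSE])
      rj <- residuals(lm(Xr[, j] ~ ., data = df))
      ry <- residuals(lm(yr ~ ., data = df))
      cor(rj, ry)
    }, numeric(1))
  }
  set.seed(3)
  X <- matrix(runif(300), ncol = 3,
              dimnames = list(NULL, c("a", "b", "c")))
  y <- 2 * X[, 1] - X[, 2] + 0.3 * X[, 1] * X[, 3] + rnorm(100, 0, 0.1)
  expect_equal(prcc(X, y)$prcc, prcc_oracle(X, y), tolerance = 1e-10)

  # monotone construction at n = 1000: signs and near +/-1 magnitudes
  set.seed(7)
  X2 <- matrix(runif(3000), ncol = 3,
               dimnames = list(NULL, c("up", "down", "null")))
  y2 <- X2[, 1] - X2[, 2] + rnorm(1000, 0, 0.02)
  res <- prcc(X2, y2)
  expect_gt(res$prcc[res$label == "up"], 0.9)
  expect_lt(res$prcc[res$label == "down"], -0.9)
  expect_lt(abs(res$prcc[res$label == "null"]), 0.05)
  expect_gt(res$p_value[res$label == "null"], 0.05)
  expect_lt(res$p_value[res$label == "up"], 1e-10)
})

test_that("PRCC is rank-invariant, permutation-stable and bounded", {
  set.seed(21)
  X <- matrix(runif(400), ncol = 4,
              dimnames = list(NULL, paste0("x", 1:4)))
  y <- X[, 1]^2 - sqrt(X[, 2]) + rnorm(100, 0, 0.05)
  base <- prcc(X, y)
  # invariance to strictly monotone transforms of the output
  expect_equal(base$prcc, prcc(X, exp(y))$prcc, tolerance = 1e-12)
  # joint row permutation leaves results unchanged
  perm <- sample(nrow(X))
  expect_equal(base$prcc, prcc(X[perm, ], y[perm])$prcc,
               tolerance = 1e-12)
  expect_true(all(abs(base$prcc) <= 1))
  # constant columns are reported as undefined
  Xc <- cbind(X, const = 1)
  expect_true(is.na(prcc(Xc, y)$prcc[5]))
})

test_that("score sensitivity ranks a directly producing rate highest", {
  # cascade where the terminal species is the output: the rates along the
  # chain have known monotone influence
  cas <- make_toy("linear_cascade", size = 3)
  nominal <- setNames(as.numeric(cas$model$parameters),
                      names(cas$model$parameters))
  plan <- mp_plan(c("k2", "d3", "d1"), nominal, n_samples = 60, seed = 13)
  res <- score_sensitivity(cas$model, plan, horizon = 40, t_eval = 40,
                           output = function(sim)
                             sim$mat[nrow(sim$mat), "X3"])
  expect_equal(res$label[1], "k2")       # produces X3 directly
  expect_gt(res$prcc[res$label == "k2"], 0.5)
  expect_lt(res$prcc[res$label == "d3"], -0.5)

  # a parameter the readout cannot reach is insignificant
  iso <- mp_model(
    rbind(mp_species("A", initial = 10), mp_species("B", initial = 5),
          mp_species("Z", initial = 100)),
    list(mp_reaction("sa", products = c(A = 1),
                     kind = "mass_action_irreversible", params = "sA"),
         mp_reaction("da", reactants = c(A = 1),
                     kind = "mass_action_irreversible", params = "dA"),
         mp_reaction("sz", products = c(Z = 1),
                     kind = "mass_action_irreversible", params = "sZ"),
         mp_reaction("dz", reactants = c(Z = 1),
                     kind = "mass_action_irreversible", params = "dZ"),
         mp_reaction("sb", products = c(B = 1),
                     kind = "mass_action_irreversible", params = "sB",
                     modifiers = "A"),
         mp_reaction("db", reactants = c(B = 1),
                     kind = "mass_action_irreversible", params = "dB")),
    mp_parameters(c(sA = 10, dA = 0.5, sZ = 50, dZ = 0.5, sB = 1,
                    dB = 0.4)))
  plan2 <- mp_plan(c("sA", "sZ"),
                   setNames(as.numeric(iso$parameters),
                            names(iso$parameters)),
                   n_samples = 50, seed = 17)
  res2 <- score_sensitivity(iso, plan2, horizon = 60, t_eval = 60,
                            output = function(sim)
                              sim$mat[nrow(sim$mat), "B"])
  expect_gt(res2$p_value[res2$label == "sZ"], 0.05)
  expect_lt(res2$p_value[res2$label == "sA"], 0.05)
})
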