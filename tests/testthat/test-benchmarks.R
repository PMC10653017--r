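test_that("supervised LASSO leaves the surrogate unpenalized", {
  lab <- make_toy_labeled(n = 50, p = 3, seed = 20)
  big <- fit_lasso(lab, lambda_grid = 5, k_folds = 5, seed = 1)
  expect_true(all(big$coefficients$beta == 0))
  ref <- stats::glm(lab$Y ~ lab$S, family = stats::binomial())
  expect_equal(big$coefficients$gamma, unname(coef(ref)[2]),
               tolerance = 1e-6)
  expect_equal(big$coefficients$zeta, unname(coef(ref)[1]),
               tolerance = 1e-6)
})

test_that("supervised LASSO matches the convex oracle on a 30x3 toy", {
  lab <- make_toy_labeled(n = 30, p = 3, seed = 21)
  lam <- 0.08
  fit <- fit_lasso(lab, lambda_grid = lam, k_folds = 5, seed = 2,
                   standardize = FALSE)
  W <- cbind(lab$S, lab$X)
  orc <- oracle_l1_fit(W, lab$Y, lam, c(0, 1, 1, 1), "binomial")
  obj <- passr:::solver_objective(W, lab$Y, fit$coefficients$zeta,
                                  c(fit$coefficients$gamma,
                                    fit$coefficients$beta),
                                  lam, c(0, 1, 1, 1), "binomial")
  expect_lt(abs(obj - orc$objective), 1e-6)
})

test_that("adaptive LASSO uses |init|^-nu weights and handles empty init", {
  lab <- make_toy_labeled(n = 60, p = 4, seed = 22)
  fit <- fit_alasso(lab, k_folds = 5, seed = 3)
  init_beta <- fit$extras$init$coefficients$beta
  expect_equal(fit$extras$weights,
               ifelse(init_beta == 0, Inf, abs(init_beta)^(-1)))
  # ALASSO support within the initial support
  expect_true(all(which(fit$coefficients$beta != 0) %in%
                    which(init_beta != 0)))

  # empty initial model: intercept + S fallback with warning
  set.seed(23)
  X <- matrix(rnorm(200), 50, 4)
  yb <- rbinom(50, 1, 0.5)
  if (length(unique(yb)) < 2) yb[1] <- 1 - yb[1]
  lab0 <- labeled_set(yb, rnorm(50), X)
  expect_warning(f0 <- fit_alasso(lab0, init_lambda_grid = 5,
                                  k_folds = 5, seed = 4),
                 "no features")
  expect_true(all(f0$coefficients$beta == 0))
})

test_that("prior-direction benchmark equals an unpenalized 3-parameter GLM", {
  lab <- make_toy_labeled(n = 80, p = 4, seed = 24)
  sur <- make_surrogate(c(1, -0.6, 0, 0))
  fit <- fit_ss_prior(lab, sur)
  xa <- as.numeric(lab$X %*% sur$alpha)
  ref <- stats::glm(lab$Y ~ lab$S + xa, family = stats::binomial())
  expect_equal(fit$coefficients$zeta, unname(coef(ref)[1]), tolerance = 1e-7)
  expect_equal(fit$coefficients$gamma, unname(coef(ref)[2]), tolerance = 1e-7)
  expect_equal(fit$extras$rho, unname(coef(ref)[3]), tolerance = 1e-7)
  expect_equal(fit$coefficients$beta, fit$extras$rho * sur$alpha)
})

test_that("prior-direction fit shrinks to null under independence", {
  set.seed(25)
  n <- 2000
  X <- matrix(rnorm(n * 3), n, 3)
  lab <- labeled_set(rbinom(n, 1, 0.4), rnorm(n), X)
  fit <- fit_ss_prior(lab, make_surrogate(c(1, 0, 0)))
  expect_lt(abs(fit$coefficients$gamma), 0.1)
  expect_lt(abs(fit$extras$rho), 0.1)
})

test_that("prior LASSO limits: eta = 0 and Yp = Y", {
  lab <- make_toy_labeled(n = 40, p = 3, seed = 26)
  sur <- make_surrogate(c(1, 0.5, 0))
  lam <- 0.06
  # eta = 0: the prior term vanishes -> supervised LASSO at the same lambda
  f0 <- fit_plasso(lab, sur, variant = 2, eta_grid = 0, lambda_grid = lam,
                   k_folds = 5, seed = 5, standardize = FALSE)
  ref <- fit_lasso(lab, lambda_grid = lam, k_folds = 5, seed = 5,
                   standardize = FALSE)
  expect_equal(f0$coefficients$beta, ref$coefficients$beta,
               tolerance = 1e-6)
  # Yp == Y: likelihood rescaling, solution equals LASSO at lambda/(1+eta)
  eta_w <- 2
  f1 <- fit_plasso(lab, sur, variant = 2, eta_grid = eta_w,
                   lambda_grid = lam, k_folds = 5, seed = 5,
                   standardize = FALSE, Yp = lab$Y)
  ref2 <- fit_lasso(lab, lambda_grid = lam / (1 + eta_w), k_folds = 5,
                    seed = 5, standardize = FALSE)
  expect_equal(f1$coefficients$beta, ref2$coefficients$beta,
               tolerance = 1e-3)
})

test_that("prior LASSO matches the stacked convex oracle at fixed (eta, lambda)", {
  lab <- make_toy_labeled(n = 30, p = 3, seed = 27)
  sur <- make_surrogate(c(1, -1, 0))
  lam <- 0.05; eta_w <- 0.5
  fit <- fit_plasso(lab, sur, variant = 2, eta_grid = eta_w,
                    lambda_grid = lam, k_folds = 5, seed = 6,
                    standardize = FALSE)
  W <- cbind(lab$S, lab$X)
  orc <- oracle_plasso_fit(W, lab$Y, fit$extras$Yp, eta_w, lam,
                           c(0, 1, 1, 1))
  cf <- c(fit$coefficients$gamma, fit$coefficients$beta)
  eta_lin <- fit$coefficients$zeta + as.numeric(W %*% cf)
  ll <- function(y, e) pmax(e, 0) - y * e + log1p(exp(-abs(e)))
  yp_lin <- eta_lin
  obj <- mean(ll(lab$Y, eta_lin)) + eta_w * mean(ll(fit$extras$Yp, yp_lin)) +
    lam * sum(abs(cf[-1]))
  expect_lt(abs(obj - orc$objective), 1e-6)
})

test_that("variant-1 prior model penalizes only off-support predictors", {
  lab <- make_toy_labeled(n = 40, p = 4, seed = 28)
  sur <- make_surrogate(c(1, -0.5, 0, 0))
  fit <- fit_plasso(lab, sur, variant = 1, eta_grid = c(0, 1),
                    k_folds = 5, seed = 7)
  expect_s3_class(fit, "benchmark_fit")
  expect_equal(fit$method, "plasso1")
  # infeasible when the support reaches the labeled size
  tiny <- make_toy_labeled(n = 3, p = 4, seed = 29)
  expect_error(fit_plasso(tiny, make_surrogate(c(1, 1, 1, 0.5)),
                          variant = 1, k_folds = 2, seed = 8),
               "infeasible")
})

test_that("unsupervised LASSO thresholds tails and recovers the driver", {
  set.seed(30)
  N <- 600
  X <- matrix(rnorm(N * 4), N, 4)
  S <- 3 * X[, 1]  # tails perfectly separable by X1
  fit <- fit_ulasso(S, X, k_folds = 5, seed = 9)
  expect_equal(fit$extras$cu, unname(stats::quantile(S, 0.9)))
  expect_equal(fit$extras$n_subset, sum(S > fit$extras$cu | S < fit$extras$cl))
  bt <- fit$extras$beta_tilde
  expect_gt(abs(bt[1]), 0)
  expect_true(all(abs(bt[-1]) < abs(bt[1]) / 5))
  expect_error(fit_ulasso(S, X, cu_quantile = 0.1, cl_quantile = 0.9,
                          k_folds = 5, seed = 9))
})

test_that("semi-supervised ULASSO rescales the tail direction by GLM", {
  lab <- make_toy_labeled(n = 80, p = 4, seed = 31)
  set.seed(33)
  pooled_X <- rbind(lab$X, matrix(rnorm(1600), 400, 4))
  pooled_S <- 3 * pooled_X[, 1] + rnorm(480, sd = 0.3)
  uf <- fit_ulasso(pooled_S, pooled_X, k_folds = 5, seed = 10)
  sf <- fit_ss_ulasso(lab, uf)
  bt <- uf$extras$beta_tilde
  expect_gt(sum(bt^2), 0)
  xb <- as.numeric(lab$X %*% bt)
  ref <- stats::glm(lab$Y ~ lab$S + xb, family = stats::binomial())
  expect_equal(sf$coefficients$gamma, unname(coef(ref)[2]), tolerance = 1e-6)
  expect_equal(sf$coefficients$beta, unname(coef(ref)[3]) * bt,
               tolerance = 1e-8)
})

test_that("predictions are probabilities and permutation-equivariant", {
  lab <- make_toy_labeled(n = 50, p = 4, seed = 32)
  fit <- fit_lasso(lab, k_folds = 5, seed = 11)
  pr <- predict(fit, lab$S, lab$X)
  expect_true(all(pr > 0 & pr < 1))

  perm <- c(3, 1, 4, 2)
  lab_p <- labeled_set(lab$Y, lab$S, lab$X[, perm])
  fit_p <- fit_lasso(lab_p, k_folds = 5, seed = 11)
  expect_equal(fit_p$coefficients$beta, fit$coefficients$beta[perm],
               tolerance = 1e-6)
  expect_equal(predict(fit_p, lab$S, lab$X[, perm]), pr, tolerance = 1e-6)
})

test_that("prior LASSO leaves a misleading prior behind (eta near 0)", {
  # overlapping support but orthogonal direction, and a surrogate that
  # carries no direct phenotype signal: the pseudo-labels are uninformative,
  # so CV should usually refuse the prior term
  hits <- 0L; total <- 0L
  for (r in 1:20) {
    set.seed(800 + r)
    n <- 100; p <- 10
    X <- matrix(rnorm(n * p), n, p)
    beta <- c(1.5, -1.2, 0.9, rep(0, p - 3))
    alpha <- c(0.6, 0.75, rep(0, p - 2))  # alpha'beta = 0
    S <- round(pmax(2 * as.numeric(X %*% alpha) + rnorm(n), 0))
    Y <- rbinom(n, 1, plogis(-0.5 + as.numeric(X %*% beta)))
    if (length(unique(Y)) < 2) next
    total <- total + 1L
    lab <- labeled_set(Y, S, X)
    fit <- fit_plasso(lab, make_surrogate(alpha), variant = 2,
                      eta_grid = c(0, 0.25, 0.5, 1, 2, 4),
                      k_folds = 5, seed = r)
    if (fit$extras$eta <= 0.25) hits <- hits + 1L
  }
  expect_gt(hits, total / 2)  # majority of replications
})
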