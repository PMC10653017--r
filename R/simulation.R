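#' Coefficient templates for the main simulation scenarios
#'
#' Six scenarios span the spectrum from a surrogate direction identical to
#' the outcome direction (I) through partial overlap in magnitude or support
#' (II-V) to essentially unrelated directions (VI).  Templates are built from
#' the fixed blocks a1 = (0.5, 1, -0.8, 0.6, 0.2),
#' a2 = (0.1, -0.2, -0.2, 0.2, 0.7), d1 = (-0.05, -0.5, 1.4, 0.5, -0.6),
#' d2 = (0.02, 0.05, 0.02, -0.02, -0.05), zero-padded to length p.
#'
#' @param scenario one of `"I".."VI"`.
#' @param p feature dimension (>= 20; default 500).
#' @return List with `alpha0` and `beta0`, each length p.
#' @export
scenario_coefficients <- function(scenario, p = 500L) {
  if (p < 20L) stop("p must be at least 20 for the coefficient templates")
  a1 <- c(0.5, 1, -0.8, 0.6, 0.2)
  a2 <- c(0.1, -0.2, -0.2, 0.2, 0.7)
  d1 <- c(-0.05, -0.5, 1.4, 0.5, -0.6)
  d2 <- c(0.02, 0.05, 0.02, -0.02, -0.05)
  pad <- function(v) c(v, rep(0, p - length(v)))
  out <- switch(as.character(scenario),
    I   = list(alpha0 = pad(c(a1, a2)), beta0 = 1.5 * pad(c(a1, a2))),
    II  = list(alpha0 = pad(c(a1, a2)), beta0 = 1.5 * pad(c(a1 + d1, a2 + d2))),
    III = list(alpha0 = pad(c(a1, a2, a2, a2)),
               beta0 = 1.5 * pad(c(a1 + d1, a2 + d2))),
    IV  = list(alpha0 = pad(a1), beta0 = 1.5 * pad(c(a1 + d1, a2 + d2))),
    V   = list(alpha0 = pad(c(a1, a2)), beta0 = 1.5 * pad(c(a2, a1))),
    VI  = list(alpha0 = pad(c(a1, a2)),
               beta0 = 1.5 * pad(c(a2, rep(0, 5), a1))),
    stop("unknown scenario: ", scenario))
  out
}

#' Zero-inflated count transform
#'
#' `h(t) = log(1 + [e^t])` where `[u]` is the nearest integer
#' (round-half-to-even at exact halves, as in base R's `round`).  Applied to
#' Gaussian variables it produces the zero-inflated, right-skewed,
#' log-transformed count features typical of EHR data.
#'
#' @param t numeric vector or matrix.
#' @return Same shape, `log(1 + round(exp(t)))`.
#' @export
h_transform <- function(t) {
  out <- log1p(round(exp(t)))
  out
}

#' Specification of a main-scenario simulated study
#'
#' @param scenario `"I".."VI"`.
#' @param n labeled size.
#' @param p feature dimension (default 500).
#' @param N total labeled + unlabeled size (default 10000).
#' @param n_test test-set size (default 10000).
#' @param seed integer RNG seed.
#' @export
main_scenario_spec <- function(scenario, n, p = 500L, N = 10000L,
                               n_test = 10000L, seed) {
  scenario <- as.character(scenario)
  if (!scenario %in% c("I", "II", "III", "IV", "V", "VI"))
    stop("scenario must be one of I..VI")
  stopifnot(p >= 20L, n >= 1L, n < N, n_test >= 1L)
  structure(list(scenario = scenario, n = as.integer(n), p = as.integer(p),
                 N = as.integer(N), n_test = as.integer(n_test),
                 seed = as.integer(seed), kind = "main"),
            class = "scenario_spec")
}

#' Specification of a mis-specification scenario
#'
#' Scenarios i-iii violate the surrogate assumptions to increasing degree:
#' `S = mu*Y + eta1'X + Y*eta2'X + eps`, with (i) mu = 1, eta1 = eta2 = 0
#' (conditional independence holds); (ii) mu = 1.5 and one block of
#' (a3, d3); (iii) mu = 2 and three blocks.  The outcome is a probit-type
#' threshold model, so the logistic phenotype model is itself misspecified
#' and the estimand is the population minimizer of the logistic risk.
#'
#' @inheritParams main_scenario_spec
#' @param scenario `"i"`, `"ii"` or `"iii"`.
#' @param mc_size Monte-Carlo sample size for the oracle-limit coefficients
#'   (>= 1e5).
#' @param mc_seed fixed seed for the oracle-limit computation (shared across
#'   replications so the limit is computed once and cached).
#' @export
misspec_scenario_spec <- function(scenario, n, p = 500L, N = 10000L,
                                  n_test = 10000L, seed, mc_size = 5e5,
                                  mc_seed = 104729L) {
  scenario <- as.character(scenario)
  if (!scenario %in% c("i", "ii", "iii"))
    stop("scenario must be one of i, ii, iii")
  stopifnot(p >= 20L, mc_size >= 1e5)
  a3 <- c(0.6, -0.4, 0.4, 0.5, -0.5)
  d3 <- c(0.3, 0.4, 0.6, -0.5, -0.5)
  pad <- function(v) c(v, rep(0, p - length(v)))
  par <- switch(scenario,
    i   = list(mu = 1,   eta1 = rep(0, p), eta2 = rep(0, p)),
    ii  = list(mu = 1.5, eta1 = pad(a3), eta2 = pad(d3)),
    iii = list(mu = 2,   eta1 = pad(rep(a3, 3)), eta2 = pad(rep(d3, 3))))
  structure(list(scenario = scenario, n = as.integer(n), p = as.integer(p),
                 N = as.integer(N), n_test = as.integer(n_test),
                 seed = as.integer(seed), mu = par$mu, eta1 = par$eta1,
                 eta2 = par$eta2, mc_size = mc_size,
                 mc_seed = as.integer(mc_seed), kind = "misspec"),
            class = "scenario_spec")
}

# AR(1) Gaussian draws by recursion: column j given j-1, marginal sd `sd`,
# lag-1 correlation 0.5.  O(n*p), no p x p factorization needed.
ar1_gaussian <- function(n, p, sd) {
  Z <- matrix(0, n, p)
  Z[, 1L] <- sd * stats::rnorm(n)
  innov_sd <- sd * sqrt(1 - 0.25)
  for (j in seq_len(p)[-1L])
    Z[, j] <- 0.5 * Z[, j - 1L] + innov_sd * stats::rnorm(n)
  Z
}

#' Generate a main-scenario study
#'
#' `Z ~ N(0, Sigma)` with `sigma_ij = 4 * 0.5^|i-j|`; `X = h(Z)` elementwise
#' (zero-inflated log counts); `S = h(1 + X'alpha0 + eps)`,
#' `eps ~ N(0, 2^2)`; `Y ~ Bernoulli(sigma(-4 + 0.5*S + X'beta0))`.  The
#' first `n` generated rows are labeled, the next `N - n` unlabeled, and
#' `n_test` further rows from the same seeded stream form the test set.
#'
#' @param spec a [main_scenario_spec()].
#' @return A `simulated_study`: `labeled`, `unlabeled`, `test` (a
#'   [labeled_set()]), `test_probs` (true event probabilities on the test
#'   set), `truth` (a [model_coefficients()] with zeta = -4, gamma = 0.5),
#'   `alpha0`, and `spec`.
#' @export
generate_main_study <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"), spec$kind == "main")
  cf <- scenario_coefficients(spec$scenario, spec$p)
  total <- spec$N + spec$n_test
  set.seed(spec$seed)
  Z <- ar1_gaussian(total, spec$p, sd = 2)
  X <- h_transform(Z)
  S <- h_transform(1 + as.numeric(X %*% cf$alpha0) + stats::rnorm(total, sd = 2))
  pr <- stats::plogis(-4 + 0.5 * S + as.numeric(X %*% cf$beta0))
  Y <- stats::rbinom(total, 1L, pr)
  assemble_study(spec, X, S, Y, pr,
                 truth = model_coefficients(-4, 0.5, cf$beta0),
                 alpha0 = cf$alpha0)
}

#' Generate a mis-specification-scenario study
#'
#' Two independent AR(1) Gaussian blocks (features 1-20 and 21-p, lag-1
#' correlation 0.5, unit variance) mapped to Uniform(-1, 1) margins via
#' `X = 2*Phi(Z) - 1`; `Y = I((0.8, 1, -1, 0.8, 0.4, 0, ...)'X + eps_y >= 0)`
#' with `eps_y ~ N(0, 1)`; `S = mu*Y + eta1'X + Y*eta2'X + eps_s` with
#' `eps_s ~ N(0, 1)`.  `truth` holds the oracle-limit coefficients (see
#' [oracle_limit_coefficients()]) and `test_probs` the limit-model
#' probabilities on the test set.
#'
#' @param spec a [misspec_scenario_spec()].
#' @return A `simulated_study` (see [generate_main_study()]).
#' @export
generate_misspec_study <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"), spec$kind == "misspec")
  truth <- oracle_limit_coefficients(spec)
  total <- spec$N + spec$n_test
  set.seed(spec$seed)
  X <- misspec_features(total, spec$p)
  ylin <- as.numeric(X[, 1:5] %*% c(0.8, 1, -1, 0.8, 0.4))
  Y <- as.numeric(ylin + stats::rnorm(total) >= 0)
  S <- spec$mu * Y + as.numeric(X %*% spec$eta1) +
    Y * as.numeric(X %*% spec$eta2) + stats::rnorm(total)
  pr <- stats::plogis(truth$zeta + truth$gamma * S +
                        as.numeric(X %*% truth$beta))
  assemble_study(spec, X, S, Y, pr, truth = truth, alpha0 = NULL)
}

misspec_features <- function(n, p) {
  b1 <- min(20L, p)
  Z <- cbind(ar1_gaussian(n, b1, sd = 1),
             if (p > 20L) ar1_gaussian(n, p - 20L, sd = 1))
  2 * stats::pnorm(Z) - 1
}

assemble_study <- function(spec, X, S, Y, pr, truth, alpha0) {
  colnames(X) <- paste0("X", seq_len(ncol(X)))
  il <- seq_len(spec$n)
  iu <- (spec$n + 1L):spec$N
  it <- (spec$N + 1L):(spec$N + spec$n_test)
  structure(list(
    labeled = labeled_set(Y[il], S[il], X[il, , drop = FALSE]),
    unlabeled = unlabeled_set(S[iu], X[iu, , drop = FALSE]),
    test = labeled_set(Y[it], S[it], X[it, , drop = FALSE]),
    test_probs = pr[it],
    truth = truth, alpha0 = alpha0, spec = spec),
    class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf(
    "<simulated_study> scenario %s: n = %d labeled, m = %d unlabeled, %d test, p = %d, prevalence = %.3f\n",
    x$spec$scenario, length(x$labeled$Y), length(x$unlabeled$S),
    length(x$test$Y), ncol(x$labeled$X), mean(x$labeled$Y)))
  invisible(x)
}

#' Pooled surrogate/feature data of a study
#'
#' Stacks the labeled and unlabeled rows (all N observations), the input to
#' [fit_alpha()] and [fit_ulasso()].
#'
#' @param study a `simulated_study`.
#' @return List with `S` (length N) and `X` (N x p).
#' @export
pooled_surrogate_data <- function(study) {
  list(S = c(study$labeled$S, study$unlabeled$S),
       X = rbind(study$labeled$X, study$unlabeled$X))
}

oracle_cache <- new.env(parent = emptyenv())

#' Oracle-limit coefficients under mis-specification
#'
#' The estimand of Scenarios i-iii is the population minimizer of the
#' expected logistic loss `E l(Y, zeta + gamma*S + X'beta)`.  It is
#' approximated by an unpenalized logistic fit of Y on (S, X_1..20) over a
#' fresh Monte-Carlo sample of `mc_size` rows: the block covariance makes
#' features beyond 20 exactly independent of (Y, S, X_1..20), so their limit
#' coefficients are 0 and `beta` is zero-padded to length p.  The result is
#' cached per (scenario, p, mc_size, mc_seed).
#'
#' @param spec a [misspec_scenario_spec()].
#' @param mc_size,seed override the spec's Monte-Carlo size and seed.
#' @return A [model_coefficients()] of length p.
#' @export
oracle_limit_coefficients <- function(spec, mc_size = spec$mc_size,
                                      seed = spec$mc_seed) {
  stopifnot(mc_size >= 1e5)
  key <- paste(spec$scenario, spec$p, mc_size, seed, sep = "_")
  if (!is.null(oracle_cache[[key]])) return(oracle_cache[[key]])
  b1 <- min(20L, spec$p)
  cf <- with_seed(seed, {
    X <- 2 * stats::pnorm(ar1_gaussian(mc_size, b1, sd = 1)) - 1
    ylin <- as.numeric(X[, 1:5] %*% c(0.8, 1, -1, 0.8, 0.4))
    Y <- as.numeric(ylin + stats::rnorm(mc_size) >= 0)
    S <- spec$mu * Y + as.numeric(X %*% spec$eta1[seq_len(b1)]) +
      Y * as.numeric(X %*% spec$eta2[seq_len(b1)]) + stats::rnorm(mc_size)
    fit <- stats::glm.fit(cbind(1, S, X), Y, family = stats::binomial())
    if (!fit$converged)
      stop("oracle-limit logistic fit did not converge; increase mc_size")
    fit$coefficients
  })
  beta <- c(cf[-(1:2)], rep(0, spec$p - b1))
  out <- model_coefficients(cf[1L], cf[2L], beta)
  oracle_cache[[key]] <- out
  out
}

#' Dispatch on the scenario kind
#' @param spec a `scenario_spec` from [main_scenario_spec()] or
#'   [misspec_scenario_spec()].
#' @return A `simulated_study`.
#' @export
generate_study <- function(spec) {
  if (spec$kind == "main") generate_main_study(spec)
  else generate_misspec_study(spec)
}
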