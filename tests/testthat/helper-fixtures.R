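# Small in-code fixtures shared across test files.

# A labeled toy set with a genuine (S, X) -> Y signal.
make_toy_labeled <- function(n = 30L, p = 5L, seed = 1L, beta = NULL,
                             gamma = 0.5, zeta = -0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  if (is.null(beta)) beta <- c(1, -0.8, rep(0, p - 2L))
  S <- pmax(round(as.numeric(X %*% beta) + rnorm(n)), 0)
  pr <- stats::plogis(zeta + gamma * S + as.numeric(X %*% beta))
  Y <- stats::rbinom(n, 1L, pr)
  # guard against a single-class draw in tiny samples
  if (sum(Y) == 0L) Y[which.max(pr)] <- 1L
  if (sum(Y) == n) Y[which.min(pr)] <- 0L
  labeled_set(Y, S, X)
}

# Wrap a fixed direction vector as a (normalized) surrogate fit object.
make_surrogate <- function(alpha, normalize = TRUE) {
  p <- length(alpha)
  w <- ifelse(alpha == 0, Inf, 1 / pmax(abs(alpha), 1e-8))
  fit <- passr:::new_surrogate_fit(tau = 0, alpha = alpha, weights = w,
                                   nu = 1, mu_init = NA_real_, mu = NA_real_,
                                   n_used = NA_integer_, report_init = NULL,
                                   report = NULL)
  if (normalize && sqrt(sum(alpha^2)) > 0) fit <- normalize_direction(fit)
  fit
}

# Evaluate the prior-adaptive objective by explicit term-by-term loops
# (test-side re-implementation, independent of pass_objective).
hand_pass_objective <- function(zeta, gamma, rho, beta, labeled, alpha,
                                lambda1, lambda2) {
  n <- length(labeled$Y)
  tot <- 0
  for (i in seq_len(n)) {
    eta <- zeta + gamma * labeled$S[i] + sum(labeled$X[i, ] * beta)
    tot <- tot + (-labeled$Y[i] * eta + log(1 + exp(eta)))
  }
  A <- which(alpha != 0)
  pen <- 0
  for (j in seq_along(alpha)) {
    d <- beta[j] - rho * alpha[j]
    pen <- pen + if (j %in% A) lambda1 * abs(d) else lambda2 * abs(beta[j])
  }
  tot / n + pen
}
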