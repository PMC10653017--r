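# Independent convex oracle: accelerated proximal gradient (FISTA) with
# adaptive restarts on
#   (1/n_norm) sum_i w_i loss(y_i, b0 + x_i'b) + lambda * sum_j f_j |b_j|
# loss: squared error (gaussian) or logistic NLL; n_norm defaults to the
# number of rows.  Deliberately shares no code with the package's
# glmnet-backed solver.
oracle_l1_fit <- function(X, y, lambda, factors,
                          family = c("gaussian", "binomial"),
                          weights = NULL, n_norm = NULL,
                          max_iter = 200000L, tol = 1e-13) {
  family <- match.arg(family)
  keep <- is.finite(factors)
  Z <- cbind(1, X[, keep, drop = FALSE])
  fk <- c(0, factors[keep])          # intercept unpenalized
  if (is.null(weights)) weights <- rep(1, nrow(Z))
  if (is.null(n_norm)) n_norm <- nrow(Z)
  ll <- function(y, eta) pmax(eta, 0) - y * eta + log1p(exp(-abs(eta)))
  smooth_loss <- function(th) {
    eta <- as.numeric(Z %*% th)
    if (family == "gaussian") sum(weights * (y - eta)^2) / n_norm
    else sum(weights * ll(y, eta)) / n_norm
  }
  smooth_grad <- function(th) {
    eta <- as.numeric(Z %*% th)
    r <- if (family == "gaussian") 2 * (eta - y) else stats::plogis(eta) - y
    as.numeric(crossprod(Z, weights * r)) / n_norm
  }
  objective <- function(th) smooth_loss(th) + lambda * sum(fk * abs(th))
  prox <- function(v, step) sign(v) * pmax(abs(v) - step * lambda * fk, 0)

  L <- max(eigen(crossprod(Z * sqrt(weights)) / n_norm, symmetric = TRUE,
                 only.values = TRUE)$values)
  L <- L * (if (family == "gaussian") 2 else 0.25) + 1e-12
  step <- 1 / L
  th <- rep(0, ncol(Z)); th_prev <- th; t_acc <- 1
  obj_prev <- objective(th)
  for (it in seq_len(max_iter)) {
    t_next <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    v <- th + ((t_acc - 1) / t_next) * (th - th_prev)
    th_prev <- th
    th <- prox(v - step * smooth_grad(v), step)
    t_acc <- t_next
    if (it %% 100L == 0L) {
      obj <- objective(th)
      if (obj > obj_prev) { t_acc <- 1 }  # adaptive restart
      if (abs(obj_prev - obj) < tol) { obj_prev <- obj; break }
      obj_prev <- obj
    }
  }
  coefs <- rep(0, ncol(X)); coefs[keep] <- th[-1L]
  list(intercept = th[1L], coefs = coefs, objective = objective(th))
}

# Oracle for the prior-pseudo-likelihood objective
#   (1/n) sum l(Y, eta) + (eta_w/n) sum l(Yp, eta) + lambda * sum f_j |b_j|
# via stacked rows with weights (1, eta_w) and normalizer n.
oracle_plasso_fit <- function(X, Y, Yp, eta_w, lambda, factors,
                              max_iter = 200000L) {
  n <- length(Y)
  oracle_l1_fit(rbind(X, X), c(Y, Yp), lambda, factors, "binomial",
                weights = c(rep(1, n), rep(eta_w, n)), n_norm = n,
                max_iter = max_iter)
}
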