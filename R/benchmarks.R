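new_benchmark_fit <- function(method, coefficients, extras = list()) {
  structure(list(method = method, coefficients = coefficients,
                 extras = extras),
            class = "benchmark_fit")
}

#' @export
print.benchmark_fit <- function(x, ...) {
  cat(sprintf("<benchmark_fit:%s> |supp(beta)| = %d of %d\n", x$method,
              sum(x$coefficients$beta != 0), length(x$coefficients$beta)))
  invisible(x)
}

#' @export
predict.benchmark_fit <- function(object, S, X, type = c("response", "link"),
                                  ...) {
  type <- match.arg(type)
  cf <- object$coefficients
  eta <- cf$zeta + cf$gamma * S + as.numeric(as.matrix(X) %*% cf$beta)
  if (type == "link") eta else stats::plogis(eta)
}

#' Supervised LASSO benchmark
#'
#' L1-penalized logistic regression of Y on (S, X) using the labeled rows
#' only; the feature coefficients `beta` are penalized while the intercept
#' and the surrogate coefficient are not.  `lambda` is tuned by stratified
#' k-fold CV deviance.
#'
#' @param labeled a [labeled_set()].
#' @param lambda_grid descending grid (`NULL` = default 100-point grid).
#' @param k_folds CV folds.
#' @param seed fold seed (required).
#' @param standardize scale penalized columns to unit SD inside the solver.
#' @return A `benchmark_fit` with method `"lasso"`.
#' @export
fit_lasso <- function(labeled, lambda_grid = NULL, k_folds = 10L, seed,
                      standardize = TRUE) {
  stopifnot(inherits(labeled, "labeled_set"))
  if (length(unique(labeled$Y)) < 2L)
    stop("labeled data must contain both classes")
  W <- cbind(S = labeled$S, labeled$X)
  factors <- c(0, rep(1, ncol(labeled$X)))
  sel <- select_by_cv(W, labeled$Y, factors, lambda_grid = lambda_grid,
                      k_folds = k_folds, seed = seed, family = "binomial",
                      standardize = standardize)
  fit <- fit_l1_logistic(W, labeled$Y, penalty_spec(sel$lambda, factors),
                         standardize = standardize)
  new_benchmark_fit("lasso",
                    model_coefficients(fit$intercept, fit$coefs[1L],
                                       fit$coefs[-1L]),
                    list(lambda = sel$lambda, cv_report = sel,
                         solver_fit = fit))
}

#' Supervised adaptive LASSO benchmark
#'
#' LASSO-initialized adaptive weights `|beta_init_j|^(-nu)` on the feature
#' block only; both stages CV-tuned on the labeled rows.
#'
#' @inheritParams fit_lasso
#' @param nu adaptive-weight exponent.
#' @param init_lambda_grid,lambda_grid grids for the two stages.
#' @return A `benchmark_fit` with method `"alasso"`.
#' @export
fit_alasso <- function(labeled, nu = 1, init_lambda_grid = NULL,
                       lambda_grid = NULL, k_folds = 10L, seed,
                       standardize = TRUE) {
  init <- fit_lasso(labeled, init_lambda_grid, k_folds, seed, standardize)
  b_init <- init$coefficients$beta
  w <- ifelse(b_init == 0, Inf, abs(b_init)^(-nu))
  if (all(!is.finite(w))) {
    warning("initial LASSO selected no features; returning intercept+S model")
    fit <- unpenalized_fit(matrix(labeled$S, ncol = 1L), labeled$Y,
                           rep(1, length(labeled$Y)), "binomial")
    return(new_benchmark_fit("alasso",
                             model_coefficients(fit$intercept, fit$coefs,
                                                rep(0, ncol(labeled$X))),
                             list(weights = w, init = init)))
  }
  W <- cbind(S = labeled$S, labeled$X)
  factors <- c(0, w)
  sel <- select_by_cv(W, labeled$Y, factors, lambda_grid = lambda_grid,
                      k_folds = k_folds, seed = seed, family = "binomial",
                      standardize = standardize)
  fit <- fit_l1_logistic(W, labeled$Y, penalty_spec(sel$lambda, factors),
                         standardize = standardize)
  new_benchmark_fit("alasso",
                    model_coefficients(fit$intercept, fit$coefs[1L],
                                       fit$coefs[-1L]),
                    list(lambda = sel$lambda, weights = w, cv_report = sel,
                         init = init, solver_fit = fit))
}

#' Semi-supervised prior-direction benchmark
#'
#' Valid when features and surrogate are conditionally independent given the
#' phenotype: the feature coefficients then share the surrogate direction, so
#' a 3-parameter unpenalized logistic fit of Y on `(1, S, X'alpha)` over the
#' labeled rows identifies `(zeta, gamma, rho)`, and `beta = rho*alpha`.
#' Separation triggers a small-ridge fallback with a warning.
#'
#' @inheritParams fit_lasso
#' @param surrogate a normalized `surrogate_fit` with nonzero direction.
#' @return A `benchmark_fit` with method `"ssprior"`; `extras$rho` holds the
#'   fitted scale.
#' @export
fit_ss_prior <- function(labeled, surrogate) {
  stopifnot(inherits(labeled, "labeled_set"), inherits(surrogate, "surrogate_fit"))
  if (sqrt(sum(surrogate$alpha^2)) == 0)
    stop("surrogate direction is zero; prior benchmark undefined")
  if (!isTRUE(surrogate$normalized)) surrogate <- normalize_direction(surrogate)
  xa <- as.numeric(labeled$X %*% surrogate$alpha)
  fit <- unpenalized_fit(cbind(labeled$S, xa), labeled$Y,
                         rep(1, length(labeled$Y)), "binomial")
  gamma <- fit$coefs[1L]; rho <- fit$coefs[2L]
  new_benchmark_fit("ssprior",
                    model_coefficients(fit$intercept, gamma,
                                       rho * surrogate$alpha),
                    list(rho = rho, surrogate = surrogate))
}

#' Prior LASSO benchmark (two pseudo-label variants)
#'
#' Builds prior predicted probabilities `Yp` and minimizes
#' `(1/n) sum l(Y_i, eta_i) + (eta/n) sum l(Yp_i, eta_i) + lambda*||beta||_1`
#' over a joint CV-tuned `(eta, lambda)` grid with shared folds.  Variant 1
#' takes `Yp` from a penalized logistic fit of Y on (S, X) in which only
#' predictors outside the surrogate support are L1-penalized (infeasible, and
#' refused, when the support size reaches n); variant 2 takes `Yp` from the
#' [fit_ss_prior()] model.
#'
#' @inheritParams fit_lasso
#' @param surrogate a normalized `surrogate_fit`.
#' @param variant 1 or 2.
#' @param eta_grid candidate prior weights.
#' @param Yp optional externally supplied prior probabilities (overrides the
#'   variant's pseudo-label construction).
#' @return A `benchmark_fit` with method `"plasso1"` or `"plasso2"`;
#'   `extras` record `eta`, `lambda` and the pseudo-labels.
#' @export
fit_plasso <- function(labeled, surrogate, variant = 2,
                       eta_grid = c(0, 0.25, 0.5, 1, 2, 4),
                       lambda_grid = NULL, k_folds = 10L, seed,
                       standardize = TRUE, Yp = NULL) {
  stopifnot(variant %in% c(1, 2))
  if (missing(seed)) stop("a fold seed is required")
  if (!isTRUE(surrogate$normalized) && sqrt(sum(surrogate$alpha^2)) > 0)
    surrogate <- normalize_direction(surrogate)
  Y <- labeled$Y
  n <- length(Y)
  p <- ncol(labeled$X)
  W <- cbind(S = labeled$S, labeled$X)

  if (!is.null(Yp)) {
    stopifnot(length(Yp) == n, all(Yp >= 0 & Yp <= 1))
  } else if (variant == 1) {
    A <- surrogate$support
    if (length(A) >= n)
      stop("prior model of variant 1 is infeasible: |supp(alpha)| >= n")
    prior_factors <- c(0, ifelse(seq_len(p) %in% A, 0, 1))
    psel <- select_by_cv(W, Y, prior_factors, k_folds = k_folds, seed = seed,
                         family = "binomial", standardize = standardize)
    pfit <- fit_l1_logistic(W, Y, penalty_spec(psel$lambda, prior_factors),
                            standardize = standardize)
    Yp <- stats::plogis(pfit$intercept + as.numeric(W %*% pfit$coefs))
  } else {
    prior <- fit_ss_prior(labeled, surrogate)
    Yp <- predict(prior, labeled$S, labeled$X)
  }

  factors <- c(0, rep(1, p))
  if (is.null(lambda_grid))
    lambda_grid <- default_lambda_grid(W, Y, factors, "binomial", standardize)
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)
  fold <- make_folds(Y, k_folds, seed, stratify = TRUE)

  plasso_path <- function(rows, eta, lam) {
    # stacked pseudo-likelihood: rows twice, weights (1, eta); lambda is
    # rescaled by n_rows_used/n_stacked so the target normalization (1/n_tr)
    # on the likelihood block is preserved
    if (eta == 0)
      return(l1_path(W[rows, , drop = FALSE], Y[rows], factors, "binomial",
                     lambda = lam, standardize = standardize))
    Xs <- rbind(W[rows, , drop = FALSE], W[rows, , drop = FALSE])
    ys <- c(Y[rows], Yp[rows])
    ws <- c(rep(1, length(rows)), rep(eta, length(rows)))
    pth <- l1_path(Xs, ys, factors, "binomial", lambda = lam / 2,
                   standardize = standardize, weights = ws)
    pth$lambda <- lam
    pth
  }

  loss_mat <- matrix(NA_real_, length(lambda_grid), length(eta_grid))
  for (ee in seq_along(eta_grid)) {
    tot <- numeric(length(lambda_grid))
    for (fd in seq_len(k_folds)) {
      tr <- which(fold != fd); te <- which(fold == fd)
      path <- plasso_path(tr, eta_grid[ee], lambda_grid)
      eta_lin <- matrix(path$a0, length(te), length(lambda_grid), byrow = TRUE) +
        W[te, , drop = FALSE] %*% path$beta
      tot <- tot + colSums(logistic_loss(Y[te], eta_lin))
    }
    loss_mat[, ee] <- tot / n
  }
  crit <- as.numeric(loss_mat)
  grid_df <- expand.grid(lambda = lambda_grid, eta = eta_grid,
                         KEEP.OUT.ATTRS = FALSE)
  cand <- which(crit <= min(crit) + 1e-12)
  ord <- order(-grid_df$lambda[cand], -grid_df$eta[cand])
  chosen <- cand[ord[1L]]
  lam_star <- grid_df$lambda[chosen]; eta_star <- grid_df$eta[chosen]

  path <- plasso_path(seq_len(n), eta_star, lam_star)
  k <- which(path$lambda == lam_star)
  cf <- path$beta[, k]
  rpt <- new_selection_report(grid_df, crit, chosen, "cv", seed)
  new_benchmark_fit(paste0("plasso", variant),
                    model_coefficients(path$a0[k], cf[1L], cf[-1L]),
                    list(eta = eta_star, lambda = lam_star, Yp = Yp,
                         cv_report = rpt))
}

#' Unsupervised LASSO on surrogate tails
#'
#' Uses extreme surrogate values as pseudo-labels: rows with `S > cu` or
#' `S < cl` (quantile thresholds over all pooled rows) are kept, and
#' `I(S > cu)` is regressed on X by CV-tuned L1 logistic regression.  Only the
#' coefficient direction `beta_tilde` is meaningful; the returned
#' coefficients carry `zeta = gamma = 0`, so predictions rank by
#' `X'beta_tilde` alone.
#'
#' @param S pooled surrogate vector (labeled and unlabeled rows).
#' @param X pooled feature matrix.
#' @param cu_quantile,cl_quantile upper/lower tail quantiles
#'   (defaults 0.9 / 0.1, chosen so the tail probabilities are small).
#' @inheritParams fit_lasso
#' @return A `benchmark_fit` with method `"ulasso"`; `extras` hold `cu`,
#'   `cl` and `beta_tilde`.
#' @export
fit_ulasso <- function(S, X, cu_quantile = 0.9, cl_quantile = 0.1,
                       lambda_grid = NULL, k_folds = 10L, seed,
                       standardize = TRUE) {
  stopifnot(0 < cl_quantile, cl_quantile < cu_quantile, cu_quantile < 1)
  X <- as.matrix(X)
  cu <- stats::quantile(S, cu_quantile, names = FALSE)
  cl <- stats::quantile(S, cl_quantile, names = FALSE)
  sub <- which(S > cu | S < cl)
  if (!length(sub)) stop("empty tail subset; adjust the quantiles")
  yb <- as.numeric(S[sub] > cu)
  if (length(unique(yb)) < 2L)
    stop("tail pseudo-labels are single-class; adjust the quantiles")
  Xs <- X[sub, , drop = FALSE]
  factors <- rep(1, ncol(X))
  sel <- select_by_cv(Xs, yb, factors, lambda_grid = lambda_grid,
                      k_folds = k_folds, seed = seed, family = "binomial",
                      standardize = standardize)
  fit <- fit_l1_logistic(Xs, yb, penalty_spec(sel$lambda, factors),
                         standardize = standardize)
  new_benchmark_fit("ulasso",
                    model_coefficients(0, 0, fit$coefs),
                    list(cu = cu, cl = cl, cu_quantile = cu_quantile,
                         cl_quantile = cl_quantile, beta_tilde = fit$coefs,
                         n_subset = length(sub), lambda = sel$lambda,
                         cv_report = sel))
}

#' Semi-supervised rescaling of the unsupervised LASSO direction
#'
#' Unpenalized logistic fit of the labeled Y on `(1, S, X'beta_tilde)`, as in
#' [fit_ss_prior()] with the tail-based direction replacing the surrogate
#' direction; `beta` is the rescaled `beta_tilde`.
#'
#' @inheritParams fit_lasso
#' @param ulasso_fit a `benchmark_fit` from [fit_ulasso()].
#' @return A `benchmark_fit` with method `"ssulasso"`.
#' @export
fit_ss_ulasso <- function(labeled, ulasso_fit) {
  stopifnot(inherits(labeled, "labeled_set"),
            identical(ulasso_fit$method, "ulasso"))
  bt <- ulasso_fit$extras$beta_tilde
  if (sqrt(sum(bt^2)) == 0)
    stop("unsupervised direction is zero; semi-supervised rescaling undefined")
  xb <- as.numeric(labeled$X %*% bt)
  fit <- unpenalized_fit(cbind(labeled$S, xb), labeled$Y,
                         rep(1, length(labeled$Y)), "binomial")
  gamma <- fit$coefs[1L]; rho <- fit$coefs[2L]
  new_benchmark_fit("ssulasso",
                    model_coefficients(fit$intercept, gamma, rho * bt),
                    list(rho = rho, beta_tilde = bt))
}
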