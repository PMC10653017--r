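#' Augmented design for the prior-adaptive estimator
#'
#' The re-parametrized problem is an ordinary weighted-L1 logistic regression
#' with covariates `(S, X'alpha, X_1, ..., X_p)` and parameters
#' `(gamma, rho, delta)`: writing `delta = beta - rho*alpha`, the penalty
#' `lambda1*||delta_A||_1 + lambda2*||delta_{A^c}||_1` (A = supp(alpha))
#' becomes a per-coefficient factor vector.  `S` and `X'alpha` are
#' unpenalized (factor 0); features in A get factor 1; features outside A get
#' the placeholder `NA`, filled with `kappa = lambda2/lambda1` at fit time.
#' A zero surrogate direction drops the `X'alpha` column (flagged), and the
#' estimator degrades to a supervised LASSO.
#'
#' @param labeled a [labeled_set()].
#' @param surrogate a `surrogate_fit` (normalized).
#' @return List with `design` (n x (2+p) or n x (1+p) matrix),
#'   `factor_template` (0/1/NA vector), `has_rho` flag.
#' @export
build_augmented_design <- function(labeled, surrogate) {
  stopifnot(inherits(labeled, "labeled_set"), inherits(surrogate, "surrogate_fit"))
  p <- ncol(labeled$X)
  if (length(surrogate$alpha) != p)
    stop("feature dimension mismatch between labeled data and surrogate fit")
  on_support <- seq_len(p) %in% surrogate$support
  xfac <- ifelse(on_support, 1, NA_real_)
  if (length(surrogate$support) == 0L) {
    design <- cbind(S = labeled$S, labeled$X)
    return(list(design = design, factor_template = c(0, xfac),
                has_rho = FALSE))
  }
  xa <- as.numeric(labeled$X %*% surrogate$alpha)
  design <- cbind(S = labeled$S, XA = xa, labeled$X)
  list(design = design, factor_template = c(0, 0, xfac), has_rho = TRUE)
}

#' Prior adaptive semi-supervised (PASS) estimator
#'
#' Fits the high-dimensional logistic phenotype model
#' `logit Pr(Y=1|S,X) = zeta + gamma*S + X'beta` on the labeled data while
#' shrinking `beta` toward a scalar multiple `rho*alpha` of the surrogate's
#' single-index direction: the penalty is
#' `lambda1*||(beta - rho*alpha)_A||_1 + lambda2*||beta_{A^c}||_1` with
#' `A = supp(alpha)` and `lambda2 = kappa*lambda1`.  `(zeta, gamma, rho)` are
#' unpenalized.  `(lambda1, kappa)` are chosen by stratified k-fold CV on the
#' held-out deviance (exhaustive over the 2-D grid, shared folds), then the
#' model is refit on all labeled rows; `beta = delta + rho*alpha`.
#'
#' @param labeled a [labeled_set()] with both classes present.
#' @param surrogate a `surrogate_fit`; normalized to unit norm first if not
#'   already (see [normalize_direction()]).
#' @param lambda1_grid descending lambda1 grid (`NULL` = 100 log-spaced
#'   points from the largest per-kappa lambda_max down to 1% of it).
#' @param kappa_grid candidate ratios `lambda2/lambda1`.
#' @param k_folds CV folds (default 10).
#' @param seed integer fold seed (required).
#' @param loss CV loss, `"deviance"` (default) or `"auc"`.
#' @param standardize scale penalized columns to unit SD inside the solver.
#' @return A `pass_fit` with `zeta`, `gamma`, `rho`, `delta`, `beta`
#'   (= `delta + rho*alpha`), selected `lambda1`, `kappa`, the consumed
#'   `surrogate`, and the CV `cv_report`.
#' @export
fit_pass <- function(labeled, surrogate, lambda1_grid = NULL,
                     kappa_grid = c(0.25, 0.5, 1, 2, 4), k_folds = 10L,
                     seed, loss = "deviance", standardize = TRUE) {
  stopifnot(inherits(labeled, "labeled_set"))
  if (missing(seed)) stop("a fold seed is required")
  if (length(unique(labeled$Y)) < 2L)
    stop("labeled data must contain both classes")
  if (!isTRUE(surrogate$normalized) && sqrt(sum(surrogate$alpha^2)) > 0)
    surrogate <- normalize_direction(surrogate)
  aug <- build_augmented_design(labeled, surrogate)

  sel <- select_by_cv(aug$design, labeled$Y, aug$factor_template,
                      lambda_grid = lambda1_grid, kappa_grid = kappa_grid,
                      k_folds = k_folds, seed = seed, family = "binomial",
                      loss = loss, standardize = standardize)
  refit_pass(labeled, surrogate, aug, sel$lambda, sel$kappa,
             standardize = standardize, cv_report = sel)
}

#' Fit the prior-adaptive model at fixed penalties
#'
#' Same model as [fit_pass()] but at user-fixed `(lambda1, kappa)`, without
#' cross-validation.  Used by the tuning loop, the algebraic-equivalence
#' tests, and the degenerate-limit cross-checks.
#'
#' @inheritParams fit_pass
#' @param lambda1 penalty level on the support block.
#' @param kappa ratio `lambda2/lambda1`.
#' @param thresh solver convergence threshold.
#' @export
fit_pass_fixed <- function(labeled, surrogate, lambda1, kappa,
                           standardize = TRUE, thresh = 1e-10) {
  if (!isTRUE(surrogate$normalized) && sqrt(sum(surrogate$alpha^2)) > 0)
    surrogate <- normalize_direction(surrogate)
  aug <- build_augmented_design(labeled, surrogate)
  refit_pass(labeled, surrogate, aug, lambda1, kappa,
             standardize = standardize, cv_report = NULL, thresh = thresh)
}

refit_pass <- function(labeled, surrogate, aug, lambda1, kappa, standardize,
                       cv_report, thresh = 1e-10) {
  p <- ncol(labeled$X)
  factors <- aug$factor_template
  factors[is.na(factors)] <- kappa
  fit <- fit_l1_logistic(aug$design, labeled$Y, penalty_spec(lambda1, factors),
                         standardize = standardize, thresh = thresh)
  if (aug$has_rho) {
    gamma <- fit$coefs[1L]; rho <- fit$coefs[2L]
    delta <- fit$coefs[-(1:2)]
  } else {
    gamma <- fit$coefs[1L]; rho <- 0
    delta <- fit$coefs[-1L]
  }
  beta <- delta + rho * surrogate$alpha
  structure(list(zeta = fit$intercept, gamma = gamma, rho = rho,
                 delta = delta, beta = beta,
                 lambda1 = lambda1, kappa = kappa, lambda2 = kappa * lambda1,
                 surrogate = surrogate, cv_report = cv_report,
                 solver_fit = fit,
                 coefficients = model_coefficients(fit$intercept, gamma, beta)),
            class = "pass_fit")
}

#' @export
print.pass_fit <- function(x, ...) {
  cat(sprintf(
    "<pass_fit> lambda1 = %.4g, kappa = %.3g, rho = %.4g, |supp(beta)| = %d of %d\n",
    x$lambda1, x$kappa, x$rho, sum(x$beta != 0), length(x$beta)))
  invisible(x)
}

#' Predicted phenotype probabilities
#'
#' `sigma(zeta + gamma*S + X'beta)` elementwise.
#'
#' @param fit a `pass_fit`.
#' @param S surrogate vector.
#' @param X feature matrix with `length(fit$beta)` columns.
#' @param type `"response"` for probabilities, `"link"` for linear scores.
#' @export
predict_pass <- function(fit, S, X, type = c("response", "link")) {
  type <- match.arg(type)
  X <- as.matrix(X)
  if (ncol(X) != length(fit$beta)) stop("feature dimension mismatch")
  if (length(S) != nrow(X)) stop("S and X must have matching rows")
  eta <- fit$zeta + fit$gamma * S + as.numeric(X %*% fit$beta)
  if (type == "link") eta else stats::plogis(eta)
}

#' @export
predict.pass_fit <- function(object, S, X, type = c("response", "link"), ...) {
  predict_pass(object, S, X, type = match.arg(type))
}

#' Penalized objective of the prior-adaptive estimator
#'
#' Evaluates `(1/n) sum l(Y_i, zeta + gamma*S_i + X_i'beta)
#' + lambda1*||(beta - rho*alpha)_A||_1 + lambda2*||beta_{A^c}||_1` at given
#' parameter values; used by the algebraic-equivalence tests.
#'
#' @param params list with `zeta`, `gamma`, `rho`, `beta`.
#' @param labeled a [labeled_set()].
#' @param surrogate a `surrogate_fit` providing `alpha` and its support.
#' @param lambda1,lambda2 penalty levels on and off the support.
#' @export
pass_objective <- function(params, labeled, surrogate, lambda1, lambda2) {
  a <- surrogate$alpha
  A <- surrogate$support
  eta <- params$zeta + params$gamma * labeled$S +
    as.numeric(labeled$X %*% params$beta)
  d <- params$beta - params$rho * a
  pen <- lambda1 * sum(abs(d[A])) +
    lambda2 * sum(abs(params$beta[setdiff(seq_along(a), A)]))
  mean(logistic_loss(labeled$Y, eta)) + pen
}

#' Serialize a pass_fit to JSON (sparse coefficients)
#' @param fit a `pass_fit`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @export
pass_to_json <- function(fit, path = NULL) {
  nz <- which(fit$beta != 0)
  obj <- list(zeta = fit$zeta, gamma = fit$gamma, rho = fit$rho,
              lambda1 = fit$lambda1, kappa = fit$kappa,
              p = length(fit$beta),
              beta = list(index = nz, value = fit$beta[nz]),
              alpha = list(index = fit$surrogate$support,
                           value = fit$surrogate$alpha[fit$surrogate$support]))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
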