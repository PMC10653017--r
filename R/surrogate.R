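#' Estimate the surrogate's single-index direction
#'
#' Under a single-index model the surrogate S depends on the features only
#' through one linear combination `X'alpha`, whose direction can be recovered
#' by least squares of S on X over all N rows (labeled and unlabeled pooled).
#' The estimator is a LASSO-initialized adaptive LASSO: an initial L1 least
#' squares fit (penalty `mu_init`, BIC-selected) supplies weights
#' `w_j = |alpha_init_j|^(-nu)`; features with a zero initial coefficient are
#' excluded (infinite weight), and the weighted fit's penalty `mu` is again
#' BIC-selected.  BIC is used rather than CV because N is large.
#'
#' @param S numeric surrogate vector over the pooled data, length N.
#' @param X numeric feature matrix, N x p.
#' @param nu adaptive-weight exponent (default 1).
#' @param mu_init_grid,mu_grid descending penalty grids (`NULL` = default
#'   100-point log grid from lambda_max down to 0.001*lambda_max).
#' @param standardize passed to the solver.
#' @return A `surrogate_fit` with `tau` (intercept), `alpha`, `support`,
#'   `weights`, `nu`, `mu_init`, `mu`, `n_used`, `normalized`, and the two
#'   BIC selection reports.
#' @export
fit_alpha <- function(S, X, nu = 1, mu_init_grid = NULL, mu_grid = NULL,
                      standardize = TRUE) {
  X <- as.matrix(X)
  S <- as.numeric(S)
  N <- nrow(X); p <- ncol(X)
  stopifnot(length(S) == N, N >= 2L, nu > 0)

  ones <- rep(1, p)
  if (is.null(mu_init_grid))
    mu_init_grid <- default_lambda_grid(X, S, ones, "gaussian", standardize)
  sel_init <- select_by_bic(X, S, ones, mu_init_grid, "gaussian", standardize)
  a_init <- sel_init$coefs

  w <- ifelse(a_init == 0, Inf, abs(a_init)^(-nu))
  if (all(!is.finite(w))) {
    warning("initial LASSO selected no features; surrogate direction is 0 ",
            "and downstream prior-adaptive fits degrade to supervised LASSO")
    return(new_surrogate_fit(sel_init$intercept, rep(0, p), w, nu,
                             sel_init$lambda, NA_real_, N,
                             sel_init, NULL, colnames(X)))
  }
  if (is.null(mu_grid))
    mu_grid <- default_lambda_grid(X, S, w, "gaussian", standardize)
  sel <- select_by_bic(X, S, w, mu_grid, "gaussian", standardize)
  new_surrogate_fit(sel$intercept, sel$coefs, w, nu, sel_init$lambda,
                    sel$lambda, N, sel_init, sel, colnames(X))
}

new_surrogate_fit <- function(tau, alpha, weights, nu, mu_init, mu, n_used,
                              report_init, report, feature_names = NULL) {
  structure(list(tau = tau, alpha = alpha, support = which(alpha != 0),
                 weights = weights, nu = nu, mu_init = mu_init, mu = mu,
                 n_used = n_used, normalized = FALSE,
                 report_init = report_init, report = report,
                 feature_names = feature_names),
            class = "surrogate_fit")
}

#' @export
print.surrogate_fit <- function(x, ...) {
  cat(sprintf(
    "<surrogate_fit> N = %d, |support| = %d of %d, nu = %g%s\n",
    x$n_used, length(x$support), length(x$alpha), x$nu,
    if (x$normalized) ", unit-norm" else ""))
  invisible(x)
}

#' Normalize a surrogate direction to unit length
#'
#' Only the direction of the single-index coefficient is identifiable, so the
#' estimate is rescaled to unit L2 norm (with the first nonzero coordinate
#' made positive, fixing the sign of the downstream scale parameter rho).
#' Applied before the prior-adaptive fit so the lambda grids are comparable
#' across datasets; the zero direction passes through with a flag.
#'
#' @param fit a `surrogate_fit`.
#' @return The fit with `alpha` rescaled and `normalized = TRUE`.
#' @export
normalize_direction <- function(fit) {
  stopifnot(inherits(fit, "surrogate_fit"))
  nrm <- sqrt(sum(fit$alpha^2))
  if (nrm == 0) {
    fit$normalized <- FALSE
    attr(fit, "zero_direction") <- TRUE
    return(fit)
  }
  a <- fit$alpha / nrm
  j1 <- which(a != 0)[1L]
  if (a[j1] < 0) a <- -a
  fit$alpha <- a
  fit$support <- which(a != 0)
  fit$normalized <- TRUE
  fit
}

#' Serialize a surrogate fit to JSON (sparse coefficients)
#' @param fit a `surrogate_fit`.
#' @param path optional output file; if `NULL` the JSON string is returned.
#' @export
surrogate_to_json <- function(fit, path = NULL) {
  obj <- list(tau = fit$tau, nu = fit$nu, mu_init = fit$mu_init, mu = fit$mu,
              n_used = fit$n_used, normalized = fit$normalized,
              p = length(fit$alpha),
              alpha = list(index = fit$support,
                           value = fit$alpha[fit$support]))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
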