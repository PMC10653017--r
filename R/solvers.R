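#' Weighted-L1 penalty specification
#'
#' One global penalty level `lambda` plus per-coefficient `factors`: a factor
#' of 0 leaves a coefficient unpenalized, `Inf` excludes it from the model,
#' and intermediate values rescale the penalty coefficient-wise (adaptive
#' LASSO weights, or the on/off-support levels of the prior-adaptive
#' estimator).
#'
#' @param lambda nonnegative global penalty level.
#' @param factors nonnegative vector, one entry per non-intercept coefficient.
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(lambda, factors) {
  stopifnot(length(lambda) == 1L, lambda >= 0, all(factors >= 0))
  structure(list(lambda = as.numeric(lambda), factors = as.numeric(factors)),
            class = "penalty_spec")
}

# Evaluate expr with a private RNG stream; the caller's stream is untouched.
with_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

# Fold assignment: seeded permutation, stratified by y for the binomial
# family so every fold sees both classes whenever the minority class has at
# least k members.
make_folds <- function(y, k, seed, stratify = TRUE) {
  n <- length(y)
  if (k < 2L) stop("k_folds must be >= 2")
  if (k > n) stop("more folds than observations")
  with_seed(seed, {
    fold <- integer(n)
    if (stratify) {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      fold[sample.int(n)] <- rep_len(seq_len(k), n)
    }
    fold
  })
}

logistic_loss <- function(y, eta) {
  # -y*eta + log(1+exp(eta)), numerically stable for large |eta|
  pmax(eta, 0) - y * eta + log1p(exp(-abs(eta)))
}

# Core path fitter.  Objective (per spec contract, on the working scale):
#   gaussian: (1/n) sum w_i (y_i - b0 - x_i'b)^2 + lambda * sum f_j |b_j|
#   binomial: (1/n) sum w_i l(y_i, b0 + x_i'b) + lambda * sum f_j |b_j|
# glmnet conventions compensated: gaussian factor 1/2, weights normalized by
# sum(w), penalty.factor rescaled to sum to nvars.  Per-coefficient factors
# are applied by column rescaling; standardization scales penalized columns
# to unit sample SD (equivalently multiplies factor j by sd_j).
l1_path <- function(X, y, factors, family = c("gaussian", "binomial"),
                    lambda = NULL, nlambda = 100L, lambda_min_ratio = NULL,
                    standardize = TRUE, weights = NULL, thresh = 1e-10,
                    maxit = 5e5) {
  family <- match.arg(family)
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, length(factors) == p)
  if (anyNA(X) || anyNA(y) || any(!is.finite(X)))
    stop("non-finite values in the design or response")
  if (is.null(weights)) weights <- rep(1, n)
  if (is.null(lambda_min_ratio))
    lambda_min_ratio <- if (family == "gaussian") 0.001 else 0.01

  sds <- apply(X, 2L, stats::sd)
  keep <- is.finite(factors) & sds > 1e-12  # constant cols: collinear w/ intercept
  d <- rep(1, p)
  pen <- factors > 0 & keep
  d[pen] <- factors[pen] * (if (standardize) sds[pen] else 1)
  f_eff <- rep(Inf, p)
  f_eff[keep & factors == 0] <- 0
  f_eff[pen] <- d[pen]

  null_mu <- stats::weighted.mean(y, weights)
  grad_null <- function(cols) {
    r <- weights * (y - null_mu)
    g <- abs(as.numeric(crossprod(X[, cols, drop = FALSE] /
                                    rep(d[cols], each = n), r))) / n
    if (family == "gaussian") 2 * g else g
  }
  lmax <- if (any(pen)) max(grad_null(which(pen))) else NA_real_

  if (is.null(lambda)) {
    if (!any(pen)) stop("no penalized coefficients; supply lambda explicitly")
    lambda <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                      length.out = nlambda))
  }
  lambda <- sort(unique(as.numeric(lambda)), decreasing = TRUE)
  nlam <- length(lambda)

  beta <- matrix(0, p, nlam)
  a0 <- numeric(nlam)

  if (!any(pen)) {
    # fully unpenalized: single (possibly guarded) fit replicated on the grid
    fit <- unpenalized_fit(X[, keep, drop = FALSE], y, weights, family)
    a0[] <- fit$intercept
    beta[keep, ] <- fit$coefs
  } else {
    Xs <- X[, keep, drop = FALSE] / rep(d[keep], each = n)
    pf <- as.numeric(factors[keep] > 0)
    if (ncol(Xs) == 1L) { # glmnet needs >= 2 columns
      Xs <- cbind(Xs, 0); pf <- c(pf, 1)
    }
    # glmnet normalizes the weighted loss by sum(w); ours is (1/n)*sum(w_i l_i)
    conv <- (if (family == "gaussian") 0.5 else 1) * n / sum(weights)
    lam_g <- lambda * conv * sum(pf) / ncol(Xs)
    # two-column response lets binomial y be fractional (pseudo-labels)
    yg <- if (family == "binomial") cbind(1 - y, y) else y
    g <- glmnet::glmnet(Xs, yg, family = family, weights = weights,
                        lambda = lam_g, standardize = FALSE,
                        penalty.factor = pf, thresh = thresh, maxit = maxit)
    cf <- as.matrix(stats::coef(g, s = lam_g, exact = FALSE))
    a0 <- cf[1L, ]
    bkeep <- cf[-1L, , drop = FALSE][seq_len(sum(keep)), , drop = FALSE]
    beta[keep, ] <- bkeep / d[keep]
  }

  structure(list(lambda = lambda, a0 = a0, beta = beta, family = family,
                 factors = factors, f_eff = f_eff, keep = keep,
                 standardize = standardize, weights = weights,
                 lambda_max = lmax),
            class = "l1_path")
}

# Unpenalized GLM/LS fit with a divergence guard for logistic separation.
unpenalized_fit <- function(X, y, weights, family) {
  n <- length(y)
  if (ncol(X) == 0L) {
    mu <- stats::weighted.mean(y, weights)
    b0 <- if (family == "gaussian") mu else stats::qlogis(min(max(mu, 1e-12), 1 - 1e-12))
    return(list(intercept = b0, coefs = numeric(0)))
  }
  if (family == "gaussian") {
    fit <- stats::lm.wfit(cbind(1, X), y, weights)
    cf <- unname(ifelse(is.na(fit$coefficients), 0, fit$coefficients))
    return(list(intercept = cf[1L], coefs = cf[-1L]))
  }
  fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y, weights = weights,
                                         family = stats::binomial()))
  cf <- unname(ifelse(is.na(fit$coefficients), 0, fit$coefficients))
  if (!fit$converged || max(abs(cf)) > 1e3) {
    warning("possible separation in unpenalized logistic fit; ",
            "applying a small ridge to cap the coefficient norm")
    Xr <- if (ncol(X) == 1L) cbind(X, 0) else X
    g <- glmnet::glmnet(Xr, y, family = "binomial", weights = weights,
                        alpha = 0, lambda = c(1, 0.1, 1e-3),
                        standardize = FALSE, thresh = 1e-10)
    cr <- as.numeric(stats::coef(g, s = 1e-3))
    cf <- c(cr[1L], cr[1L + seq_len(ncol(X))])
  }
  list(intercept = cf[1L], coefs = cf[-1L])
}

solver_objective <- function(X, y, intercept, coefs, lambda, f_eff, family,
                             weights = NULL) {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  eta <- intercept + as.numeric(X %*% coefs)
  loss <- if (family == "gaussian") sum(weights * (y - eta)^2) / n
          else sum(weights * logistic_loss(y, eta)) / n
  pen_f <- ifelse(coefs == 0, 0, f_eff)  # excluded coefs are 0; 0*Inf guard
  loss + lambda * sum(pen_f * abs(coefs))
}

solver_kkt <- function(X, y, intercept, coefs, lambda, f_eff, family,
                       weights = NULL) {
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  eta <- intercept + as.numeric(X %*% coefs)
  mu <- if (family == "gaussian") eta else 1 / (1 + exp(-eta))
  scale <- if (family == "gaussian") 2 else 1
  g <- -scale * as.numeric(crossprod(X, weights * (y - mu))) / n
  viol <- abs(sum(weights * (y - mu)) / n)  # intercept stationarity
  for (j in seq_along(coefs)) {
    if (!is.finite(f_eff[j])) next
    lamj <- lambda * f_eff[j]
    v <- if (coefs[j] != 0) abs(g[j] + lamj * sign(coefs[j]))
         else max(0, abs(g[j]) - lamj)
    viol <- max(viol, v)
  }
  viol
}

make_solver_fit <- function(X, y, intercept, coefs, lambda, f_eff, family,
                            weights = NULL, kkt_tol = 1e-4) {
  obj <- solver_objective(X, y, intercept, coefs, lambda, f_eff, family, weights)
  kkt <- solver_kkt(X, y, intercept, coefs, lambda, f_eff, family, weights)
  structure(list(intercept = unname(intercept), coefs = unname(coefs),
                 objective = obj, converged = kkt <= kkt_tol,
                 kkt_violation = kkt, lambda = lambda, family = family),
            class = "solver_fit")
}

#' Weighted-L1 penalized least squares
#'
#' Minimizes `(1/n) sum (y - b0 - x'b)^2 + lambda * sum f_j |b_j|` with the
#' intercept always unpenalized.  With `standardize = TRUE` (default),
#' penalized columns are scaled to unit sample SD before fitting, which
#' multiplies factor j by the column SD in the objective; coefficients are
#' returned on the original scale.
#'
#' @param X design matrix (no intercept column).
#' @param y numeric response.
#' @param penalty a [penalty_spec()].
#' @param standardize scale penalized columns to unit SD first?
#' @param thresh solver convergence threshold.
#' @return A `solver_fit` with `intercept`, `coefs`, `objective`,
#'   `converged`, `kkt_violation`.
#' @export
fit_l1_linear <- function(X, y, penalty, standardize = TRUE, thresh = 1e-10) {
  fit_l1(X, y, penalty, "gaussian", standardize, thresh)
}

#' Weighted-L1 penalized logistic regression
#'
#' Minimizes `(1/n) sum l(y, b0 + x'b) + lambda * sum f_j |b_j|` with
#' `l(y, eta) = -y*eta + log(1 + exp(eta))`.  See [fit_l1_linear()] for the
#' standardization and penalty-factor conventions.
#'
#' @inheritParams fit_l1_linear
#' @param y binary 0/1 response with both classes present.
#' @export
fit_l1_logistic <- function(X, y, penalty, standardize = TRUE, thresh = 1e-10) {
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L)
    stop("y contains a single class; logistic fit undefined")
  fit_l1(X, y, penalty, "binomial", standardize, thresh)
}

fit_l1 <- function(X, y, penalty, family, standardize, thresh) {
  stopifnot(inherits(penalty, "penalty_spec"))
  X <- as.matrix(X)
  p <- ncol(X)
  stopifnot(length(penalty$factors) == p)
  if (all(is.infinite(penalty$factors)) && penalty$lambda > 0) {
    fit <- unpenalized_fit(X[, 0, drop = FALSE], y, rep(1, nrow(X)), family)
    return(make_solver_fit(X, y, fit$intercept, rep(0, p), penalty$lambda,
                           rep(Inf, p), family))
  }
  if (penalty$lambda == 0 || all(penalty$factors == 0)) {
    keep <- penalty$factors < Inf
    fit <- unpenalized_fit(X[, keep, drop = FALSE], y, rep(1, nrow(X)), family)
    coefs <- rep(0, p); coefs[keep] <- fit$coefs
    f_eff <- ifelse(keep, 0, Inf)
    return(make_solver_fit(X, y, fit$intercept, coefs, penalty$lambda,
                           f_eff, family))
  }
  # dense geometric warm-start path down to the target lambda: coordinate
  # descent converges poorly when dropped straight to a small lambda
  path <- l1_path(X, y, penalty$factors, family,
                  lambda = exp(seq(log(50 * penalty$lambda),
                                   log(penalty$lambda), length.out = 25L)),
                  standardize = standardize, thresh = thresh)
  k <- which.min(abs(path$lambda - penalty$lambda))
  make_solver_fit(X, y, path$a0[k], path$beta[, k], penalty$lambda,
                  path$f_eff, family)
}

#' Smallest penalty level that zeroes all penalized coefficients
#'
#' KKT at the intercept-only fit: `max_j |gradient_j| / factor_j` over
#' penalized coefficients, with the gradient of the family's average loss
#' (so the gaussian value carries the factor 2 of d/db (1/n)RSS).
#'
#' @inheritParams fit_l1_linear
#' @param factors nonnegative penalty factors (at least one finite positive).
#' @param family `"gaussian"` or `"binomial"`.
#' @export
lambda_max <- function(X, y, factors, family = c("gaussian", "binomial"),
                       standardize = TRUE) {
  family <- match.arg(family)
  X <- as.matrix(X)
  if (!any(factors > 0 & is.finite(factors)))
    stop("lambda_max undefined: no finite positive penalty factors")
  n <- nrow(X)
  sds <- apply(X, 2L, stats::sd)
  pen <- factors > 0 & is.finite(factors) & sds > 1e-12
  d <- factors[pen] * (if (standardize) sds[pen] else 1)
  r <- y - mean(y)
  g <- abs(as.numeric(crossprod(X[, pen, drop = FALSE], r))) / (n * d)
  (if (family == "gaussian") 2 else 1) * max(g)
}

default_lambda_grid <- function(X, y, factors, family, standardize = TRUE,
                                nlambda = 100L) {
  lmax <- lambda_max(X, y, factors, family, standardize)
  ratio <- if (family == "gaussian") 0.001 else 0.01
  exp(seq(log(lmax), log(lmax * ratio), length.out = nlambda))
}

new_selection_report <- function(grid, criterion, chosen, method, seed = NA) {
  structure(list(grid = grid, criterion_values = criterion,
                 chosen_index = chosen, method = method, fold_seed = seed),
            class = "selection_report")
}

#' Select a penalty level by BIC along a path
#'
#' For the linear family, `BIC = n*log(RSS/n) + df*log(n)` with `df` the
#' number of nonzero coefficients; for the logistic family the deviance
#' replaces the first term.  Ties go to the largest penalty (parsimony).
#'
#' @inheritParams lambda_max
#' @param grid descending vector of candidate penalty levels.
#' @return A `selection_report` with `grid`, `criterion_values`,
#'   `chosen_index`, and the chosen `lambda`.
#' @export
select_by_bic <- function(X, y, factors, grid,
                          family = c("gaussian", "binomial"),
                          standardize = TRUE) {
  family <- match.arg(family)
  if (!length(grid)) stop("empty grid")
  if (is.unsorted(rev(grid), strictly = FALSE)) stop("grid must be descending")
  X <- as.matrix(X); y <- as.numeric(y); n <- nrow(X)
  path <- l1_path(X, y, factors, family, lambda = grid,
                  standardize = standardize)
  eta <- sweep(X %*% path$beta, 2L, path$a0, `+`)
  df <- colSums(path$beta != 0)
  bic <- if (family == "gaussian") {
    rss <- colSums((y - eta)^2)
    if (any(rss <= .Machine$double.eps * n))
      warning("RSS numerically zero on the BIC path; -Inf guard applied")
    ifelse(rss <= .Machine$double.eps * n, -Inf,
           n * log(rss / n) + df * log(n))
  } else {
    2 * colSums(logistic_loss(y, eta)) + df * log(n)
  }
  best <- min(bic)
  chosen <- which(bic <= best + 1e-9)[1L]  # path is descending: first = largest
  rpt <- new_selection_report(path$lambda, bic, chosen, "bic")
  rpt$lambda <- path$lambda[chosen]
  rpt$intercept <- path$a0[chosen]
  rpt$coefs <- path$beta[, chosen]
  rpt
}

#' Select penalty level(s) by k-fold cross-validation
#'
#' Mean held-out loss per grid point; default loss is half the deviance
#' (the average logistic negative log-likelihood) for the binomial family
#' and the mean squared error for the gaussian family; `loss = "auc"`
#' maximizes held-out AUC instead.  Folds are a seeded permutation,
#' stratified by `y` for the binomial family.  Supports a 2-D grid: entries
#' of `factors` equal to `NA` are placeholders filled with each value of
#' `kappa_grid` in turn.  Ties go to the largest `lambda`, then the largest
#' `kappa`.
#'
#' @inheritParams lambda_max
#' @param factors penalty-factor template; `NA` entries mark kappa slots.
#' @param lambda_grid descending candidate lambdas (`NULL` = default grid).
#' @param kappa_grid candidate ratios for the `NA` slots (`NULL` = none).
#' @param k_folds number of folds (>= 2).
#' @param seed integer seed for the fold permutation (required).
#' @param loss `"deviance"` (binomial), `"mse"` (gaussian) or `"auc"`.
#' @return A `selection_report`; `grid` is a data.frame with columns
#'   `lambda` and `kappa`, and the chosen values are in `$lambda`, `$kappa`.
#' @export
select_by_cv <- function(X, y, factors, lambda_grid = NULL, kappa_grid = NULL,
                         k_folds = 10L, seed,
                         family = c("gaussian", "binomial"),
                         loss = NULL, standardize = TRUE) {
  family <- match.arg(family)
  if (missing(seed)) stop("a fold seed is required")
  if (is.null(loss)) loss <- if (family == "binomial") "deviance" else "mse"
  X <- as.matrix(X); n <- nrow(X)
  has_slots <- anyNA(factors)
  if (is.null(kappa_grid)) {
    if (has_slots) stop("factors has NA slots but kappa_grid is NULL")
    kappa_grid <- 1
  }
  fill <- function(kap) { f <- factors; f[is.na(f)] <- kap; f }
  if (is.null(lambda_grid)) {
    lmax <- max(vapply(kappa_grid, function(k)
      lambda_max(X, y, fill(k), family, standardize), numeric(1)))
    ratio <- if (family == "gaussian") 0.001 else 0.01
    lambda_grid <- exp(seq(log(lmax), log(lmax * ratio), length.out = 100L))
  }
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)
  fold <- make_folds(y, k_folds, seed, stratify = family == "binomial")

  loss_mat <- matrix(NA_real_, length(lambda_grid), length(kappa_grid))
  for (kk in seq_along(kappa_grid)) {
    f <- fill(kappa_grid[kk])
    tot <- numeric(length(lambda_grid))
    for (fd in seq_len(k_folds)) {
      tr <- fold != fd; te <- !tr
      path <- l1_path(X[tr, , drop = FALSE], y[tr], f, family,
                      lambda = lambda_grid, standardize = standardize)
      eta <- matrix(path$a0, sum(te), length(lambda_grid), byrow = TRUE) +
        X[te, , drop = FALSE] %*% path$beta
      tot <- tot + switch(loss,
        deviance = colSums(logistic_loss(y[te], eta)),
        mse = colSums((y[te] - eta)^2),
        auc = -vapply(seq_len(ncol(eta)), function(k)
          auc(eta[, k], y[te]) * sum(te), numeric(1)),
        stop("unknown loss"))
    }
    loss_mat[, kk] <- tot / n
  }

  grid_df <- expand.grid(lambda = lambda_grid, kappa = kappa_grid,
                         KEEP.OUT.ATTRS = FALSE)
  crit <- as.numeric(loss_mat)
  best <- min(crit)
  cand <- which(crit <= best + 1e-12)
  # parsimony tie-break: largest lambda, then largest kappa
  ord <- order(-grid_df$lambda[cand], -grid_df$kappa[cand])
  chosen <- cand[ord[1L]]
  rpt <- new_selection_report(grid_df, crit, chosen, "cv", seed)
  rpt$lambda <- grid_df$lambda[chosen]
  rpt$kappa <- grid_df$kappa[chosen]
  rpt$folds <- fold
  rpt
}

`%||%` <- function(a, b) if (is.null(a)) b else a
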