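#' Area under the ROC curve
#'
#' Mann-Whitney form: the probability that a random positive outscores a
#' random negative, ties counted 1/2 (computed from average ranks).
#'
#' @param scores numeric scores (any monotone transform gives the same AUC).
#' @param y binary 0/1 labels with both classes present.
#' @export
auc <- function(scores, y) {
  stopifnot(length(scores) == length(y))
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: y contains a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Excess logistic risk of a fitted linear score
#'
#' Mean logistic loss of the fitted scores on the test set minus the mean
#' loss of the true (or limit) linear score `zeta0 + gamma0*S + X'beta0`.
#' Nonnegative in expectation when `truth` is the population risk minimizer.
#'
#' @param scores fitted linear scores on the test rows.
#' @param test a [labeled_set()] drawn from the generating law.
#' @param truth a [model_coefficients()].
#' @export
excess_risk <- function(scores, test, truth) {
  stopifnot(inherits(test, "labeled_set"), inherits(truth, "model_coefficients"))
  eta0 <- truth$zeta + truth$gamma * test$S +
    as.numeric(test$X %*% truth$beta)
  mean(logistic_loss(test$Y, scores)) - mean(logistic_loss(test$Y, eta0))
}

#' Mean squared error of predicted probabilities
#' @param predicted,truth probability vectors in \[0, 1\] of equal length.
#' @export
mse_p <- function(predicted, truth) {
  stopifnot(length(predicted) == length(truth))
  if (any(predicted < 0 | predicted > 1 | truth < 0 | truth > 1))
    stop("probabilities must lie in [0, 1]")
  mean((predicted - truth)^2)
}

#' Brier skill score
#'
#' `1 - mean((Y - p)^2) / mean((Y - Ybar)^2)` with `Ybar` the empirical event
#' rate of the evaluation sample: a binary R-squared, at most 1, and exactly
#' 0 for the constant event-rate forecast.
#'
#' @param predicted probability vector.
#' @param y binary 0/1 labels with both classes present.
#' @export
bss <- function(predicted, y) {
  stopifnot(length(predicted) == length(y))
  ybar <- mean(y)
  if (ybar == 0 || ybar == 1)
    stop("BSS undefined: y contains a single class")
  1 - mean((y - predicted)^2) / mean((y - ybar)^2)
}

#' Evaluate a fitted model on a simulated test set
#'
#' @param fit a `pass_fit` or `benchmark_fit`.
#' @param study a `simulated_study` (its `test`, `test_probs`, `truth` are
#'   used).
#' @param method optional method tag; defaults to the fit's own.
#' @param replication,seed bookkeeping fields.
#' @return A one-row data.frame with `auc`, `excess_risk`, `mse_p`, `bss`,
#'   `n_test`, `method`, `replication`, `seed`.
#' @export
evaluate_fit <- function(fit, study, method = NULL, replication = NA_integer_,
                         seed = NA_integer_) {
  if (is.null(method))
    method <- if (inherits(fit, "pass_fit")) "pass" else fit$method
  test <- study$test
  scores <- if (inherits(fit, "pass_fit"))
    predict_pass(fit, test$S, test$X, type = "link")
  else predict(fit, test$S, test$X, type = "link")
  p_hat <- stats::plogis(scores)
  data.frame(method = method, replication = replication, seed = seed,
             auc = auc(scores, test$Y),
             excess_risk = excess_risk(scores, test, study$truth),
             mse_p = mse_p(p_hat, study$test_probs),
             bss = bss(p_hat, test$Y),
             n_test = length(test$Y))
}
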