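#' Labeled phenotyping dataset
#'
#' Bundle a chart-reviewed cohort: a binary phenotype `Y`, a scalar surrogate
#' `S` (e.g. an ICD billing-code count) and a numeric feature matrix `X`.
#'
#' @param Y binary vector (0/1) of gold-standard labels, length n.
#' @param S numeric surrogate vector, length n.
#' @param X numeric matrix, n x p.
#' @param feature_names optional character vector of length p; defaults to the
#'   column names of `X` or `X1..Xp`.
#' @return An object of class `labeled_set` with elements `Y`, `S`, `X`,
#'   `feature_names`.
#' @export
labeled_set <- function(Y, S, X, feature_names = NULL) {
  X <- as_feature_matrix(X)
  Y <- as.numeric(Y)
  S <- as.numeric(S)
  if (anyNA(Y) || anyNA(S) || anyNA(X))
    stop("missing values are not supported; complete data required")
  if (!all(Y %in% c(0, 1)))
    stop("Y must contain only 0/1 values")
  n <- nrow(X)
  if (length(Y) != n || length(S) != n)
    stop("Y, S and X must have matching number of rows")
  if (ncol(X) < 1L) stop("X must have at least one feature column")
  feature_names <- resolve_feature_names(X, feature_names)
  colnames(X) <- feature_names
  structure(list(Y = Y, S = S, X = X, feature_names = feature_names),
            class = "labeled_set")
}

#' Unlabeled dataset (surrogate and features only)
#'
#' @param S numeric surrogate vector, length m.
#' @param X numeric matrix, m x p.
#' @param feature_names optional character vector of length p.
#' @return An object of class `unlabeled_set`.
#' @export
unlabeled_set <- function(S, X, feature_names = NULL) {
  X <- as_feature_matrix(X)
  S <- as.numeric(S)
  if (anyNA(S) || anyNA(X))
    stop("missing values are not supported; complete data required")
  if (length(S) != nrow(X))
    stop("S and X must have matching number of rows")
  feature_names <- resolve_feature_names(X, feature_names)
  colnames(X) <- feature_names
  structure(list(S = S, X = X, feature_names = feature_names),
            class = "unlabeled_set")
}

#' Model coefficients for the phenotype model
#'
#' The linear predictor is `zeta + gamma * S + X %*% beta`, i.e. the surrogate
#' enters the outcome model as an ordinary (unpenalized) covariate.
#'
#' @param zeta intercept.
#' @param gamma surrogate coefficient.
#' @param beta numeric feature-coefficient vector, length p.
#' @return An object of class `model_coefficients`.
#' @export
model_coefficients <- function(zeta, gamma, beta) {
  stopifnot(length(zeta) == 1L, length(gamma) == 1L)
  structure(list(zeta = as.numeric(zeta), gamma = as.numeric(gamma),
                 beta = as.numeric(beta)),
            class = "model_coefficients")
}

#' @export
print.labeled_set <- function(x, ...) {
  cat(sprintf("<labeled_set> n = %d, p = %d, prevalence = %.3f\n",
              length(x$Y), ncol(x$X), mean(x$Y)))
  invisible(x)
}

#' @export
print.unlabeled_set <- function(x, ...) {
  cat(sprintf("<unlabeled_set> m = %d, p = %d\n", length(x$S), ncol(x$X)))
  invisible(x)
}

#' @export
print.model_coefficients <- function(x, ...) {
  cat(sprintf("<model_coefficients> zeta = %.4g, gamma = %.4g, |supp(beta)| = %d of %d\n",
              x$zeta, x$gamma, sum(x$beta != 0), length(x$beta)))
  invisible(x)
}

as_feature_matrix <- function(X) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(as.numeric(X), ncol = 1L)
  storage.mode(X) <- "double"
  X
}

resolve_feature_names <- function(X, feature_names) {
  if (is.null(feature_names)) feature_names <- colnames(X)
  if (is.null(feature_names)) feature_names <- paste0("X", seq_len(ncol(X)))
  if (length(feature_names) != ncol(X))
    stop("feature_names must have one entry per column of X")
  as.character(feature_names)
}

#' Read a labeled or unlabeled dataset from a delimited file
#'
#' Comma- or tab-delimited with a header row (delimiter sniffed by
#' [data.table::fread()]).  The outcome and surrogate columns are located by
#' name; every remaining column, in file order, is a feature.
#'
#' @param path file path.
#' @param y_column name of the binary outcome column, or `NULL` for an
#'   unlabeled file.
#' @param s_column name of the surrogate column.
#' @return A [labeled_set()] when `y_column` is given, otherwise an
#'   [unlabeled_set()].
#' @export
read_dataset <- function(path, y_column = NULL, s_column = "S") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  need <- c(y_column, s_column)
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols))
    stop("column(s) not found in ", path, ": ",
         paste(missing_cols, collapse = ", "))
  S <- as.numeric(dt[[s_column]])
  feat <- setdiff(names(dt), need)
  if (!length(feat)) stop("no feature columns remain after removing Y/S")
  X <- as.matrix(dt[feat])
  if (!is.null(y_column)) {
    Y <- dt[[y_column]]
    if (!all(Y %in% c(0, 1)))
      stop("column '", y_column, "' must contain only 0/1 values")
    labeled_set(Y, S, X, feature_names = feat)
  } else {
    unlabeled_set(S, X, feature_names = feat)
  }
}

#' Write a dataset to a delimited file
#'
#' Numeric values are written in shortest round-trippable form, so a
#' write/read cycle reproduces the data bit-exactly.
#'
#' @param x a `labeled_set` or `unlabeled_set`.
#' @param path output path; `.tsv` extension selects tab delimiting.
#' @param y_column,s_column column names to use in the header.
#' @export
write_dataset <- function(x, path, y_column = "Y", s_column = "S") {
  stopifnot(inherits(x, c("labeled_set", "unlabeled_set")))
  fmt <- function(v) sub("^(-?\\d+)\\.0*$", "\\1", sprintf("%.17g", v))
  df <- as.data.frame(apply(x$X, 2L, fmt), stringsAsFactors = FALSE)
  names(df) <- x$feature_names
  df <- cbind(stats::setNames(data.frame(fmt(x$S)), s_column), df)
  if (inherits(x, "labeled_set"))
    df <- cbind(stats::setNames(data.frame(fmt(x$Y)), y_column), df)
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  data.table::fwrite(df, path, sep = sep, quote = FALSE)
  invisible(path)
}

#' Log-transform count features
#'
#' EHR count features are zero-inflated and right-skewed; the standard
#' preprocessing maps each entry x to log(1 + x).
#'
#' @param X nonnegative numeric matrix (or vector).
#' @return Matrix of the same shape with `log1p` applied elementwise.
#' @export
log1p_counts <- function(X) {
  if (any(X < 0)) stop("log1p_counts requires nonnegative entries")
  log1p(X)
}

#' Residualize features against a utilization measure
#'
#' Patients with high healthcare utilization have elevated counts for most
#' features; each column of `X` is replaced by its residual from a
#' least-squares fit on (intercept, u), so returned columns have zero mean and
#' zero sample correlation with `u`.
#'
#' @param X numeric matrix.
#' @param u numeric vector, `length(u) == nrow(X)`, not constant.
#' @return Matrix of residuals, same shape and column names as `X`.
#' @export
orthogonalize_features <- function(X, u) {
  X <- as_feature_matrix(X)
  u <- as.numeric(u)
  if (length(u) != nrow(X)) stop("length(u) must equal nrow(X)")
  if (stats::sd(u) < .Machine$double.eps^0.5 || length(u) < 2L)
    stop("utilization vector u is (numerically) constant; cannot residualize")
  fit <- stats::lm.fit(cbind(1, u), X)
  res <- as.matrix(fit$residuals)
  dimnames(res) <- dimnames(X)
  res
}
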