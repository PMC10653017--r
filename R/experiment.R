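#' Configuration for a replicated simulation experiment
#'
#' @param scenario `"I".."VI"` (main) or `"i".."iii"` (mis-specification).
#' @param n labeled size used by default for every method.
#' @param methods character vector drawn from `"pass"`, `"lasso"`,
#'   `"alasso"`, `"ssprior"`, `"plasso1"`, `"plasso2"`, `"ulasso"`,
#'   `"ssulasso"`; a method may carry an `"@n"` suffix (e.g. `"lasso@400"`)
#'   to use a different number of labeled rows.
#' @param replications number of independent replications (>= 1).
#' @param base_seed integer; replication r uses seed `base_seed + r`.
#' @param p,N,n_test dimensions passed to the scenario spec.
#' @param k_folds,kappa_grid,eta_grid,nu,cu_quantile,cl_quantile method
#'   tuning settings.
#' @param standardize solver standardization flag.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(scenario, n, methods = c("pass", "lasso"),
                              replications = 20L, base_seed = 1L,
                              p = 500L, N = 10000L, n_test = 10000L,
                              k_folds = 10L,
                              kappa_grid = c(0.25, 0.5, 1, 2, 4),
                              eta_grid = c(0, 0.25, 0.5, 1, 2, 4),
                              nu = 1, cu_quantile = 0.9, cl_quantile = 0.1,
                              standardize = TRUE) {
  stopifnot(replications >= 1L)
  structure(list(scenario = as.character(scenario), n = as.integer(n),
                 methods = methods, replications = as.integer(replications),
                 base_seed = as.integer(base_seed), p = as.integer(p),
                 N = as.integer(N), n_test = as.integer(n_test),
                 k_folds = as.integer(k_folds), kappa_grid = kappa_grid,
                 eta_grid = eta_grid, nu = nu, cu_quantile = cu_quantile,
                 cl_quantile = cl_quantile, standardize = standardize),
            class = "experiment_config")
}

parse_method <- function(m, default_n) {
  parts <- strsplit(m, "@", fixed = TRUE)[[1L]]
  n <- if (length(parts) > 1L) as.integer(parts[2L]) else default_n
  list(label = m, name = parts[1L], n = n)
}

subset_labeled <- function(labeled, n) {
  if (n >= length(labeled$Y)) return(labeled)
  labeled_set(labeled$Y[seq_len(n)], labeled$S[seq_len(n)],
              labeled$X[seq_len(n), , drop = FALSE])
}

needs_surrogate <- function(name)
  name %in% c("pass", "ssprior", "plasso1", "plasso2")

#' Run a replicated scenario comparison
#'
#' For each replication r: generate the study with seed `base_seed + r`, fit
#' the surrogate direction once on the pooled (S, X) rows, fit every
#' configured method, and evaluate AUC, excess risk, MSE of predicted
#' probabilities and Brier skill score on the study's independent test set.
#' A method failure in one replication is recorded (value `NA`, flag set)
#' and the run continues.
#'
#' @param config an [experiment_config()].
#' @param verbose print per-replication timing?
#' @return A tidy data.frame (class `experiment_results`) with columns
#'   `scenario`, `method`, `replication`, `seed`, `metric`, `value`,
#'   `failed`; per-replication tuning selections are kept in the
#'   `"selections"` attribute.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  methods <- lapply(config$methods, parse_method, default_n = config$n)
  n_max <- max(vapply(methods, `[[`, integer(1), "n"))
  metrics <- c("auc", "excess_risk", "mse_p", "bss")
  rows <- list()
  selections <- list()

  for (r in seq_len(config$replications)) {
    seed_r <- config$base_seed + r
    t0 <- proc.time()[["elapsed"]]
    spec <- if (config$scenario %in% c("i", "ii", "iii"))
      misspec_scenario_spec(config$scenario, n = n_max, p = config$p,
                            N = config$N, n_test = config$n_test,
                            seed = seed_r)
    else
      main_scenario_spec(config$scenario, n = n_max, p = config$p,
                         N = config$N, n_test = config$n_test, seed = seed_r)
    study <- generate_study(spec)

    surrogate <- NULL
    if (any(vapply(methods, function(m) needs_surrogate(m$name), logical(1)))) {
      pooled <- pooled_surrogate_data(study)
      surrogate <- normalize_direction(
        fit_alpha(pooled$S, pooled$X, nu = config$nu,
                  standardize = config$standardize))
    }
    ulasso_fit <- NULL

    for (m in methods) {
      lab <- subset_labeled(study$labeled, m$n)
      res <- tryCatch({
        fit <- switch(m$name,
          pass = fit_pass(lab, surrogate, kappa_grid = config$kappa_grid,
                          k_folds = config$k_folds, seed = seed_r,
                          standardize = config$standardize),
          lasso = fit_lasso(lab, k_folds = config$k_folds, seed = seed_r,
                            standardize = config$standardize),
          alasso = fit_alasso(lab, nu = config$nu, k_folds = config$k_folds,
                              seed = seed_r,
                              standardize = config$standardize),
          ssprior = fit_ss_prior(lab, surrogate),
          plasso1 = fit_plasso(lab, surrogate, variant = 1,
                               eta_grid = config$eta_grid,
                               k_folds = config$k_folds, seed = seed_r,
                               standardize = config$standardize),
          plasso2 = fit_plasso(lab, surrogate, variant = 2,
                               eta_grid = config$eta_grid,
                               k_folds = config$k_folds, seed = seed_r,
                               standardize = config$standardize),
          ulasso = {
            pooled <- pooled_surrogate_data(study)
            ulasso_fit <- fit_ulasso(pooled$S, pooled$X,
                                      cu_quantile = config$cu_quantile,
                                      cl_quantile = config$cl_quantile,
                                      k_folds = config$k_folds,
                                      seed = seed_r,
                                      standardize = config$standardize)
            ulasso_fit
          },
          ssulasso = {
            if (is.null(ulasso_fit)) {
              pooled <- pooled_surrogate_data(study)
              ulasso_fit <- fit_ulasso(pooled$S, pooled$X,
                                        cu_quantile = config$cu_quantile,
                                        cl_quantile = config$cl_quantile,
                                        k_folds = config$k_folds,
                                        seed = seed_r,
                                        standardize = config$standardize)
            }
            fit_ss_ulasso(lab, ulasso_fit)
          },
          stop("unknown method: ", m$name))
        ev <- evaluate_fit(fit, study, method = m$label, replication = r,
                           seed = seed_r)
        sel <- list(method = m$label, replication = r)
        if (inherits(fit, "pass_fit"))
          sel <- c(sel, list(lambda1 = fit$lambda1, kappa = fit$kappa))
        if (inherits(fit, "benchmark_fit") && !is.null(fit$extras$lambda))
          sel <- c(sel, list(lambda = fit$extras$lambda,
                             eta = fit$extras$eta))
        selections[[length(selections) + 1L]] <- sel
        data.frame(scenario = config$scenario, method = m$label,
                   replication = r, seed = seed_r, metric = metrics,
                   value = as.numeric(ev[1L, metrics]), failed = FALSE)
      }, error = function(e) {
        warning(sprintf("replication %d, method %s failed: %s",
                        r, m$label, conditionMessage(e)))
        data.frame(scenario = config$scenario, method = m$label,
                   replication = r, seed = seed_r, metric = metrics,
                   value = NA_real_, failed = TRUE)
      })
      rows[[length(rows) + 1L]] <- res
    }
    if (verbose)
      message(sprintf("replication %d/%d done in %.1fs (seed %d)",
                      r, config$replications,
                      proc.time()[["elapsed"]] - t0, seed_r))
  }
  out <- do.call(rbind, rows)
  attr(out, "selections") <- selections
  attr(out, "config") <- config
  class(out) <- c("experiment_results", class(out))
  out
}

#' Summarize experiment results per method and metric
#'
#' @param results an `experiment_results` data.frame from [run_experiment()].
#' @return Data.frame with mean, SD and quartiles of each metric per method,
#'   plus the failure count.
#' @export
summarize_experiment <- function(results) {
  sp <- split(results, list(results$method, results$metric), drop = TRUE)
  out <- do.call(rbind, lapply(sp, function(d) {
    v <- d$value[!d$failed]
    data.frame(scenario = d$scenario[1L], method = d$method[1L],
               metric = d$metric[1L], n_reps = nrow(d),
               n_failed = sum(d$failed), mean = mean(v), sd = stats::sd(v),
               q25 = stats::quantile(v, 0.25, names = FALSE),
               median = stats::median(v),
               q75 = stats::quantile(v, 0.75, names = FALSE))
  }))
  rownames(out) <- NULL
  out[order(out$metric, out$method), ]
}

#' Mean of one metric for one method
#' @param results an `experiment_results` data.frame.
#' @param method,metric selectors.
#' @export
metric_mean <- function(results, method, metric = "auc") {
  v <- results$value[results$method == method & results$metric == metric &
                       !results$failed]
  mean(v)
}
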