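# Cross-validation machinery: pseudo-observed data sets (PODs),
# leave-one-out designs, and Pearson r / RMSE scoring.

#' Simulate pseudo-observed data sets
#'
#' Independent simulations with recorded true hyperparameters and parameter
#' summaries, for scoring estimators.  A thin wrapper around
#' [simulate_reference_table()]; give it a seed distinct from the reference
#' table's so the POD stream is independent by construction.
#'
#' @inheritParams simulate_codemo
#' @param count Number of PODs (ignored when `sims_per_psi` is given).
#' @return A `"ref_table"` whose rows are the PODs.
#' @export
generate_pods <- function(spec, count = NULL, sims_per_psi = NULL,
                          n_samples = 20, n_genealogies = 5000,
                          mode = c("asfs", "mito"), locus_length = 600,
                          mu = 2e-6, seed = NULL, sim_offset = 0) {
  simulate_reference_table(spec, n_sims = count,
                           sims_per_psi = sims_per_psi,
                           n_samples = n_samples,
                           n_genealogies = n_genealogies, mode = mode,
                           locus_length = locus_length, mu = mu,
                           seed = seed, sim_offset = sim_offset)
}

#' Score estimates against truths
#'
#' Pearson's r correlation and root mean squared error of estimated values
#' against true POD values.  When either vector has zero variance r is
#' undefined and reported as `NA` with a warning.
#'
#' @param estimates,truths Numeric vectors of equal length >= 2.
#' @return Named list with `pearson_r` and `rmse`.
#' @export
score_estimates <- function(estimates, truths) {
  stopifnot(length(estimates) == length(truths), length(truths) >= 2)
  r <- if (sd(estimates) == 0 || sd(truths) == 0) {
    warning("zero variance; Pearson r undefined")
    NA_real_
  } else cor(estimates, truths)
  list(pearson_r = r, rmse = sqrt(mean((estimates - truths)^2)))
}

#' Leave-one-out (and cross-design) cross-validation
#'
#' Scores an estimator of a hyperparameter (Psi) or parameter summary
#' (Omega_tau, E(tau)) on PODs taken from a reference table.  PODs are
#' selected stratified by the Psi label (`pods_per_value` per distinct
#' value) or unstratified (`n_pods` random rows).
#'
#' The two estimators treat exclusion differently, by design: for ABC
#' rejection each POD is excluded from its own reference set one at a time,
#' whereas for the random forest all selected PODs are collectively removed
#' once and a single forest trained on the remainder serves every POD.
#' When `pod_table` is supplied (cross-design runs, e.g. PODs simulated
#' without a pulse buffer against a buffered reference table), the full
#' `table` is used as the reference for every POD and nothing is removed.
#'
#' @param table Reference `ref_table`.
#' @param estimator `"rf"` or `"abc"`.
#' @param target `"Psi"`, `"omega_tau"` or `"e_tau"`.
#' @param pods_per_value PODs per distinct Psi value (stratified selection).
#' @param n_pods Unstratified POD count (alternative).
#' @param point ABC point estimate to score: `"mean"`, `"median"` or
#'   `"mode"`.
#' @param retain Retained simulations per ABC rejection (e.g. 1500);
#'   alternatively give `tolerance`.
#' @param tolerance ABC tolerance proportion (used when `retain` is NULL).
#' @param rf List of forest options passed to [rf_train()]
#'   (`n_cycles`, `trees_per_cycle`, `per_class`, `mtry`).
#' @param pod_table Optional separate `ref_table` to draw PODs from.
#' @return An object of class `"cv_report"`: per-POD truths and estimates,
#'   `pearson_r`, `rmse`, and the design metadata.
#' @export
loo_crossval <- function(table, estimator = c("rf", "abc"),
                         target = c("Psi", "omega_tau", "e_tau"),
                         pods_per_value = NULL, n_pods = NULL,
                         point = c("mean", "median", "mode"),
                         retain = 1500, tolerance = NULL,
                         rf = list(), pod_table = NULL) {
  estimator <- match.arg(estimator)
  target <- match.arg(target)
  point <- match.arg(point)
  stopifnot(inherits(table, "ref_table"))
  src <- pod_table %||% table
  cross <- !is.null(pod_table)
  strata_label <- src$labels$Psi
  if (!is.null(pods_per_value)) {
    values <- sort(unique(strata_label))
    pod_idx <- unlist(lapply(values, function(v) {
      pool <- which(strata_label == v)
      if (length(pool) < pods_per_value)
        stop("stratum Psi = ", v, " has fewer than ", pods_per_value,
             " simulations")
      pool[sample.int(length(pool), pods_per_value)]
    }), use.names = FALSE)
  } else {
    stopifnot(!is.null(n_pods))
    pod_idx <- sample.int(nrow(src$summaries), n_pods)
  }
  truth_pool <- if (target == "Psi") src$labels$Psi else
    src$param_summaries[[target]]
  truths <- truth_pool[pod_idx]
  targets <- src$summaries[pod_idx, , drop = FALSE]
  values_all <- if (target == "Psi") table$labels$Psi else
    table$param_summaries[[target]]
  if (estimator == "rf") {
    keep <- if (cross) seq_len(nrow(table$summaries)) else
      setdiff(seq_len(nrow(table$summaries)), pod_idx)
    forest <- do.call(rf_train, c(list(
      table = table$summaries[keep, , drop = FALSE],
      values = values_all[keep],
      balance_by = table$labels$psi[keep]), rf))
    estimates <- rf_predict(forest, targets)
  } else {
    estimates <- vapply(seq_along(pod_idx), function(j) {
      keep <- if (cross) seq_len(nrow(table$summaries)) else
        setdiff(seq_len(nrow(table$summaries)), pod_idx[j])
      post <- abc_reject(targets[j, ], table$summaries[keep, , drop = FALSE],
                         values_all[keep], tolerance = tolerance,
                         retain = retain, discrete = target == "Psi")
      post$point_estimates[[point]]
    }, 0)
  }
  sc <- score_estimates(estimates, truths)
  structure(list(estimator = estimator, target = target, point = point,
                 pod_indices = pod_idx, truth = truths,
                 estimate = estimates,
                 pearson_r = sc$pearson_r, rmse = sc$rmse,
                 design = list(
                   n_table = nrow(table$summaries),
                   n_pods = length(pod_idx),
                   pods_per_value = pods_per_value,
                   retain = if (estimator == "abc") retain,
                   tolerance = if (estimator == "abc") tolerance,
                   rf = if (estimator == "rf") rf,
                   cross_design = cross)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "cv_report: %s estimation of %s%s on %d PODs (table of %d)\n",
    if (x$estimator == "rf") "hRF" else "hABC", x$target,
    if (x$estimator == "abc") paste0(" (", x$point, ")") else "",
    x$design$n_pods, x$design$n_table))
  cat(sprintf("  Pearson r = %.3f   RMSE = %.4g\n", x$pearson_r, x$rmse))
  invisible(x)
}
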