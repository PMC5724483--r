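# Hierarchical ABC under the simple rejection algorithm.

# Per-statistic scale for standardization before Euclidean distance: median
# absolute deviation of the reference column, falling back to the standard
# deviation; columns with no variation are dropped from the distance.
abc_scales <- function(summaries) {
  s <- apply(summaries, 2L, mad)
  zero <- s == 0 | !is.finite(s)
  s[zero] <- apply(summaries[, zero, drop = FALSE], 2L, sd)
  s
}

resolve_values <- function(table, values) {
  if (is.character(values) && length(values) == 1L) {
    stopifnot(inherits(table, "ref_table"))
    v <- c(as.list(table$labels), as.list(table$param_summaries))[[values]]
    if (is.null(v)) stop("unknown reference-table column: ", values)
    return(v)
  }
  values
}

#' ABC rejection against a reference table
#'
#' Ranks reference simulations by Euclidean distance between standardized
#' summary vectors and retains the `round(tolerance * n_sims)` nearest
#' (or exactly `retain` when given).  Point estimates of the target quantity
#' are the mean and median of the retained values plus a mode: for
#' continuous targets the argmax of a Gaussian kernel density (Silverman
#' bandwidth, 512-point grid over the retained range), for discrete targets
#' the plurality category with ties broken towards the lowest value.
#'
#' Summaries are standardized per statistic by the median absolute deviation
#' of the reference column (standard deviation as fallback; invariant
#' columns are dropped), making the rejection invariant to per-statistic
#' affine rescaling.
#'
#' @param target Numeric summary vector of length `ncol(summaries)`.
#' @param table A `ref_table` (see [simulate_reference_table()]) or a plain
#'   numeric summary matrix.
#' @param values The per-simulation quantity to estimate: a numeric vector
#'   of length `nrow`, or (for a `ref_table`) a column name such as
#'   `"Psi"`, `"omega_tau"` or `"e_tau"`.
#' @param tolerance Proportion of simulations to retain (0 < tolerance <= 1).
#' @param retain Alternatively, the exact number of simulations to retain.
#' @param discrete Treat the target as a set of discrete categories (used by
#'   [abc_model_select()]).
#' @return An object of class `"posterior_result"`: retained indices and
#'   values, distances, point estimates, and (when `discrete`) category
#'   posterior probabilities summing to 1.
#' @export
abc_reject <- function(target, table, values, tolerance = NULL,
                       retain = NULL, discrete = FALSE) {
  summaries <- if (inherits(table, "ref_table")) table$summaries else table
  values <- resolve_values(table, values)
  stopifnot(is.matrix(summaries), length(values) == nrow(summaries),
            length(target) == ncol(summaries))
  n <- nrow(summaries)
  if (is.null(retain)) {
    stopifnot(!is.null(tolerance), tolerance > 0, tolerance <= 1)
    retain <- round(tolerance * n)
  }
  if (retain < 1) stop("tolerance retains zero simulations")
  if (retain > n) stop("cannot retain more simulations than available")
  s <- abc_scales(summaries)
  keep <- s > 0 & is.finite(s)
  d2 <- colSums((t(summaries[, keep, drop = FALSE]) / s[keep] -
                   target[keep] / s[keep])^2)
  ord <- order(d2)
  acc <- ord[seq_len(retain)]
  vals <- values[acc]
  est <- c(mean = mean(vals), median = median(vals),
           mode = posterior_mode(vals, discrete))
  post <- NULL
  if (discrete) {
    tab <- table(factor(vals, levels = sort(unique(values))))
    post <- as.numeric(tab) / retain
    names(post) <- names(tab)
  }
  structure(list(accepted_indices = acc, distances = sqrt(d2[acc]),
                 tolerance = tolerance %||% retain / n, retain = retain,
                 values = vals, point_estimates = est,
                 category_posteriors = post),
            class = "posterior_result")
}

posterior_mode <- function(vals, discrete) {
  u <- sort(unique(vals))
  if (length(u) == 1L) return(u)
  if (discrete) {
    cnt <- tabulate(match(vals, u))
    return(u[which.max(cnt)])  # which.max takes the first = lowest value
  }
  d <- density(vals, bw = "nrd0", n = 512)
  d$x[which.max(d$y)]
}

#' ABC model selection over discrete event counts
#'
#' Treats each discrete value of the total event count Psi as a separate
#' model: the category posterior is the proportion of retained simulations
#' per Psi value, while the numeric Psi values of the retained simulations
#' are exploited for the mean and median point estimates; the mode is the
#' highest-posterior category (ties towards the lowest value).
#'
#' @inheritParams abc_reject
#' @param values Discrete per-simulation labels (or a `ref_table` column
#'   name, default `"Psi"`).
#' @return A `"posterior_result"` with `category_posteriors`.
#' @export
abc_model_select <- function(target, table, values = "Psi",
                             tolerance = NULL, retain = NULL) {
  abc_reject(target, table, values, tolerance = tolerance, retain = retain,
             discrete = TRUE)
}

#' @export
print.posterior_result <- function(x, ...) {
  cat(sprintf("ABC rejection: retained %d simulations (tolerance %.5g)\n",
              x$retain, x$tolerance))
  cat("point estimates:\n")
  print(round(x$point_estimates, 4))
  if (!is.null(x$category_posteriors)) {
    cat("category posteriors:\n")
    print(round(x$category_posteriors, 4))
  }
  invisible(x)
}
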