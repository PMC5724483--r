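# Optional partial-least-squares transformation of the summary statistics.
# Retained for completeness: on aggregate-SFS reference tables this
# transformation tends to degrade hyperparameter estimation accuracy and is
# therefore not part of the default workflow.

#' Partial-least-squares transformation of reference summaries
#'
#' Fits a PLS regression of the label on a training subset of the summary
#' statistics, keeps the smallest number of latent components whose
#' cumulative explained summary-statistic variance reaches
#' `var_explained`, and projects the remaining rows (and any targets) into
#' that component space.  Rank deficiency yields fewer components, with a
#' warning.  The training subset should be disjoint from the rows being
#' transformed.
#'
#' @param x_train Numeric matrix of training summaries.
#' @param y_train Numeric label vector for the training rows.
#' @param x_new Numeric matrix of summaries to transform (reference rows
#'   and/or targets).
#' @param var_explained Cumulative proportion of summary variance the kept
#'   components must explain (default 0.95).
#' @param max_comp Upper bound on the number of fitted components.
#' @return List with `train_scores`, `new_scores`, `n_comp` and
#'   `cum_var_explained`.
#' @export
pls_transform <- function(x_train, y_train, x_new, var_explained = 0.95,
                          max_comp = 30) {
  stopifnot(is.matrix(x_train), length(y_train) == nrow(x_train),
            is.matrix(x_new), ncol(x_new) == ncol(x_train),
            var_explained > 0, var_explained <= 1)
  if (!requireNamespace("mixOmics", quietly = TRUE))
    stop("pls_transform requires the mixOmics package")
  if (is.null(colnames(x_train)))
    colnames(x_train) <- sprintf("s%03d", seq_len(ncol(x_train)))
  colnames(x_new) <- colnames(x_train)
  ncomp <- min(max_comp, ncol(x_train), nrow(x_train) - 1L)
  fit <- mixOmics::pls(X = x_train, Y = as.numeric(y_train), ncomp = ncomp,
                       mode = "regression")
  cum <- unname(cumsum(fit$prop_expl_var$X))
  n_comp <- which(cum >= var_explained)[1L]
  if (is.na(n_comp)) {
    warning(sprintf(
      "only %.1f%% of summary variance explained by %d components; keeping all",
      100 * cum[length(cum)], ncomp))
    n_comp <- ncomp
  }
  new_scores <- predict(fit, newdata = x_new)$variates[, seq_len(n_comp),
                                                       drop = FALSE]
  list(train_scores = fit$variates$X[, seq_len(n_comp), drop = FALSE],
       new_scores = new_scores, n_comp = n_comp,
       cum_var_explained = cum[seq_len(n_comp)])
}
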