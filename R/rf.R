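# Hierarchical random-forest regression on reference tables.

#' Train a random-forest regression on a reference table
#'
#' Builds a regression forest as `n_cycles` cycles of `trees_per_cycle`
#' trees, each cycle grown on a class-balanced subsample of `per_class`
#' simulations per balancing class (the pulse count by default), with the
#' subsample replaced between cycles.  The default split-candidate count is
#' `max(floor(n_stats/3), 1)` (33 for a 100-bin aggregate SFS).  The label
#' is numeric (the total event count Psi), so trees use variance-reduction
#' splits and predictions are real-valued.
#'
#' @param table A `ref_table` or numeric summary matrix.
#' @param values Numeric per-simulation label to regress on (or a
#'   `ref_table` column name, default `"Psi"`).
#' @param balance_by Class used for the balanced subsampling; defaults to
#'   the label values themselves (or the `psi` column of a `ref_table`).
#' @param n_cycles,trees_per_cycle,per_class Subsampling plan: cycles,
#'   trees per cycle, and simulations drawn per class per cycle.  A class
#'   with fewer rows than `per_class` is sampled with replacement, with a
#'   warning.
#' @param mtry Split candidates per node; default `max(floor(p/3), 1)`.
#' @return An object of class `"codemo_forest"` wrapping the combined
#'   `randomForest` ensemble.
#' @export
rf_train <- function(table, values = "Psi", balance_by = NULL,
                     n_cycles = 100, trees_per_cycle = 10, per_class = 1000,
                     mtry = NULL) {
  summaries <- if (inherits(table, "ref_table")) table$summaries else table
  y <- as.numeric(resolve_values(table, values))
  if (is.null(balance_by))
    balance_by <- if (inherits(table, "ref_table")) table$labels$psi else y
  stopifnot(is.matrix(summaries), length(y) == nrow(summaries),
            length(balance_by) == nrow(summaries))
  if (length(unique(y)) < 2L)
    stop("rf_train needs at least two distinct label values")
  if (is.null(colnames(summaries)))
    colnames(summaries) <- sprintf("s%03d", seq_len(ncol(summaries)))
  mtry <- as.integer(mtry %||% max(floor(ncol(summaries) / 3), 1L))
  cls <- split(seq_len(nrow(summaries)), balance_by)
  short <- vapply(cls, length, 0L) < per_class
  if (any(short))
    warning("classes smaller than per_class are subsampled with replacement: ",
            paste(names(cls)[short], collapse = ", "))
  forests <- vector("list", n_cycles)
  for (cyc in seq_len(n_cycles)) {
    idx <- unlist(lapply(cls, function(i)
      i[sample.int(length(i), per_class, replace = length(i) < per_class)]),
      use.names = FALSE)
    # regression on a numeric label with few distinct values is deliberate
    forests[[cyc]] <- withCallingHandlers(
      randomForest::randomForest(
        x = summaries[idx, , drop = FALSE], y = y[idx],
        ntree = trees_per_cycle, mtry = mtry),
      warning = function(w) {
        if (grepl("five or fewer unique values", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
  }
  ens <- if (n_cycles > 1L) do.call(randomForest::combine, forests) else
    forests[[1L]]
  structure(list(forest = ens, feature_names = colnames(summaries),
                 n_trees = n_cycles * trees_per_cycle, mtry = mtry,
                 label_range = range(y)),
            class = "codemo_forest")
}

#' Predict the event count for target summaries
#'
#' Real-valued prediction as the mean over all trees in the ensemble.
#'
#' @param forest A [rf_train()] result.
#' @param target A numeric summary vector, or a matrix with one target per
#'   row, matching the training statistics.
#' @return Numeric vector of predictions.
#' @export
rf_predict <- function(forest, target) {
  stopifnot(inherits(forest, "codemo_forest"))
  if (is.null(dim(target))) target <- matrix(target, nrow = 1L)
  if (ncol(target) != length(forest$feature_names))
    stop("target has ", ncol(target), " statistics; forest expects ",
         length(forest$feature_names))
  colnames(target) <- forest$feature_names
  as.numeric(predict(forest$forest, newdata = target))
}

#' @export
print.codemo_forest <- function(x, ...) {
  cat(sprintf(
    "codemo_forest: %d regression trees on %d statistics (mtry = %d)\n",
    x$n_trees, length(x$feature_names), x$mtry))
  invisible(x)
}
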