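# Aggregate site frequency spectrum: the exchangeable multi-taxa summary.

#' Build the aggregate SFS from per-taxon folded spectra
#'
#' Normalises each taxon's folded SFS to proportions, then, independently
#' within each allele-frequency class, sorts the n taxa's proportions in
#' descending order and concatenates the classes in ascending frequency
#' order.  The result is a vector of length `n_taxa * n_classes` that is
#' invariant to the input order of taxa - exactly the exchangeability the
#' hierarchical model assumes (taxa are independent, unidentified and
#' exchangeable units).
#'
#' @param sfs_list A list of [folded_sfs()] objects sharing `n_samples`, or
#'   a numeric matrix with one row per taxon and one column per frequency
#'   class.
#' @return An object of class `"aggregate_sfs"`: list with `values`,
#'   `n_taxa` and `n_classes`.
#' @examples
#' m <- rbind(c(0.7, 0.3), c(0.4, 0.6))
#' build_asfs(m)$values  # 0.7 0.4 0.6 0.3
#' @export
build_asfs <- function(sfs_list) {
  if (is.matrix(sfs_list)) {
    P <- sfs_list
  } else {
    stopifnot(length(sfs_list) >= 2,
              all(vapply(sfs_list, inherits, TRUE, "folded_sfs")))
    ns <- vapply(sfs_list, `[[`, 0L, "n_samples")
    if (length(unique(ns)) != 1L)
      stop("all taxa must share the same haploid sample count")
    P <- do.call(rbind, lapply(sfs_list, `[[`, "proportions"))
  }
  if (nrow(P) < 2L) stop("the aSFS needs at least two taxa")
  P <- P / rowSums(P)
  sorted <- apply(P, 2L, sort, decreasing = TRUE)   # n_taxa x n_classes
  structure(list(values = as.numeric(sorted),
                 n_taxa = nrow(P), n_classes = ncol(P)),
            class = "aggregate_sfs")
}

# Row-wise aSFS conversion for a batch: props is n_sims x (n_taxa*n_classes)
# laid out taxon-major (taxon 1 classes, taxon 2 classes, ...).  Returns
# n_sims x (n_taxa*n_classes) with the aSFS layout (class blocks, descending
# within class).
asfs_rows <- function(props, n_taxa, n_classes) {
  out <- matrix(0, nrow(props), n_taxa * n_classes)
  for (s in seq_len(nrow(props))) {
    P <- matrix(props[s, ], n_taxa, n_classes, byrow = TRUE)
    out[s, ] <- as.numeric(apply(P, 2L, sort, decreasing = TRUE))
  }
  colnames(out) <- paste0("asfs_c", rep(seq_len(n_classes), each = n_taxa),
                          "_r", rep(seq_len(n_taxa), n_classes))
  out
}

#' @export
print.aggregate_sfs <- function(x, ...) {
  cat(sprintf("aggregate SFS: %d taxa x %d classes (length %d)\n",
              x$n_taxa, x$n_classes, length(x$values)))
  invisible(x)
}
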