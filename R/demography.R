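#' Single-population instantaneous size-change demography
#'
#' One taxon's history: a panmictic population of current effective size
#' `n_current` (in gene copies) that had ancestral size
#' `epsilon * n_current` before generation `tau` (time measured backwards
#' from sampling).  `epsilon < 1` encodes a forward-time expansion,
#' `epsilon > 1` a contraction, `epsilon = 1` constant size.
#'
#' The coalescence rate while k lineages remain in a population of size M
#' gene copies is k(k-1)/(2M) per generation; M switches from `n_current` to
#' `epsilon * n_current` at `tau` exactly (events at time >= `tau` use the
#' ancestral size).
#'
#' @param n_current Current effective population size in gene copies
#'   (integer-valued, >= 2).
#' @param epsilon Ratio of ancestral to current effective size (> 0).
#' @param tau Time of the instantaneous change, in generations (>= 0).
#' @return An object of class `"demography"`.
#' @examples
#' demography(1e5, epsilon = 0.05, tau = 20000)  # 20-fold expansion
#' @export
demography <- function(n_current, epsilon = 1, tau = 0) {
  stopifnot(is.numeric(n_current), length(n_current) == 1L, n_current >= 2,
            is.numeric(epsilon), length(epsilon) == 1L,
            is.numeric(tau), length(tau) == 1L, tau >= 0)
  if (!is.finite(epsilon) || epsilon <= 0)
    stop("'epsilon' must be a finite positive ratio")
  structure(list(n_current = n_current, epsilon = epsilon, tau = tau),
            class = "demography")
}

#' @export
print.demography <- function(x, ...) {
  kind <- if (x$epsilon < 1) "expansion" else if (x$epsilon > 1)
    "contraction" else "constant size"
  cat(sprintf("demography: N = %g, epsilon = %g, tau = %g (%s)\n",
              x$n_current, x$epsilon, x$tau, kind))
  invisible(x)
}

#' Folded site frequency spectrum container
#'
#' Proportions of SNPs in each minor-allele-count class 1..floor(n/2); the
#' monomorphic class is excluded.  Entries are non-negative and sum to 1
#' whenever `n_snps > 0`.
#'
#' @param proportions Numeric vector of length `floor(n_samples/2)`.
#' @param n_samples Haploid sample count.
#' @param n_snps Number of SNPs summarised.
#' @return An object of class `"folded_sfs"`.
#' @export
folded_sfs <- function(proportions, n_samples, n_snps) {
  stopifnot(n_samples >= 2, length(proportions) == n_samples %/% 2,
            all(proportions >= 0), n_snps >= 0)
  if (n_snps > 0 && abs(sum(proportions) - 1) > 1e-8)
    stop("folded SFS proportions must sum to 1")
  structure(list(proportions = as.numeric(proportions),
                 n_samples = as.integer(n_samples),
                 n_snps = as.integer(n_snps)),
            class = "folded_sfs")
}

#' @export
print.folded_sfs <- function(x, ...) {
  cat(sprintf("folded SFS: %d haploid samples, %d SNPs\n",
              x$n_samples, x$n_snps))
  print(round(x$proportions, 4))
  invisible(x)
}
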