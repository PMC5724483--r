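# Multi-taxa single-locus (mitochondrial) summary statistics: per-taxon
# (K, H, pi, Tajima's D), then the first four moments of each across taxa.

#' Per-taxon single-locus summary statistics
#'
#' Computes, from one taxon's haplotype block: the number of distinct
#' haplotypes K, haplotype diversity H = (n/(n-1))(1 - sum p_i^2) over
#' haplotype frequencies p_i, nucleotide diversity pi (mean pairwise
#' difference per site), and Tajima's D with the standard (Tajima 1989)
#' constants.  When there are no segregating sites D is undefined; it is
#' returned as 0 with attribute `D_defined = FALSE`.
#'
#' @param block A [simulate_sequences()] result, or any list with a 0/1
#'   `sequences` matrix (rows = samples, columns = segregating sites) and a
#'   `locus_length`.
#' @return Named numeric vector `c(K, H, pi, D)` with attribute `D_defined`.
#' @export
mito_taxon_stats <- function(block) {
  seqs <- block$sequences
  stopifnot(is.matrix(seqs), nrow(seqs) >= 2)
  n <- nrow(seqs)
  S <- ncol(seqs)
  hap <- apply(seqs, 1L, paste, collapse = "")
  K <- length(unique(hap))
  p <- table(hap) / n
  H <- (n / (n - 1)) * (1 - sum(p^2))
  # mean pairwise difference: for 0/1 columns, sum over sites of
  # 2 * d_j * (n - d_j) unordered mismatching pairs
  if (S > 0) {
    d <- colSums(seqs)
    pi_total <- sum(d * (n - d)) / choose(n, 2)
  } else pi_total <- 0
  pi_site <- pi_total / block$locus_length
  D_defined <- S > 0
  if (D_defined) {
    i <- seq_len(n - 1)
    a1 <- sum(1 / i); a2 <- sum(1 / i^2)
    b1 <- (n + 1) / (3 * (n - 1))
    b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
    c1 <- b1 - 1 / a1
    c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
    e1 <- c1 / a1
    e2 <- c2 / (a1^2 + a2)
    denom <- sqrt(e1 * S + e2 * S * (S - 1))
    D <- if (denom > 0) (pi_total - S / a1) / denom else 0
  } else D <- 0
  structure(c(K = K, H = H, pi = pi_site, D = D), D_defined = D_defined)
}

#' Multi-taxa moments of the single-locus statistics
#'
#' Given per-taxon (K, H, pi, D) rows, computes for each statistic its mean,
#' variance (divisor n - 1), skewness and kurtosis across taxa - 16 values
#' in the fixed order K, H, pi, D x (mean, var, skew, kurt).  Skewness and
#' kurtosis are standardized central moments (divisor n, kurtosis
#' non-excess); in the zero-variance degenerate case both are mapped to 0
#' with a warning.
#'
#' @param stats A numeric matrix with one row per taxon and columns
#'   K, H, pi, D (at least 2 taxa).
#' @return An object of class `"mito_summary"`: named numeric vector of
#'   length 16.
#' @export
mito_moments <- function(stats) {
  stopifnot(is.matrix(stats), nrow(stats) >= 2, ncol(stats) == 4L)
  out <- numeric(0)
  degenerate <- FALSE
  for (j in seq_len(4L)) {
    x <- stats[, j]
    m <- mean(x)
    v <- var(x)
    m2 <- mean((x - m)^2)
    if (m2 > 0) {
      skew <- mean((x - m)^3) / m2^1.5
      kurt <- mean((x - m)^4) / m2^2
    } else {
      degenerate <- TRUE
      skew <- 0; kurt <- 0
    }
    out <- c(out, m, v, skew, kurt)
  }
  if (degenerate)
    warning("zero variance across taxa; skewness and kurtosis set to 0")
  names(out) <- paste0(rep(c("K", "H", "pi", "D"), each = 4L),
                       c("_mean", "_var", "_skew", "_kurt"))
  class(out) <- c("mito_summary", "numeric")
  out
}
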