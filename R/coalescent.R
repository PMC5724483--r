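# Single-population coalescent under an instantaneous size change, and the
# FREQ-style folded-SFS sampler (one SNP per independent genealogy).

# Block-size distribution for the Kingman coalescent: probability that a
# uniformly chosen lineage, among the k ancestral lineages of n samples,
# subtends i of them: q(i | k, n) = C(n-i-1, k-2) / C(n-1, k-1).
# Topology is independent of coalescence times, which is what lets the SFS
# sampler draw a level and then a block size instead of building trees.
class_size_probs <- function(n_samples) {
  n <- n_samples
  Q <- matrix(0, n - 1, n - 1)
  for (k in 2:n)
    for (i in 1:(n - k + 1))
      Q[k - 1, i] <- choose(n - i - 1, k - 2) / choose(n - 1, k - 1)
  Q
}

# Waiting time (generations) until the next coalescence among k lineages,
# starting at time t, under demog; rescales one unit exponential across the
# size-change boundary (exact by memorylessness).
coal_wait <- function(t, k, demog) {
  pair <- k * (k - 1) / 2
  e <- rexp(1)
  N0 <- demog$n_current
  Na <- demog$epsilon * N0
  if (t < demog$tau) {
    w1 <- e * N0 / pair
    if (t + w1 <= demog$tau) return(w1)
    return((demog$tau - t) + (e - (demog$tau - t) * pair / N0) * Na / pair)
  }
  e * Na / pair
}

#' Simulate one genealogy and return per-class branch lengths
#'
#' Simulates a single coalescent genealogy of `n_samples` lineages under an
#' instantaneous size-change demography, with explicit topology, and returns
#' the total branch length subtending i leaves for each derived-allele class
#' i = 1..n_samples-1, in generations.  This is the reference implementation
#' used to validate the vectorised SFS engine; it is not the fast path.
#'
#' @param n_samples Number of haploid samples (>= 2).
#' @param demog A [demography()].
#' @return Numeric vector of length `n_samples - 1`; element i is the branch
#'   length apportioned to branches with i descendant leaves.
#' @export
simulate_genealogy <- function(n_samples, demog) {
  stopifnot(n_samples >= 2, inherits(demog, "demography"))
  sizes <- rep(1L, n_samples)
  ell <- numeric(n_samples - 1)
  t <- 0
  for (k in n_samples:2) {
    dt <- coal_wait(t, k, demog)
    t <- t + dt
    ell <- ell + dt * tabulate(sizes, n_samples - 1)
    idx <- sample.int(k, 2L)
    sizes <- c(sizes[-idx], sizes[idx[1L]] + sizes[idx[2L]])
  }
  ell
}

fold_classes <- function(n_samples) {
  i <- seq_len(n_samples - 1)
  pmin(i, n_samples - i)
}

#' Simulate a folded SFS in the one-SNP-per-genealogy (FREQ) setting
#'
#' Each of `n_genealogies` independent genealogies contributes exactly one
#' SNP, assigned to derived class i with probability equal to the fraction of
#' that genealogy's branch length subtending i leaves; classes are then
#' folded (class i merged with n-i) and normalised to proportions.  This
#' emulates direct SFS simulation where a fixed number of independent
#' genealogies approximates the number of SNPs sampled.
#'
#' Sampling is performed without building trees: conditional on the level
#' times, the SNP class is a mixture over levels k (weight k*T_k) of the
#' block-size distribution q(. | k, n), which is distribution-identical to
#' per-genealogy tree building because topology is independent of times.
#'
#' @inheritParams simulate_genealogy
#' @param n_genealogies Number of independent genealogies (= SNPs).
#' @return A [folded_sfs()].
#' @examples
#' set.seed(1)
#' simulate_sfs_freq(20, 1000, demography(1e5, 0.05, 2e4))
#' @export
simulate_sfs_freq <- function(n_samples, n_genealogies, demog) {
  stopifnot(n_genealogies >= 1)
  counts <- sfs_freq_batch(n_samples, n_genealogies,
                           n_cur = demog$n_current, epsilon = demog$epsilon,
                           tau = demog$tau)
  folded_sfs(counts[1L, ] / sum(counts[1L, ]), n_samples, n_genealogies)
}

# Batched engine call: one row of folded SNP counts per demography.
# The cumulative block-size table depends only on n_samples; cache it.
cumQ_cache <- new.env(parent = emptyenv())
cum_class_probs <- function(n_samples) {
  key <- as.character(n_samples)
  if (is.null(cumQ_cache[[key]]))
    cumQ_cache[[key]] <- t(apply(class_size_probs(n_samples), 1, cumsum))
  cumQ_cache[[key]]
}

sfs_freq_batch <- function(n_samples, n_genealogies, n_cur, epsilon, tau) {
  stopifnot(length(n_cur) == length(epsilon), length(n_cur) == length(tau),
            all(epsilon > 0), all(is.finite(epsilon)), all(tau >= 0))
  sfs_freq_engine_cpp(as.integer(n_samples), as.integer(n_genealogies),
                      as.numeric(n_cur), as.numeric(epsilon),
                      as.numeric(tau), cum_class_probs(n_samples))
}

#' Expected folded SFS proportions
#'
#' Returns the expected per-SNP folded class probabilities
#' E\[l_i / l_tot\] under the one-SNP-per-genealogy setting.
#'
#' `method = "mc"` (default) estimates the expectation by averaging the
#' conditional class distribution over `n_reps` replicate draws of the level
#' times; this is the quantity the FREQ sampler converges to and is valid for
#' any demography.  `method = "closed_form"` returns the classical
#' constant-size ratio of expected branch lengths (folded 1/i + 1/(n-i)
#' weights) and is only available for `epsilon = 1`; it differs from
#' E\[l_i / l_tot\] by a small ratio bias (about 0.016 at the singleton class
#' for n = 20), which is documented rather than hidden.
#'
#' @inheritParams simulate_genealogy
#' @param method `"mc"` or `"closed_form"`.
#' @param n_reps Monte-Carlo replicates for `method = "mc"`.
#' @return Numeric vector of folded class probabilities, length
#'   `floor(n_samples/2)`, summing to 1.
#' @export
expected_sfs <- function(n_samples, demog, method = c("mc", "closed_form"),
                         n_reps = 200000) {
  stopifnot(n_samples >= 2, inherits(demog, "demography"))
  method <- match.arg(method)
  if (method == "closed_form") {
    if (demog$epsilon != 1)
      stop("closed_form expected SFS is only available for epsilon = 1")
    i <- seq_len(n_samples - 1)
    w <- 1 / i
    f <- rowsum(w, fold_classes(n_samples))[, 1L]
    return(as.numeric(f / sum(f)))
  }
  e <- expected_sfs_mc_cpp(as.integer(n_samples), as.integer(n_reps),
                           demog$n_current, demog$epsilon, demog$tau,
                           class_size_probs(n_samples))
  as.numeric(e)
}

#' Simulate an infinite-sites haplotype block
#'
#' Simulates one genealogy with explicit topology, drops a Poisson number of
#' mutations (mean `mu * locus_length * total branch length`) uniformly on
#' branches, and assigns each mutation its own previously unused site (the
#' infinite-sites model mapped onto a finite locus).  If the number of
#' mutations exceeds `locus_length` the locus is saturated and an error is
#' raised rather than silently recycling sites.
#'
#' @inheritParams simulate_genealogy
#' @param locus_length Number of sites available.
#' @param mu Per-site, per-generation mutation rate (> 0).
#' @return An object of class `"haplotype_block"`: list with `sequences`
#'   (n_samples x n_sites 0/1 matrix, every column polymorphic),
#'   `locus_length` and `mu`.
#' @export
simulate_sequences <- function(n_samples, locus_length, mu, demog) {
  stopifnot(n_samples >= 2, locus_length >= 1, mu > 0,
            inherits(demog, "demography"))
  # Segments: each (lineage, inter-coalescence interval) carries a leaf set.
  members <- lapply(seq_len(n_samples), identity)
  seg_leaves <- list()
  seg_len <- numeric(0)
  t <- 0
  for (k in n_samples:2) {
    dt <- coal_wait(t, k, demog)
    t <- t + dt
    seg_leaves <- c(seg_leaves, members)
    seg_len <- c(seg_len, rep(dt, k))
    idx <- sample.int(k, 2L)
    merged <- c(members[[idx[1L]]], members[[idx[2L]]])
    members <- c(members[-idx], list(merged))
  }
  total_len <- sum(seg_len)
  n_mut <- rpois(1, mu * locus_length * total_len)
  if (n_mut > locus_length)
    stop(sprintf("locus saturated: %d mutations exceed %d sites",
                 n_mut, locus_length))
  seqs <- matrix(0L, n_samples, n_mut)
  sites <- integer(0)
  if (n_mut > 0) {
    hit <- sample.int(length(seg_len), n_mut, replace = TRUE,
                      prob = seg_len)
    for (m in seq_len(n_mut)) seqs[seg_leaves[[hit[m]]], m] <- 1L
    sites <- sort(sample.int(locus_length, n_mut))
  }
  structure(list(sequences = seqs, sites = sites,
                 locus_length = as.integer(locus_length), mu = mu),
            class = "haplotype_block")
}
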