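# Reference-table simulation: hierarchical draws -> per-taxon data ->
# multi-taxa summaries.

# Deterministic per-simulation substream seed: a counter-based expansion of
# one global seed, so sharded runs concatenate to exactly the rows a single
# run would produce.  Kept below 2^31 - 1.
derive_seed <- function(seed, counter) {
  s <- ((as.numeric(seed) %% 1000003) * 2039 + counter * 48271) %% 2147483647
  if (s == 0) s <- 1
  as.integer(s)
}

#' Simulate a batch of hierarchical co-demographic data sets
#'
#' Draws `n_sims` configurations from the hyperprior (optionally stratified
#' with `sims_per_psi` simulations per psi value), realizes per-taxon
#' parameters, and simulates each taxon's data: a folded SFS from
#' `n_genealogies` independent genealogies (genomic mode) or an
#' infinite-sites haplotype block reduced to (K, H, pi, D) (single-locus
#' mode).  Per-taxon summaries are kept unaggregated so batches can be
#' written to simulation directories and aggregated later.
#'
#' Each simulation consumes its own RNG substream derived from `seed` and
#' the simulation counter, so runs sharded across machines or sessions
#' reproduce a single run exactly.
#'
#' @param spec A [hyperprior_spec()].
#' @param n_sims Number of simulations with psi drawn from the hyperprior.
#' @param sims_per_psi Alternatively, simulations per psi value (stratified;
#'   enumeration schemes only).
#' @param n_samples Haploid samples per taxon (genomic mode).
#' @param n_genealogies Independent genealogies (= SNPs) per SFS.
#' @param mode `"asfs"` (folded SFS per taxon) or `"mito"` (single-locus
#'   statistics per taxon).
#' @param locus_length,mu Single-locus mode: sites per locus and per-site
#'   mutation rate (a length-2 `mu` is a uniform prior range drawn per
#'   taxon).
#' @param seed Integer seed expanded into per-simulation substreams; when
#'   `NULL` the ambient RNG stream is used (not shardable).
#' @param sim_offset Counter offset for resumed or sharded runs.
#' @return An object of class `"sim_batch"`.
#' @export
simulate_codemo <- function(spec, n_sims = NULL, sims_per_psi = NULL,
                            n_samples = 20, n_genealogies = 5000,
                            mode = c("asfs", "mito"),
                            locus_length = 600, mu = 2e-6,
                            seed = NULL, sim_offset = 0) {
  stopifnot(inherits(spec, "hyperprior_spec"))
  mode <- match.arg(mode)
  n <- spec$n_taxa
  if (!is.null(sims_per_psi)) {
    if (spec$scheme == "dirichlet_process")
      stop("stratified simulation needs an enumeration scheme")
    psi_seq <- rep(spec$psi_support, each = sims_per_psi)
  } else {
    stopifnot(!is.null(n_sims))
    psi_seq <- rep(NA_integer_, n_sims)
  }
  total <- length(psi_seq)
  n_cols <- if (mode == "asfs") n_samples %/% 2L else 4L
  taxon_stats <- array(NA_real_, c(total, n, n_cols))
  psi_v <- integer(total); sigma_v <- integer(total)
  Psi_v <- integer(total); zeta_v <- numeric(total)
  omega_v <- numeric(total); etau_v <- numeric(total)
  tau <- matrix(0, total, n)
  epsilon <- matrix(0, total, n)
  n_e <- matrix(0, total, n)
  for (i in seq_len(total)) {
    if (!is.null(seed)) set.seed(derive_seed(seed, sim_offset + i))
    fp <- if (is.na(psi_seq[i])) NULL else psi_seq[i]
    draw <- draw_codemo(spec, force_psi = fp)
    tp <- draw_taxon_params(draw, spec)
    ps <- summarize_params(tp)
    psi_v[i] <- draw$psi; sigma_v[i] <- draw$sigma
    Psi_v[i] <- draw$Psi; zeta_v[i] <- draw$zeta_T
    omega_v[i] <- ps$omega_tau; etau_v[i] <- ps$e_tau
    tau[i, ] <- tp$tau; epsilon[i, ] <- tp$epsilon; n_e[i, ] <- tp$n_e
    if (mode == "asfs") {
      counts <- sfs_freq_batch(n_samples, n_genealogies,
                               n_cur = tp$n_e, epsilon = tp$epsilon,
                               tau = tp$tau)
      taxon_stats[i, , ] <- counts / rowSums(counts)
    } else {
      for (tx in seq_len(n)) {
        mu_tx <- if (length(mu) == 2L) runif(1, mu[1], mu[2]) else mu
        blk <- sim_block_retry(n_samples, locus_length, mu_tx,
                               demography(tp$n_e[tx], tp$epsilon[tx],
                                          tp$tau[tx]))
        taxon_stats[i, tx, ] <- mito_taxon_stats(blk)
      }
    }
  }
  labels <- data.frame(psi = psi_v, sigma = sigma_v, Psi = Psi_v,
                       zeta_T = zeta_v)
  param_summaries <- data.frame(omega_tau = omega_v, e_tau = etau_v)
  structure(list(mode = mode, n_taxa = n, n_samples = as.integer(n_samples),
                 n_stat_cols = n_cols, taxon_stats = taxon_stats,
                 labels = labels, param_summaries = param_summaries,
                 tau = tau, epsilon = epsilon, n_e = n_e,
                 provenance = list(seed = seed, sim_offset = sim_offset,
                                   n_genealogies = n_genealogies,
                                   locus_length = locus_length, mu = mu)),
            class = "sim_batch")
}

# Locus saturation under the infinite-sites model is an error; for prior
# draws it is rare, so retry a few times before giving up.
sim_block_retry <- function(n_samples, locus_length, mu, demog,
                            max_tries = 10L) {
  for (k in seq_len(max_tries)) {
    blk <- tryCatch(simulate_sequences(n_samples, locus_length, mu, demog),
                    error = function(e)
                      if (grepl("saturated", conditionMessage(e))) NULL
                      else stop(e))
    if (!is.null(blk)) return(blk)
  }
  stop("locus repeatedly saturated; lower mu or lengthen the locus")
}

#' Aggregate a simulation batch into a reference table
#'
#' Converts per-taxon summaries into one multi-taxa summary row per
#' simulation: the aggregate SFS (per-class descending sort, classes
#' concatenated) in genomic mode, or the 16 moment statistics in
#' single-locus mode, paired with the hyperparameter labels and parameter
#' summaries.
#'
#' @param batch A [simulate_codemo()] result (or several row-bound via
#'   [bind_sim_batches()]).
#' @return An object of class `"ref_table"` with elements `summaries`
#'   (matrix), `labels`, `param_summaries`, `tau`, `epsilon`, `n_e` and
#'   `provenance`.
#' @export
aggregate_batch <- function(batch) {
  stopifnot(inherits(batch, "sim_batch"))
  total <- nrow(batch$labels)
  if (batch$mode == "asfs") {
    props <- matrix(0, total, batch$n_taxa * batch$n_stat_cols)
    for (tx in seq_len(batch$n_taxa))
      props[, (tx - 1L) * batch$n_stat_cols + seq_len(batch$n_stat_cols)] <-
        batch$taxon_stats[, tx, ]
    summaries <- asfs_rows(props, batch$n_taxa, batch$n_stat_cols)
  } else {
    summaries <- t(vapply(seq_len(total), function(i)
      as.numeric(mito_moments(batch$taxon_stats[i, , ])),
      numeric(16L)))
    colnames(summaries) <- names(mito_moments(batch$taxon_stats[1L, , ]))
  }
  structure(list(summaries = summaries, labels = batch$labels,
                 param_summaries = batch$param_summaries,
                 tau = batch$tau, epsilon = batch$epsilon, n_e = batch$n_e,
                 mode = batch$mode, n_taxa = batch$n_taxa,
                 n_samples = batch$n_samples,
                 provenance = batch$provenance),
            class = "ref_table")
}

#' Simulate a reference table in one call
#'
#' Convenience wrapper: [simulate_codemo()] followed by
#' [aggregate_batch()].
#'
#' @inheritParams simulate_codemo
#' @return A `"ref_table"`.
#' @examples
#' spec <- hyperprior_spec(4, "psi_conditioned", psi_support = 0:2,
#'                         tau_prior = c(1000, 50000),
#'                         epsilon_prior = c(0.01, 0.1),
#'                         n_prior = c(10000, 50000))
#' rt <- simulate_reference_table(spec, n_sims = 5, n_samples = 10,
#'                                n_genealogies = 200, seed = 1)
#' dim(rt$summaries)
#' @export
simulate_reference_table <- function(spec, n_sims = NULL,
                                     sims_per_psi = NULL, n_samples = 20,
                                     n_genealogies = 5000,
                                     mode = c("asfs", "mito"),
                                     locus_length = 600, mu = 2e-6,
                                     seed = NULL, sim_offset = 0) {
  aggregate_batch(simulate_codemo(
    spec, n_sims = n_sims, sims_per_psi = sims_per_psi,
    n_samples = n_samples, n_genealogies = n_genealogies, mode = mode,
    locus_length = locus_length, mu = mu, seed = seed,
    sim_offset = sim_offset))
}

#' Row-bind simulation batches from sharded runs
#'
#' @param ... `sim_batch` objects with identical taxa, mode and statistic
#'   layout.
#' @return A single `sim_batch`.
#' @export
bind_sim_batches <- function(...) {
  batches <- list(...)
  if (length(batches) == 1L && is.list(batches[[1L]]) &&
      !inherits(batches[[1L]], "sim_batch"))
    batches <- batches[[1L]]
  stopifnot(length(batches) >= 1L,
            all(vapply(batches, inherits, TRUE, "sim_batch")))
  b1 <- batches[[1L]]
  for (b in batches[-1L])
    if (b$n_taxa != b1$n_taxa || b$mode != b1$mode ||
        b$n_stat_cols != b1$n_stat_cols)
      stop("sim batches have incompatible schemas")
  stat_list <- lapply(batches, `[[`, "taxon_stats")
  total <- sum(vapply(stat_list, function(a) dim(a)[1L], 0L))
  stats <- array(NA_real_, c(total, b1$n_taxa, b1$n_stat_cols))
  at <- 0L
  for (a in stat_list) {
    stats[at + seq_len(dim(a)[1L]), , ] <- a
    at <- at + dim(a)[1L]
  }
  out <- b1
  out$taxon_stats <- stats
  out$labels <- do.call(rbind, lapply(batches, `[[`, "labels"))
  out$param_summaries <- do.call(rbind,
                                 lapply(batches, `[[`, "param_summaries"))
  out$tau <- do.call(rbind, lapply(batches, `[[`, "tau"))
  out$epsilon <- do.call(rbind, lapply(batches, `[[`, "epsilon"))
  out$n_e <- do.call(rbind, lapply(batches, `[[`, "n_e"))
  out$provenance <- lapply(batches, `[[`, "provenance")
  out
}

#' @export
print.sim_batch <- function(x, ...) {
  cat(sprintf("sim_batch: %d simulations x %d taxa (%s mode)\n",
              nrow(x$labels), x$n_taxa, x$mode))
  invisible(x)
}

#' @export
print.ref_table <- function(x, ...) {
  cat(sprintf(
    "ref_table: %d simulations, %d summary statistics (%s mode, %d taxa)\n",
    nrow(x$summaries), ncol(x$summaries), x$mode, x$n_taxa))
  cat("Psi counts:\n")
  print(table(x$labels$Psi))
  invisible(x)
}
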