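# Aggregate SFS construction and multi-taxa mitochondrial statistics.

test_that("aSFS sorts within classes and concatenates in class order", {
  m <- rbind(c(0.7, 0.3), c(0.4, 0.6))
  a <- build_asfs(m)
  expect_equal(a$values, c(0.7, 0.4, 0.6, 0.3))  # hand-sorted oracle
  expect_identical(a$n_taxa, 2L)
  expect_identical(a$n_classes, 2L)
  # identical taxa: each class block is n copies of one value
  ident <- rbind(c(0.6, 0.4), c(0.6, 0.4), c(0.6, 0.4))
  expect_equal(build_asfs(ident)$values, c(0.6, 0.6, 0.6, 0.4, 0.4, 0.4))
})

test_that("aSFS dimensions follow taxa x classes and feed the forest default", {
  set.seed(21)
  sfs_list <- lapply(1:10, function(i)
    simulate_sfs_freq(20, 500, demography(5e4, 0.05, 2e4)))
  a <- build_asfs(sfs_list)
  expect_length(a$values, 100)
  expect_identical(max(floor(100 / 3), 1), 33)
})

test_that("aSFS is invariant to taxon input order and round-trips per class", {
  set.seed(22)
  P <- matrix(runif(50), 5, 10)
  P <- P / rowSums(P)
  a1 <- build_asfs(P)
  a2 <- build_asfs(P[sample(5), ])
  expect_equal(a1$values, a2$values)
  # per-class multiset equals the input proportions per class
  v <- matrix(a1$values, 5, 10)
  for (cl in 1:10)
    expect_equal(sort(v[, cl]), sort(P[, cl]))
})

test_that("mismatched class counts are refused", {
  a <- folded_sfs(c(0.5, 0.5), 4, 10)
  b <- folded_sfs(c(0.3, 0.3, 0.4), 6, 10)
  expect_error(build_asfs(list(a, b)), "sample count")
})

test_that("per-taxon statistics match a brute-force pairwise oracle", {
  # hand-built 4 x 3 block
  seqs <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(1L, 1L, 0L), c(1L, 1L, 1L))
  blk <- list(sequences = seqs, locus_length = 100L)
  st <- mito_taxon_stats(blk)
  n <- 4; S <- 3
  # oracle: explicit loops over all pairs
  pid <- 0; np <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pid <- pid + sum(seqs[i, ] != seqs[j, ]); np <- np + 1
  }
  pi_total <- pid / np
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  D_oracle <- (pi_total - S / a1) /
    sqrt((c1 / a1) * S + (c2 / (a1^2 + a2)) * S * (S - 1))
  expect_equal(unname(st["K"]), 4)
  expect_equal(unname(st["H"]), (4 / 3) * (1 - 4 * (1 / 4)^2))
  expect_equal(unname(st["pi"]), pi_total / 100)
  expect_equal(unname(st["D"]), D_oracle)
  expect_true(attr(st, "D_defined"))
})

test_that("monomorphic block gives K = 1, H = 0, pi = 0 and flagged D", {
  blk <- list(sequences = matrix(integer(0), 5, 0), locus_length = 100L)
  st <- mito_taxon_stats(blk)
  expect_equal(unname(st[c("K", "H", "pi", "D")]), c(1, 0, 0, 0))
  expect_false(attr(st, "D_defined"))
})

test_that("duplicating all sequences keeps K and recomputes H at doubled n", {
  seqs <- rbind(c(0L, 1L), c(1L, 0L), c(1L, 1L))
  st1 <- mito_taxon_stats(list(sequences = seqs, locus_length = 50L))
  st2 <- mito_taxon_stats(list(sequences = rbind(seqs, seqs),
                               locus_length = 50L))
  expect_equal(st1["K"], st2["K"])
  p <- rep(1 / 3, 3)
  expect_equal(unname(st2["H"]), (6 / 5) * (1 - sum((2 / 6)^2 * 3)))
})

test_that("moment summaries match direct arithmetic and have length 16", {
  x <- c(0.01, 0.02, 0.06)
  stats <- cbind(K = c(2, 3, 4), H = c(0.2, 0.5, 0.9), pi = x,
                 D = c(-1, 0, 2))
  mm <- mito_moments(stats)
  expect_length(mm, 16)
  m <- sum(x) / 3
  v <- sum((x - m)^2) / 2
  m2 <- sum((x - m)^2) / 3
  expect_equal(unname(mm["pi_mean"]), m)
  expect_equal(unname(mm["pi_var"]), v)
  expect_equal(unname(mm["pi_skew"]), (sum((x - m)^3) / 3) / m2^1.5)
  expect_equal(unname(mm["pi_kurt"]), (sum((x - m)^4) / 3) / m2^2)
})

test_that("single-locus reference tables carry 16 moment statistics", {
  spec <- free_spec(n_taxa = 4)
  rt <- simulate_reference_table(spec, n_sims = 3, n_samples = 8,
                                 mode = "mito", locus_length = 800,
                                 mu = 1e-6, seed = 24)
  expect_identical(dim(rt$summaries), c(3L, 16L))
  expect_identical(colnames(rt$summaries)[1], "K_mean")
  expect_true(all(is.finite(rt$summaries)))
  # haplotype counts bounded by the sample size
  expect_true(all(rt$summaries[, "K_mean"] >= 1 &
                    rt$summaries[, "K_mean"] <= 8))
  # a mutation-rate prior range draws per-taxon rates
  rt2 <- simulate_reference_table(spec, n_sims = 2, n_samples = 8,
                                  mode = "mito", locus_length = 800,
                                  mu = c(1e-7, 1e-6), seed = 25)
  expect_identical(dim(rt2$summaries), c(2L, 16L))
})

test_that("moments are permutation-invariant and degenerate cases flagged", {
  set.seed(23)
  stats <- matrix(runif(20), 5, 4)
  p <- sample(5)
  expect_equal(mito_moments(stats), mito_moments(stats[p, ]))
  const <- matrix(rep(c(1, 0.5, 0.01, 0), each = 3), 3, 4)
  expect_warning(mm <- mito_moments(const), "zero variance")
  expect_equal(unname(mm["K_skew"]), 0)
  expect_equal(unname(mm["K_kurt"]), 0)
})
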