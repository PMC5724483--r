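# Hyperprior construction, buffered event-time draws, taxon parameters and
# parameter summaries.

test_that("even zeta_T = 1 splits match the fixed per-psi taxon counts", {
  spec <- study_spec()
  w <- hyperprior_weights(spec)
  expect_equal(sort(unique(w$psi)), 0:5)
  # psi = 2 -> {0.5, 0.5}; psi = 3 -> {0.4, 0.3, 0.3}; psi = 5 -> five 0.2
  expect_identical(w$parts[w$psi == 2], "5+5")
  expect_identical(w$parts[w$psi == 3], "4+3+3")
  expect_identical(w$parts[w$psi == 4], "3+3+2+2")
  expect_identical(w$parts[w$psi == 5], "2+2+2+2+2")
  expect_equal(w$zeta_T[w$psi > 0], rep(1, 5))
  set.seed(1)
  d2 <- draw_codemo(spec, force_psi = 2)
  expect_equal(sort(d2$zeta_s), c(0.5, 0.5))
  d3 <- draw_codemo(spec, force_psi = 3)
  expect_equal(sort(d3$zeta_s), c(0.3, 0.3, 0.4))
})

test_that("psi = 0 means complete idiosyncrasy", {
  spec <- study_spec()
  set.seed(2)
  d <- draw_codemo(spec, force_psi = 0)
  expect_identical(d$psi, 0L)
  expect_length(d$zeta_s, 0)
  expect_identical(d$zeta_T, 0)
  expect_identical(d$sigma, spec$n_taxa)
  expect_identical(d$Psi, spec$n_taxa)
  tp <- draw_taxon_params(d, spec)
  expect_identical(anyDuplicated(tp$tau), 0L)  # beta > 0 forces distinct
})

test_that("dirichlet-process scheme weights all set partitions equally", {
  spec <- hyperprior_spec(4, "dirichlet_process",
                          tau_prior = c(1000, 100000),
                          epsilon_prior = c(0.01, 0.1),
                          n_prior = c(1000, 10000))
  w <- hyperprior_weights(spec)
  # exhaustive oracle: Bell(4) = 15 partitions; one has a single block
  expect_equal(sum(choose(3, 0:3) * c(1, 1, 2, 5)), 15)  # Bell recursion
  expect_equal(w$weight[w$Psi == 1], 1 / 15)
  expect_equal(w$weight[w$Psi == 2], 7 / 15)   # S(4,2) = 7
  expect_equal(sum(w$weight), 1)
  set.seed(3)
  draws <- replicate(6000, draw_codemo(spec)$Psi)
  freq <- tabulate(draws, 4) / 6000
  expect_true(all(abs(freq - w$weight) < 4 * prop_se(w$weight, 6000)))
})

test_that("scheme-1 draw frequencies match the constructed weights", {
  spec <- hyperprior_spec(10, "zeta_conditioned",
                          tau_prior = c(5000, 250000),
                          epsilon_prior = c(0.01, 0.1),
                          n_prior = c(50000, 250000))
  w <- hyperprior_weights(spec)
  expect_equal(w$weight[w$psi == 0], 0.5)       # P(psi = 0)
  expect_equal(sum(w$weight[w$psi == 1]), 0.5)  # zeta_T uniform within
  expect_equal(length(w$weight[w$psi == 1]), 9) # S_T in 2..10
  set.seed(4)
  n_draws <- 20000
  key <- replicate(n_draws, {
    d <- draw_codemo(spec)
    paste(d$psi, d$S_T)
  })
  obs <- table(key) / n_draws
  lab <- paste(w$psi, w$S_T)
  chi2 <- sum((as.numeric(obs[lab]) - w$weight)^2 / w$weight) * n_draws
  expect_lt(chi2, qchisq(0.999, df = length(lab) - 1))
})

test_that("buffer worked example splits the prior exactly", {
  adm <- buffer_admissible(c(10000, 1000000), 100000, 20000)
  expect_equal(unname(adm),
               rbind(c(10000, 79999), c(120001, 1000000)))
  # beta = 0 removes only the drawn point
  adm0 <- buffer_admissible(c(10, 20), 15, 0)
  expect_equal(unname(adm0), rbind(c(10, 14), c(16, 20)))
})

test_that("buffered event times always stay pairwise apart by more than beta", {
  spec <- study_spec()
  set.seed(5)
  for (r in 1:300) {
    psi <- sample(0:5, 1)
    d <- draw_codemo(spec, force_psi = psi)
    times <- c(d$tau_s, d$tau_i)
    beta_eff <- if (psi == 0) 10000 else 30000
    if (length(times) > 1)
      expect_gt(min(diff(sort(times))), beta_eff)
  }
})

test_that("the prior width caps the number of buffered events", {
  # width 245,001 with beta = 30,000: at most 9 mutually buffered events
  # (pairwise separation > beta needs (k - 1) * beta < width); 10 always
  # fails, however the first 9 land
  set.seed(6)
  for (r in 1:20)
    expect_error(codemo:::draw_buffered_times(10, c(5000, 250000), 30000),
                 "buffer infeasibility")
})

test_that("taxa sharing a pulse share its time exactly and priors are uniform", {
  spec <- study_spec()
  set.seed(7)
  d <- draw_codemo(spec, force_psi = 3)
  tp <- draw_taxon_params(d, spec)
  for (j in seq_len(d$psi)) {
    members <- tp$pulse_id == paste0("P", j)
    expect_equal(sum(members), d$S[j])
    expect_true(all(tp$tau[members] == d$tau_s[j]))
  }
  # nuisance marginals uniform on the stated ranges
  eps <- numeric(0); nn <- numeric(0)
  for (r in 1:500) {
    tpp <- draw_taxon_params(draw_codemo(spec), spec)
    eps <- c(eps, tpp$epsilon); nn <- c(nn, tpp$n_e)
  }
  ks_e <- suppressWarnings(ks.test(eps, "punif", 0.01, 0.10))
  expect_gt(ks_e$p.value, 1e-4)
  ks_n <- suppressWarnings(ks.test(nn, "punif", 50000, 250000))
  expect_gt(ks_n$p.value, 1e-4)
})

test_that("contraction taxa draw reciprocal size ratios", {
  spec <- hyperprior_spec(4, "psi_conditioned", psi_support = 0:1,
                          tau_prior = c(1000, 100000),
                          epsilon_prior = c(0.01, 0.1),
                          n_prior = c(1000, 10000),
                          scenario = c("expansion", "expansion",
                                       "contraction", "contraction"))
  set.seed(8)
  tp <- draw_taxon_params(draw_codemo(spec), spec)
  expect_true(all(tp$epsilon[1:2] < 1))
  expect_true(all(tp$epsilon[3:4] > 1))
  expect_true(all(tp$epsilon[3:4] >= 10 & tp$epsilon[3:4] <= 100))
})

test_that("dispersion index matches a two-pass oracle and scales linearly", {
  tau <- c(10000, 10000, 40000)
  ps <- summarize_params(list(tau = tau))
  m <- (10000 + 10000 + 40000) / 3
  v <- ((10000 - m)^2 + (10000 - m)^2 + (40000 - m)^2) / 2
  expect_equal(ps$e_tau, m)
  expect_equal(ps$omega_tau, v / m)
  # homogeneity: scaling tau by c scales both summaries by c
  ps3 <- summarize_params(list(tau = 3 * tau))
  expect_equal(ps3$omega_tau, 3 * ps$omega_tau)
  expect_equal(ps3$e_tau, 3 * ps$e_tau)
  # perfect synchrony
  expect_equal(summarize_params(list(tau = rep(7, 5)))$omega_tau, 0)
  expect_error(summarize_params(list(tau = c(0, 0))), "mean")
})

test_that("draw invariants hold across random specs and draws", {
  set.seed(9)
  for (r in 1:400) {
    n <- sample(4:12, 1)
    spec <- hyperprior_spec(n, "psi_conditioned",
                            psi_support = 0:sample(1:(n %/% 2), 1),
                            tau_prior = c(1000, 200000),
                            epsilon_prior = c(0.01, 0.1),
                            n_prior = c(1000, 50000),
                            beta = sample(c(0, 5000, 15000), 1))
    d <- draw_codemo(spec)
    expect_identical(d$Psi, d$psi + d$sigma)
    expect_equal(d$zeta_T, sum(d$zeta_s))
    expect_equal(d$S_T + d$sigma, n)
    expect_equal(d$S_T, round(d$zeta_T * n))
    if (d$psi > 0) {
      expect_true(all(d$zeta_s >= 2 / n & d$zeta_s <= 1))
      expect_true(!is.unsorted(d$tau_s, strictly = TRUE))
    }
    expect_length(d$zeta, d$Psi)
    times <- c(d$tau_s, d$tau_i)
    if (length(times) > 1)
      expect_gt(min(diff(sort(times))), spec$beta)
    expect_true(all(times >= 1000 & times <= 200000))
  }
})

test_that("Psi conversion under forced full synchrony", {
  spec <- study_spec()
  set.seed(10)
  for (psi in 0:5) {
    d <- draw_codemo(spec, force_psi = psi)
    expect_identical(d$Psi, if (psi == 0) 10L else psi)
  }
})

test_that("infeasible hyperprior constraints are rejected at build time", {
  expect_error(
    hyperprior_spec(6, "psi_conditioned", psi_support = 2,
                    zeta_T_min = 0.95, zeta_min = 0.45, zeta_max = 0.49,
                    tau_prior = c(1000, 10000),
                    epsilon_prior = c(0.01, 0.1), n_prior = c(100, 1000)),
    "empty admissible")
})
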