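# Shared fixtures, built in code.

# The co-expansion study design: n = 10 taxa, psi-conditioned hyperprior,
# zeta_T = 1 split evenly across pulses (psi = 0 means complete
# idiosyncrasy), pulse buffer 30,000 generations relaxed to 10,000 under
# psi = 0, and the standard study prior ranges.
even_split <- list("1" = 10, "2" = c(5, 5), "3" = c(4, 3, 3),
                   "4" = c(3, 3, 2, 2), "5" = c(2, 2, 2, 2, 2))

study_spec <- function(psi_max = 5, beta = 30000,
                       beta_overrides = c("0" = 10000)) {
  hyperprior_spec(10, "psi_conditioned", psi_support = 0:psi_max,
                  fixed_zeta = even_split[as.character(seq_len(psi_max))],
                  tau_prior = c(5000, 250000),
                  epsilon_prior = c(0.01, 0.10),
                  n_prior = c(50000, 250000),
                  beta = beta, beta_overrides = beta_overrides)
}

# A small free spec (idiosyncratic taxa permitted) for property tests.
free_spec <- function(n_taxa = 6, psi_max = 2, beta = 0) {
  hyperprior_spec(n_taxa, "psi_conditioned", psi_support = 0:psi_max,
                  tau_prior = c(1000, 100000),
                  epsilon_prior = c(0.01, 0.1),
                  n_prior = c(10000, 100000), beta = beta)
}

# Monte-Carlo tolerance: k standard errors of a proportion.
prop_se <- function(p, n) sqrt(p * (1 - p) / n)
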