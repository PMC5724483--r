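# codemo

Hierarchical co-demographic simulation and inference for comparative
population genomics.

## The problem

Comparative phylogeographers ask whether co-distributed taxa — say, ten
bird populations spanning a glacial refugium — expanded (or contracted) in
response to the *same* event, or idiosyncratically. codemo answers this
with a hierarchical co-demographic model: each of *n* independent
panmictic populations undergoes one instantaneous effective-size change,
from εᵢNᵢ to Nᵢ gene copies at time τᵢ generations before sampling, and
the change times co-vary across taxa through hyperparameters:

* **ψ** — number of synchronous pulses (events shared by ≥ 2 taxa),
* **σ** — number of idiosyncratic events (private to one taxon),
* **Ψ = ψ + σ** — total events,
* **ζ_T, ζ_s** — proportions of taxa in any pulse / in each pulse,
* **Ω_τ = Var(τ)/E(τ)** — dispersion index of the times (0 = synchrony).

Simulated data sets are summarised by the **aggregate site frequency
spectrum** (aSFS): per-taxon folded SFS, normalised, then sorted in
descending order *within* each frequency class and concatenated — an
exchangeable multi-taxa summary that needs no homology between taxa.
Single-locus (mitochondrial) data use 16 moment statistics of (haplotype
count, haplotype diversity, nucleotide diversity, Tajima's D) across taxa.
Hyperparameters are then estimated by **hierarchical ABC rejection** or
**hierarchical random-forest regression** on simulated reference tables,
with leave-one-out cross-validation machinery (Pearson's r, RMSE) to
calibrate designs before touching empirical data. A pulse buffer **β**
keeps distinct event times at least β generations apart a priori, which
markedly improves Ψ estimation.

The simulation engine emulates direct SFS simulation with one SNP per
independent genealogy: conditional on the coalescent level times, a SNP's
frequency class is a mixture over levels of the classical block-size
distribution, which lets a reference table of 5 × 10⁸ genealogies run on
one CPU in minutes (see the methods vignette for the equivalence argument
and its verification).

## Worked example

The truncated-hyperprior design: ψ ∈ {0, 1} with ζ_T = 1, i.e. either all
ten taxa co-expand in one pulse (Ψ = 1) or all behave idiosyncratically
(Ψ = 10), with β = 30,000 generations (10,000 under ψ = 0) and priors
τ ~ U{5,000, 250,000}, ε ~ U(0.01, 0.10), N ~ U{50,000, 250,000}:

```r
library(codemo)

spec <- hyperprior_spec(
  n_taxa = 10, scheme = "psi_conditioned", psi_support = c(0, 1),
  fixed_zeta = list("1" = 10),
  tau_prior = c(5000, 250000), epsilon_prior = c(0.01, 0.10),
  n_prior = c(50000, 250000),
  beta = 30000, beta_overrides = c("0" = 10000))

table <- simulate_reference_table(spec, sims_per_psi = 5000,
                                  n_genealogies = 5000, seed = 1001)

set.seed(2001)
cv <- loo_crossval(table, "rf", "Psi", pods_per_value = 20,
                   rf = list(n_cycles = 100, trees_per_cycle = 10,
                             per_class = 1000))
cv
#> cv_report: hRF estimation of Psi on 40 PODs (table of 10000)
#>   Pearson r = 0.981   RMSE = 0.8921

set.seed(2002)
loo_crossval(table, "abc", "Psi", pods_per_value = 20,
             retain = 1500, point = "mean")
#> cv_report: hABC estimation of Psi (mean) on 40 PODs (table of 10000)
#>   Pearson r = 0.944   RMSE = 1.616
```

Forty reference simulations are treated as pseudo-observed data sets (20
per Ψ value), each estimated from the remaining table. Pearson r ≈ 0.98
means the forest separates full synchrony from full idiosyncrasy almost
perfectly; the RMSE below one Ψ unit (on the 1–10 scale) reflects mild
shrinkage of predictions away from the extremes. The ABC posterior mean
over the 1,500 nearest simulations tracks slightly behind the forest.

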