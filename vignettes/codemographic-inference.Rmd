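---
title: "Hierarchical co-demographic inference with codemo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical co-demographic inference with codemo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Comparative phylogeography asks whether co-distributed taxa responded to the
same environmental event — a glacial retreat, a habitat fragmentation — at
the same time. codemo frames this as a hierarchical co-demographic model:
each of $n$ taxa is an independent panmictic population that underwent one
instantaneous change of effective size, from an ancestral size
$\varepsilon_i N_i$ to a current size $N_i$ (gene copies), at a time
$\tau_i$ generations before sampling. $\varepsilon_i < 1$ is a forward-time
expansion, $\varepsilon_i > 1$ a contraction.

The times co-vary across taxa through hyperparameters. Of $\Psi$ distinct
event times, $\psi$ are *synchronous pulses* shared by at least two taxa
and $\sigma$ are *idiosyncratic* (private to one taxon), with
$\Psi = \psi + \sigma$. The proportion of taxa in any pulse is $\zeta_T$,
the per-pulse proportions are $\zeta_s = \{\zeta_1, \dots, \zeta_\psi\}$
(each in $[2/n, 1]$, ordered so $\zeta_1$ labels the most recent pulse),
and the taxon counts are $S_T = \zeta_T n$ and $S = \zeta_s n$. Complete
synchrony is $\psi = 1, \zeta_T = 1$ ($\Psi = 1$); complete idiosyncrasy is
$\psi = 0$ ($\Psi = n$). The dispersion index
$\Omega_\tau = \mathrm{Var}(\tau)/E(\tau)$ summarises temporal spread:
zero under perfect synchrony. $\varepsilon$ and $N$ are per-taxon nuisance
parameters drawn independently from their priors.

### Hyperprior schemes

`hyperprior_spec()` supports three weightings over $(\psi, \zeta)$
configurations plus a constrained variant:

* **psi-conditioned** (default): each $\psi$ value in the support gets
  equal weight; within it each admissible $\zeta_T$ gets equal weight;
  within that each $\zeta_s$ multiset gets equal weight. A `fixed_zeta`
  table instead pins $\zeta_s$ per $\psi$ value — e.g. the even
  $\zeta_T = 1$ splits used throughout the validation experiments
  ($\psi = 3 \to \{0.4, 0.3, 0.3\}$, in random temporal order per draw).
* **zeta-conditioned**: the $\psi \in \{0, 1\}$ special case (complete
  idiosyncrasy, one pulse of varying size, or full synchrony), with
  $\Psi = 1 + n - S_T$ when $\psi = 1$.
* **dirichlet-process**: every set partition of the $n$ taxa weighted
  equally (blocks of $\ge 2$ are pulses, singletons idiosyncratic), the
  Chinese-restaurant-type prior; $P(\Psi = k) \propto S(n, k)$, the
  Stirling numbers, sampled exactly by the standard recursion.
* **custom**: psi-conditioned machinery plus min/max rules on $\zeta_T$ and
  the $\zeta_s$ elements. Only $\zeta$ grids with integer taxon counts are
  enumerated, since $S_T$ must be a whole number of taxa.

### The pulse buffer

Estimating $\psi$ is confounded when distinct pulses sit arbitrarily close
in time: many pulses clustered together look like one. The pulse buffer
$\beta$ (generations) requires all event times to be pairwise more than
$\beta$ apart, a priori: each successive draw comes from the prior range
minus the closed windows $[t - \beta, t + \beta]$ around the times already
placed (`apply_buffer()`; with integer arithmetic, a first draw of 100,000
under $\tau \sim U\{10^4, 10^6\}$ and $\beta = 20{,}000$ leaves
$U\{10{,}000, 79{,}999\} \cup U\{120{,}001, 10^6\}$). The prior width caps
how many buffered events fit ($(k-1)\beta$ must be less than the width).
Two subtleties are worth stating:

* Sequential placement can dead-end by bad luck even when a feasible
  arrangement exists. `draw_codemo()` restarts the whole placement up to
  100 times before raising a buffer-infeasibility error; `apply_buffer()`
  itself errors immediately.
* Under complete idiosyncrasy ($\psi = 0$) all $n$ times are buffered
  events; a per-$\psi$ `beta_overrides` entry (e.g. 10,000 instead of
  30,000 at $\psi = 0$) keeps that scenario feasible and temporally
  flexible. Whether idiosyncratic times are buffered at all is a spec flag
  (`buffer_idiosyncratic`, default TRUE — all $\Psi$ events are buffered).

## The simulation engine

Genomic-mode data are folded site frequency spectra in the
one-SNP-per-independent-genealogy setting: each of `n_genealogies`
genealogies contributes exactly one SNP, landing in derived class $i$ with
probability $\ell_i/\ell_{tot}$, the fraction of that genealogy's branch
length subtending $i$ leaves. The engine never builds trees: conditional on
the inter-coalescence level times $T_k$ (piecewise-exponential under the
size change), the SNP class is a mixture over levels $k$ (weight
$k T_k / \sum_j j T_j$) of the classical block-size law
$q(i \mid k, n) = \binom{n-i-1}{k-2}/\binom{n-1}{k-1}$, which is
independent of the times. Sampling a level and then a block size is
distribution-identical to building the tree, because exactly one SNP is
taken per genealogy; the equivalence is verified in the test suite against
a pure-R simulator with explicit topology. This is what makes reference
tables of $10^4$ simulations $\times$ 10 taxa $\times$ 5,000 genealogies
(5 x 10^8 genealogies) practical on one CPU.

`expected_sfs()` reports $E[\ell_i/\ell_{tot}]$ by high-replicate
averaging of the conditional class distribution (`method = "mc"`, the
default, valid for any demography). The constant-size closed form
(folded $1/i + 1/(n-i)$ weights) is also available; it is a ratio of
expectations, not the expectation of the ratio, and differs from the
sampler's true target by up to about 0.017 in the singleton class at
$n = 20$. That bias is documented and tested rather than hidden; the
convergence tests compare against the MC estimator.

Times are generations backward from sampling; $N$ is counted in gene
copies with coalescence rate $k(k-1)/(2N)$, applied consistently so the
standard prior ranges keep their intended scale. The size change is
instantaneous at $\tau$ exactly (times $\ge \tau$ use the ancestral size).

Single-locus mode (`simulate_sequences()`) builds one genealogy with
explicit topology and drops Poisson($\mu L \ell_{tot}$) infinite-sites
mutations on branches, each at a previously unused site; exceeding the
locus length is a saturation error, never silent recycling (the
reference-table path retries a saturated locus a few times, since under
the priors used it is a rare event).

## Summaries

The aggregate SFS (`build_asfs()`) normalises each taxon's folded SFS to
proportions and, independently within each frequency class, sorts the $n$
taxa's values in descending order, concatenating classes in ascending
frequency order (10 taxa x 10 classes = 100 bins). Per-class sorting
(rather than ranking taxa once globally) is chosen because it preserves
exchangeability exactly: the aSFS is invariant to taxon input order, which
is precisely the model's assumption that taxa are unidentified,
exchangeable units. The suite verifies both the invariance and that the
per-class multisets round-trip.

Single-locus mode reduces each taxon to (number of haplotypes, haplotype
diversity with the $n/(n-1)$ correction, nucleotide diversity per site,
Tajima's D with the 1989 constants; D of a monomorphic block is 0 with a
flag), then takes mean, variance (divisor $n-1$), skewness and kurtosis
(standardized central moments, kurtosis non-excess, zero-variance cases
mapped to 0 with a warning) of each across taxa: 16 statistics in the
fixed order K, H, pi, D x (mean, var, skew, kurt).

## Inference

`abc_reject()` implements simple-rejection ABC: summaries standardized
per statistic by the median absolute deviation of the reference column
(falling back to the standard deviation; invariant columns dropped),
Euclidean distance, and exact retention of `round(tolerance * n)` (or a
given count, e.g. the 1,500 used throughout the validation designs).
Point estimates are the mean and median of the retained values plus a
mode: plurality with lowest-value tie-break for discrete targets,
Gaussian-kernel density argmax (Silverman bandwidth, 512-point grid) for
continuous ones — "mode" is otherwise undefined and these conventions are
fixed here. `abc_model_select()` treats each discrete $\Psi$ as a model
(category posteriors are retained-count proportions) while still
exploiting the numeric $\Psi$ values for mean and median.

`rf_train()` builds the hierarchical random-forest regression: 100 cycles
of 10 trees, each cycle on a class-balanced subsample (1,000 simulations
per $\psi$, replaced between cycles), split candidates
$\max(\lfloor p/3 \rfloor, 1)$ — 33 for the 100-bin aSFS. Regression on
numeric $\Psi$ (variance-reduction splits), not classification, so
predictions are real-valued means over trees.

`pls_transform()` (backed by mixOmics) is retained as an optional
transformation — fit on a training subset, keeping the fewest latent
components explaining $\ge 95\%$ of summary variance — but the package's
own comparison finds it does not improve, and tends to degrade, forest
accuracy on aSFS tables, so it is not part of the default workflow.

## Validation machinery

`loo_crossval()` scores estimators on pseudo-observed data sets. The two
estimators deliberately treat exclusion differently: ABC excludes each POD
from its own reference set one at a time, while the forest removes all
selected PODs collectively and trains once. POD selection is stratified by
$\Psi$ value (`pods_per_value`) or unstratified (`n_pods`); cross-design
runs (PODs from an unbuffered table against a buffered reference table)
are supported via `pod_table`. Scores are Pearson's r and RMSE, with RMSE
on the $\Psi$ scale after the $\psi \to \Psi$ conversion (under forced
$\zeta_T = 1$, $\psi = 0$ maps to $\Psi = n$ and $\psi = k > 0$ to
$\Psi = k$; no special casing is needed since $\Psi = \psi + \sigma$).

## Reproducibility and file formats

One global seed expands into per-simulation substreams by a counter-based
scheme (`simulate_codemo(seed =, sim_offset =)`), so runs sharded across
machines, or resumed after interruption, concatenate to exactly the rows a
single run would produce; the suite asserts this through the text formats
too. Simulation directories are plain text at 6 significant digits: one
file per taxon plus one file per requested hyperparameter, parameter
vector or parameter summary; partial rows from an interrupted run are
detected and refused on resume. Empirical folded SFS import accepts the
dadi-style text dialect.

## Problem sizes used in the checks

The full-scale validation designs use reference tables of $10^5$ to
$10^6$ simulations. The package's own checks run the same designs at
reduced sizes chosen to keep a desk run practical while preserving the
qualitative structure:

* the truncated $\psi \sim U\{0,1\}$ experiment at 5,000 simulations per
  $\psi$ value with 1,500 retained, in both the acceptance script (three
  seed replicates, scores averaged) and the test suite (one replicate);
* the buffer comparison ($\beta = 0$ vs $\beta = 30{,}000$) at 1,000
  simulations per $\psi$ value over two seed replicates, with the forest
  at 50 cycles and 400 per class, and ABC retention at 2.5%;
* the PLS comparison on the free hyperprior at 4,000 simulations, judged
  on the rejection-mean estimator over 200 identical PODs (the rejection
  route has no forest-construction noise, so the paired comparison is far
  tighter).

At these sizes Pearson's r for synchrony estimation is stable across seeds
(about $\pm 0.01$ observed), but RMSE has substantial seed-to-seed
variance because a handful of genuinely ambiguous PODs (idiosyncratic
draws whose times happen to cluster) dominate the squared error; the
acceptance script therefore averages three replicates. Dispersion-index
recovery is slightly weaker at small table sizes than the full-scale
figures, and the buffer-ordering comparison is asserted on the mean of two
replicates for the same reason. Free-hyperprior estimation accuracy at
4,000 simulations is modest (r around 0.4), so the only PLS claim
resolvable at desk scale is that the transformation does not help;
detecting more than that would need far larger tables.

## What the generator does and does not emulate

Simulated taxa are ideal panmictic Wright-Fisher populations with free
recombination between SNPs (independent genealogies), no migration, no
selection, exact infinite-sites mutation, and identical sampling across
taxa. Real reduced-representation data violate all of these to varying
degrees — linked SNPs within loci, population structure, missing data and
unequal sampling (which the import path expects the user to have
projected to a common level). Passing checks therefore demonstrate that
the estimators recover hyperparameters *under the model*, not that the
model is adequate for any particular empirical system; robustness and
goodness-of-fit checks on empirical data remain the analyst's
responsibility.

## Known limitations

Exponential growth, multi-epoch histories, migration, unfolded spectra
and class masking beyond the basic layout are out of scope. The
composite-likelihood route is deliberately absent. Hyperpriors on
$\varepsilon$ or $N$ pulses (and their own buffers) are not implemented.
The Dirichlet-process scheme does not support stratified-by-$\psi$ table
construction, since $\psi$ is an emergent property of the partition.

## A worked example

```{r, eval = FALSE}
library(codemo)

spec <- hyperprior_spec(
  n_taxa = 10, scheme = "psi_conditioned", psi_support = c(0, 1),
  fixed_zeta = list("1" = 10),
  tau_prior = c(5000, 250000), epsilon_prior = c(0.01, 0.10),
  n_prior = c(50000, 250000), beta = 30000,
  beta_overrides = c("0" = 10000))

table <- simulate_reference_table(spec, sims_per_psi = 5000,
                                  n_genealogies = 5000, seed = 910)

set.seed(62)
cv <- loo_crossval(table, "rf", "Psi", pods_per_value = 20,
                   rf = list(n_cycles = 100, trees_per_cycle = 10,
                             per_class = 1000))
cv
```
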