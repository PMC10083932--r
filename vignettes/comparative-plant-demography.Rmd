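---
title: "Comparative plant demography with demopace: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative plant demography with demopace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(demopace)
```

## The problem

Population models for plant species of conservation concern are scarce
because the species themselves are data-poor. A practical workaround is to
find well-studied surrogate species whose life histories resemble the listed
species of interest. `demopace` implements the quantitative machinery for
that comparison: it screens stage-structured projection matrices, converts
them into a common set of age-based life-history traits, groups species by
trait similarity, asks how population growth would respond to perturbations
of survival, growth and reproduction in each group, and measures how much of
the trait variation is structured by shared evolutionary history.

## The demographic model

Each species enters as an annual stage-structured projection model
`A = T + F`: `T[i, j]` is the probability that an individual in stage `j`
survives the year and is found in stage `i` next year (so column sums of `T`
are stage-specific survival probabilities), and `F[i, j]` is the number of
sexual offspring in stage `i` produced per stage-`j` individual per year.
The dominant eigenvalue of `A` is the asymptotic growth rate `lambda`; its
right and left eigenvectors are the stable stage distribution `w` and the
reproductive values `v`.

### Eligibility screening

`validate_record()` applies nine conditions before any trait is computed:
unmanipulated study conditions; an explicit `T`/`F` decomposition with
`A = T + F` (checked at 1e-9); at least one year of study; annual
periodicity; stage- or size-based classification; mean/pooled/individual
matrix composition; at least 2x2 stages; survival issue (maximum column sum
of `T`) strictly below 1.05, tolerating small estimation error in survival;
and irreducibility of `A`. Conditions 1 and 3-6 are metadata flags — they
cannot be derived from the matrices and are trusted as supplied, mirroring
how matrix databases annotate records. The survival-issue rule is applied to
the maximum column sum; since the filter is pass/fail, "max column sum
< 1.05" and "no column sum >= 1.05" are the same rule.

### Age from stage

The stage model is collapsed onto an age axis by projecting a birth cohort
through `T` (the Markov-chain, age-from-stage decomposition). With birth
stage mixing `w0`:

* survivorship `lx(x) = sum(T^x w0)`, the probability of being alive at age
  `x` (`l0 = 1`);
* fertility `mx(x) = sum(F T^x w0) / lx(x)`, offspring per survivor at age
  `x` (defined as 0 where `lx = 0`);
* the fundamental matrix `N = (I - T)^-1` gives expected years spent in each
  stage.

`w0` defaults to all mass on the first stage. This is the dominant
convention for plant matrices, where fertilities are recorded into the
first (seed or seedling) row; the alternative `"offspring"` convention
(row sums of `F`, normalized) is kept as an option for sensitivity
analysis. The scalar Euler–Lotka identity
`sum(lambda^-(x+1) lx mx) = 1` is exact under the first convention whenever
offspring genuinely enter the first stage, and the test suite verifies it
on random life cycles of that form.

### The seven traits

* `lam` — dominant eigenvalue of `A` (per year).
* `Lmax` — longevity: the first age at which `lx` drops below a critical
  level, default 0.01.
* `H` — Keyfitz entropy, `H = (-sum lx log lx) / sum lx` (natural logs),
  the shape of the survivorship curve. Constant hazard (log-linear
  survivorship) gives `H = 1`; the package reports the numeric value only
  and leaves the Type I/II/III labeling to the user, because published
  conventions disagree about which side of 1 to call "Type I".
* `Lalpha` — age at first reproduction: the expected number of years before
  an individual first occupies a reproductive stage (a stage whose `F`
  column sum is positive), computed on the absorbing Markov chain in which
  reproductive stages absorb. Because death competes for absorption, the
  estimate conditions on ever reproducing; this matches what an
  individual-based cohort records when averaging the first-reproduction
  ages of the individuals that reproduce. The coarser "first age with
  `mx > 0`" variant is available via `method = "first_mx"`.
* `Lmean` — mean life expectancy, `sum(N w0)`, counting the birth year.
  Equivalently the total of the untruncated `lx` schedule; the two agree
  analytically for a common `w0`.
* `S` — degree of iteroparity: the Shannon entropy of the normalized
  distribution `p_x` proportional to `lambda^-(x+1) lx(x) mx(x)`. The age
  discounting follows the post-breeding-census Euler–Lotka weighting;
  because `p` is renormalized before the entropy is taken, `S` is robust to
  the census convention, and strict semelparity gives exactly `S = 0`.
* `Ro` — net reproductive rate, the dominant eigenvalue of `F N`.

Schedules are truncated at the first age with `lx < lx_tol` (default 1e-7)
or at `x_cap = 1000` years, whichever comes first; hitting the cap sets a
warning flag and the traits are computed on the truncated schedule. These
defaults keep all traits finite for any substochastic `T` while changing
them negligibly for life cycles that die out naturally.

### Normalization

Before clustering, each trait column is min-max rescaled:
`(y - min y) / (max y - min y)`, mapping every trait to `[0, 1]` so that
traits measured in years, nats and offspring counts contribute comparably.
A constant column maps to zero. The denominator is `max - min`; any other
reading of the transformation fails to land on `[0, 1]`, which the
downstream Bray–Curtis dissimilarity requires.

## Clustering and ordination

`bray_curtis()` computes `D[a, b] = sum|x_a - x_b| / sum(x_a + x_b)` on the
normalized traits (through `vegan::vegdist`); `upgma()` builds the
average-linkage dendrogram (`stats::hclust`), which is monotone, so merge
heights never invert; `cut_dendrogram()` cuts at a configurable height,
default 0.3, or into exactly `k` groups. Tie-breaking among equidistant
merges follows `hclust`'s deterministic order.

`select_k()` provides the K-means cross-check used to sanity-check the cut:
it profiles the within-cluster sum of squares over candidate `k` (25 random
restarts each, seeded) and recommends the elbow, located as the knee of the
profile — the point furthest below the chord joining the profile's endpoints
after rescaling both axes to the unit square. The rescaling makes the rule
invariant to the units of either axis; raw second differences, by contrast,
always favour the first large drop. The full profile is returned and written
out by the pipeline so the recommendation can be inspected.

PERMANOVA partitions the squared dissimilarities:
`SS_total = sum_{a<b} D^2/m`, `SS_within = sum_g sum_{a<b in g} D^2/n_g`,
`pseudo-F = ((SS_total - SS_within)/(g-1)) / (SS_within/(m-g))`, with
`p = (1 + #{F_perm >= F_obs}) / (n_perm + 1)` over seeded label
permutations (999 by default). Pairwise tests subset the distance matrix to
each label pair and report raw and Holm step-down adjusted p-values; both
are reported because no single adjustment convention dominates in this
literature. P-values are only computed where every group has at least two
members. The type-I error of the global test is verified by simulation in
the test suite (1000 null replicates at m = 20).

PCA (`pca_traits()`) runs on the centered — but not re-standardized —
normalized traits: min-max normalization already equalizes ranges, and
re-scaling to unit variance would re-weight the traits a second time.
Component signs are fixed so each loading's largest-magnitude entry is
positive.

## Elasticity analysis

`elasticity_matrix()` computes `e_ij = (a_ij / lambda) s_ij` with
sensitivities `s_ij = v_i w_j / <v, w>`; entries where `a_ij = 0` are
exactly zero and the matrix sums to 1 (de Kroon's property, asserted at
1e-6 and checked against a finite-difference oracle at 1e-4 in the tests).
`group_elasticities()` partitions the total into fertility (positions with
`F > 0`), growth (sub-diagonal `T` positions: progression) and survival
(diagonal and super-diagonal `T` positions: stasis and retrogression).
Published groupings differ on where retrogression belongs, so
`retrogression = "growth"` reassigns it; positions positive in both `T` and
`F` are split in proportion `T : F`, which preserves the sum-to-one
property exactly. Density summaries use a Gaussian kernel with Silverman
bandwidth and reflection at 0 and 1 (elasticities are bounded; an
unreflected kernel leaks mass), with degenerate strata shown as a narrow
peak (bandwidth 0.01) and strata below two species reported by median only.
The pipeline restricts density comparisons to clusters with at least
`min_cluster_size` (default 5) species, since density contrasts among
two- or three-member clusters are not robust.

## Phylogenetic signal

Under Pagel's lambda, tip traits are multivariate normal with covariance
`sigma2 * C(lambda)`, where `C(1)` is the Brownian-motion covariance
(shared root-to-MRCA path lengths) and `lambda` in `[0, 1]` scales only the
off-diagonals. `pagel_mcmc()` samples `(lambda, sigma2, mu)` by
Metropolis–Hastings:

* priors (the choice is the package's own; nothing in the underlying method
  prescribes them): `lambda ~ Uniform(0, 1)`,
  `log sigma2 ~ Uniform(-10, 10)`, `mu ~ Normal(mean(y), (10 sd(y))^2)` —
  weakly informative, with bounded support matching the lambda transform;
* proposals: reflective Gaussian walk for `lambda` on `[0, 1]`, Gaussian
  walk on `log sigma2`, Gaussian walk for `mu`; one randomly chosen
  parameter per generation;
* step sizes adapt toward 20-40% acceptance during burn-in only and are
  frozen afterwards, preserving detailed balance for the retained samples;
* defaults: 1e6 generations, 20% burn-in, thinning 100 (memory hygiene;
  the effective sample size is computed on the stored samples);
* the likelihood is evaluated through a Cholesky factorization, cached per
  accepted `lambda` so that `sigma2`/`mu` updates cost O(n).

The point estimate `eta` is the posterior median of the lambda chain with a
central 95% credible interval; convergence is flagged when the ESS of that
chain (Geyer initial-positive-sequence truncation of the autocorrelation
sum) reaches 200. Lambda is estimated independently per trait. Trees are
trimmed to the sampled species with `trim_tree()` (path lengths preserved);
`graft_missing()` adds an absent species at the midpoint of its sister
lineage's subtending branch, keeping tips contemporaneous on ultrametric
trees (on non-ultrametric trees the new branch is half the sister's
subtending branch, since no common tip height exists).

## What the synthetic data emulate — and what they do not

`make_archetype()` generates records along the fast-slow continuum. Each
archetype is a single base life cycle (fast: 3 stages, stasis 0.06,
progression 0.65, fertilities 3-10 from stage 2; intermediate: 4 stages,
stasis 0.45, progression 0.3, fertilities 1-5 in the last two stages; slow:
6 stages, stasis rising 0.7-0.9, progression 0.125, fertilities 0.1-1 in
the last two stages), and records are lognormal multiplicative
perturbations (`noise_sd = 0.1`) of the base, emulating between-study
sampling variation around a shared life history. Per-record uniform
redraws of the rates were deliberately rejected: near-unity stasis under
resampling produces heavy-tailed longevity that swamps the archetype
structure the fixture exists to provide. Columns of `T` exceeding 0.99
after noise are renormalized to 0.99, so records are valid by construction.
Death is implicit as `1 - colSums(T)` throughout.

These generators provide recoverable structure, realistic trait ranges and
exact distributional knowledge — which is what the tests need — but they do
not emulate several features of real compadre-style data: measurement error
correlated across matrix entries, seed banks and clonality, varying stage
definitions across studies, or taxonomic non-independence of sampling.
Passing the archetype-recovery and calibration tests therefore demonstrates
that the machinery is correct, not that any particular empirical clustering
is right.

`cohort_oracle()` is the package's independent check on the age-from-stage
analytics: an individual-based simulation through `T` whose empirical
survivorship, life expectancy, longevity and first-reproduction age are
compared with the analytic values within Monte-Carlo error (100 000
individuals, 50 random life cycles in the test suite). `yule_tree()` and
`simulate_bm()` provide seeded ultrametric trees and lambda-scaled
Brownian traits for the phylogenetic-signal checks.

## Numerical choices and degenerate inputs

* Eigen-analysis uses LAPACK (`eigen`); the dominant eigenvalue must be
  real within 1e-10 and eigenvectors are sign-flipped to the non-negative
  orientation guaranteed by Perron–Frobenius for irreducible matrices.
* `fundamental_matrix()` refuses spectral radius >= 1 ("immortal stage
  structure") rather than returning a misleading inverse.
* Zero rows in Bray–Curtis input are defined to be at distance 0 from each
  other; negative inputs are rejected with a pointer to normalization.
* A constant MCMC chain has ESS 1; chains shorter than 10 are refused.
* `iteroparity_entropy()` errors on non-reproducing schedules instead of
  returning 0, so a missing `F` cannot masquerade as semelparity.
* All stochastic stages (K-means restarts, permutations, MCMC, generators)
  take explicit seeds; `run_pipeline()` fans a single master seed out to
  named per-stage substreams, so a full run is bit-reproducible.

## Problem sizes used by the tests

The shipped test suite runs the full machinery at sizes chosen to give
stable statistical verdicts while remaining quick on a laptop: 100 random
matrices for elasticity conservation, 50 random matrices against a
100 000-individual cohort simulation, 1000 null replicates (999
permutations each, m = 20) for PERMANOVA calibration, and 10 + 10 seeded
lambda-recovery runs at 100 000 MCMC generations on 100-tip trees. The
MCMC default of 1e6 generations remains the analysis-scale setting; the
recovery tests scale it down tenfold, which the ESS diagnostics show is
already comfortably past convergence for trees of this size.

## Known limitations

* Periodic (seasonal) matrix products, stochastic environments and
  density dependence are out of scope; matrices are single annual models.
* Traits carry no uncertainty: point matrices give point traits.
* The elasticity analysis perturbs matrix elements, not lower-level vital
  rates; element elasticities conflate survival and growth where a single
  element encodes both.
* Pagel's lambda is the only signal statistic; no correlated-evolution or
  multi-trait models.
* The I/II/III survivorship-type labels are not assigned automatically (see
  `H` above).
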