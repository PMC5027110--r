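---
title: "Models and methods behind coexpair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coexpair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexpair)
```

`coexpair` analyzes how pairs of transcripts relate, non-linearly, to a
binary disease outcome, and how stable their co-expression is across
individuals. This vignette explains the statistical models, the tunable
parameters and their defaults, what the synthetic generators emulate, and
the numerical and design choices that were genuinely open.

## 1. Logistic screens on an unmatched cohort

For a cohort with per-sample expression $x$, outcome $y \in \{0,1\}$ and
covariates (age, sex, race by default), the package fits, by maximum
likelihood via `stats::glm`:

* single gene: $\mathrm{logit}\,P(y=1) = \beta_0 + \beta_A x_A + \gamma'z$;
* additive pair: adds $\beta_B x_B$;
* interactive pair: adds the product $\beta_{AB}\, x_A x_B$;
* path model, for an ordered path $R_1,\dots,R_k$: a main effect per node
  plus a product for every **consecutive** pair only,
  $\sum_i \beta_i x_i + \sum_{i<k} \beta_{i,i+1} x_i x_{i+1}$.

A pair is called *non-linearly interacting* when the Wald p-value of
$\beta_{AB}$ is below $\alpha = 0.05$, regardless of the main effects.
Each term's Wald test is reported; Wald and likelihood-ratio p-values
agree in rank to better than 0.95 on null screens (tested), so the cheaper
Wald test is used throughout, as is conventional.

**Standardization.** Expression is z-scored per feature before products
are formed (toggle `standardize = FALSE`). This makes coefficients
per-SD and matches the SD-step odds-ratio convention below. Because the
span of $\{1, x_A, x_B, x_A x_B\}$ is invariant to affine changes of
either axis, the interaction Wald p-value is unchanged by the toggle
(tested to $10^{-6}$); only the coefficient scale moves.

**Multiple testing.** Screens use the nominal $p < 0.05$ per pair, the
convention for candidate-panel screens of this kind; a Benjamini–Hochberg
adjusted column is emitted for the user but never used in classification.

**Degenerate inputs.** Zero-variance features are an error. Perfect
separation is flagged (`converged = FALSE`) rather than raised, so screens
over thousands of pairs keep running; flagged rows propagate. Samples with
missing covariates are dropped with a logged count; missing expression
values are rejected outright.

## 2. Matched resampling with conditional logistic regression

Population cohorts with rare cases and family structure need a matched
design: a control is *eligible* for a case when its age is within ±2 years
(boundary inclusive), its sex matches, and it comes from a different
family. `controls_per_case` defaults to 1 (the matching ratio is a free
design choice; 1:1 keeps strata maximally informative per control drawn).

Each of `n_resamples` replicates draws, for every case, a fresh control
set uniformly without replacement from its pool — no control is reused
within a replicate, and the case processing order is randomized per
replicate so that overlapping pools are shared fairly over the run. The
conditional (stratified) logistic likelihood is maximized with
`survival::clogit`; matching variables cancel within strata. Strata with
no exposure contrast are dropped; a replicate with no informative strata
records p = 1. With 1:1 matching and a binary exposure the estimate
reduces to the discordant-pair closed form $\log(n_{10}/n_{01})$ (tested
to $10^{-6}$).

Stability summaries per term: `fraction_significant` (exactly
`mean(p < alpha)`) and `median_p`. Two significance rules: median p
strictly below 0.05, or significance in at least half of the resamples.
A third, weaker call — *informativeness* — captures terms whose p-value
histogram is right-skewed without passing the median rule: a one-sided
Kolmogorov–Smirnov test against Uniform(0,1) in the stochastically-smaller
direction, with the extra requirement that the median p be below 0.5.
The extra clause is needed because the one-sided KS statistic also rises
when p-mass concentrates *above* 0.5 (e.g. a point mass at 0.9), which no
one would call evidence for the outcome; the original call was made by
visual histogram inspection, so this is our concrete operationalization.

The same machinery runs unchanged on SNP dosage columns (0/1/2 coding,
`standardize = FALSE`) including a product term for pairwise epistasis;
`filter_variants()` removes variants with minor-allele count below 10
first, since near-monomorphic variants make conditional fits unstable.

## 3. Odds-ratio curves and log-odds surfaces

For a fitted interactive pair model, the odds ratio of a one-SD increase
in gene A at gene-B level $b$ is closed form,
$\mathrm{OR}(b) = \exp\{sd_A(\beta_A + \beta_{AB} b)\}$: every covariate
term cancels in the ratio, so no reference values are needed. Its log is
affine in $b$ with slope $sd_A\,\beta_{AB}$ and crosses 1 at
$b = -\beta_A/\beta_{AB}$. The identity against direct evaluation of the
fitted predictor is verified to $10^{-10}$ at every grid point.

Grids default to 101 points spanning the empirical 1st–99th percentile of
the conditioning gene, on the fitted (z-score) scale; a binned histogram
export (`expression_histogram()`) accompanies curves so readers can see
where the population actually sits. Resample bands are pointwise
2.5/50/97.5 percentiles over per-replicate curves — bands come from
resampling, not the delta method.

The log-odds surface fixes covariates at reference values (mean for
continuous, mode for categorical; overridable) and evaluates
$\eta(a,b) = \eta_0 + \beta_A a + \beta_B b + \beta_{AB} ab$. Its mixed
second difference over any 2×2 sub-grid equals $\beta_{AB}\Delta a\Delta b$
— the saddle curvature *is* the interaction, and its sign is invariant to
orientation-preserving affine rescaling of the axes.

## 4. Consensus co-expression networks

The network stage asks a different question: not whether two transcripts
move with disease, but whether their dependence is *stable across
individuals*. Per subsample of individuals:

1. **Filter** (count data): keep transcripts non-zero in strictly more
   than 65 % of samples (`min_nonzero_frac = 0.65`).
2. **Discretize** each feature into `n_bins` equal-frequency bins
   (bin counts differ by ≤ 1; ties broken by stable sample order, making
   labels invariant to monotone transforms).
3. **Score** every pair with Rényi mutual information of order $\alpha$:
   the Rényi divergence between the empirical joint and the product of
   its marginals, in nats. It is symmetric, non-negative, zero exactly on
   product tables, and recovers plug-in Shannon MI as $\alpha \to 1$
   (all tested against brute-force summation).
4. **Prune** with the data-processing-inequality rule: in every triangle
   whose three edges are present, the strictly smallest MI edge is
   removed if it is below both others by more than `eps` (default 0);
   ties remove nothing, and all triangles are judged against the original
   MI values so the result is traversal-order independent.
5. **Support rule**: a surviving edge counts as "observed" only if its MI
   exceeds a per-pair permutation-null quantile (default: 95th percentile
   of 100 within-subsample permutations). Without some support rule every
   pruned graph is near-complete — plug-in MI is strictly positive on
   almost any finite table — and consensus frequencies saturate at 1,
   making "observed as co-expressed" meaningless.

The consensus matrix entry $M(i,j)$ is the exact fraction of the $k$
subsampled networks containing edge $(i,j)$. The retention threshold
$\tau = 0.5$ has a clean rationale: if a direct dependence is truly
stronger than an indirect one in the population, its sample MI exceeds
the indirect one's in at least half the resamples, so direct edges land
above 0.5 and indirect ones below — verified on planted Markov chains.
Edges between isoforms of one gene are legal and reported as such.

**Defaults for unstated knobs.** $\alpha = 0.5$ (the symmetric Rényi
order); `n_bins` $= \lceil I^{1/3}\rceil$ for subsample size $I$ (a
standard bias/variance compromise for plug-in MI on $I$ samples);
subsample fraction 0.8 without replacement; $k$ defaults to 50 000 for
small panels (≤ 200 features) and 300 for transcriptome-scale inputs,
the two regimes this design targets — desk-scale analyses should pass an
explicit, smaller `k`. All are exposed as arguments.

## 5. Relay paths

On the retained graph, `k_shortest_paths()` enumerates loopless paths by
best-first search ordered by (cost, lexicographic node sequence); cost is
hop count, or `1 - frequency` summed along the path with
`weight = "one_minus_frequency"`. The lexicographic tie-break makes
output independent of internal node ordering; agreement with exhaustive
enumeration is tested on random graphs. Paths are computed at transcript
level (isoforms may repeat a gene) and evaluated for disease relevance
with the path-chained logistic model; nodes and consecutive-pair edges
are flagged at $\alpha = 0.05$.

## 6. What the synthetic generators emulate — and what they don't

`simulate_cohort()` draws standardized multivariate-normal log-expression
with a chosen correlation structure; the outcome follows the logistic
model with planted main, product and covariate effects. Defaults: age
uniform on 40–80 years, sex 50/50, race 80/15/5, intercept −1 (case
fraction ≈ 0.27, typical of catheterization-cohort enrichment). Because
features are generated at unit variance, planted coefficients are per-SD
and directly comparable to fitted ones.

`simulate_family_cohort()` adds a shared Gaussian intercept per family to
every feature (SD 0.3) and uses a small marginal case rate; matching
removes the family effect by design, which is exactly why the matched arm
exists. Note the family component inflates each feature's total SD to
$\sqrt{1 + 0.3^2} \approx 1.044$, so per-SD estimates from the matched
arm sit correspondingly above the planted per-unit value. Ages are
redrawn (bounded retries) until every case has an eligible control.

`simulate_count_matrix()` maps latent Gaussian motifs — first-order
chains (Z depends on Y only, so the DPI holds by construction),
equicorrelated triangles, shared latent factors — through an exponential
link to negative-binomial counts (overdispersion 0.5; raw read counts
are overdispersed and NB is the standard model), with per-transcript
zero inflation and an optional poorly-expressed block (zero fraction 0.5)
that fails the 65 % filter by construction.

Not emulated: array probe-level artifacts, batch and platform effects,
library-size variation, genotype→expression (eQTL) coupling, and
linkage between family structure and expression beyond a shared
intercept. Passing tests therefore demonstrate the *statistical
machinery* is correct and calibrated under the stated generative
assumptions; they do not certify robustness to the technical artifacts
of any particular platform.

## 7. Problem sizes used in the test suite

Calibration and recovery checks run at sizes chosen to make Monte-Carlo
error small relative to the tolerances they assert: 2000 null cohorts of
n = 500 for type-I error (binomial SE ≈ 0.005 against a ±0.01 band);
n = 5000 cohorts, averaged over replicates, for 3-SE parameter recovery;
500 conditional-logistic resamples spread over 10 independent null
cohorts; consensus networks with k = 200 resamples of n = 2000 samples
for the chain-separation property; 50 random graphs of ≤ 8 nodes against
the exhaustive path oracle.

## 8. Known limitations

* Wald inference is asymptotic; at strong planted effects and modest n,
  single-fit estimates can sit several SE from truth by chance, which is
  why recovery checks average replicate fits.
* The permutation-null support rule makes "observed co-expression"
  well-defined but adds a tuning pair (`n_null`, `null_quantile`);
  results at very small subsample sizes are sensitive to the bin count.
* `k_shortest_paths()` is exact but enumerative; it is intended for the
  sparse retained graphs this pipeline produces, not dense graphs with
  exponentially many equal-length paths (a `max_pop` cap guards against
  pathological inputs).
* Conditional logistic fits silently lose strata without exposure
  contrast; with tiny pools this can leave few informative strata, and
  the p = 1 convention for empty replicates is conservative.
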