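---
title: "Topic models for multi-omic gut microbiome integration: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topic models for multi-omic gut microbiome integration: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`topicomics` implements a topic-model workflow for integrating several omic
measurements (16S amplicon variants, metagenomic and metatranscriptomic KEGG
orthologs, metabolites) taken on the same stool samples. This vignette is the
package's own account of the statistics: the model, the tunable parameters
and their defaults, the synthetic cohort the tests run on, the numerical
choices, and the known limitations. Nothing here states an empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The model

Latent Dirichlet Allocation treats each sample as a "document" and each omic
feature as a "word". With $K$ topics over a vocabulary of $V$ features:

$$\theta_d \sim \mathrm{Dir}(\alpha), \quad \beta_k \sim \mathrm{Dir}(\gamma),$$
$$z_{dn} \mid \theta_d \sim \mathrm{Mult}(1, \theta_d), \quad
  w_{dn} \mid z_{dn} \sim \mathrm{Mult}(1, \beta_{z_{dn}}),$$

for documents $d = 1 \ldots D$ and tokens $n = 1 \ldots N_d$. A topic is a
probability vector over features — a latent sub-community or sub-process —
and $\theta_d$ is sample $d$'s mixture over those processes. Because all
omics are measured on the same samples, topics fitted *independently per
omic* can be correlated across omics through their per-sample attributions;
clusters of such correlated topics are the "cross-omic topics" the pipeline
exists to find.

### Inference

`fit_lda_gibbs()` runs a collapsed Gibbs sampler (compiled, in `src/`) over
the token expansion of a discretized count table, with the standard
conditional

$$p(z_i = k \mid \cdot) \propto (n_{dk} + \alpha)\,
  \frac{n_{kv} + \gamma}{n_k + V\gamma}.$$

$\theta$ and $\beta$ are **posterior means** of the smoothed count ratios,
averaged over post-burn-in sweeps (every `thin`-th). A last-sample estimate
would be noisier and no cheaper; the posterior mean also makes the $K = 1$
case an exact closed form, which the tests pit against the sampler.
Defaults: $\alpha = 50/K$, $\gamma = 0.1$, 2000 iterations, 500 burn-in,
thin 10 — common practice for collapsed Gibbs LDA; every one is exposed.
All randomness flows through R's RNG, so a seed fixes the chain bit-for-bit.
Token expansion is capped at $10^5$ tokens per document (proportional
downscaling) to bound memory; all-zero samples error by default and are
dropped with a warning in pipeline mode.

## Normalization

Counts are divided by per-sample size factors, log-transformed
($\log_2(x+1)$, which preserves zeros), and rounded half-to-even back to
integers for the count-based sampler. The rounding convention is unbiased;
the pseudo-count keeps sparse tables sparse. `rle_size_factors()` is the
median-of-ratios estimator (the RLE / DESeq family): the size factor of a
sample is the median over reference features of count / feature geometric
mean. The reference set is the all-positive features; for sparse omics where
none exists, features positive in ≥ 90% of samples are used with geometric
means over their positive entries — the published estimator does not define
zero handling, so the fallback is ours and is stated here.

Which normalization to use is itself data-driven (`select_normalization()`):
in a sibling-pair cohort, siblings share environment and genetics, so a good
normalization should shrink the **sibling distance ratio** — mean distance
between the two siblings of a family over mean distance between samples of
different families. The grid runs eight community-ecology distances
(manhattan, euclidean, canberra, clark, Bray–Curtis, kulczynski, jaccard as
the Bray–Curtis transform $2B/(1+B)$, alt-Gower), all via `vegan::vegdist`
conventions; distances are computed on log-normalized values (the scale the
model trains on — the choice is ours and configurable). The winner is the
candidate taking the most metrics, ties to the first listed.

## Choosing the number of topics

For each candidate $K$ the fitted model simulates tables at the observed
per-sample depths, and three posterior-predictive correlations compare
simulated to observed (`fit_metrics()`):

1. **sample-quantile**: Pearson correlation of concatenated per-sample
   1st–99th percentiles (linear interpolation; the percentile grid is our
   choice, the published method does not fix one);
2. **feature-quantile**: the same with features and samples swapped;
3. **pairwise-marginal**: correlation between the upper triangles of the two
   feature–feature correlation matrices — "correlation of feature
   correlations", the most diagnostic of the three because it tracks whether
   the model reproduces feature co-occurrence.

Each is averaged over `n_simulations` (default 5) simulated tables.
`select_k()` formalizes the elbow: the smallest $K$ whose pairwise-marginal
metric is within `rel_tolerance` (default 0.02, relative) of its maximum
*and* whose other two metrics are within twice that of theirs. When no
candidate satisfies the conjunction the rule falls back to the
pairwise-marginal condition alone, since that metric is the stated priority.
Feature–feature correlations are computed on the discretized training-space
values. Pearson is used for all three ("correlation" is otherwise
unspecified).

## Cross-omic topics

Each topic is represented by its attribution vector — its $\theta$ column
restricted to the samples shared by all omics. `cluster_topics()` builds
average-linkage trees per distance metric (manhattan, euclidean,
inverse-correlation) and scores every candidate cluster count $n$ by the
mean over clusters of (mean within-cluster pairwise distance)/(mean distance
from members to all non-members), averaged over metrics; singletons
contribute zero within-distance. The selected $n$ is the smallest whose
score is within 5% (relative) of the minimum. Final labels at that $n$ come
from the tree on $1 - \rho_{\mathrm{Spearman}}$, matching the convention of
clustering topics by their correlation across samples; per-metric labels are
also returned.

**Known limitation.** Because singletons score zero, the ratio curve
decreases toward large $n$ on noisy data and the 5% rule can select a
near-singleton clustering; the published criterion ("minimized adequately")
was a visual judgment. The analysis scripts therefore print the whole curve,
and downstream stages can be run at a chosen count — mirroring the original
study, which fixed its cluster count before null validation.

`null_validation()` tests whether within-cluster correlation exceeds chance:
each of 15 null tables redraws every sample from a multinomial whose total
is that sample's own total and whose probabilities are the empirical feature
distribution of a uniformly chosen *other* sample; LDA is refit with the
true fits' $K/\alpha/\gamma$/schedule/seeds; topics are clustered into the
same number of clusters as the true data (reusing the count follows the
original procedure); and within-cluster topic pairs with Spearman $p < .05$
(*uncorrected* — the counting rule is deliberately literal) are counted.
Spearman $p$-values use the $t$ approximation with $n - 2$ df and
average-rank ties.

A topic whose total attribution dwarfs all others (≥ 10× the runner-up —
"orders of magnitude" made operational) *and* that owns no feature passing
the interpretation criteria is flagged by `flag_dominant_topic()` and can be
excluded before pooling: such a topic orders no samples and sways every
downstream clustering.

Samples are clustered on their pooled attribution vectors with
$1 - r_{\mathrm{Pearson}}$ distance and complete linkage (the default of the
heat-map tooling this convention comes from), cut at 2; the sibling
co-clustering rate is reported when metadata is supplied. Topic clustering
uses average linkage; both linkages are configurable since neither is fixed
by the published description.

## Interpreting topics

`select_topic_features()` keeps a feature when both of:

1. **specificity**: $\max_k \beta_{kv} > \mathrm{median}_k\,\beta_{kv} +
   1.5\,\mathrm{SD}_k(\beta_{kv})$ — excluding features ubiquitous across
   topics. (The source material states this criterion once as "more than"
   and once as "less than"; only "more than" excludes ubiquitous features,
   so that reading is implemented.)
2. **drivers**: SVD of the column-centered $\beta$ (centering isolates
   between-topic variation); the feature's absolute loading on any of the
   top $K-1$ right-singular axes must exceed the chosen percentile of
   absolute loadings on that axis (99 for 16S/metabolite-scale tables, 99.9
   for the ten-thousand-feature KO tables; absolute rather than signed
   loadings, since a direction's sign is arbitrary).

Each passing feature is attributed to its argmax topic.
`topic_metadata_correlation()` reports Spearman $\rho$ and $p$ per
(topic, covariate) with pairwise deletion of missing values and a
significance star at uncorrected $p < .05$, matching exploratory
topic–metadata heat maps.

## Differential abundance within sample clusters

Within each sample cluster, case vs control testing runs on normalized
log-scale values (not the discretized model input):

1. `boruta_trial()`: the table is extended with a permuted shadow copy of
   every feature; a random forest (via `ranger`, permutation importance =
   mean decrease in OOB accuracy) is fit `n_runs` times; each column's
   $Z$ = mean/SD of importance across runs; a feature is *important* iff its
   $Z$ exceeds the maximum shadow $Z$. The shadow permutation is drawn
   **once per trial**: with fixed shadows, features and shadows are
   exchangeable under a global null and the max-shadow rule is conservative
   (each feature wins with probability $\approx 1/(F+1)$). Re-permuting
   shadows inside every run — a plausible alternative reading — is
   measurably anti-conservative, because a feature's chance correlation with
   the labels persists across runs while a fresh shadow's does not.
2. `tally_and_test()`: the trial is repeated (fresh shadows each repeat,
   default 100; the tests use a reduced 20×25×100-tree profile), verdicts
   are tallied, and features at or above the 90th tally percentile (linear
   interpolation, ties included; an all-zero tally yields an empty report)
   go to a two-sided Wilcoxon rank-sum (exact for small tie-free groups,
   else normal approximation with continuity correction) with
   Benjamini–Hochberg adjustment **over the survivor set only**, reported at
   adjusted $p < .05$.

**Known limitation.** Filtering and testing use the same samples, so the
survivor set is enriched for chance label associations and BH within it does
not control the null error rate: on fully null data the probability of a
non-empty report is about 0.15–0.2 at the reduced profile (the acceptance
suite measures this), not the ≤ 0.1 one might hope for. This is a property
of the filter-then-test design itself; power on planted fold-changes and the
empirical false-discovery proportion are measured alongside it. A fold
change planted on a feature with near-zero baseline counts is undetectable
in principle, so the power checks plant on abundant features.

## Generalization across cohorts

`beta_cosine_distance()` turns a fitted $\beta$ into a feature–feature
cosine distance matrix over the $K$ topic dimensions: features that load on
the same processes are close regardless of abundance. `mantel_test()`
compares two such matrices on their common features: observed $r$ is the
Pearson correlation of upper triangles; the null jointly permutes the rows
*and columns* of one matrix (permuting rows alone would break symmetry and
is not a valid Mantel null); $p$ is one-sided for concordance with the
add-one convention $(1 + \#\{r^\ast \ge r\})/(1 + P)$, and a $z$-score
against the permutation null is reported alongside. One unified permutation
scheme yields both the $r$-based $p$ and the $z$, since nothing suggests
the two published numbers used different schemes.

## The synthetic cohort generator

`generate_cohort()` produces the structure every stage assumes, so the whole
pipeline is testable without any downloads:

- **sibling pairs**: each family draws a topic vector from
  $\mathrm{Dir}(\alpha)$; each sibling's $\theta$ is
  $s \cdot \text{family} + (1-s) \cdot \text{individual draw}$ with
  $s$ = `sibling_correlation` (default 0.5 — no quantitative
  sibling-similarity figure exists to calibrate it, so the midpoint is a
  declared free choice); one sibling is case, the other control;
- **shared processes**: one $\theta$ per sample drives *all* omics (their
  $\beta$s differ) — the structural premise of cross-omic topics;
  `shared_theta = FALSE` draws independent $\theta$ per omic and is the
  negative control;
- **counts**: multinomial at depth $N_d$ from $\theta_d^\top \beta$, so
  column sums are exact;
- **covariates**: linear in $\theta$ plus Gaussian noise (only the
  *existence* of topic–diet correlation is established empirically; the
  mechanism here is the simplest that produces it);
- **planted differentials**: `plant_differentials()` scales case-sample
  expected counts by $2^{\mathrm{log2FC}}$ — binomial thinning below 1,
  added Poisson counts above 1, both exact in expectation.

Default test scale is 20–40 families, $V$ = 60–300, $N_d$ = 1000–3000,
$K_{\text{true}}$ = 3–4: large enough for recovery, small enough that the
full suite runs in minutes on one CPU. The generator does **not** emulate
sequencing error, compositional closure artifacts, batch effects, realistic
taxonomies, or metabolite chemistry — passing tests demonstrate that the
algorithms recover the structure they assume, not that real stool data
satisfies those assumptions.

## Numerical choices and degenerate inputs

- Distance matrices are symmetrized to kill floating-point asymmetry;
  constant sample vectors get inverse-correlation distance 1 with a warning.
- Quantiles everywhere use R's default linear interpolation (type 7).
- Ties in Spearman correlations use average ranks.
- Topic-count selection at flat metric curves returns the smallest
  candidate; tie-breaks in normalization selection go to candidate order.
- `align_omics()` orders shared samples lexicographically so every
  seed-fixed run is reproducible; repeated samples per individual can be
  collapsed with `first_sample_per_individual()` (first in metadata order —
  how the original 81-sample subset was collapsed is not recorded, so the
  rule is explicit and replaceable).
- Per-stage seeds in `run_pipeline()` derive from the global seed by a
  counter scheme, keeping every stage independently reproducible.

## Problem sizes used by the checks

The acceptance checks run, per fresh seed: topic recovery at
$D = 200, V = 50, K = 3, N_d = 500$; topic-count selection at
$D = 60, V = 40$ over $K \in 2..6$; a three-omic shared-$\theta$ cohort of
30 families with a 15-table null ensemble (and 10 independent-$\theta$
cohorts as negative controls); differential power/FDP on 20 families at the
reduced forest profile; Mantel calibration over 100–200 null replicates at
999 permutations plus a split-cohort replication. These sizes are the
package's declared desk-scale study conditions.
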