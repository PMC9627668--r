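---
title: "Methods: models, calibration and design choices in metaboline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, calibration and design choices in metaboline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`metaboline` analyses replicate-structured, untargeted metabolomics of
cell-line panels. This vignette documents the statistical models behind each
stage, the assumptions the synthetic-study generator encodes, the numerical
conventions, and the choices we made where the design was genuinely open.
Everything quantitative stated here is computed by the test suite or the
worked example in the README; nothing is quoted from elsewhere.

## 1. The data model

A study is a samples × features intensity matrix plus per-sample metadata
(cell line, tissue, biological replicate, technical replicate, injection
index, confluency, batch, plate, optional doubling time). On the natural-log
scale the generator composes each intensity as

```
log x[s, f] = baseline[f] + tissue[t(s), f] + line[l(s), f]
            + bio[c(s), f] + tech[s, f]
            + drift(i(s)) * scale[f] + conf_coef * (confluency[c(s)] - 0.65)
            + batch_offset[b(s), f] + plate_offset[p(s), f]     (batch subset only)
```

and exponentiates. All standard deviations below are in natural-log units.

Key structural commitments, each of which is a statement about how real
panels behave rather than a convenience:

* **Technical replicates are consecutive injections of one extract.** They
  share the culture's confluency and (nearly) its drift offset. Without
  this, shared injection artifacts would inflate technical-pair distances
  and the technical replicate AUC would drop *below* the biological one —
  the opposite of what replicate-structured MS data show.
* **Confluency is a culture property**, drawn Uniform(0.3, 1) per
  (cell line, biological replicate) and applied as a multiplicative factor
  on total intensity (`confluency_effect = 1.0` by default).
* **Batch and plate are culture-level factors** (experiment round, culture
  plate), not blocks of the injection sequence. Injection-contiguous blocks
  would be smooth functions of injection order and the Lowess drift
  correction would silently absorb them, leaving the ANOVA batch filter
  with nothing to detect.
* **Cell-line effects are low-rank.** `n_latent_factors = 4` shared
  programs carry `latent_frac = 0.6` of the between-line variance
  (`between_line_sd = 0.5`). With independent features, distances between
  samples concentrate so strongly that the biological AUC pins at a purely
  combinatorial ceiling; co-regulated programs spread the distance
  distributions the way real metabolite panels do.
* **Some cultures diverge.** `bio_outlier_frac = 0.08` of cultures get
  their biological noise SD (`noise_sd_bio = 0.15`) multiplied by
  `bio_outlier_mult = 5`. This is what keeps the *post-normalization*
  biological AUC in the low-0.9 range instead of at the ceiling, matching
  the reproducibility levels reported for large MS panels. Technical
  replicates share the culture state and are unaffected.
* **Drift** is a shared shape — linear trend plus 1.5 periods of a
  sinusoid, per-feature amplitude scaled Uniform(0.5, 1.5) — with default
  amplitude 0.8. The sinusoid is orthogonal to the linear term, so the
  correction has to be genuinely nonparametric.
* **Noise ordering** `noise_sd_tech (0.05) < noise_sd_bio (0.15) <
  between_line_sd (0.5)` produces technical AUC > biological AUC > 0.5.
* **Baseline** log-mean defaults to `log(2^26) - log(n_features) - 0.5`, so
  the per-sample log2 total intensity sits near 26 for any panel size
  (total ion current is an instrument property); the low-intensity cutoff
  of 25 then has the same meaning at 60 features as at 300.

What the generator does **not** emulate: raw spectra, m/z peaks, retention
times, adduct or HMDB assignment, missing values, heteroscedastic
(intensity-dependent) technical noise, and correlated drift across batches.
A green test therefore establishes that the statistics recover planted
structure of the modelled kinds — not that the pipeline is robust to peak
picking or annotation error, which are upstream of its inputs.

## 2. Normalization chain

The stage order is fixed: injection drift → low-intensity removal →
confluency → batch/plate filter. Corrections are fitted on log intensities
and back-transformed (artifacts in MS data are multiplicative), using
`stats::lowess` with 2 robustness iterations; the drift span defaults to
0.3 and the confluency span to 0.5 (the confluency trend is a single smooth
monotone curve, so a wider window is appropriate). After subtracting a
fitted curve, each feature is re-centred at its pre-correction mean, so the
correction never changes a feature's overall level.

The replicate ROC AUC is computed from Euclidean distances on log10
intensities (z-scored matrices are used as-is) with the Wilcoxon midrank
formulation, so tied distances contribute 0.5. At the biological level the
negative class includes technical pairs, which are nearly always closer
than biological pairs; the biological AUC therefore has a combinatorial
ceiling below 1 (0.9913 for the default 20 × 3 × 2 design).

The batch/plate filter ranks features by `min(p_batch, p_plate)` from
one-way ANOVAs on log intensities and sweeps removal counts (every count to
50, then steps of 5), recomputing the biological AUC each time; the
AUC-maximizing count wins, ties to the smallest count. The sweep is
deterministic given the matrix, so the tie-break matters only on exact
plateaus.

## 3. Rank-based pathway activity

Features are ranked by average abundance across cell lines (rank 1 =
highest; average ranks on ties) and within each line; a pathway's rank-sum
change in a line is `Σ_members (bulk rank − line rank)`.

Two consequences worth stating explicitly:

* The input must preserve the bulk abundance ordering, so pathway activity
  consumes replicate-averaged **log10 intensities**. Z-scoring sets every
  feature mean to zero and reduces the bulk ranking to noise; z-scored
  matrices are for the association analyses.
* Rank-sum change is antisymmetric under negation of the whole matrix
  (both orderings reverse). Reversing a single line with the bulk held
  fixed does *not* negate it in general — the property test asserts the
  former, not the latter.

Significance uses the minimum-hypergeometric (mHG) statistic: order
features by delta (descending for the increase test, ascending for
decrease), and take `s = min over prefixes n of P(X ≥ k_n)` with
`X ~ Hypergeom(N, K, n)`. The minimum over all prefixes is attained at a
member position (between members the upper tail only grows), so only K
tails are evaluated. Because `s` is a minimum of dependent tails it is not
a p-value; it is calibrated by

* **exhaustive enumeration** of all `choose(N, K)` placements when that
  count is ≤ 5000 (exact null fraction, no smoothing),
* **Monte-Carlo** otherwise, `(#{s' ≤ s} + 1) / (n_perm + 1)`, which can
  never return 0, or
* a **Bonferroni bound** `min(1, s · K)` — the speed default inside the
  per-(line, pathway) scan, conservative but rank-preserving.

Direction labels need both `p < alpha` (0.05) and `|rank-sum change|`
above `350 · n_features / 1099`: the conventional ±350 cutoff is calibrated
for a 1,099-feature panel, and the maximal attainable rank-sum change
scales linearly with the feature count, so raw reuse at other panel sizes
would be meaningless. A pathway is flagged for reporting when
≥ 40 % of lines reach `p < alpha`.

## 4. Association models

For each (gene, feature): OLS of the z-scored feature on a mutation
indicator plus one-hot tissue dummies (reference level dropped), over lines
with known status; the mutation coefficient's T-statistic is the score.
T-statistics, unlike p-values, do not saturate at extreme significance,
which keeps ranking meaningful. Conventions:

* minimum group size 3 mutants and 3 wild-type (below that the T-statistic
  is unstable);
* a gene whose indicator lies in the span of the covariates (e.g. mutation
  ≡ one tissue) is skipped with a `collinear` flag — the criterion is a QR
  residual projection of the indicator on the covariates, not the design's
  overall rank, so redundancy among tissue dummies alone is repaired by
  dropping columns instead;
* fits are vectorised: one QR per gene, all features solved together;
* two-sided p-values throughout.

`tissue_adjust = FALSE` exposes the unadjusted model; the confounding test
shows a tissue-enriched decoy mutation stays in the null range with
dummies and inflates without them.

Differential abundance uses the pooled-variance two-sample T with BH
adjustment; the volcano's x-axis is the mean level on the matrix's own
scale.

## 5. Score, drug and network analyses

Score–metabolite correlation is plain Pearson over the shared lines
(pairwise-complete, no imputation — imputing would fabricate signal).
Pathway enrichment ranks features by |r| and applies mHG; the association's
direction is the sign of the mean member correlation — signed −log10 p
displays need a sign rule, and the mean member r is the simplest statistic
consistent with the |r|-based ranking. The signed statistic is
`−log10(p_adjusted) × direction`, so a pathway at `p_adjusted = 1`
contributes 0.

For drugs, ln IC50 is the sensitivity score (GDSC convention): positive
signed statistics mean higher pathway activity associates with resistance.
Drug pairs are compared by Pearson correlation of their signed pathway
vectors; strongly anticorrelated pairs are candidate "always sensitive"
combinations, and known synergies (ZIP > 0, strict) are tested for
concentration among them by mHG down the ascending-r ranking.

The correlation network links any two columns (genes log1p-transformed;
metabolites on their given scale) with Pearson r above the threshold —
signed by default (a literal reading of "correlation coefficient > 0.8");
`absolute = TRUE` exposes the alternative. "Strongly connected components"
degenerates to plain connected components on an undirected graph, which is
how they are computed (via igraph). Component ORA uses the graph's
same-typed node set as the universe, so enrichment is relative to what the
network could have contained.

## 6. Mutation subtypes and permutation machinery

Class–pathway association: per mutation class (protein-change classes such
as DNA-contact vs conformation; unclassified mutants are excluded rather
than pooled, which would dilute class-specific signal), the differential
set against wild type is tested per pathway with a two-sided Fisher exact
test on the 2×2 table over the measured universe, BH across (class,
pathway). The two-sided p follows the point-probability rule — the sum of
the probabilities of all tables (fixed margins) no more probable than the
observed one — implemented directly from the hypergeometric mass so the
test agrees with an enumeration oracle to machine precision.

The pathway similarity tree is average-linkage clustering on
`1 − Pearson r` between pathway rank-sum-change vectors, emitted as Newick
with branch lengths from merge heights; columns are name-sorted first so
ties break deterministically. This is a deliberate reduction of
WGCNA-style module detection to its testable core (grouping plus class
association) without soft-thresholding machinery.

Permutation tests: the tissue adjacency score counts equal adjacent labels
in a display order. When the number of distinct multiset orderings is ≤
`factorial(8)`, the null is enumerated exactly; otherwise Monte-Carlo with
+1 smoothing (`n_perm` defaults to 10,000 — a desk-scale stand-in for the
millions used on cluster hardware; the flag accepts any value).

## 7. Numerical conventions and degenerate inputs

* Ranks use average ties everywhere.
* Z-scoring uses the sample SD (n − 1); zero-variance features are dropped
  with a warning, and z-scoring is idempotent to ~1e-12.
* Exhaustive-vs-observed comparisons use a relative tolerance of 1e-9 when
  counting `s' ≤ s`, so ties in floating point are counted as ties.
* `K = N` (every feature a member) returns p = 1; `K = 0` is an error.
* Constant confluency → identity transform with a warning; fewer than 10
  injections → drift not estimable, error.
* Averaging weights biological replicates equally regardless of surviving
  technical replicate counts.
* All randomness flows through one integer seed per entry point
  (`withr::with_seed`), so identical configs are bit-identical.

## 8. Known limitations

* The Bonferroni calibration of mHG is conservative; per-line pathway
  p-values near the 0.05 boundary are better judged with
  `calibration = "permutation"`.
* The AUC-guided batch filter can stop early when the AUC gradient is flat
  (its objective is reproducibility, not feature recovery); on default
  synthetic settings it recovers a median of ~90 % of planted batch
  features over seeds, with seed-to-seed spread.
* The network stage computes a full correlation matrix — quadratic in
  column count; pre-filter by variance for panels beyond a few thousand
  columns.
* Scores (transcriptional programs, TF activities) are consumed, never
  computed; their provenance and confidence filtering belong to the
  providing tool.
* The pipeline config is JSON, not YAML.
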