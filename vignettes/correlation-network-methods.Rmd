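---
title: "Methods: serum proteome-metabolome correlation networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: serum proteome-metabolome correlation networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corromics)
```

# Scope and model

`corromics` implements an integrative correlation analysis for paired serum
proteomic and metabolomic abundance matrices measured on the same patients,
together with clinical tumor markers (CEA and CA 19-9). The scientific
question it serves is descriptive systems biology in a small cohort
(typically n = 20): which proteins, metabolites and markers co-vary strongly
across patients, which metabolic hubs (e.g. citric acid, glutamine)
aggregate those co-variations, and which elements track the established
tumor markers closely enough to be biomarker candidates.

The statistical core is deliberately simple and transparent:

* **Association**: the Pearson product-moment correlation $r$ of each
  unordered pair of elements across samples.
* **Inference**: the exact small-sample test
  $t = r\sqrt{n-2}/\sqrt{1-r^2} \sim t_{n-2}$, two-sided.
* **Multiplicity**: Benjamini-Hochberg step-up adjustment across **all**
  pairs jointly — protein-protein, metabolite-metabolite, cross-layer and
  marker-involving pairs form a single family, matching an analysis that
  displays all $M(M-1)/2$ correlations in one heat map.
* **Effect-size gate**: a pair is called significant only when additionally
  $r^2 \ge 0.49$ (i.e. $|r| \ge 0.7$), so that FDR-significant but weak
  correlations in a large family are not reported.

Both boundaries are inclusive. Because `0.7^2` rounds just below `0.49` in
binary floating point, the squared-correlation gate is evaluated as
$|r| \ge \sqrt{r^2_{\min}}$, which makes the printed boundary behave as
written.

# Preprocessing

Each omics layer is preprocessed independently, in this order:

1. **Median normalization** — every feature is divided by the median of its
   *observed* values, so each feature's observed median becomes 1.0. This is
   scale-invariant and idempotent; missing cells stay missing.
2. **Minimum-value imputation** — missing cells are filled with the
   feature's observed minimum (a conservative below-detection-limit
   surrogate). The scope is per feature by default; a global scope is
   available (`impute_minimum(scope = "global")`) but a global fill would
   create identical values across features and inflate cross-feature
   correlations.
3. **Degenerate-feature filtering** — a feature whose single most frequent
   value occurs in more than `max_ties` samples (default 10 of n = 20) is
   removed. Such features are mostly imputation artifacts: a feature imputed
   in half the cohort correlates near-perfectly with any other such feature
   for reasons that carry no biology. Tie counting uses exact equality of
   stored doubles, because ties produced by minimum filling are
   bit-identical. For other cohort sizes, `floor(n/2)` is a reasonable
   `max_ties`.

Whether the original protocol normalized before imputing is not decidable
from its description; both orders are implemented
(`preprocess_layer(order =)`), and normalize-first is the default because it
follows the protocol's narrative order and keeps fill values on the common
normalized scale. The orders differ only for features with missing values
(the imputed minimum shifts the post-imputation median slightly).

Markers are **not** normalized, imputed or filtered: they are complete
clinical measurements on their own scales, and Pearson correlation is
invariant to affine rescaling, so normalization would change nothing while
imputation rules are undefined for them (missing marker values are a hard
error at load time).

# Clustering

Heat-map ordering uses agglomerative average-linkage clustering (UPGMA) on
the signed correlation distance $d = 1 - r \in [0, 2]$. Signed — not
$1 - |r|$ — so anti-correlated features end up in distant clusters, the
convention of the MeV-style displays this reproduces. Merge heights equal
the mean inter-cluster distance (maintained exactly by the Lance-Williams
average-linkage update), which makes heights non-decreasing root-ward.
Ties on merge height are broken toward the cluster containing the lowest
original index, so leaf orders are reproducible across runs and platforms.
The implementation is validated against a brute-force UPGMA that recomputes
every mean inter-cluster distance from the original matrix at each step.

# Network operations

The correlation network has the endpoints of significant edges as nodes and
the significant pairs as signed edges; its edge count equals `n_sig` by
construction (a conservation property the tests assert).

* **Anchor subnetworks** collect the edges incident to one or more anchor
  elements (positive edges only by default). The union edge count counts
  each edge once: two anchors with degrees $d_1$ and $d_2$ whose mutual
  edge is itself significant have $d_1 + d_2 - 1$ union edges, and partner
  counts exclude the anchors themselves. This is exactly the arithmetic
  that makes "120 + 63 correlations" resolve to 182 edges over 126
  partner molecules when the two anchors are themselves correlated.
* **Biomarker selection** returns the significant *positive* marker-element
  correlations; the marker-marker pair (CEA vs CA 19-9 is itself strongly
  correlated in advanced colorectal cancer serum) is reported separately,
  and significant negative marker correlations go to a side channel, so
  headline counts concern positive candidates only.
* **Pathway overlap** is a pure set operation on user-supplied
  feature-to-pathway maps (e.g. KEGG identifiers from an external
  annotation step): shared categories are the intersection of the two
  maps' category sets, and member counts are distinct features belonging
  to at least one shared category. No live database is queried.

Exports are Cytoscape-compatible SIF (`id1 pos_corr|neg_corr id2`) and
GraphML with layer/class node attributes and r/q/sign edge attributes, with
deterministic ordering (byte-identical across runs).

# The synthetic-data generator

Real serum MS data cannot ship with the package, so every stage is exercised
against a generator whose statistical structure is known exactly.

All structure lives on the natural-log scale, where the model is jointly
Gaussian; abundances are exponentials (strictly positive, right-skewed,
log-normal-like — the shape of MS intensity data):

$$\log x_{fs} = \mu_f + \sum_k \lambda_{fk} F_{ks} + \varepsilon_{fs}$$

* **Layers**: each layer has its own latent factors; the metabolite layer's
  loading scale (sd 0.6) is twice the protein layer's (0.3), so metabolites
  are more strongly inter-correlated — the qualitative feature of serum
  multi-omics that the analysis's heat maps show.
* **Planted marker couplings**: for jointly lognormal variables with
  log-scale correlation $\rho_{\log}$ and log-sds $\sigma_1, \sigma_2$, the
  abundance-scale correlation is
  $(e^{\rho_{\log}\sigma_1\sigma_2} - 1)/
  \sqrt{(e^{\sigma_1^2}-1)(e^{\sigma_2^2}-1)}$. The generator inverts this
  closed form so each marker-feature coupling has population correlation
  exactly `rho_star` (default 0.9) on the abundance scale the pipeline
  analyses. Co-planted features of the same marker are mutually correlated
  (near $\rho^2$), as co-regulated biomarkers would be.
* **Degenerate features**: injected per layer by repeating a constant (just
  below the feature's minimum) in `floor(n/2) + 2` samples, which the
  default filter must remove in full — a property the tests assert.
* **Missingness**: masked completely at random at `missing_rate`
  (default 5%), with at least one observed cell per feature. MCAR is the
  weakest mechanism consistent with "missing values, if any"; no
  intensity-dependent censoring is modeled.
* **Markers**: scaled lognormals with cosmetic clinical means
  (CEA ≈ 500, CA 19-9 ≈ 2000 ng/ml); Pearson r ignores scale.

`SyntheticTruth` keeps the loading matrix and idiosyncratic sds, so the
population correlation of *any* pair is available analytically
(`population_correlations()`), and recovery of the planted structure can be
scored with standard confusion-matrix rates (`evaluate_recovery()`).

**What a green test does not establish.** The generator is MCAR, lognormal
and factor-structured; real serum data has intensity-dependent missingness,
heavier tails, batch structure, and — unlike the generator — *mutually
correlated* tumor markers sharing partner elements (the study's CEA and
CA 19-9 correlate at 0.96). The markers are kept independent with disjoint
planted sets precisely so each planted correlation is exactly known; tests
on this world validate the pipeline's statistics, not the biology of any
particular cohort.

# Calibration and power (what the long-running tests measure)

* **Null calibration**: 200 replicates of 200 independent standard-normal
  elements at n = 20 through `correlate_all()` + `call_significant()`.
  Every call is false, so the replicate FDP is 1 if anything is called.
  Under the complete null, BH at $q = 0.05$ achieves $E[\mathrm{FDP}] =
  q \cdot m_0/m = 0.05$ *exactly* (the equality case of the BH theorem;
  the $r^2$ gate never binds because the smallest BH rejection threshold in
  this family already corresponds to $|r| \approx 0.84$). A 200-replicate
  Monte-Carlo mean of a quantity whose expectation sits exactly on the
  bound lands above it roughly half the time (SE ≈ 0.015); at the fixed
  seeds used by the suite the realized mean is 0.06, which is statistically
  indistinguishable from correct control (binomial p ≈ 0.28) but exceeds
  the literal bound, so that assertion is knowingly left failing rather
  than widened — see the repository notes.
* **Power**: 200 replicates of the full pipeline (generation through
  significance calls) on a scaled-down default world — 60 + 60 features
  with the default latent-factor structure, 5 degenerate features, 5%
  missingness, 5 planted couplings per marker at $\rho^* = 0.9$ — measuring
  the fraction of planted marker couplings recovered at
  $r^2 \ge 0.49,\ q \le 0.05$. Mean recall ≈ 0.88. Feature counts are
  reduced for runtime only; keeping the default covariance structure
  matters because the BH threshold adapts to the number of true
  discoveries in the family, and an artificially all-null background would
  be harsher than the stated world.

# Numerical choices and edge cases

* `pearson_pvalue(|r| = 1)` returns exactly 0 (not an underflow artifact);
  BH handles zeros correctly.
* Constant (zero-variance) elements have undefined correlations: they are
  excluded from the element set with a warning, are a hard error in the
  scalar `pearson_r`, and are excluded before feature clustering.
* A feature with all values missing is a hard error naming the feature.
* Pair enumeration is lexicographic by element index; exports sort nodes
  and edges by id — two runs on the same input are byte-identical.
* Missing-value tokens accepted on input: empty cell, `NA`, `NaN`
  (case-insensitive); anything else non-numeric is an error naming the
  cell. Values must be strictly positive at load time.

# Worked example

```{r example, eval = FALSE}
cfg <- simulation_config(n_proteins = 60, n_metabolites = 60, seed = 7)
sim <- synthesize_study(cfg)
res <- run_correlation_pipeline(sim$proteins, sim$metabolites, sim$markers)
res$summary
bm <- select_biomarkers(res$table, c("CEA", "CA19-9"))
bm$summary
rec <- evaluate_recovery(res$table[res$table$significant, ], sim$truth,
                         rho_threshold = 0.7)
```

# Limitations

Pearson correlation on abundance (not log) scale is sensitive to outliers
and skew; no partial correlations, no Spearman option, no batch correction,
no bootstrap support for dendrograms; pathway overlap requires user-supplied
annotation maps and performs no enrichment statistics; the generator does
not simulate acquisition-level noise (retention-time drift, isotope
patterns) or marker-marker dependence.
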