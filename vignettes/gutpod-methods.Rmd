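---
title: "Methods and design notes for gutpod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for gutpod}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

gutpod implements a complete case/control diagnostic-modelling workflow for
gut-microbiome OTU tables, of the kind used to build non-invasive
classifiers for kidney disease and other conditions from 16S profiles. This
vignette explains the models and the design decisions; it states no
empirical result that the test suite does not itself compute.

## The diagnostic model

The core procedure takes a discovery cohort (an OTU count table plus
case/control labels) and produces a small OTU panel, a random-forest
classifier, and per-sample **probability-of-disease (POD)** scores:

1. **Matching and split.** Cases and controls are 1:1 propensity-matched on
   age and sex (logistic model, greedy nearest-neighbour on the logit
   scale, caliper 0.2 SD of the logit) and the matched pairs are randomised
   2:1 into discovery and validation cohorts. Pairs, never individuals, are
   randomised, so the case/control structure survives the split.
2. **Three-criterion screen.** A candidate OTU must (a) exceed 0.5%
   relative abundance in at least one sample (strict inequality), (b) have
   a two-sided Wilcoxon rank-sum p below 0.01, and (c) have a forest
   permutation importance (mean decrease in accuracy) above 1e-4. A looser
   p < 0.05 pre-pass decides which OTUs enter the screening forest; the
   stricter p < 0.01 is applied to the final set. The two thresholds are
   kept as separate configurables because the screening protocol genuinely
   uses both stages, and screening statistics are computed on relative
   abundances (the abundance criterion is expressed in percent); a
   `use_counts` flag switches to raw counts.
3. **Feature-count selection (RFCV).** Repeated stratified five-fold
   cross-validation over a descending grid of feature counts (halvings of
   the candidate count plus every k <= 10). Crucially, the candidate
   ranking is **re-derived inside every training fold**: ranking once on
   the full data before cross-validating is the classic selection leak that
   silently inflates AUC. A `legacy_leaky` flag reproduces the naive
   protocol for comparison. The default `min` rule picks the smallest k
   achieving the minimum mean CV error ("lower CV error with fewer
   variables"); a `one-se` rule is also provided.
4. **Final model and POD.** The forest is refit on the full discovery data
   restricted to the top-k panel; panel members whose refit importance
   falls below the model-level floor of 0.001 are reported (and optionally
   dropped). POD is defined as the fraction of trees voting the disease
   class — the natural forest vote score; the literature using this
   pipeline does not define POD numerically, so the definition is logged in
   every model file. Discovery-cohort POD is computed **cross-validated**
   (each sample scored only by forests that never saw it); external cohorts
   are scored by the final model unchanged.
5. **ROC.** AUC is the Mann-Whitney statistic U/(n1 n0) computed from
   midranks, which equals the trapezoidal area under the empirical curve.
   The operating cut-off maximises Youden's J over midpoints between
   consecutive distinct scores, ties broken toward higher specificity
   (`closest-topleft` is available; the cut-off criterion is a
   configuration, not a hard-coded choice, because published reports print
   cut-offs without naming the rule).

### The bundled random forest

No random-forest package is assumed: the classifier is a compact compiled
implementation (bootstrap, CART with Gini splits, `sqrt(p)` candidate
features per node, trees grown to purity). Importance is the **unscaled**
OOB permutation mean decrease in accuracy, averaged over all trees; the
screening (1e-4) and model (0.001) floors are interpreted on this raw
vote-fraction scale. Only features actually used by a tree are permuted
(others have exactly zero decrease). All randomness flows from a single
64-bit generator seeded per fit, so fits are bit-reproducible and
independent of R's RNG state.

## Diversity, ordination and group tests

* **Observed OTUs / ACE** for alpha diversity. ACE uses the standard
  rare-threshold of 10 reads (the mothur/EstimateS convention). When every
  rare OTU is a singleton the coverage estimate is zero and ACE is
  undefined; the bias-corrected Chao1 value is returned instead and
  flagged. Tables are **not rarefied by default** — the normalisation
  choice is left explicit via `rarefy_table(depth, seed)` because silently
  subsampling is a reproducibility hazard.
* **Group comparisons**: Mann-Whitney U (exact for combined n <= 20 without
  ties, else normal approximation with tie correction; the switch point is
  configurable) and Kruskal-Wallis for three or more groups.
* **Beta diversity**: Bray-Curtis and unweighted/weighted UniFrac. Weighted
  UniFrac is normalised by default so values are comparable across
  sequencing depths; both variants are exposed because figures in the
  literature rarely say which was used. UniFrac is computed by a single
  postorder accumulation of per-branch read fractions, and is checked in
  the tests against a brute-force per-branch oracle.
* **PCoA** reports negative eigenvalues rather than silently correcting
  them (Cailliez correction is an opt-in flag). **NMDS** minimises Kruskal
  stress-1 via the vegan `monoMDS` engine under 20 seeded random restarts.
* **ANOSIM** uses Clarke's n(n-1)/4 denominator with midranks on ties
  (matching vegan, which the tests use as an independent oracle) and the
  add-one permutation p-value, so p is never exactly zero.

## SparCC and clinical indicators

Compositional correlation between panel OTUs and clinical chemistry (serum
albumin, 24-h urine protein, serum creatinine) uses the SparCC estimator:
Dirichlet-posterior resamples of component fractions, log-ratio variation
matrix, basis variances solved under sparsity with iterative exclusion of
the strongest pair above |rho| = 0.1, averaged over 20 inner resamples.
Running a compositional estimator across data types (counts vs continuous
chemistry) is a modelling stretch, so indicators enter as **fixed log
pseudo-components** (min-shifted when zeros occur, and flagged) that skip
the posterior draw — per-sample scaling cancels in log-ratio variances, so
no renormalisation is needed — and a plain Spearman fallback
(`method = "spearman"`) is reported alongside when asked. Significance is a
column-shuffle bootstrap with the add-one rule. Samples with incomplete
indicators are dropped complete-case (with counts reported) rather than
pairwise, because the joint basis solve needs one consistent sample set.

## The synthetic cohort generator

The generator is the test bed standing in for real sequencing data. Its
defaults state the world the recovery tests assume: 30 cases vs 31
controls, 200 OTUs, 8 planted differential OTUs at 4-fold change (half
enriched, half depleted, mirroring the mixture of increased pathogens and
decreased commensals seen in real dysbiosis), log-normal baseline
abundances (sigma 1.5), Dirichlet-multinomial compositions (concentration
theta = 50, a realistic gut-microbiome overdispersion), negative-binomial
sequencing depth (mean 20 000, size 10, floored at 1000 reads), a random
bifurcating phylogeny with exponential branch lengths, a +5-year case age
shift so matching has work to do, and serum creatinine coupled to the
first planted OTU (slope 1 on log relative abundance, noise SD 0.3).

Planted OTUs are drawn from the **abundant quartile** of the baseline
community: differential taxa in real studies are community members, and an
OTU below the screen's 0.5% abundance criterion could never be recovered
regardless of effect size, so planting effects uniformly would test the
generator's tail behaviour, not the pipeline. External cohorts share the
ground truth and receive independent per-OTU multiplicative log-normal
batch offsets (scale `batch_sigma`); an adversarial flag flips the planted
directions, which should collapse external AUC below 0.5.

What a green recovery test does **not** establish: the generator draws
samples i.i.d. within groups (no enterotype structure, no
covariate-driven confounding beyond the stated age shift), taxonomy is a
placeholder, and batch effects are multiplicative and OTU-wise rather than
lineage-correlated. Performance numbers on synthetic cohorts say the
machinery is leak-free and calibrated, not that any particular real cohort
will reach them.

## Numerical and engineering choices

* Every random stage derives an independent stream from one master seed
  (a mixed congruential hash, kept below 2^31), so reports are
  byte-identical across reruns and no stage's draws shift another's.
* Table orientation on disk is declared, never guessed (`--orientation`,
  default OTUs-as-rows): silent transposition is the classic
  microbiome-pipeline bug.
* "Bacteroidota" is treated as a synonym of "Bacteroidetes" in the
  Firmicutes/Bacteroidetes ratio (the SILVA 138 renaming); the synonym
  table is configurable. A zero Bacteroidetes total yields `NA`
  ("undefined"), never `Inf`.
* Unannotated OTUs aggregate into a reserved `unclassified` bin so taxon
  aggregation conserves per-sample totals exactly.
* Non-divisible 2:1 splits give discovery the ceiling share
  (deterministically favouring training data).
* The screening importance floor (1e-4) and the model importance floor
  (0.001) are deliberately separate constants; their relation is not
  documented in the source protocol, so both stay configurable.
* External validation **reuses** the discovery-trained forest (no refit):
  the workflow validates "the model", and refitting per cohort would test
  a different claim.
* Degenerate inputs fail fast with named errors: empty samples, duplicate
  identifiers, OTUs absent from the phylogeny, panel OTUs absent from an
  external table (zero-fill only on explicit request), singleton ANOSIM
  groups, sub-identifiable SparCC systems (< 4 components), zero-variance
  indicators.

## Known limitations

* The propensity caliper (0.2 SD of the logit) can leave cases unmatched
  when the control reservoir is thin; unmatched cases are reported, not
  force-paired. With fully exchangeable covariates the noise-fitted logit
  makes the caliper an arbitrary filter — that is inherent to
  caliper-on-noise, not to this implementation.
* RFCV's `min` rule can legitimately choose k = 1 when one planted OTU
  dominates; the curve and SDs are always reported so the `one-se` rule or
  a manual k can be applied.
* SparCC p-values from column shuffles are pseudo-p-values over a
  dependent family; no multiplicity control is applied (the convention in
  the source literature is raw significance stars).
* The bundled forest handles binary outcomes only; multi-class and
  probability calibration are out of scope.
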