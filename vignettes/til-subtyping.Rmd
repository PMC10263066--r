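---
title: "Methods: TIL-based immune subtyping of NSCLC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TIL-based immune subtyping of NSCLC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilprofiler)
```

## The model

`tilprofiler` classifies resected NSCLC tumors into three immune
microenvironment subtypes from flow-cytometry profiles of dissociated
tissue:

* **Cold** — scant leukocyte infiltration;
* **Myeloid** — abundant infiltrate dominated by suppressive myeloid cells
  (macrophages, monocytic MDSCs, CD14+ monocytes);
* **CD8** — abundant infiltrate dominated by T cells, with elevated
  CD8-attractant chemokines, interferon signatures, more diverse TCR
  repertoires and longer event-free survival.

The subtype call is unsupervised: samples are described by a
dual-representation feature vector, clustered hierarchically, and the three
clusters are named by a fixed decision rule. Every stage below is a
package function with a documented contract; `run_pipeline()` composes
them.

## Gating

Events are classified through a declarative threshold hierarchy
(`load_gating_config()`, `gate_events()`). The packaged configuration
encodes: live (viability-dye negative) → leukocytes (CD45+CD326−) →
CD3+/CD3− split; CD3+ resolves NKT (CD3+CD56+, CD4+/CD8+ subsets), CD4+ and
CD8+ T cells, naive/CM/EM/EMRA memory quadrants (CD45RA × CD197), and
FOXP3-expressing fractions (Fr. I naive Treg CD45RA+FOXP3lo, Fr. II
effector Treg CD45RA−FOXP3hi, Fr. III non-Treg CD45RA−FOXP3lo); CD3−
resolves B (CD19+), NK (CD56+), cDC (HLA-DR+CD11c+), pDC
(HLA-DR+CD11c−CD123+), macrophages (CD68+SSChi), mMDSC
(HLA-DRlo CD14+CD11b+CD33+) and CD14+ monocytes. Functional overlays
(Ki-67+, PD-1+, PD-L1+, CTLA-4+) are non-exclusive children of their
parent populations.

Design choices worth knowing:

* **Fixed thresholds.** Gates are static per-channel values from the
  configuration, not data-derived: manual gating workflows fix gates per
  analysis, and static gates make recovery against planted truth exactly
  testable. Polarity semantics: *positive/high* is `x ≥ t_pos`,
  *negative* is the complement `x < t_pos` (so binary splits partition
  their parent exactly), *low* is the interval `[t_neg, t_pos)` needed for
  HLA-DRlo and the FOXP3 lo/hi discrimination, and *expressed* is
  `x ≥ t_neg`.
* **The 30-population census.** The packaged list is 23 cell types
  (including total Treg and CD14+ monocytes as a CD3− population distinct
  from mMDSC) plus 7 overlays (Ki-67+ CD4/CD8 T, PD-1+ CD4/CD8 T, PD-L1+
  CD8 T, PD-L1+ mMDSC, CTLA-4+ eTreg). Which overlays count toward the
  census is a configuration fact, documented here, and
  `enumerate_populations()` reflects any edit.
* **Quadrants partition.** The memory quadrant is applied to *all* CD4+ T
  cells, so FOXP3-expressing cells also fall into a quadrant; the
  invariant naive + CM + EM + EMRA = CD4 T holds exactly (same for CD8),
  and `expected_gated_counts()` maps simulated leaf truth onto these
  definitions for validation.

## Features

For every population `p` of a sample with tissue mass `m` grams:

* density `= log10(count_p / m + 1)` — zero exactly when the count is
  zero, invariant to scaling counts and mass together;
* %CD45 `= 100 · count_p / count_CD45`; subset tables (%CD4, %CD8,
  %myeloid, percent-of-parent overlays) use their hierarchy denominators.
  A zero denominator yields a missing value, never zero.

`build_feature_matrix()` z-scales each feature across the supplied samples
(sample-sd, `n − 1`, the `scale()` convention) and concatenates the two
blocks. Constant features map to z = 0 with a warning rather than NaN.
The scaling cohort is exactly the sample set passed in, so tumors+NATs are
scaled together for the combined analysis and tumors alone for the subtype
run — both modes are used and explicit.

Two feature presets exist: `fig2` (the 11 top-level cell types; 22
features) for tumor subtype discovery, and `fig1g_23` (all 23 cell types;
46 features) for the combined tumor+NAT analysis. The subset populations
matter for the latter: the tumor-vs-normal contrast lives largely in
naive/effector memory composition, which the top-level types do not see.

## Clustering and labelling

`spearman_distance()` computes `d = 1 − ρ_spearman` between sample feature
vectors (average ranks for ties, pairwise-complete for missing values; a
sample needs ≥ 3 non-missing features). `ward_d2_linkage()` is a native
Lance–Williams implementation of the ward.D2 criterion — the recurrence is
applied to squared dissimilarities and heights reported unsquared — so the
merge order is fully specified (ties break towards the lowest cluster
index) and the merge sequence can be checked against a brute-force
minimum-variance-increase agglomerator; the tests do exactly that, and also
cross-check against `stats::hclust(method = "ward.D2")`. `k = 3` is a
default, not auto-selected: three profiles is a modelling commitment, and
`cut_clusters()` exposes `k` for other uses (e.g. `k = 2` for the
tumor/NAT clade question).

`label_subtypes()` automates the cluster naming that would otherwise be
done by inspecting heat maps: lowest mean CD45+ density → Cold; of the
remaining two, higher mean myeloid %CD45 → Myeloid, the other → CD8; an
exact myeloid tie falls back to the higher T-cell %CD45 → CD8, with a
warning. The rule is permutation-invariant in the cluster numbering.

## Transcriptome scores

* `signature_score()`: mean over the gene set of per-gene z-scores of
  `log2(TPM + 1)`. The scoring scheme is deliberately the simplest one
  consistent with "signature score" language; it is closed-form testable
  and swappable.
* `assign_molecular_subtype()`: `log(TPM + 1)`, per-gene median centering,
  Pearson correlation with predictor centroids, argmax. Median centering
  absorbs per-gene additive shifts on the log scale, and the label is
  invariant to the log base (correlation is invariant to positive affine
  maps); both invariances are tested. Centroid matrices are user-supplied
  inputs — the package ships only synthetic test centroids.
* `compute_immunogram()`: eight axes; per axis the cohort percentile of the
  signature score, `p = (rank − 1)/(n − 1)` with average ranks, scaled to
  `[0, 5]`. The extremes hit exactly 0 and 5 and an odd-cohort median
  scores 2.5. Antitumor axes 1–5 score high when the signature is high;
  suppressive axes 6–8 are inverted (`5(1 − p)`). Axis 2 (tumor
  antigenicity) needs neoantigen input and is emitted as not-computed by
  default. The packaged axis gene sets are pragmatic defaults; replace
  them with curated sets for real analyses.

## TCR diversity

`filter_clonotypes()` removes clonotype calls supported by fewer than 7
UMIs (a deliberately stringent false-positive filter; the threshold is a
parameter). `shannon_entropy()` then computes `H = −Σ p_i ln p_i` per
sample and chain from the *filtered* UMI counts — filter first, normalise
after. Units are nats by default (base is a flag), and raw entropy is
reported by default with Pielou normalisation (`H / ln R`) as an option.
The tests cross-check against `vegan::diversity`.

## Outcome analyses

Event-free survival is time from surgery to relapse or death; analyses
delegate numerics to the `survival` package (Efron ties). The bespoke
content is orchestration and reporting:

* `km_logrank()`: product-limit curves, global and pairwise log-rank.
* `cox_scan()`: one univariate fit per immune feature; `z = coef/se`
  (positive = higher feature, higher hazard); non-convergent or constant
  features are reported as failed rows, not fatal errors.
* `multivariate_cox()`: binary "ref vs. alt" contrasts; univariate pass,
  then a joint fit of the contrasts with univariate `p < 0.05`. Hazard
  ratios are reported as `exp(−coef)` with the indicator coded 1 for the
  reference level, i.e. the hazard of the alternative level relative to
  the reference. When several selected contrasts share one clinical
  column (CD8 vs. Myeloid and CD8 vs. Cold), only the most significant
  enters the joint fit — jointly coding overlapping pairwise contrasts
  would shrink the complete cases to the reference level alone.
* `fisher_holm_scan()`: exact tests per contingency table (Monte-Carlo
  with a fixed seed above a size bound), Holm adjustment across the
  scanned family (one family per scan/panel), and two flag tiers: raw
  `p ≤ 0.05` and Holm-adjusted `p ≤ 0.2`.

## The synthetic cohort generator

The generator exists because the cytometry and sequencing data this
analysis was designed for are controlled-access; it emulates the
*statistical structure* the analysis assumes, not the instruments.

* **Marker model.** Within a population, marker intensities are
  independent lognormals (log10 a.u.): negative mode mean 1.0 (sd 0.15),
  "lo" mode 2.05 (0.15), positive mode 3.4 (0.25); thresholds 1.5/2.6
  (side scatter 2.8). Positive modes sit ≥ 3 sd above the positive
  threshold and "lo" modes ≥ 3 sd inside the interval, so gating recovery
  is limited by tail leakage (< 0.5 percentage points at study depths),
  not by overlap. There is no spillover/compensation, doublet geometry or
  batch structure — gates are thresholds, so marginal separation is what
  matters, and passing tests say nothing about compensation quality on
  real data.
* **Composition templates.** CD45+ leukocytes are split over 20 leaf
  populations per study condition. Tumor templates share an
  effector-dominant shape (EM subsets, effector Tregs, myeloid lineage);
  the NAT template is naive/NK-dominant with low mMDSC. Cold tumors use a
  leukocyte yield factor of 0.12 versus 1.0 for Myeloid/CD8 (NAT 0.45),
  driving the planted density differences. Per-sample composition jitter
  is Dirichlet (concentration 150) and yield jitter lognormal
  (sdlog 0.3). Absolute per-population density scales are not published
  numerically anywhere we could anchor them, so the templates encode
  qualitative orderings only.
* **Contaminants.** Dead cells (viability-dye positive) and CD45−
  epithelial cells are added on top of the leukocyte events (defaults 8%
  and 15%), exercising the live and CD45 gates; contamination only adds
  events, never removes them.
* **Mass.** Tissue mass is lognormal with mean 0.5 g, sd 0.2 g — a
  plausible surgical-fragment scale that exercises the per-gram
  normalisation.
* **Expression.** `log2 TPM ~ N(base + effect, sd)`: CD8-attractant
  chemokines (CCL5, CXCL9/10/11), effector/interferon/checkpoint genes
  shifted +1.8 log2 units in CD8-subtype samples; suppressive myeloid
  genes +1.2 in Myeloid; background genes exchangeable.
* **TCR.** Clonotype abundances are symmetric Dirichlet; UMI counts
  multinomial at depth 10^4 per chain. The closed form
  `E[H] = ψ(Rα + 1) − ψ(α + 1)` (`expected_repertoire_entropy()`) is used
  to calibrate planted diversity gaps; CD8-subtype samples get richness
  250 / concentration 0.55 versus 100/0.35 for Myeloid.
* **Survival.** Exponential event times (Weibull shape 1 — the simplest
  model satisfying proportional hazards) with hazard multipliers
  Myeloid 3.0 > Cold 1.8 > CD8 1.0 over a baseline median of 60 months,
  censored by an independent uniform 36–84 month administrative window;
  categorical clinicopathologic factors carry planted subtype
  associations.
* **Truth channel.** Every simulated bundle carries its ground truth
  (labels, drawn counts), which the analysis path never reads; tests and
  the acceptance script compare outputs to truth externally.

Determinism: one master seed fans out to per-sample and per-stage child
seeds by a stable integer derivation (`child_seed()`), so identical
configurations give byte-identical outputs and stages can be rerun in
isolation.

## Problem sizes and numerical choices

The shipped study templates use 4,000 leukocyte-scale events per sample
(2,000 for `mini`) — enough that composition recovery error is well under
one percentage point per population while a full 292-sample cohort
simulates, gates and clusters in seconds. Calibration checks use 500 null
replicates (Cox scan coverage), 50 replicates for planted-direction rates
(expression, TCR) and 100 for log-rank power.

Degenerate inputs are contracts, not crashes: empty event tables gate to
zero counts; zero denominators give missing fractions; constant features
z-scale to 0 with a warning; constant Cox features fail per-feature;
empty-margin contingency tables are skipped with a warning; correlation
ties in centroid assignment take the first centroid with a warning.

## Limitations

* Gating assumes the synthetic intensity scale or instrument data
  transformed to a comparable log scale with matched thresholds; there is
  no automatic gate inference or compensation. Event tables are accepted
  as matrices/CSV; binary FCS containers are out of scope.
* The subtype labelling rule encodes the qualitative cluster definitions;
  on cohorts whose clusters do not differ in density or myeloid content it
  will still label deterministically (with a tie warning), which may not
  be meaningful.
* Immunogram axis gene sets and molecular-subtype centroids are
  placeholders/synthetic; results on real data depend on supplying the
  curated versions.
* Synthetic validation demonstrates internal consistency and parameter
  recovery, not clinical validity on real cohorts.
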