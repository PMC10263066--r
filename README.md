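# tilprofiler

Immune subtyping of non-small cell lung cancer (NSCLC) tumors from
flow-cytometry profiles of tumor-infiltrating leukocytes (TILs).

## The problem

The composition of the immune tumor microenvironment — whether a tumor is
scantly infiltrated, dominated by suppressive myeloid cells, or rich in
effector CD8+ T cells — shapes prognosis and the response to checkpoint
blockade. `tilprofiler` implements a cytometry-first subtyping workflow for
researchers who profile dissociated tumor tissue with a multicolor panel:

1. **Gating.** A declarative gating engine classifies event-level marker
   intensities through a fixed threshold hierarchy
   (live → CD45+CD326− → CD3± → lineages) into 30 immune populations
   (23 cell types plus Ki-67/PD-1/PD-L1/CTLA-4 functional overlays) from a
   26-marker panel.
2. **Features.** Each population contributes two complementary features:
   cell *density* `log10(count / mass_g + 1)` (cells per gram of tissue)
   and *%CD45* (percentage of CD45+ leukocytes). Both blocks are z-scaled
   across patients and concatenated.
3. **Subtyping.** Samples are clustered on Spearman correlation distance
   `d(i,j) = 1 − ρ_s(x_i, x_j)` with Ward.D2 agglomeration (Lance–Williams
   recurrence on squared dissimilarities, heights on the unsquared scale),
   the tree is cut at `k = 3`, and clusters are named by a decision rule:
   lowest mean CD45+ density → **Cold**; of the rest, higher myeloid
   (macrophage + mMDSC + CD14+ monocyte) %CD45 → **Myeloid**; the other →
   **CD8**.
4. **Characterisation.** Gene-signature scores (mean per-gene z of
   `log2(TPM+1)`), nearest-centroid molecular subtype assignment (Pearson
   correlation of median-centered log TPM with predictor centroids),
   eight-axis cancer-immunity-cycle immunograms on a 0–5 percentile scale
   (suppressive axes 6–8 inverted), TCR repertoire Shannon entropy (nats,
   after a ≥7-UMI clonotype support filter), Kaplan–Meier/log-rank and Cox
   analyses of event-free survival, and Fisher-exact association scans with
   dual-threshold flagging (raw p ≤ 0.05; Holm-adjusted p ≤ 0.2).

Because raw patient-level cytometry and sequencing data of this kind are
typically controlled-access, the package ships a fully seeded synthetic
cohort generator (`simulate_cohort()` and friends) that plants the subtype
structure the analysis assumes, so the entire pipeline is testable end to
end.

## Worked example

```r
library(tilprofiler)

spec   <- default_cohort_spec("mini")          # 14 tumors + 6 NATs
cohort <- simulate_cohort(spec, seed = 42)
tree   <- load_gating_config()
counts <- gate_cohort(cohort$samples, tree)

tumors <- cohort$meta$sample_id[cohort$meta$histology != "NAT"]
fit <- til_subtype(counts[tumors], cohort$masses, k = 3, tree = tree)
fit
#> TIL immune-subtype fit (Ward.D2 on Spearman correlation distance)
#>   samples:14  features:22 (preset 'fig2')
#>   k = 3
#> subtype
#>     CD8    Cold Myeloid
#>       5       4       5

adjusted_rand_index(cohort$truth$subtype[names(fit$subtype)], fit$subtype)
#> [1] 1
```

The fitted labels recover the planted subtypes exactly (ARI = 1): 14
tumors split into 5 CD8, 4 Cold and 5 Myeloid. Downstream, the same labels
drive survival and repertoire summaries:

```r
ent <- shannon_entropy(filter_clonotypes(simulate_tcr(fit$subtype, seed = 7)))
round(tapply(ent$entropy, fit$subtype[ent$sample_id], mean), 2)
#>     CD8    Cold Myeloid
#>    4.79    3.87    3.62
```

Mean TCR entropy is highest in the CD8 subtype, the planted diversity
ordering. `run_pipeline(run_config(out_dir, template = "mini", seed = 11))`
executes all seven stages (simulate → gate → features → cluster → score →
tcr → report) and writes tidy CSV outputs plus a provenance manifest.

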