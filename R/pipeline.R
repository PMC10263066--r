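# End-to-end orchestration: simulate -> gate -> features -> cluster ->
# label -> score -> tcr -> report, with per-stage child seeds and a
# provenance manifest.  The synthetic truth channel is written alongside
# the outputs for external validation but is never read by any stage.

#' Build a pipeline run configuration
#'
#' @param out_dir output directory for stage outputs and the manifest.
#' @param template cohort template name (see [default_cohort_spec()]).
#' @param seed master seed; each stage derives its own child seed.
#' @param k number of clusters for the subtype stage.
#' @param preset feature-set preset for the tumor subtype clustering.
#' @param clade_preset feature-set preset for the combined tumor + NAT
#'   clade analysis; defaults to the full 23-type set, whose naive/memory
#'   subset contrast carries the tumor-vs-NAT signal.
#' @param min_umi UMI support filter for the TCR stage.
#' @param selection_alpha univariate inclusion threshold for the
#'   multivariate Cox stage.
#' @param gating_config path to the gating YAML.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir, template = "mini", seed = 1L, k = 3,
                       preset = "fig2", clade_preset = "fig1g_23",
                       min_umi = 7, selection_alpha = 0.05,
                       gating_config = default_gating_config()) {
  if (!file.exists(gating_config)) {
    stop("gating config does not exist: ", gating_config)
  }
  structure(list(out_dir = out_dir, template = template, seed = seed,
                 k = k, preset = preset, clade_preset = clade_preset,
                 min_umi = min_umi,
                 selection_alpha = selection_alpha,
                 gating_config = gating_config),
            class = "run_config")
}

.write_csv <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  path
}

#' Run the full subtype pipeline
#'
#' Executes all seven stages on a synthetic cohort and writes tidy outputs
#' plus a JSON manifest (stage list, files, seeds, package version) to the
#' run directory.  Reruns with an identical configuration reproduce
#' identical outputs.
#'
#' @param cfg a `run_config`.
#' @return invisibly, a list with the key in-memory results (`fit`,
#'   `counts`, `clinical`, `entropy`, `manifest`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(template = cfg$template, seed = cfg$seed, k = cfg$k,
                   preset = cfg$preset, min_umi = cfg$min_umi,
                   package_version = as.character(
                     utils::packageVersion("tilprofiler")),
                   stages = list())
  files <- character(0)
  add_stage <- function(name, outputs) {
    manifest$stages[[length(manifest$stages) + 1L]] <<-
      list(name = name, outputs = unname(outputs))
    files <<- c(files, outputs)
  }

  # 1. simulate
  spec <- default_cohort_spec(cfg$template)
  cohort <- simulate_cohort(spec, seed = child_seed(cfg$seed, 1L))
  truth_df <- data.frame(sample_id = names(cohort$truth$subtype),
                         true_subtype = unname(cohort$truth$subtype))
  f_truth <- .write_csv(truth_df, file.path(cfg$out_dir, "truth.csv"))
  f_mass <- .write_csv(
    data.frame(sample_id = names(cohort$masses),
               mass_g = unname(cohort$masses)),
    file.path(cfg$out_dir, "masses.csv"))
  add_stage("simulate", c(f_truth, f_mass))

  # 2. gate
  tree <- load_gating_config(cfg$gating_config)
  counts <- gate_cohort(cohort$samples, tree)
  cm <- counts_matrix(counts)
  tidy_counts <- data.frame(
    sample_id = rep(rownames(cm), times = ncol(cm)),
    population_id = rep(colnames(cm), each = nrow(cm)),
    count = as.vector(cm))
  f_counts <- .write_csv(tidy_counts, file.path(cfg$out_dir, "counts.csv"))
  add_stage("gate", f_counts)

  # 3. features
  fm <- build_feature_matrix(counts, cohort$masses, preset = cfg$preset,
                             tree = tree)
  f_feat <- file.path(cfg$out_dir, "features.tsv")
  utils::write.table(data.frame(sample_id = rownames(fm), unclass(fm),
                                check.names = FALSE),
                     f_feat, sep = "\t", row.names = FALSE, quote = FALSE)
  add_stage("features", f_feat)

  # 4. cluster (tumors only for the subtype call)
  tumor_ids <- cohort$meta$sample_id[cohort$meta$histology != "NAT"]
  fit <- til_subtype(counts[tumor_ids], cohort$masses[tumor_ids],
                     k = cfg$k, preset = cfg$preset, tree = tree)
  lab <- fit$subtype %||% as.character(fit$groups)
  f_lab <- .write_csv(
    data.frame(sample_id = names(fit$groups), group = unname(fit$groups),
               subtype = unname(lab)),
    file.path(cfg$out_dir, "labels.csv"))
  f_nwk <- file.path(cfg$out_dir, "dendrogram.nwk")
  ape::write.tree(ape::as.phylo(fit$dendrogram), file = f_nwk)
  f_merge <- file.path(cfg$out_dir, "merges.tsv")
  utils::write.table(
    data.frame(left = fit$dendrogram$merge[, 1],
               right = fit$dendrogram$merge[, 2],
               height = fit$dendrogram$height),
    f_merge, sep = "\t", row.names = FALSE, quote = FALSE)
  outs <- c(f_lab, f_nwk, f_merge)
  # tumor/NAT clade split over the combined cohort, when NATs are present
  if (length(tumor_ids) < nrow(cohort$meta)) {
    fm_all <- build_feature_matrix(counts, cohort$masses,
                                   preset = cfg$clade_preset, tree = tree)
    d_all <- spearman_distance(fm_all)
    cl2 <- cut_clusters(ward_d2_linkage(d_all), 2)
    f_clade <- .write_csv(
      data.frame(sample_id = names(cl2), clade = unname(cl2)),
      file.path(cfg$out_dir, "clades.csv"))
    outs <- c(outs, f_clade)
  }
  add_stage("cluster", outs)

  # 5. score (expression simulated from the *fitted* labels so downstream
  # stages stay independent of the truth channel)
  subtype_by_sample <- stats::setNames(rep("none", nrow(cohort$meta)),
                                       cohort$meta$sample_id)
  subtype_by_sample[names(lab)] <- lab
  expr <- simulate_expression(subtype_by_sample[tumor_ids],
                              seed = child_seed(cfg$seed, 5L))
  igs <- compute_immunogram(expr)
  f_igs <- .write_csv(
    data.frame(sample_id = rownames(igs), as.data.frame(unclass(igs))),
    file.path(cfg$out_dir, "immunogram.csv"))
  sig <- signature_score(expr, c("CCL5", "CXCL9", "CXCL11"))
  f_sig <- .write_csv(
    data.frame(sample_id = names(sig), chemokine_score = unname(sig)),
    file.path(cfg$out_dir, "signatures.csv"))
  add_stage("score", c(f_igs, f_sig))

  # 6. tcr
  clono <- simulate_tcr(subtype_by_sample[tumor_ids],
                        seed = child_seed(cfg$seed, 6L))
  ent <- shannon_entropy(filter_clonotypes(clono, cfg$min_umi))
  f_ent <- .write_csv(ent, file.path(cfg$out_dir, "tcr_entropy.csv"))
  add_stage("tcr", f_ent)

  # 7. report
  clinical <- simulate_clinical(subtype_by_sample[tumor_ids],
                                seed = child_seed(cfg$seed, 7L))
  km <- km_logrank(clinical)
  contr <- data.frame(
    name = c("TIL_CD8_Myeloid", "TIL_CD8_Cold", "Differentiation", "Stage"),
    column = c("subtype", "subtype", "differentiation", "stage"),
    ref = c("CD8", "CD8", "well-moderate", "I-II"),
    alt = c("Myeloid", "Cold", "poor", "III-IV"),
    stringsAsFactors = FALSE)
  cox <- multivariate_cox(clinical, contr,
                          selection_alpha = cfg$selection_alpha)
  f_cox <- .write_csv(cox$univariate,
                      file.path(cfg$out_dir, "cox_univariate.csv"))
  fac_tabs <- list(
    differentiation = table(clinical$differentiation, clinical$subtype),
    stage = table(clinical$stage, clinical$subtype),
    TLS_grade = table(clinical$TLS_grade, clinical$subtype))
  fac_tabs <- fac_tabs[vapply(fac_tabs, function(tb) {
    all(rowSums(tb) > 0) && all(colSums(tb) > 0)
  }, logical(1))]
  fisher <- fisher_holm_scan(fac_tabs, seed = child_seed(cfg$seed, 8L))
  f_fisher <- .write_csv(fisher, file.path(cfg$out_dir, "fisher_scan.csv"))
  f_km <- .write_csv(km$pairwise, file.path(cfg$out_dir, "km_pairwise.csv"))
  add_stage("report", c(f_cox, f_fisher, f_km))

  f_manifest <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(fit = fit, counts = counts, cohort = cohort,
                 clinical = clinical, entropy = ent, immunogram = igs,
                 manifest = manifest, files = c(files, f_manifest)))
}
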