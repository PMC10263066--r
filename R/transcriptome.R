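# Transcriptome characterisation: gene-signature scores, nearest-centroid
# molecular subtype assignment, and the eight-axis cancer-immunity-cycle
# immunogram.

#' Gene-signature score
#'
#' Default scoring: per gene, z-score of `log2(TPM + 1)` across samples
#' (sample-sd convention; genes constant across the cohort contribute 0),
#' then the mean over the signature genes present in the matrix.  Genes
#' absent from the matrix are dropped with a warning.
#'
#' @param expr genes x samples TPM matrix (non-negative, unique rownames).
#' @param gene_set character vector of gene identifiers.
#' @return named numeric vector of per-sample scores.
#' @export
signature_score <- function(expr, gene_set) {
  if (ncol(expr) < 2) stop("need >= 2 samples")
  present <- intersect(gene_set, rownames(expr))
  if (length(present) == 0) {
    stop("no signature gene present in the expression matrix; missing: ",
         paste(gene_set, collapse = ", "))
  }
  missing <- setdiff(gene_set, present)
  if (length(missing)) {
    warning("signature gene(s) absent and dropped: ",
            paste(missing, collapse = ", "))
  }
  lg <- log2(expr[present, , drop = FALSE] + 1)
  z <- t(zscale_columns(t(lg), warn_constant = FALSE))
  colMeans(z)
}

#' Nearest-centroid molecular subtype assignment
#'
#' Log-transforms `TPM + 1`, centers each gene at its cohort median,
#' correlates every sample with every centroid (Pearson, over the shared
#' genes), and assigns the subtype with the largest correlation.  Because
#' median centering absorbs per-gene shifts and Pearson correlation is
#' scale-invariant, the assignment does not depend on the log base; both
#' natural log and log2 are offered.
#'
#' @param expr genes x samples TPM matrix.
#' @param centroids genes x subtypes centroid matrix.
#' @param min_overlap minimum number of shared genes (default 10).
#' @param log_base `"natural"` or `"log2"`.
#' @return data.frame with `sample_id`, `subtype`, and one correlation
#'   column per centroid.
#' @export
assign_molecular_subtype <- function(expr, centroids, min_overlap = 10,
                                     log_base = c("natural", "log2")) {
  log_base <- match.arg(log_base)
  if (ncol(centroids) < 2) stop("need >= 2 centroid subtypes")
  shared <- intersect(rownames(expr), rownames(centroids))
  if (length(shared) < min_overlap) {
    stop("gene overlap with centroids (", length(shared),
         ") below minimum (", min_overlap, ")")
  }
  lg <- if (log_base == "log2") log2(expr[shared, , drop = FALSE] + 1) else
    log(expr[shared, , drop = FALSE] + 1)
  centered <- lg - apply(lg, 1, stats::median)
  cen <- as.matrix(centroids[shared, , drop = FALSE])
  cors <- suppressWarnings(stats::cor(centered, cen, method = "pearson"))
  cors[!is.finite(cors)] <- 0
  lab <- character(ncol(expr))
  for (i in seq_len(nrow(cors))) {
    best <- which(cors[i, ] == max(cors[i, ]))
    if (length(best) > 1) {
      warning("correlation tie for sample '", colnames(expr)[i],
              "'; taking first centroid in order")
    }
    lab[i] <- colnames(cen)[best[1]]
  }
  out <- data.frame(sample_id = colnames(expr), subtype = lab,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(cors))
}

#' Default immunogram axis configuration
#'
#' Eight cancer-immunity-cycle axes.  Axis 2 (tumor antigenicity) has no
#' default gene set because it requires neoantigen calls, so it is emitted
#' as not-computed; axes 6-8 capture immunosuppressive features and are
#' inverted (high signature maps to a low score).  The packaged gene sets
#' are pragmatic defaults and are expected to be replaced by curated sets
#' for real analyses.
#'
#' @return named list of axes, each with `genes`, `invert`, `label`.
#' @export
default_igs_config <- function() {
  list(
    IGS1 = list(label = "T-cell immunity",
                genes = c("CD8A", "CD8B", "GZMA", "GZMB", "PRF1"),
                invert = FALSE),
    IGS2 = list(label = "Tumor antigenicity", genes = NULL, invert = FALSE),
    IGS3 = list(label = "Priming and activation",
                genes = c("CD80", "CD86", "CD28", "ICOS"),
                invert = FALSE),
    IGS4 = list(label = "Trafficking and infiltration",
                genes = c("CCL5", "CXCL9", "CXCL10", "CXCL11"),
                invert = FALSE),
    IGS5 = list(label = "Recognition of tumor cells",
                genes = c("HLA-A", "HLA-B", "HLA-C", "B2M", "TAP1", "TAP2"),
                invert = FALSE),
    IGS6 = list(label = "Inhibitor cells",
                genes = c("FOXP3", "CD163", "MRC1", "CCL22"),
                invert = TRUE),
    IGS7 = list(label = "Checkpoint expression",
                genes = c("PDCD1", "CD274", "CTLA4", "HAVCR2", "LAG3"),
                invert = TRUE),
    IGS8 = list(label = "Inhibitory molecules",
                genes = c("IDO1", "TGFB1", "IL10", "VEGFA"),
                invert = TRUE)
  )
}

#' Cancer-immunity-cycle immunogram
#'
#' Per axis: signature score, cohort rank percentile (average ranks,
#' `(rank - 1) / (n - 1)` so the cohort extremes hit 0 and 1 exactly),
#' scaled to \[0, 5\].  Inverted axes map percentile `p` to `5 * (1 - p)`,
#' so strong immunosuppressive signatures score low.  Axes without a
#' resolvable gene set are flagged not-computed (`NA`) unless
#' `strict = TRUE`.
#'
#' @param expr genes x samples TPM matrix (>= 3 samples).
#' @param axis_config axis list as from [default_igs_config()].
#' @param strict error (rather than flag) on unresolvable axes.
#' @return numeric samples x axes matrix in \[0, 5\] with `NA` columns for
#'   not-computed axes; attribute `not_computed` lists them.
#' @export
compute_immunogram <- function(expr, axis_config = default_igs_config(),
                               strict = FALSE) {
  if (ncol(expr) < 3) stop("need >= 3 samples for percentile scaling")
  n <- ncol(expr)
  out <- matrix(NA_real_, nrow = n, ncol = length(axis_config),
                dimnames = list(colnames(expr), names(axis_config)))
  skipped <- character(0)
  for (ax in names(axis_config)) {
    cfg <- axis_config[[ax]]
    genes <- intersect(cfg$genes %||% character(0), rownames(expr))
    if (length(genes) == 0) {
      if (strict) stop("axis ", ax, " has no resolvable gene set")
      skipped <- c(skipped, ax)
      next
    }
    sc <- signature_score(expr, genes)
    p <- (rank(sc, ties.method = "average") - 1) / (n - 1)
    out[, ax] <- if (isTRUE(cfg$invert)) 5 * (1 - p) else 5 * p
  }
  attr(out, "not_computed") <- skipped
  out
}
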