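# TCR repertoire preprocessing and diversity: UMI-support filtering of
# clonotype calls followed by Shannon entropy per sample and chain.

#' Filter clonotypes by UMI support
#'
#' Removes clonotype rows supported by fewer than `min_umi` UMIs.  The
#' default of 7 is a deliberately stringent false-positive filter for
#' CDR3 clonotype calls.  Probabilities for diversity are computed after
#' this filter.
#'
#' @param t data.frame with columns `sample_id`, `chain`, `cdr3`,
#'   `umi_count`.
#' @param min_umi minimum supporting UMI count (>= 1).
#' @return filtered data.frame (possibly empty) with attribute `min_umi`.
#' @export
filter_clonotypes <- function(t, min_umi = 7) {
  if (min_umi < 1) stop("min_umi must be >= 1")
  req <- c("sample_id", "chain", "cdr3", "umi_count")
  if (!all(req %in% names(t))) {
    stop("clonotype table must have columns: ", paste(req, collapse = ", "))
  }
  out <- t[t$umi_count >= min_umi, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "min_umi") <- min_umi
  out
}

#' Shannon entropy of TCR repertoires
#'
#' Per (sample, chain): `p_i = umi_i / sum(umi)`,
#' `H = -sum(p_i * log(p_i))`.  Natural-log units (nats) by default.
#' Optionally normalised by `log(richness)` (Pielou evenness).
#'
#' @param t a (typically UMI-filtered) clonotype data.frame.
#' @param base logarithm base (`exp(1)` for nats, 2 for bits).
#' @param normalize divide by the maximal entropy `log(n_clonotypes)`.
#' @return data.frame `sample_id`, `chain`, `n_clonotypes`, `total_umi`,
#'   `entropy`; samples/chains absent from `t` simply yield no row.
#' @export
shannon_entropy <- function(t, base = exp(1), normalize = FALSE) {
  if (nrow(t) == 0) {
    return(data.frame(sample_id = character(0), chain = character(0),
                      n_clonotypes = integer(0), total_umi = numeric(0),
                      entropy = numeric(0)))
  }
  key <- interaction(t$sample_id, t$chain, drop = TRUE)
  parts <- split(t, key)
  rows <- lapply(parts, function(p) {
    pr <- p$umi_count / sum(p$umi_count)
    h <- -sum(pr * log(pr, base = base))
    if (normalize) {
      h <- if (nrow(p) > 1) h / log(nrow(p), base = base) else 0
    }
    data.frame(sample_id = p$sample_id[1], chain = p$chain[1],
               n_clonotypes = nrow(p), total_umi = sum(p$umi_count),
               entropy = h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$sample_id, out$chain), , drop = FALSE]
  rownames(out) <- NULL
  out
}
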