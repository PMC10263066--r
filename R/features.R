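# Feature construction: cell density (log10 cells per gram + 1), fraction
# tables (%CD45, %CD4, %CD8, %myeloid, percent-of-parent overlays) and the
# combined z-scaled feature matrix used for clustering.

#' Cell density on the log10 cells-per-gram scale
#'
#' `log10(count / mass_g + 1)`.  Zero counts map to exactly 0.
#'
#' @param count non-negative cell count (vectorised).
#' @param mass_g tissue mass in grams (> 0).
#' @return numeric density value(s).
#' @export
cell_density <- function(count, mass_g) {
  if (any(mass_g <= 0)) stop("mass_g must be > 0")
  if (any(count < 0)) stop("count must be >= 0")
  log10(count / mass_g + 1)
}

#' Feature-set presets
#'
#' `"fig2"` carries the eleven top-level immune cell types (no subsets or
#' functional overlays) used for the subtype clustering; `"fig1g_23"`
#' carries all 23 cell types (still no overlays).
#'
#' @param preset preset name.
#' @return character vector of population ids.
#' @export
feature_presets <- function(preset = c("fig2", "fig1g_23")) {
  preset <- match.arg(preset)
  top <- c("cd4_t", "cd8_t", "nkt_cd4", "nkt_cd8", "b_cell", "nk",
           "cdc", "pdc", "macrophage", "mmdsc", "cd14_mono")
  if (preset == "fig2") return(top)
  c(top, "cd4_naive", "cd4_cm", "cd4_em", "cd4_emra",
    "treg", "treg_fr1", "treg_fr2", "treg_fr3",
    "cd8_naive", "cd8_cm", "cd8_em", "cd8_emra")
}

#' Fraction tables with hierarchy-aware denominators
#'
#' Computes percentage tables: `%CD45` (cell types per CD45+ cells), `%CD4`
#' (CD4 subsets per total CD4+ T), `%CD8`, `%myeloid`, and percent-of-parent
#' for functional overlay populations.  Zero denominators yield `NA`
#' (missing, not zero).
#'
#' @param counts_list list of `population_counts` from [gate_events()].
#' @param tree the `gating_tree` the counts came from.
#' @return list of numeric matrices (`pct_cd45`, `pct_cd4`, `pct_cd8`,
#'   `pct_myeloid`, `pct_overlay`), percentages in \[0, 100\] or `NA`.
#' @export
fraction_tables <- function(counts_list, tree = load_gating_config()) {
  cm <- counts_matrix(counts_list)
  tm <- totals_matrix(counts_list)
  cls <- vapply(tree$populations, function(p) p$class %||% "type",
                character(1))
  fgrp <- vapply(tree$populations, function(p) p$fraction_group %||% "",
                 character(1))
  ids <- tree$population_ids
  pct <- function(num, den) {
    out <- sweep(num, 1, den, "/") * 100
    out[den == 0, ] <- NA_real_
    out
  }
  types <- ids[cls == "type"]
  res <- list(pct_cd45 = pct(cm[, types, drop = FALSE], tm[, "cd45"]))
  for (g in c("cd4", "cd8", "myeloid")) {
    sel <- ids[fgrp == g]
    res[[paste0("pct_", g)]] <- pct(cm[, sel, drop = FALSE], tm[, g])
  }
  ov <- ids[cls == "overlay"]
  if (length(ov)) {
    par <- vapply(tree$populations[match(ov, ids)],
                  function(p) p$parent_population, character(1))
    po <- sapply(seq_along(ov), function(i) {
      den <- cm[, par[i]]
      out <- cm[, ov[i]] / den * 100
      out[den == 0] <- NA_real_
      out
    })
    po <- matrix(po, nrow = nrow(cm),
                 dimnames = list(rownames(cm), paste0(ov, "_of_", par)))
    res$pct_overlay <- po
  }
  zero_den <- rownames(tm)[tm[, "cd45"] == 0]
  if (length(zero_den)) {
    message("zero CD45 denominator; fractions recorded as missing for: ",
            paste(zero_den, collapse = ", "))
  }
  res
}

#' Combined density + %CD45 feature matrix
#'
#' For every population in the chosen preset, computes the cell density
#' (`log10(count/mass + 1)`) and the %CD45 fraction, z-scales each feature
#' across the supplied samples (sample-sd convention, n - 1), and
#' concatenates the two blocks with `dens_` / `pcd45_` column prefixes.
#' Constant features map to z = 0 with a warning; missing values are
#' excluded from the moments and retained as missing.  The scaling cohort
#' is exactly the set of samples passed in, so callers decide whether
#' tumors and NATs are scaled together or tumors alone.
#'
#' @param counts_list list of `population_counts`.
#' @param masses named numeric vector of tissue masses (grams), covering
#'   every sample.
#' @param preset feature-set preset name (see [feature_presets()]), or a
#'   character vector of population ids.
#' @param tree the `gating_tree` the counts came from.
#' @return numeric samples x features matrix (class `feature_matrix`) with
#'   `center` / `scale` attributes for provenance.
#' @export
build_feature_matrix <- function(counts_list, masses,
                                 preset = "fig2",
                                 tree = load_gating_config()) {
  if (length(counts_list) < 2) stop("need >= 2 samples")
  pops <- if (length(preset) == 1 && preset %in% c("fig2", "fig1g_23")) {
    feature_presets(preset)
  } else {
    preset
  }
  cm <- counts_matrix(counts_list)
  tm <- totals_matrix(counts_list)
  if (!all(pops %in% colnames(cm))) {
    stop("preset population(s) absent from counts: ",
         paste(setdiff(pops, colnames(cm)), collapse = ", "))
  }
  if (!all(rownames(cm) %in% names(masses))) {
    stop("missing mass for sample(s): ",
         paste(setdiff(rownames(cm), names(masses)), collapse = ", "))
  }
  mass <- masses[rownames(cm)]
  dens <- apply(cm[, pops, drop = FALSE], 2, cell_density, mass_g = mass)
  frac <- sweep(cm[, pops, drop = FALSE], 1, tm[, "cd45"], "/") * 100
  frac[tm[, "cd45"] == 0, ] <- NA_real_
  colnames(dens) <- paste0("dens_", pops)
  colnames(frac) <- paste0("pcd45_", pops)
  raw <- cbind(dens, frac)
  z <- zscale_columns(raw)
  structure(z, class = c("feature_matrix", class(z)))
}
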