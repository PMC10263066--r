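# Subtype discovery: Spearman correlation distance between sample feature
# profiles, natively implemented Ward.D2 agglomeration (Lance-Williams on
# squared dissimilarities, heights on the unsquared scale), tree cutting,
# and the automated Cold / Myeloid / CD8 labelling rule.

#' Spearman correlation distance between samples
#'
#' `d(i, j) = 1 - rho_spearman(row i, row j)`, ranks computed per sample
#' with average ranks for ties; missing entries handled pairwise-complete.
#'
#' @param m samples x features numeric matrix (e.g. a `feature_matrix`).
#' @return symmetric distance matrix with zero diagonal, entries in
#'   \[0, 2\].
#' @export
spearman_distance <- function(m) {
  m <- unclass(m)
  if (nrow(m) < 2 || ncol(m) < 2) stop("need >= 2 samples and >= 2 features")
  n_ok <- rowSums(!is.na(m))
  if (any(n_ok < 3)) {
    stop("sample(s) with < 3 non-missing features: ",
         paste(rownames(m)[n_ok < 3], collapse = ", "))
  }
  rho <- stats::cor(t(m), method = "spearman",
                    use = "pairwise.complete.obs")
  d <- 1 - rho
  diag(d) <- 0
  d
}

#' Ward.D2 agglomerative clustering
#'
#' Native Lance-Williams implementation of the ward.D2 criterion: the
#' recurrence is applied to squared input dissimilarities and merge heights
#' are reported on the unsquared scale.  Ties in the minimum-dissimilarity
#' search are broken deterministically towards the pair containing the
#' lowest cluster index.  The result is a standard `hclust` object, so
#' `stats::cutree()` and plotting work unchanged.
#'
#' @param d symmetric dissimilarity matrix (or `dist`).
#' @return an object of class `hclust` with `method = "ward.D2"`.
#' @export
ward_d2_linkage <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2) stop("need >= 2 observations")
  if (!isTRUE(all.equal(dm, t(dm), tolerance = 1e-8))) {
    stop("dissimilarity matrix must be symmetric")
  }
  if (any(dm < -1e-12)) stop("dissimilarities must be non-negative")
  labels <- rownames(dm) %||% as.character(seq_len(n))

  D2 <- dm^2
  diag(D2) <- Inf
  size <- rep(1, n)
  active <- rep(TRUE, n)
  code <- -seq_len(n)                 # hclust merge codes
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)

  for (s in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- D2[idx, idx, drop = FALSE]
    best <- min(sub)
    w <- which(sub == best, arr.ind = TRUE)
    w <- w[w[, 1] < w[, 2], , drop = FALSE]
    # deterministic tie-break: lowest first slot, then lowest second slot
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
    i <- idx[w[1, 1]]
    j <- idx[w[1, 2]]
    height[s] <- sqrt(max(D2[i, j], 0))
    merge[s, ] <- c(code[i], code[j])

    keep <- idx[idx != i & idx != j]
    if (length(keep)) {
      ni <- size[i]; nj <- size[j]; nk <- size[keep]
      upd <- ((ni + nk) * D2[i, keep] + (nj + nk) * D2[j, keep] -
                nk * D2[i, j]) / (ni + nj + nk)
      D2[i, keep] <- upd
      D2[keep, i] <- upd
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    code[i] <- s
  }

  order <- integer(0)
  expand <- function(k) {
    if (k < 0) return(-k)
    c(expand(merge[k, 1]), expand(merge[k, 2]))
  }
  order <- expand(n - 1L)

  structure(list(
    merge = merge, height = height, order = order, labels = labels,
    method = "ward.D2", call = match.call(), dist.method = "user"
  ), class = "hclust")
}

#' Cut a dendrogram into k groups
#'
#' Groups are renumbered stably by order of first appearance along the
#' dendrogram leaf order, so group 1 is always the leftmost clade.
#'
#' @param dend an `hclust` object.
#' @param k number of groups, `1 <= k <= n`.
#' @return named integer vector of group memberships.
#' @export
cut_clusters <- function(dend, k) {
  n <- length(dend$labels)
  if (k < 1 || k > n) stop("k must be in [1, ", n, "]")
  g <- stats::cutree(dend, k = k)
  first <- g[dend$order]
  remap <- stats::setNames(seq_along(unique(first)), unique(first))
  out <- remap[as.character(g)]
  stats::setNames(as.integer(out), names(g))
}

#' Label three clusters as Cold / Myeloid / CD8
#'
#' Decision rule mirroring the qualitative cluster descriptions: the group
#' with the lowest mean total CD45+ cell density is `Cold`; of the
#' remaining two, the group with the higher mean myeloid %CD45 (macrophage
#' + mMDSC + CD14+ monocyte) is `Myeloid` and the other `CD8`.  An exact
#' tie on the myeloid fraction is broken by assigning `CD8` to the group
#' with the higher T-cell %CD45 (with a warning).
#'
#' @param groups named integer vector with exactly 3 distinct groups.
#' @param counts_list list of `population_counts` for the same samples.
#' @param masses named numeric masses (grams).
#' @param tree the `gating_tree` used for gating.
#' @return named character vector of subtype labels, with attribute
#'   `group_map` giving the group -> subtype assignment.
#' @export
label_subtypes <- function(groups, counts_list, masses,
                           tree = load_gating_config()) {
  if (length(unique(groups)) != 3) {
    stop("labelling rule requires exactly 3 groups, got ",
         length(unique(groups)))
  }
  cm <- counts_matrix(counts_list)[names(groups), , drop = FALSE]
  tm <- totals_matrix(counts_list)[names(groups), , drop = FALSE]
  mass <- masses[names(groups)]
  dens_cd45 <- cell_density(tm[, "cd45"], mass)
  myeloid_pct <- tm[, "myeloid"] / tm[, "cd45"] * 100
  t_pct <- (cm[, "cd4_t"] + cm[, "cd8_t"] + cm[, "nkt_cd4"] +
              cm[, "nkt_cd8"]) / tm[, "cd45"] * 100

  gids <- sort(unique(groups))
  mean_by <- function(v) {
    vapply(gids, function(g) mean(v[groups == g], na.rm = TRUE), numeric(1))
  }
  m_dens <- mean_by(dens_cd45)
  cold <- gids[which.min(m_dens)]
  rest <- setdiff(gids, cold)
  m_mye <- mean_by(myeloid_pct)[match(rest, gids)]
  if (isTRUE(all.equal(m_mye[1], m_mye[2]))) {
    warning("tie on myeloid fraction; breaking by T-cell %CD45")
    m_t <- mean_by(t_pct)[match(rest, gids)]
    cd8 <- rest[which.max(m_t)]
    myeloid <- setdiff(rest, cd8)
  } else {
    myeloid <- rest[which.max(m_mye)]
    cd8 <- setdiff(rest, myeloid)
  }
  map <- stats::setNames(character(3), as.character(gids))
  map[as.character(cold)] <- "Cold"
  map[as.character(myeloid)] <- "Myeloid"
  map[as.character(cd8)] <- "CD8"
  out <- map[as.character(groups)]
  names(out) <- names(groups)
  attr(out, "group_map") <- map
  out
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected partition agreement in \[-1, 1\].
#'
#' @param a,b label vectors over the same samples.
#' @return numeric ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("labelings differ in length")
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(0)
  (sum_ij - expected) / (max_index - expected)
}

#' Fit the TIL immune-subtype model
#'
#' End-to-end subtype fit from gated counts: builds the combined density +
#' %CD45 feature matrix, computes Spearman correlation distance, runs
#' Ward.D2 agglomeration, cuts the tree at `k`, and (for `k = 3`) applies
#' the Cold / Myeloid / CD8 labelling rule.
#'
#' @param counts_list list of `population_counts` from [gate_cohort()].
#' @param masses named numeric masses in grams.
#' @param k number of clusters (default 3, the three immune subtypes).
#' @param preset feature-set preset (see [feature_presets()]).
#' @param tree the `gating_tree` used for gating.
#' @return an object of class `til_subtype` with components `features`,
#'   `distance`, `dendrogram` (`hclust`), `groups`, `subtype` (named
#'   character, `k = 3` only), `k`, `call`.
#' @export
til_subtype <- function(counts_list, masses, k = 3, preset = "fig2",
                        tree = load_gating_config()) {
  fm <- build_feature_matrix(counts_list, masses, preset = preset,
                             tree = tree)
  d <- spearman_distance(fm)
  hc <- ward_d2_linkage(d)
  groups <- cut_clusters(hc, k)
  subtype <- if (k == 3) {
    label_subtypes(groups, counts_list, masses, tree = tree)
  } else {
    NULL
  }
  structure(list(
    features = fm, distance = d, dendrogram = hc, groups = groups,
    subtype = subtype, k = k, n = nrow(fm), preset = preset,
    call = match.call()
  ), class = "til_subtype")
}

#' @export
print.til_subtype <- function(x, ...) {
  cat("TIL immune-subtype fit (Ward.D2 on Spearman correlation distance)\n")
  cat("  samples:", x$n, "  features:", ncol(x$features),
      " (preset '", x$preset, "')\n", sep = "")
  cat("  k =", x$k, "\n")
  if (!is.null(x$subtype)) {
    print(table(subtype = x$subtype))
  } else {
    print(table(group = x$groups))
  }
  invisible(x)
}

#' @export
summary.til_subtype <- function(object, ...) {
  lab <- object$subtype %||% object$groups
  fm <- unclass(object$features)
  by_grp <- t(vapply(split(seq_along(lab), lab), function(idx) {
    colMeans(fm[idx, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(fm))))
  out <- list(k = object$k, sizes = table(lab), feature_means = by_grp)
  class(out) <- "summary.til_subtype"
  out
}

#' @export
print.summary.til_subtype <- function(x, ...) {
  cat("TIL subtype summary (k =", x$k, ")\n\nGroup sizes:\n")
  print(x$sizes)
  cat("\nMean z-scaled features by group (first 8 columns):\n")
  print(round(x$feature_means[, seq_len(min(8, ncol(x$feature_means))),
                              drop = FALSE], 2))
  invisible(x)
}

#' Plot a fitted subtype dendrogram
#'
#' @param x a `til_subtype` object.
#' @param ... passed to `plot.hclust`.
#' @export
plot.til_subtype <- function(x, ...) {
  graphics::plot(x$dendrogram, labels = FALSE, hang = -1,
                 main = "Ward.D2 / Spearman TIL clustering",
                 xlab = "", sub = "", ...)
  lab <- x$subtype %||% as.character(x$groups)
  cols <- c(Cold = "#4575b4", Myeloid = "#d73027", CD8 = "#1a9850")
  ord <- x$dendrogram$order
  pc <- cols[lab[ord]]
  pc[is.na(pc)] <- "grey40"
  graphics::points(seq_along(ord), rep(0, length(ord)), pch = 15, col = pc)
  invisible(x)
}
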