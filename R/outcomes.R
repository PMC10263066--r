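# Outcome reporting: Kaplan-Meier / log-rank by subtype, univariate Cox
# z-score scans over immune features, univariate -> multivariate Cox
# selection with the exp(-coef) reporting orientation, and Fisher-exact
# association scans with dual-threshold Holm flagging.
#
# Proportional-hazards fitting and exact-test internals delegate to
# survival::coxph / survdiff and stats::fisher.test; the bespoke content is
# the scan orchestration, the selection rule and the flagging scheme.

.flag_scan <- function(p_raw, raw_tier = 0.05, holm_tier = 0.2) {
  p_holm <- stats::p.adjust(p_raw, method = "holm")
  data.frame(p = p_raw, p_holm = p_holm,
             flag_raw = !is.na(p_raw) & p_raw <= raw_tier,
             flag_holm = !is.na(p_holm) & p_holm <= holm_tier)
}

#' Kaplan-Meier curves and log-rank tests by group
#'
#' @param clinical data.frame with `efs_months`, `event` and the grouping
#'   column.
#' @param group_by name of the grouping column (default `subtype`).
#' @return list with `fit` (a `survfit`), `global` (chisq, df, p) and
#'   `pairwise` (data.frame of pairwise log-rank p values).
#' @export
km_logrank <- function(clinical, group_by = "subtype") {
  g <- factor(clinical[[group_by]])
  if (nlevels(g) < 2) stop("need >= 2 groups for a log-rank comparison")
  if (sum(clinical$event) < 1) {
    stop("no events observed; log-rank statistic undefined")
  }
  s <- survival::Surv(clinical$efs_months, clinical$event)
  fit <- survival::survfit(s ~ g)
  sd <- survival::survdiff(s ~ g)
  global_p <- stats::pchisq(sd$chisq, df = nlevels(g) - 1,
                            lower.tail = FALSE)
  prs <- utils::combn(levels(g), 2, simplify = FALSE)
  pairwise <- do.call(rbind, lapply(prs, function(pr) {
    sel <- g %in% pr
    sub <- survival::survdiff(s[sel] ~ droplevels(g[sel]))
    data.frame(group1 = pr[1], group2 = pr[2],
               chisq = sub$chisq,
               p = stats::pchisq(sub$chisq, df = 1, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  list(fit = fit, global = list(chisq = sd$chisq, df = nlevels(g) - 1,
                                p = global_p), pairwise = pairwise)
}

#' Univariate Cox z-score scan over features
#'
#' One proportional-hazards fit per feature column (Efron ties); positive
#' z means higher feature value, higher hazard.  Features with fewer than
#' `min_n` non-missing samples, constant values, or non-convergent fits
#' are reported as failed rows and the scan continues.  Holm adjustment
#' and the dual flag tiers (raw p <= 0.05, Holm p <= 0.2) are computed over
#' the successfully fitted family.
#'
#' @param features samples x features numeric matrix (rownames = sample
#'   ids), e.g. a density or fraction table.
#' @param clinical data.frame with `sample_id`, `efs_months`, `event`.
#' @param min_n minimum non-missing samples per feature.
#' @return data.frame `feature`, `n`, `coef`, `z`, `p`, `p_holm`,
#'   `flag_raw`, `flag_holm`, `status`.
#' @export
cox_scan <- function(features, clinical, min_n = 10) {
  idx <- match(clinical$sample_id, rownames(features))
  if (anyNA(idx)) stop("features missing for some clinical samples")
  fm <- features[idx, , drop = FALSE]
  res <- lapply(colnames(fm), function(f) {
    x <- fm[, f]
    ok <- !is.na(x) & !is.na(clinical$efs_months)
    if (sum(ok) < min_n || stats::sd(x[ok]) == 0) {
      return(data.frame(feature = f, n = sum(ok), coef = NA_real_,
                        z = NA_real_, p = NA_real_, status = "failed"))
    }
    fit <- tryCatch(
      suppressWarnings(survival::coxph(
        survival::Surv(clinical$efs_months[ok], clinical$event[ok]) ~ x[ok],
        ties = "efron")),
      error = function(e) NULL
    )
    if (is.null(fit) || anyNA(stats::coef(fit))) {
      return(data.frame(feature = f, n = sum(ok), coef = NA_real_,
                        z = NA_real_, p = NA_real_, status = "failed"))
    }
    sm <- summary(fit)$coefficients
    data.frame(feature = f, n = sum(ok), coef = sm[1, "coef"],
               z = sm[1, "z"], p = sm[1, "Pr(>|z|)"], status = "ok",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ok <- out$status == "ok"
  out$p_holm <- NA_real_
  out$flag_raw <- FALSE
  out$flag_holm <- FALSE
  if (any(ok)) {
    fl <- .flag_scan(out$p[ok])
    out$p_holm[ok] <- fl$p_holm
    out$flag_raw[ok] <- fl$flag_raw
    out$flag_holm[ok] <- fl$flag_holm
  }
  rownames(out) <- NULL
  out
}

#' Univariate and multivariate Cox analysis over binary contrasts
#'
#' Each contrast row names a clinical column and a pair of levels
#' (`ref vs. alt`); samples outside the pair are excluded from that
#' contrast.  Hazard ratios are reported as `exp(-coef)` with the
#' indicator coded 1 for the reference level, i.e. the hazard of `alt`
#' relative to `ref` -- the orientation in which "ref vs. alt" rows read
#' naturally.  Contrasts significant in the univariate pass
#' (p < `selection_alpha`) enter a joint multivariate fit on the samples
#' complete for all selected contrasts.
#'
#' @param clinical data.frame with `efs_months`, `event` and the factor
#'   columns.
#' @param contrasts data.frame with columns `name`, `column`, `ref`,
#'   `alt`.
#' @param selection_alpha univariate inclusion threshold (default 0.05).
#'
#' @details When several selected contrasts address the same clinical
#' column (e.g. `CD8 vs. Myeloid` and `CD8 vs. Cold` both on `subtype`),
#' only the most significant of them enters the joint fit: jointly coding
#' overlapping pairwise contrasts would restrict the complete cases to the
#' samples shared by all pairs (here, the reference level alone).
#'
#' @return list with `univariate`, `multivariate` data.frames (columns
#'   `name`, `contrast`, `hr`, `lower95`, `upper95`, `p`) and `selected`.
#' @export
multivariate_cox <- function(clinical, contrasts, selection_alpha = 0.05) {
  code_one <- function(cc) {
    v <- clinical[[cc$column]]
    x <- rep(NA_real_, nrow(clinical))
    x[v == cc$ref] <- 1
    x[v == cc$alt] <- 0
    x
  }
  rows <- lapply(seq_len(nrow(contrasts)), function(i) {
    cc <- contrasts[i, ]
    x <- code_one(cc)
    ok <- !is.na(x)
    fit <- tryCatch(
      suppressWarnings(survival::coxph(
        survival::Surv(clinical$efs_months[ok], clinical$event[ok]) ~ x[ok],
        ties = "efron")),
      error = function(e) NULL
    )
    if (is.null(fit)) {
      return(data.frame(name = cc$name,
                        contrast = paste(cc$ref, "vs.", cc$alt),
                        n = sum(ok), hr = NA_real_, lower95 = NA_real_,
                        upper95 = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    sm <- summary(fit)$coefficients
    se <- sm[1, "se(coef)"]
    cf <- sm[1, "coef"]
    data.frame(name = cc$name, contrast = paste(cc$ref, "vs.", cc$alt),
               n = sum(ok),
               hr = exp(-cf),
               lower95 = exp(-cf - 1.96 * se),
               upper95 = exp(-cf + 1.96 * se),
               p = sm[1, "Pr(>|z|)"], stringsAsFactors = FALSE)
  })
  uni <- do.call(rbind, rows)
  sel <- which(!is.na(uni$p) & uni$p < selection_alpha)
  if (length(sel) > 1) {
    by_col <- split(sel, contrasts$column[sel])
    sel <- sort(vapply(by_col, function(ii) ii[which.min(uni$p[ii])],
                       integer(1)))
  }
  multi <- uni[0, ]
  if (length(sel) > 0) {
    X <- vapply(sel, function(i) code_one(contrasts[i, ]),
                numeric(nrow(clinical)))
    X <- matrix(X, ncol = length(sel),
                dimnames = list(NULL, uni$name[sel]))
    ok <- stats::complete.cases(X)
    Xok <- X[ok, , drop = FALSE]
    if (qr(cbind(1, Xok))$rank < ncol(Xok) + 1) {
      stop("multivariate design is rank deficient; collinear factors among: ",
           paste(colnames(Xok), collapse = ", "))
    }
    fit <- survival::coxph(
      survival::Surv(clinical$efs_months[ok], clinical$event[ok]) ~ Xok,
      ties = "efron")
    sm <- summary(fit)$coefficients
    multi <- data.frame(
      name = uni$name[sel], contrast = uni$contrast[sel], n = sum(ok),
      hr = exp(-sm[, "coef"]),
      lower95 = exp(-sm[, "coef"] - 1.96 * sm[, "se(coef)"]),
      upper95 = exp(-sm[, "coef"] + 1.96 * sm[, "se(coef)"]),
      p = sm[, "Pr(>|z|)"], stringsAsFactors = FALSE)
    rownames(multi) <- NULL
  }
  list(univariate = uni, multivariate = multi,
       selected = uni$name[sel])
}

#' Fisher-exact association scan with Holm flagging
#'
#' One Fisher exact test per contingency table (exact for 2x2 or small
#' tables, Monte-Carlo with a fixed seed for large non-2x2 tables), Holm
#' adjustment across the scanned family, and the dual flag tiers: raw
#' p <= 0.05 and Holm-adjusted p <= 0.2.  Tables with an empty margin are
#' skipped with a warning.
#'
#' @param tables named list of contingency matrices (factor x subtype).
#' @param exact_limit largest table total for exact enumeration of r x c
#'   tables.
#' @param mc_B Monte-Carlo replicates for large tables.
#' @param seed seed for the Monte-Carlo path.
#' @return data.frame `factor`, `p`, `p_holm`, `flag_raw`, `flag_holm`,
#'   `method`.
#' @export
fisher_holm_scan <- function(tables, exact_limit = 1000, mc_B = 10000,
                             seed = 1L) {
  stopifnot(length(tables) > 0, !is.null(names(tables)))
  rows <- lapply(names(tables), function(nm) {
    tb <- as.matrix(tables[[nm]])
    if (any(rowSums(tb) == 0) || any(colSums(tb) == 0)) {
      warning("table '", nm, "' has an empty margin; skipped")
      return(data.frame(factor = nm, p = NA_real_, method = "skipped",
                        stringsAsFactors = FALSE))
    }
    if (all(dim(tb) == 2) || sum(tb) <= exact_limit) {
      p <- stats::fisher.test(tb)$p.value
      meth <- "exact"
    } else {
      p <- with_seed(seed, stats::fisher.test(
        tb, simulate.p.value = TRUE, B = mc_B)$p.value)
      meth <- "monte-carlo"
    }
    data.frame(factor = nm, p = p, method = meth, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$p)
  out$p_holm <- NA_real_
  out$flag_raw <- FALSE
  out$flag_holm <- FALSE
  if (any(ok)) {
    fl <- .flag_scan(out$p[ok])
    out$p_holm[ok] <- fl$p_holm
    out$flag_raw[ok] <- fl$flag_raw
    out$flag_holm[ok] <- fl$flag_holm
  }
  rownames(out) <- NULL
  out
}
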