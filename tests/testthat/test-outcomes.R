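test_that("log-rank handles identical, degenerate and grouped inputs", {
  base <- data.frame(sample_id = sprintf("S%02d", 1:20),
                     efs_months = rep(c(10, 20, 30, 40, 50), 4),
                     event = rep(c(1, 0), 10),
                     subtype = rep(c("A", "B"), each = 10),
                     stringsAsFactors = FALSE)
  # identical survival data in both groups: statistic is zero
  base$efs_months[11:20] <- base$efs_months[1:10]
  base$event[11:20] <- base$event[1:10]
  km <- km_logrank(base)
  expect_lt(km$global$chisq, 1e-10)
  expect_equal(nrow(km$pairwise), 1L)

  one <- base[base$subtype == "A", ]
  expect_error(km_logrank(one), ">= 2 groups")
  none <- base
  none$event <- 0
  expect_error(km_logrank(none), "no events")
})

test_that("log-rank is invariant under group relabeling", {
  labels <- stats::setNames(rep(c("Myeloid", "CD8"), each = 25),
                            sprintf("S%02d", 1:50))
  cl <- simulate_clinical(labels, seed = 8)
  km1 <- km_logrank(cl)
  cl2 <- cl
  cl2$subtype <- ifelse(cl$subtype == "Myeloid", "grpX", "grpY")
  km2 <- km_logrank(cl2)
  expect_equal(km1$global$chisq, km2$global$chisq)
})

test_that("the cox scan flags planted effects and survives failures", {
  set.seed(61)
  n <- 150
  risk <- rnorm(n)
  rate <- 0.02 * exp(0.9 * risk)
  tt <- rexp(n, rate)
  cens <- runif(n, 20, 80)
  clinical <- data.frame(sample_id = sprintf("S%03d", 1:n),
                         efs_months = pmin(tt, cens),
                         event = as.integer(tt <= cens))
  features <- cbind(planted = risk,
                    noise = rnorm(n),
                    constant = rep(1, n))
  rownames(features) <- clinical$sample_id
  res <- cox_scan(features, clinical)
  expect_equal(res$status[res$feature == "constant"], "failed")
  expect_true(res$flag_raw[res$feature == "planted"])
  expect_gt(res$z[res$feature == "planted"], 1.96)
  expect_true(all(res$p_holm >= res$p, na.rm = TRUE))
  # small-n floor
  res2 <- cox_scan(features[1:5, , drop = FALSE], clinical[1:5, ])
  expect_true(all(res2$status == "failed"))
})

test_that("multivariate cox applies the selection rule and contrast coding", {
  labels <- stats::setNames(
    rep(c("Cold", "Myeloid", "CD8"), times = c(20, 35, 30)),
    sprintf("S%03d", 1:85))
  cl <- simulate_clinical(labels, seed = 44)
  contr <- data.frame(
    name = c("TIL_CD8_Myeloid", "TIL_CD8_Cold"),
    column = "subtype", ref = "CD8", alt = c("Myeloid", "Cold"),
    stringsAsFactors = FALSE)
  res <- multivariate_cox(cl, contr)
  # the CD8-vs-Myeloid contrast excludes Cold samples
  expect_equal(res$univariate$n[1], sum(labels != "Cold"))
  expect_equal(res$univariate$contrast[1], "CD8 vs. Myeloid")
  # planted Myeloid excess hazard: HR (alt vs ref) above 1
  expect_gt(res$univariate$hr[1], 1)
  # selection: the multivariate block holds the univariate hits, reduced
  # to one contrast per clinical column
  hits <- res$univariate$name[!is.na(res$univariate$p) &
                                res$univariate$p < 0.05]
  expect_true(all(res$multivariate$name %in% hits))
  expect_lte(nrow(res$multivariate), 1L)   # both contrasts share "subtype"
  if (length(hits) > 0) expect_gte(nrow(res$multivariate), 1L)

  # no factor passes a tiny alpha: empty multivariate block
  res0 <- multivariate_cox(cl, contr, selection_alpha = 1e-12)
  expect_equal(nrow(res0$multivariate), 0L)

  # a duplicated clinical column makes the joint design rank deficient
  cl2 <- cl
  cl2$stage_copy <- cl2$stage
  dup <- data.frame(name = c("Stage", "StageCopy"),
                    column = c("stage", "stage_copy"),
                    ref = "I-II", alt = "III-IV", stringsAsFactors = FALSE)
  expect_error(
    suppressWarnings(multivariate_cox(cl2, dup, selection_alpha = 1)),
    "rank deficient")
})

test_that("a single strong planted factor enters the multivariate fit alone", {
  set.seed(88)
  n <- 120
  grp <- rep(c("lo", "hi"), each = n / 2)
  rate <- ifelse(grp == "hi", 0.06, 0.015)
  tt <- rexp(n, rate)
  cens <- runif(n, 30, 90)
  cl <- data.frame(sample_id = sprintf("S%03d", 1:n),
                   efs_months = pmin(tt, cens),
                   event = as.integer(tt <= cens),
                   risk = grp,
                   noise = sample(c("a", "b"), n, replace = TRUE),
                   stringsAsFactors = FALSE)
  contr <- data.frame(name = c("Risk", "Noise"),
                      column = c("risk", "noise"),
                      ref = c("lo", "a"), alt = c("hi", "b"),
                      stringsAsFactors = FALSE)
  res <- multivariate_cox(cl, contr)
  expect_equal(res$selected, "Risk")
  expect_equal(res$multivariate$name, "Risk")
  # univariate and multivariate HR agree (identical model here)
  expect_equal(res$multivariate$hr, res$univariate$hr[1], tolerance = 1e-8)
  expect_gt(res$univariate$hr[1], 1)
})

test_that("fisher scan matches hypergeometric enumeration and Holm rules", {
  tab <- matrix(c(10, 0, 0, 10), 2, 2)
  res <- fisher_holm_scan(list(sep = tab))
  # two-sided exact p from direct hypergeometric enumeration
  probs <- dhyper(0:10, 10, 10, 10)
  p_exact <- sum(probs[probs <= dhyper(10, 10, 10, 10) * (1 + 1e-7)])
  expect_equal(res$p, p_exact, tolerance = 1e-10)
  expect_equal(res$p, 1.083e-5, tolerance = 1e-3)
  expect_true(res$flag_raw && res$flag_holm)

  # independent table: p near 1
  ind <- matrix(c(10, 10, 10, 10), 2, 2)
  expect_gt(fisher_holm_scan(list(ind = ind))$p, 0.9)

  # empty margin is skipped with a warning
  expect_warning(res2 <- fisher_holm_scan(list(
    ok = ind, bad = matrix(c(0, 0, 5, 5), 2, 2))), "empty margin")
  expect_equal(res2$method[res2$factor == "bad"], "skipped")
})

test_that("holm step-down arithmetic and flag tiers are exact", {
  fl <- tilprofiler:::.flag_scan(c(0.01, 0.04))
  expect_equal(fl$p_holm, c(0.02, 0.04))
  expect_true(all(fl$flag_raw))
  expect_true(all(fl$flag_holm))
  # monotonicity on a random family
  set.seed(3)
  p <- runif(12)
  fl2 <- tilprofiler:::.flag_scan(p)
  expect_true(all(fl2$p_holm >= fl2$p))
  ord <- order(fl2$p)
  expect_true(all(diff(fl2$p_holm[ord]) >= -1e-12))
  # hand-computed step-down on a 3-value family
  fl3 <- tilprofiler:::.flag_scan(c(0.03, 0.005, 0.2))
  expect_equal(fl3$p_holm, c(0.06, 0.015, 0.2))
})
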