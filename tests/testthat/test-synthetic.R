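test_that("cohort templates encode the study group sizes", {
  luad <- default_cohort_spec("study_luad")
  expect_equal(sum(luad$groups$n), 85L)
  expect_equal(luad$groups$n[match(c("Cold", "Myeloid", "CD8"),
                                   luad$groups$subtype)],
               c(19L, 36L, 30L))
  lusq <- default_cohort_spec("study_lusq")
  expect_equal(sum(lusq$groups$n), 50L)
  full <- default_cohort_spec("study_full")
  expect_equal(sum(full$groups$n), 85L + 50L + 157L)
  expect_equal(full$groups$n[full$groups$histology == "NAT"], 157L)
  mini <- default_cohort_spec("mini")
  expect_lte(sum(mini$groups$n), 30L)
  expect_true(all(c("Cold", "Myeloid", "CD8") %in% mini$groups$subtype))
  expect_error(default_cohort_spec("nope"), "study_luad")
})

test_that("simulate_fcm_sample validates inputs and honors the mixture", {
  pops <- default_population_specs("CD8")
  expect_error(simulate_fcm_sample(pops, n_events = 0, mass_g = 1),
               "n_events")
  expect_error(simulate_fcm_sample(pops, n_events = 10, mass_g = 0),
               "mass_g")
  bad <- pops
  bad[[1]]$expected_fraction <- bad[[1]]$expected_fraction + 0.5
  expect_error(simulate_fcm_sample(bad, n_events = 10, mass_g = 1),
               "sum to 1")
  wrong <- pops
  names(wrong[[1]]$mean_log_intensity)[1] <- "NOT_A_MARKER"
  expect_error(simulate_fcm_sample(wrong, n_events = 10, mass_g = 1),
               "panel")

  # degenerate mixture: one population takes every event
  fr <- stats::setNames(rep(0, length(pops)),
                        vapply(pops, `[[`, "", "population_id"))
  fr["cd8_em"] <- 1
  one <- default_population_specs("CD8", fractions = fr)
  sim <- simulate_fcm_sample(one, n_events = 1000, mass_g = 1, seed = 7)
  expect_equal(unname(sim$true_counts["cd8_em"]), 1000)
  expect_equal(sum(sim$true_counts), 1000)
})

test_that("true counts follow the multinomial of the planted fractions", {
  pops <- default_population_specs("CD8")
  fr <- stats::setNames(rep(0, length(pops)),
                        vapply(pops, `[[`, "", "population_id"))
  fr["cd4_em"] <- 0.3
  fr["cd8_em"] <- 0.7
  two <- default_population_specs("CD8", fractions = fr)
  sim <- simulate_fcm_sample(two, n_events = 10000, mass_g = 1, seed = 11)
  k <- sim$true_counts[["cd4_em"]]
  # exact binomial 99% envelope
  expect_gte(k, qbinom(0.005, 10000, 0.3))
  expect_lte(k, qbinom(0.995, 10000, 0.3))
})

test_that("cohort simulation is deterministic and plants density effects", {
  spec <- default_cohort_spec("mini")
  a <- simulate_cohort(spec, seed = 33)
  b <- simulate_cohort(spec, seed = 33)
  expect_identical(a$samples, b$samples)
  expect_identical(a$truth, b$truth)

  # Cold-only cohort sits below the Myeloid/CD8 yield
  cold_spec <- spec
  cold_spec$groups <- data.frame(histology = "LUAD", subtype = "Cold",
                                 n = 6L)
  hot_spec <- spec
  hot_spec$groups <- data.frame(histology = "LUAD",
                                subtype = c("Myeloid", "CD8"), n = c(3L, 3L))
  cold <- simulate_cohort(cold_spec, seed = 5)
  hot <- simulate_cohort(hot_spec, seed = 5)
  n_cold <- mean(vapply(cold$truth$true_counts, sum, numeric(1)))
  n_hot <- mean(vapply(hot$truth$true_counts, sum, numeric(1)))
  expect_lt(n_cold, n_hot / 3)
})

test_that("expression simulator plants CD8 chemokine shifts", {
  labels <- stats::setNames(rep(c("Cold", "Myeloid", "CD8"), each = 25),
                            sprintf("S%03d", 1:75))
  tpm <- simulate_expression(labels, seed = 9)
  expect_equal(ncol(tpm), 75)
  expect_true(all(tpm >= 0))
  expect_error(simulate_expression(c(a = "Weird")), "unknown subtype")

  # planted effect direction: CCL5 median higher in CD8 than Myeloid in
  # almost every replicate
  hits <- vapply(1:50, function(r) {
    m <- simulate_expression(labels, seed = 1000 + r)
    stats::median(m["CCL5", labels == "CD8"]) >
      stats::median(m["CCL5", labels == "Myeloid"])
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  # null config: rank-sum rejections near the nominal rate
  null_cfg <- default_gene_config(n_background = 10)
  null_cfg$effect_CD8 <- 0
  null_cfg$effect_Myeloid <- 0
  rej <- vapply(1:100, function(r) {
    m <- simulate_expression(labels, gene_config = null_cfg,
                             seed = 2000 + r)
    stats::wilcox.test(m["CCL5", labels == "CD8"],
                       m["CCL5", labels == "Myeloid"])$p.value < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.12)
})

test_that("tcr simulator spans degenerate and planted-diversity cases", {
  cfg1 <- data.frame(condition = "CD8", richness = 1L, concentration = 1)
  t1 <- simulate_tcr(c(s1 = "CD8"), tcr_config = cfg1, umi_depth = 500,
                     chains = "TRB", seed = 3)
  expect_equal(nrow(t1), 1L)
  expect_equal(t1$umi_count, 500)

  # equal configs: entropy difference centred at zero
  cfg <- data.frame(condition = c("CD8", "Myeloid"),
                    richness = 150L, concentration = 0.4)
  labels <- stats::setNames(rep(c("CD8", "Myeloid"), each = 10),
                            sprintf("S%02d", 1:20))
  gaps <- vapply(1:30, function(r) {
    tt <- simulate_tcr(labels, tcr_config = cfg, umi_depth = 3000,
                       chains = "TRB", seed = 300 + r)
    e <- shannon_entropy(tt)
    mean(e$entropy[labels[e$sample_id] == "CD8"]) -
      mean(e$entropy[labels[e$sample_id] == "Myeloid"])
  }, numeric(1))
  expect_lt(abs(mean(gaps)), 0.1)
})

test_that("a planted diversity gap is recovered near its closed form", {
  # two symmetric-Dirichlet configurations whose expected entropies differ
  # by ~0.5 nats (closed form)
  r1 <- 200L; a1 <- 0.50
  r2 <- 200L
  target <- expected_repertoire_entropy(r1, a1) - 0.5
  f <- function(a) expected_repertoire_entropy(r2, a) - target
  a2 <- uniroot(f, c(0.01, 5), tol = 1e-12)$root
  planted <- expected_repertoire_entropy(r1, a1) -
    expected_repertoire_entropy(r2, a2)
  expect_equal(planted, 0.5, tolerance = 1e-6)

  cfg <- data.frame(condition = c("CD8", "Myeloid"),
                    richness = c(r1, r2), concentration = c(a1, a2))
  labels <- c(hi = "CD8", lo = "Myeloid")
  gaps <- vapply(1:50, function(r) {
    tt <- simulate_tcr(labels, tcr_config = cfg, umi_depth = 10000,
                       chains = "TRB", seed = 700 + r)
    e <- shannon_entropy(tt)
    e$entropy[e$sample_id == "hi"] - e$entropy[e$sample_id == "lo"]
  }, numeric(1))
  expect_lt(abs(mean(gaps) - 0.5), 0.15)
})

test_that("clinical simulator respects hazard and censoring contracts", {
  labels <- stats::setNames(rep(c("Myeloid", "CD8"), each = 30),
                            sprintf("S%02d", 1:60))
  expect_error(simulate_clinical(labels, hazard_config = c(
    Myeloid = -1, CD8 = 1)), "positive")

  # full censoring: no events at all
  cl <- simulate_clinical(labels,
                          censor_config = list(min = 36, max = 84, rate = 1),
                          seed = 2)
  expect_true(all(cl$event == 0))
  expect_true(all(cl$efs_months > 0))

  # equal hazards: log-rank near nominal
  eq <- c(Myeloid = 1, CD8 = 1)
  rej <- vapply(1:60, function(r) {
    cli <- simulate_clinical(labels, hazard_config = eq, seed = 400 + r)
    km <- km_logrank(cli)
    km$global$p < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.15)
})
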