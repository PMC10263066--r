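test_that("spearman distance matches hand-computed rank correlations", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1, 3, 2, 4), c = c(4, 3, 2, 1))
  d <- spearman_distance(m)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "c"], 2)        # exactly reversed ranks
  expect_equal(d["a", "b"], 0.2)      # rho = 0.8
  expect_true(isSymmetric(d))
  expect_true(all(d >= 0 & d <= 2 + 1e-12))
})

test_that("spearman distance rejects samples with too few features", {
  m <- rbind(a = c(1, NA, NA, NA), b = c(1, 2, 3, 4))
  expect_error(spearman_distance(m), "a")
})

test_that("ward.D2 linkage reproduces the variance-increase oracle", {
  # three 1-D points: closest pair merges first
  x <- matrix(c(0, 1, 10), ncol = 1)
  hc <- ward_d2_linkage(as.matrix(dist(x)))
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))

  # identical samples merge at height zero
  d0 <- matrix(0, 2, 2)
  hc0 <- ward_d2_linkage(d0)
  expect_equal(hc0$height, 0)

  # random Euclidean instances: merge sequence equals brute force
  set.seed(404)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    X <- matrix(rnorm(n * 3), ncol = 3)
    hc <- ward_d2_linkage(as.matrix(dist(X)))
    expect_identical(hclust_merge_sets(hc), brute_force_ward_sets(X))
  }
})

test_that("ward.D2 linkage agrees with the reference hclust implementation", {
  set.seed(77)
  X <- matrix(rnorm(20 * 4), ncol = 4)
  d <- dist(X)
  ours <- ward_d2_linkage(as.matrix(d))
  ref <- hclust(d, method = "ward.D2")
  expect_equal(sort(ours$height), sort(ref$height), tolerance = 1e-10)
  for (k in 2:6) {
    expect_equal(adjusted_rand_index(cutree(ours, k), cutree(ref, k)), 1)
  }
  # heights are monotone non-decreasing
  expect_true(all(diff(ours$height) > -1e-12))
})

test_that("ward.D2 validates its input", {
  bad <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(ward_d2_linkage(bad), "symmetric")
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(ward_d2_linkage(neg), "non-negative")
})

test_that("cut_clusters covers the trivial cuts and nests partitions", {
  set.seed(5)
  X <- matrix(rnorm(12 * 3), ncol = 3)
  hc <- ward_d2_linkage(as.matrix(dist(X)))
  expect_equal(length(unique(cut_clusters(hc, 1))), 1L)
  expect_equal(length(unique(cut_clusters(hc, 12))), 12L)
  expect_error(cut_clusters(hc, 0), "k must")
  expect_error(cut_clusters(hc, 13), "k must")
  for (k in 3:8) {
    fine <- cut_clusters(hc, k)
    coarse <- cut_clusters(hc, k - 1)
    # every fine group maps into exactly one coarse group
    expect_true(all(tapply(coarse, fine,
                           function(v) length(unique(v))) == 1))
  }
})

test_that("adjusted Rand index matches the direct formula", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(1:6, rep(1, 6)), 0)
  a <- c(1, 1, 1, 2, 2, 3)
  b <- c(1, 2, 1, 2, 2, 3)
  expect_equal(adjusted_rand_index(a, b), ari_from_table(table(a, b)))
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
  skip_if_not_installed("mclust")
  set.seed(11)
  for (rep in 1:10) {
    x <- sample(1:3, 30, replace = TRUE)
    y <- sample(1:4, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y),
                 mclust::adjustedRandIndex(x, y))
  }
})

test_that("the labelling rule recovers planted subtypes on mini cohorts", {
  fx <- mini_fixture()
  tumor <- fx$coh$meta$sample_id[fx$coh$meta$histology != "NAT"]
  fit <- til_subtype(fx$counts[tumor], fx$coh$masses, k = 3,
                     tree = default_tree())
  truth <- fx$coh$truth$subtype[names(fit$subtype)]
  # at 14 tumors a single boundary sample may swap clusters; essentially
  # all labels must match the planted truth
  expect_lte(sum(as.character(fit$subtype) != as.character(truth)), 1L)
  expect_setequal(unique(fit$subtype), c("Cold", "Myeloid", "CD8"))
})

test_that("subtype labels are invariant to group renumbering", {
  fx <- mini_fixture()
  tumor <- fx$coh$meta$sample_id[fx$coh$meta$histology != "NAT"]
  fit <- til_subtype(fx$counts[tumor], fx$coh$masses, k = 3,
                     tree = default_tree())
  g <- fit$groups
  perm <- stats::setNames(c(3L, 1L, 2L), c(1, 2, 3))
  g2 <- stats::setNames(perm[as.character(g)], names(g))
  lab2 <- label_subtypes(g2, fx$counts[tumor], fx$coh$masses,
                         tree = default_tree())
  expect_equal(as.character(lab2[names(fit$subtype)]),
               as.character(fit$subtype))
  expect_error(label_subtypes(g[g != 1], fx$counts[tumor], fx$coh$masses,
                              tree = default_tree()), "3 groups")
})

test_that("identical group profiles trigger the documented tie-break", {
  fx <- mini_fixture()
  tumor <- fx$coh$meta$sample_id[fx$coh$meta$histology != "NAT"][1:3]
  one <- fx$counts[tumor[1]]
  trip <- list(a = one[[1]], b = one[[1]], c = one[[1]])
  trip$a$sample_id <- "a"; trip$b$sample_id <- "b"; trip$c$sample_id <- "c"
  masses <- stats::setNames(rep(0.5, 3), c("a", "b", "c"))
  g <- stats::setNames(1:3, c("a", "b", "c"))
  expect_warning(lab <- label_subtypes(g, trip, masses,
                                       tree = default_tree()), "tie")
  expect_setequal(unname(lab), c("Cold", "Myeloid", "CD8"))
})

test_that("til_subtype objects print, summarise and plot", {
  fx <- mini_fixture()
  tumor <- fx$coh$meta$sample_id[fx$coh$meta$histology != "NAT"]
  fit <- til_subtype(fx$counts[tumor], fx$coh$masses, k = 3,
                     tree = default_tree())
  expect_output(print(fit), "Ward.D2")
  sm <- summary(fit)
  expect_s3_class(sm, "summary.til_subtype")
  expect_output(print(sm), "Group sizes")
  pdf(NULL)
  on.exit(dev.off())
  expect_invisible(plot(fit))
})
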