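test_that("sample assignment takes the largest H coefficient", {
  H <- rbind(c(0.1, 0.7, 0.2), c(0.5, 0.5, 0), c(0.2, 0.3, 0.9))
  expect_equal(assign_samples(fake_fit(H = H)), c(2, 1, 3))
  set.seed(18)
  H <- matrix(runif(40 * 4), 40, 4)
  lab <- assign_samples(fake_fit(H = H))
  for (i in 1:40) expect_equal(lab[i], which.max(H[i, ]))
})

test_that("gene assignment uses max/min W coefficients, flags constants", {
  W <- rbind(c(-1, 0, 2), c(3, 3, 3), c(0.5, -2, 1))
  expect_equal(assign_genes(fake_fit(W = W), "max"), c(3, NA, 3))
  expect_equal(assign_genes(fake_fit(W = W), "min"), c(1, NA, 2))
  set.seed(19)
  W <- matrix(rnorm(60), 20, 3)
  expect_equal(assign_genes(fake_fit(W = W), "max"),
               apply(W, 1, which.max))
})

test_that("Kruskal-Wallis matches the hand-ranked computation", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  kw <- kruskal_wallis_gene(groups)
  expect_equal(kw$statistic, 32 / 7, tolerance = 1e-12)
  expect_equal(kw$p, exp(-(32 / 7) / 2), tolerance = 1e-10)

  # all-identical values: degenerate null, p = 1 by decision
  expect_equal(kruskal_wallis_gene(list(c(2, 2), c(2, 2), c(2, 2))),
               list(statistic = 0, p = 1))
  expect_error(kruskal_wallis_gene(list(1:2, 3:4)), "3 groups")
  expect_error(kruskal_wallis_gene(list(1:2, 3:4, numeric(0))), "empty")

  set.seed(20)
  for (rep in 1:100) {
    groups <- lapply(1:3, function(i) round(rnorm(sample(3:8, 1)), 1))
    kw <- suppressWarnings(kruskal_wallis_gene(groups))
    bf <- bf_kruskal(groups)
    expect_equal(kw$statistic, bf$statistic, tolerance = 1e-10)
    expect_equal(kw$p, bf$p, tolerance = 1e-10)
  }
})

test_that("Dunn z-test matches the hand-ranked computation", {
  groups <- list(c(1, 2), c(3, 4), c(5, 6))
  d <- dunn_pairwise(groups, c(1, 3))
  expect_equal(d$z, (1.5 - 5.5) / sqrt(3.5), tolerance = 1e-12)
  expect_equal(d$p, 2 * pnorm((1.5 - 5.5) / sqrt(3.5)), tolerance = 1e-12)

  expect_equal(dunn_pairwise(groups, c(2, 2)), list(z = 0, p = 1))
  expect_equal(dunn_pairwise(list(c(1, 1), c(1, 1), c(1, 1)), c(1, 2)),
               list(z = 0, p = 1))

  set.seed(21)
  for (rep in 1:100) {
    groups <- lapply(1:4, function(i) round(rnorm(sample(3:8, 1)), 1))
    pr <- sort(sample(4, 2))
    d <- suppressWarnings(dunn_pairwise(groups, pr))
    bf <- bf_dunn(groups, pr)
    expect_equal(d$z, bf$z, tolerance = 1e-10)
    expect_equal(d$p, bf$p, tolerance = 1e-10)
  }
})

test_that("gene filtering recovers planted markers and only removes genes", {
  arm <- generate_disease_dataset(small_design(seed = 22), "A")
  fc <- preprocess_dataset(arm$dataset)$fold_change
  fit <- convex_nmf_fit(fc$values, 3, seed = 23)
  lab <- assign_samples(fit)
  ca <- select_cluster_genes(fc, lab, assign_genes(fit, "max"),
                             assign_genes(fit, "min"))
  map <- match_clusters(lab, arm$truth$sample_cluster)
  for (i in 1:3) {
    planted_up <- arm$truth$up_modules[[map[i]]]
    expect_gte(mean(planted_up %in% ca$G_up[[i]]), 0.9)
    planted_dn <- arm$truth$down_modules[[map[i]]]
    expect_gte(mean(planted_dn %in% ca$G_down[[i]]), 0.9)
    # filtering only removes genes from the raw assignment
    expect_true(all(ca$G_up[[i]] %in%
                      fc$gene_ids[which(ca$up_assignment == i)]))
    expect_true(all(ca$G_down[[i]] %in%
                      fc$gene_ids[which(ca$down_assignment == i)]))
  }
  # a gene is never in two up-sets or two down-sets
  expect_equal(anyDuplicated(unlist(ca$G_up)), 0)
  expect_equal(anyDuplicated(unlist(ca$G_down)), 0)
})

test_that("a gene differing only between other clusters is filtered out", {
  set.seed(24)
  n_per <- 10
  lab <- rep(1:3, each = n_per)
  # gene 1: clusters 1 and 2 identical, cluster 3 shifted; assigned to 1
  # genes 2..20: background noise forming the Bonferroni family
  v <- matrix(rnorm(20 * 30, sd = 0.05), 20, 30)
  v[1, lab == 3] <- v[1, lab == 3] + 5
  fc <- structure(list(values = v, gene_ids = sprintf("g%02d", 1:20),
                       patient_ids = sprintf("p%02d", 1:30),
                       control_means = rep(1, 20)),
                  class = "fold_change_matrix")
  up <- c(1L, rep(NA_integer_, 19))   # force the Max assignment to cluster 1
  dn <- rep(NA_integer_, 20)
  ca <- select_cluster_genes(fc, lab, up, dn)
  expect_false("g01" %in% ca$G_up[[1]])
  # but assigned to its truly distinct cluster it passes
  up3 <- c(3L, rep(NA_integer_, 19))
  ca3 <- select_cluster_genes(fc, lab, up3, dn)
  expect_true("g01" %in% ca3$G_up[[3]])
})

test_that("filtering requires at least three sample clusters", {
  fc <- structure(list(values = matrix(rnorm(20), 2, 10),
                       gene_ids = c("g1", "g2"),
                       patient_ids = sprintf("p%d", 1:10),
                       control_means = c(1, 1)),
                  class = "fold_change_matrix")
  expect_error(select_cluster_genes(fc, rep(1:2, 5), c(1L, 2L), c(2L, 1L)),
               "at least 3")
})
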