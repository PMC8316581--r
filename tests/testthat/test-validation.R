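test_that("zero-epoch logistic regression predicts exactly 0.5", {
  set.seed(37)
  X <- matrix(rnorm(40), 20, 2)
  y <- rep(0:1, 10)
  w <- fit_logistic_gd(X, y, epochs = 0)
  expect_identical(w, rep(0, 3))
  expect_identical(predict_logistic(w, X), rep(0.5, 20))
})

test_that("gradient descent separates separable 1-D data", {
  x <- matrix(c(-(5:1), 1:5), ncol = 1)
  y <- rep(0:1, each = 5)
  w <- fit_logistic_gd(x, y, learning_rate = 0.05, epochs = 500)
  expect_equal(roc_auc(predict_logistic(w, x), y), 1.0)
  expect_gt(w[2], 0)
})

test_that("class-swapped mirror data keeps the intercept at zero", {
  set.seed(38)
  x <- matrix(rnorm(15, mean = 2), ncol = 1)
  X <- rbind(x, -x)
  y <- rep(c(1, 0), each = 15)
  w <- fit_logistic_gd(X, y, epochs = 200)
  expect_lt(abs(w[1]), 1e-10)
})

test_that("logistic input contracts are enforced", {
  expect_error(fit_logistic_gd(matrix(1:4, 2), c(1, 1)), "single class")
  expect_error(fit_logistic_gd(matrix(c(1, NA), 1), 1), "non-finite")
})

test_that("rank-based AUC matches pair enumeration", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(rep(0.3, 8), rep(0:1, 4)), 0.5)
  expect_equal(roc_auc(1:10, rep(0:1, c(5, 5))), 1.0)

  set.seed(39)
  for (rep in 1:50) {
    sc <- round(runif(20), 1)   # ties likely
    lb <- sample(0:1, 20, replace = TRUE, prob = c(0.5, 0.5))
    if (length(unique(lb)) < 2) next
    expect_equal(roc_auc(sc, lb), bf_auc(sc, lb))
  }
  expect_error(roc_auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(40)
  sc <- rnorm(30); lb <- rep(0:1, 15)
  a <- roc_auc(sc, lb)
  expect_equal(roc_auc(exp(sc), lb), a)
  expect_equal(roc_auc(2 * sc - 7, lb), a)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(41)
  for (rep in 1:10) {
    sc <- rnorm(40); lb <- rep(0:1, 20)
    ref <- suppressMessages(as.numeric(
      pROC::auc(pROC::roc(lb, sc, levels = c(0, 1), direction = "<"))
    ))
    expect_equal(roc_auc(sc, lb), ref, tolerance = 1e-12)
  }
})

test_that("stratified folds partition samples and preserve both classes", {
  y <- rep(c(1, 0), c(25, 71))
  fold <- crossnmf:::stratified_folds(y, 3, seed = 42)
  expect_length(fold, 96)
  expect_true(all(fold %in% 1:3))
  for (f in 1:3) {
    expect_gt(sum(y[fold == f] == 1), 0)
    expect_gt(sum(y[fold == f] == 0), 0)
  }
  expect_identical(crossnmf:::stratified_folds(y, 3, seed = 42), fold)
})

test_that("cross-validated AUC separates a planted panel and not noise", {
  arm <- generate_disease_dataset(small_design(seed = 43), "A")
  panel <- unique(unlist(c(arm$truth$up_modules, arm$truth$down_modules)))
  cv <- cross_validated_auc(arm$dataset, panel, n_folds = 5,
                            learning_rate = 0.05, epochs = 300, seed = 44)
  expect_gte(cv$mean_auc, 0.99)
  expect_equal(cv$mean_auc, mean(cv$per_fold_auc))
  expect_length(cv$per_fold_auc, 5)

  # pure-noise data: AUC near chance over a few seeds
  nds <- random_dataset(30, 200, 100, seed = 45)
  aucs <- vapply(1:5, function(s) {
    cross_validated_auc(nds, nds$gene_ids[1:20], n_folds = 5,
                        epochs = 100, seed = 45 + s)$mean_auc
  }, numeric(1))
  expect_gt(mean(aucs), 0.4)
  expect_lt(mean(aucs), 0.6)

  expect_error(cross_validated_auc(arm$dataset, c("absent1", "absent2")),
               "no panel gene")
})

test_that("panel genes missing from the data are dropped with a count", {
  arm <- generate_disease_dataset(small_design(seed = 46), "A")
  panel <- c(arm$truth$up_modules[[1]], "ghost1", "ghost2")
  cv <- cross_validated_auc(arm$dataset, panel, n_folds = 4, epochs = 50,
                            seed = 47)
  expect_equal(cv$n_panel_missing, 2)
  expect_length(cv$gene_panel, length(panel) - 2)
})

test_that("random-gene baseline is seeded and centred under the null", {
  nds <- random_dataset(40, 60, 30, seed = 48)
  b1 <- random_gene_baseline(nds, panel_size = 10, reps = 4, n_folds = 3,
                             epochs = 50, seed = 49)
  b2 <- random_gene_baseline(nds, panel_size = 10, reps = 4, n_folds = 3,
                             epochs = 50, seed = 49)
  expect_identical(b1$baseline_aucs, b2$baseline_aucs)

  # candidate equal to the baseline mean: comparison p close to 1
  b3 <- random_gene_baseline(nds, panel_size = 10, reps = 4, n_folds = 3,
                             epochs = 50, seed = 49,
                             candidate_auc = mean(b1$baseline_aucs))
  expect_gt(b3$p, 0.99)
  expect_error(random_gene_baseline(nds, panel_size = 1000, reps = 3),
               "exceeds")
})

test_that("a planted panel beats every random baseline panel", {
  arm <- generate_disease_dataset(small_design(seed = 50), "A")
  panel <- unique(unlist(arm$truth$up_modules))
  cv <- cross_validated_auc(arm$dataset, panel, n_folds = 5, epochs = 200,
                            seed = 51)
  base <- random_gene_baseline(arm$dataset, panel_size = 10, reps = 20,
                               n_folds = 5, epochs = 200, seed = 52,
                               candidate_auc = cv$mean_auc)
  expect_true(all(base$baseline_aucs <= cv$mean_auc))
  expect_lt(base$p, 0.01)
})

test_that("covariate ANOVA matches the classical F computation", {
  g <- c(1, 2, 3, 11, 12, 13)
  cl <- rep(1:2, each = 3)
  got <- covariate_anova(g, cl)
  bf <- bf_anova(list(1:3, 11:13))
  expect_equal(got$F, 150, tolerance = 1e-12)  # SSB/1 = 150, SSW/4 = 1
  expect_equal(got$F, bf$F, tolerance = 1e-12)
  expect_equal(got$p, bf$p, tolerance = 1e-10)
  expect_lt(got$p, 0.01)

  # copied groups: no between-group variance
  same <- covariate_anova(c(1, 2, 3, 1, 2, 3), rep(1:2, each = 3))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  set.seed(53)
  for (rep in 1:20) {
    groups <- lapply(1:3, function(i) rnorm(sample(4:8, 1)))
    got <- covariate_anova(unlist(groups),
                           rep(seq_along(groups), lengths(groups)))
    bf <- bf_anova(groups)
    expect_equal(got$F, bf$F, tolerance = 1e-10)
    expect_equal(got$p, bf$p, tolerance = 1e-10)
  }
  expect_error(covariate_anova(1:4, c(1, 1, 1, 2)), "fewer than 2")
})
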