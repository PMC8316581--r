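#' Logistic regression by full-batch gradient descent
#'
#' Weights (intercept first) start at zero and are updated for a fixed
#' number of epochs by gradient ascent on the mean log-likelihood with a
#' constant learning rate: `w <- w + lr * t(X1) (y - p) / n`. No
#' regularisation is applied. With `epochs = 0` the returned weights are
#' all zero, so every predicted probability is exactly 0.5.
#'
#' @param X Numeric feature matrix (samples x features).
#' @param y Binary labels (0/1), both classes present.
#' @param learning_rate Step size.
#' @param epochs Number of full-batch updates.
#' @return Numeric weight vector of length `ncol(X) + 1` (intercept first).
#' @export
fit_logistic_gd <- function(X, y, learning_rate = 0.05, epochs = 500L) {
  X <- as.matrix(X)
  if (!all(is.finite(X))) stop("non-finite features", call. = FALSE)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("label count does not match rows", call. = FALSE)
  if (length(unique(y)) < 2L) stop("labels contain a single class", call. = FALSE)
  n <- nrow(X)
  X1 <- cbind(1, X)
  w <- numeric(ncol(X1))
  for (e in seq_len(epochs)) {
    p <- plogis(X1 %*% w)
    w <- w + learning_rate * crossprod(X1, y - p) / n
  }
  as.vector(w)
}

#' Predicted probabilities from logistic weights
#' @param w Weight vector (intercept first).
#' @param X Feature matrix.
#' @return Vector of probabilities.
#' @export
predict_logistic <- function(w, X) {
  as.vector(plogis(cbind(1, as.matrix(X)) %*% w))
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney formulation with half credit for tied scores: the
#' probability that a random positive outscores a random negative.
#'
#' @param scores Numeric prediction scores.
#' @param labels Binary labels (0/1), both classes present.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("both classes required", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Seeded stratified fold assignment
#' @noRd
stratified_folds <- function(y, n_folds, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

#' Cross-validated AUC of a gene panel
#'
#' Stratified seeded k-fold cross-validation of a zero-initialised
#' gradient-descent logistic regression on the panel's expression values
#' (samples x genes, patients = 1 vs controls = 0). Within each fold the
#' features are z-scored with training-fold statistics (constant features
#' get unit scale). Panel genes absent from the dataset are dropped with a
#' recorded count.
#'
#' @param ds An [expression_dataset()].
#' @param panel Character vector of gene identifiers.
#' @param n_folds Folds (default 10).
#' @param learning_rate,epochs Gradient-descent settings.
#' @param seed Seed for the fold assignment.
#' @return Object of class `cv_result` with fields `per_fold_auc`,
#'   `mean_auc`, `n_folds`, `learning_rate`, `epochs`, `seed`,
#'   `gene_panel`, `n_panel_missing`.
#' @export
cross_validated_auc <- function(ds, panel, n_folds = 10L,
                                learning_rate = 0.05, epochs = 500L,
                                seed = 1L) {
  present <- intersect(panel, ds$gene_ids)
  n_missing <- length(setdiff(panel, ds$gene_ids))
  if (!length(present)) {
    stop("no panel gene is measured in the dataset", call. = FALSE)
  }
  y <- as.numeric(ds$group == "patient")
  if (min(sum(y == 1), sum(y == 0)) < n_folds) {
    stop("each class needs at least n_folds samples", call. = FALSE)
  }
  X <- t(ds$values[match(present, ds$gene_ids), , drop = FALSE])
  fold <- stratified_folds(y, n_folds, seed)
  aucs <- vapply(seq_len(n_folds), function(f) {
    tr <- fold != f; te <- !tr
    mu <- colMeans(X[tr, , drop = FALSE])
    sdv <- apply(X[tr, , drop = FALSE], 2L, stats::sd)
    sdv[sdv == 0] <- 1
    Ztr <- sweep(sweep(X[tr, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    Zte <- sweep(sweep(X[te, , drop = FALSE], 2L, mu), 2L, sdv, "/")
    w <- fit_logistic_gd(Ztr, y[tr], learning_rate, epochs)
    roc_auc(predict_logistic(w, Zte), y[te])
  }, numeric(1L))
  structure(
    list(per_fold_auc = aucs, mean_auc = mean(aucs), n_folds = n_folds,
         learning_rate = learning_rate, epochs = epochs, seed = seed,
         gene_panel = present, n_panel_missing = n_missing),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("cv_result: mean AUC %.4f over %d folds (%d panel genes, %d missing)\n",
              x$mean_auc, x$n_folds, length(x$gene_panel), x$n_panel_missing))
  invisible(x)
}

#' Random-gene baseline for a candidate panel
#'
#' Repeats the cross-validated evaluation on `reps` random gene panels of
#' the candidate panel's size and compares the candidate mean AUC to the
#' baseline mean AUCs with a one-sample two-sided t test.
#'
#' @param ds An [expression_dataset()].
#' @param panel_size Number of genes per random panel.
#' @param reps Number of random panels (>= 2).
#' @param candidate_auc Mean AUC of the candidate panel to compare against.
#' @inheritParams cross_validated_auc
#' @return List with `baseline_aucs` (length `reps`), `mean_baseline_auc`
#'   and `p` (comparison t-test p-value; `NA` when `candidate_auc` is not
#'   supplied).
#' @export
random_gene_baseline <- function(ds, panel_size, reps = 100L,
                                 n_folds = 10L, learning_rate = 0.05,
                                 epochs = 500L, seed = 1L,
                                 candidate_auc = NULL) {
  if (panel_size > length(ds$gene_ids)) {
    stop("panel_size exceeds the number of measured genes", call. = FALSE)
  }
  if (reps < 2L) stop("reps must be >= 2", call. = FALSE)
  seeds <- derive_seeds(seed, 2L * reps)
  aucs <- vapply(seq_len(reps), function(r) {
    panel <- with_seed(seeds[r], sample(ds$gene_ids, panel_size))
    cross_validated_auc(ds, panel, n_folds, learning_rate, epochs,
                        seed = seeds[reps + r])$mean_auc
  }, numeric(1L))
  p <- NA_real_
  if (!is.null(candidate_auc)) {
    p <- if (stats::sd(aucs) == 0) {
      if (abs(mean(aucs) - candidate_auc) < 1e-15) 1 else 0
    } else {
      stats::t.test(aucs, mu = candidate_auc)$p.value
    }
  }
  list(baseline_aucs = aucs, mean_baseline_auc = mean(aucs), p = p)
}

#' One-way ANOVA of a covariate across clusters
#'
#' Classical (equal-variance) one-way ANOVA, e.g. of patient age across the
#' discovered sample clusters, to check that the subgrouping is not driven
#' by the covariate.
#'
#' @param covariate Numeric vector, one value per sample.
#' @param clusters Cluster labels, at least 2 clusters with >= 2 samples.
#' @return List with `F` and `p`.
#' @export
covariate_anova <- function(covariate, clusters) {
  cl <- factor(clusters)
  if (nlevels(cl) < 2L) stop("need at least 2 clusters", call. = FALSE)
  if (any(table(cl) < 2L)) stop("cluster with fewer than 2 samples", call. = FALSE)
  if (stats::var(covariate) == 0) return(list(F = 0, p = 1))
  ow <- stats::oneway.test(covariate ~ cl, var.equal = TRUE)
  list(F = unname(ow$statistic), p = unname(ow$p.value))
}
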