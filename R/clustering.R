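#' Assign samples to clusters from a factorization
#'
#' Each sample takes the cluster whose coefficient in its row of `H` is
#' largest ("Max" rule); exact ties go to the lowest cluster index.
#'
#' @param fit A [convex_nmf_fit()].
#' @return Integer vector of cluster labels in `1..k`.
#' @export
assign_samples <- function(fit) {
  argmax_rows(fit$H)
}

#' Assign genes to clusters from the basis matrix
#'
#' The gene coefficients are the rows of `W = A F`. Under the `"max"` rule a
#' gene joins the cluster with its largest coefficient (relatively
#' upregulated there); under `"min"`, the cluster with its smallest
#' coefficient (relatively downregulated). Constant rows carry no direction
#' and are flagged `NA` so the downstream filter skips them.
#'
#' @param fit A [convex_nmf_fit()].
#' @param direction `"max"` or `"min"`.
#' @return Integer vector of cluster labels (`NA` for constant rows).
#' @export
assign_genes <- function(fit, direction = c("max", "min")) {
  direction <- match.arg(direction)
  W <- fit$W
  lab <- if (direction == "max") argmax_rows(W) else argmin_rows(W)
  constant <- apply(W, 1L, function(r) max(r) == min(r))
  lab[constant] <- NA_integer_
  lab
}

#' Kruskal-Wallis test across cluster value groups of one gene
#'
#' Mid-rank Kruskal-Wallis statistic with tie correction, chi-square
#' p-value on k - 1 degrees of freedom. Groups whose pooled values are all
#' identical have zero rank variance; the statistic is undefined there and
#' the test returns `statistic = 0, p = 1` by convention.
#'
#' @param values_by_cluster List of k >= 3 non-empty numeric vectors.
#' @return List with `statistic` and `p`.
#' @export
kruskal_wallis_gene <- function(values_by_cluster) {
  check_groups(values_by_cluster)
  pooled <- unlist(values_by_cluster, use.names = FALSE)
  if (max(pooled) == min(pooled)) return(list(statistic = 0, p = 1))
  g <- rep(seq_along(values_by_cluster), lengths(values_by_cluster))
  kw <- stats::kruskal.test(pooled, factor(g))
  list(statistic = unname(kw$statistic), p = unname(kw$p.value))
}

#' Dunn's post-hoc z test between two cluster value groups
#'
#' Mean-rank comparison on the pooled ranking of all k groups, with tie
#' correction:
#' `z = (R_i - R_j) / sqrt((N(N+1)/12 - sum(t^3 - t)/(12(N-1))) (1/n_i + 1/n_j))`
#' where `R` are group mean ranks, N the pooled size, and the tie sum runs
#' over groups of tied values. Two-sided normal p-value. When all pooled
#' values are tied the denominator vanishes and `z = 0, p = 1` is returned.
#'
#' @param values_by_cluster List of k >= 3 non-empty numeric vectors.
#' @param pair Length-2 integer vector of group indices (i, j).
#' @return List with `z` and `p`.
#' @export
dunn_pairwise <- function(values_by_cluster, pair) {
  check_groups(values_by_cluster)
  i <- pair[1L]; j <- pair[2L]
  if (i == j) return(list(z = 0, p = 1))
  pooled <- unlist(values_by_cluster, use.names = FALSE)
  g <- rep(seq_along(values_by_cluster), lengths(values_by_cluster))
  N <- length(pooled)
  r <- rank(pooled)
  ties <- table(pooled)
  tie_sum <- sum(ties^3 - ties)
  var_term <- N * (N + 1) / 12 - tie_sum / (12 * (N - 1))
  ni <- sum(g == i); nj <- sum(g == j)
  den2 <- var_term * (1 / ni + 1 / nj)
  if (den2 <= 0) return(list(z = 0, p = 1))
  z <- (mean(r[g == i]) - mean(r[g == j])) / sqrt(den2)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' @noRd
check_groups <- function(groups) {
  if (length(groups) < 3L) stop("need at least 3 groups", call. = FALSE)
  if (any(lengths(groups) == 0L)) stop("empty group", call. = FALSE)
  if (any(lengths(groups) == 1L)) {
    warning("group with a single sample; rank tests will have low power")
  }
  invisible(groups)
}

#' Refine gene clusters with Kruskal-Wallis and Dunn filtering
#'
#' For every gene (in each direction) the per-cluster distributions of its
#' fold-change values over the sample clusters are compared: the gene's
#' Kruskal-Wallis p-value is Bonferroni-adjusted over the genes tested in
#' that direction and must fall below `alpha`; surviving genes then need
#' every Dunn pairwise comparison involving their assigned cluster to be
#' significant after Bonferroni adjustment over the `k(k-1)/2` pairs of
#' that gene. Genes passing both filters enter the relatively
#' up/downregulated sets `G_up[[i]]` / `G_down[[i]]` of their assigned
#' cluster.
#'
#' @param fc A `fold_change_matrix` (see [log2_fold_change()]).
#' @param sample_cluster Integer vector of per-patient cluster labels.
#' @param up_assignment,down_assignment Per-gene cluster labels from
#'   [assign_genes()] (`NA` = skipped).
#' @param alpha Significance level (default 0.05).
#' @return Object of class `cluster_assignment` with fields
#'   `sample_cluster`, `up_assignment`, `down_assignment`, `G_up`, `G_down`
#'   (lists of gene-id vectors per cluster), `per_gene_stats` (data frame
#'   with KW statistic, KW q-value and minimum relevant Dunn q per gene and
#'   direction) and `counts` (per-cluster summary table).
#' @export
select_cluster_genes <- function(fc, sample_cluster, up_assignment,
                                 down_assignment, alpha = 0.05) {
  k <- max(sample_cluster)
  if (k < 3L) stop("gene filtering needs at least 3 sample clusters", call. = FALSE)
  if (length(sample_cluster) != ncol(fc$values)) {
    stop("sample_cluster length does not match patient count", call. = FALSE)
  }
  genes <- fc$gene_ids
  idx_by_cluster <- lapply(seq_len(k), function(i) which(sample_cluster == i))
  if (any(lengths(idx_by_cluster) == 0L)) {
    stop("a sample cluster is empty; cannot filter genes", call. = FALSE)
  }
  n_pairs <- k * (k - 1) / 2
  pair_tab <- utils::combn(k, 2L)

  # KW and Dunn depend only on the gene's grouped values, not the direction,
  # so compute them once per testable gene
  testable <- !is.na(up_assignment) | !is.na(down_assignment)
  kw_p <- rep(NA_real_, length(genes))
  kw_stat <- rep(NA_real_, length(genes))
  dunn_p <- matrix(NA_real_, length(genes), n_pairs)
  for (gi in which(testable)) {
    groups <- lapply(idx_by_cluster, function(ix) fc$values[gi, ix])
    kw <- suppressWarnings(kruskal_wallis_gene(groups))
    kw_stat[gi] <- kw$statistic
    kw_p[gi] <- kw$p
  }

  res <- list()
  stats_rows <- list()
  for (direction in c("up", "down")) {
    assignment <- if (direction == "up") up_assignment else down_assignment
    tested <- which(!is.na(assignment))
    n_tested <- length(tested)
    q_kw <- pmin(kw_p * n_tested, 1)
    pass_kw <- tested[!is.na(q_kw[tested]) & q_kw[tested] < alpha]
    sel <- lapply(seq_len(k), function(i) character(0L))
    dunn_q_min <- rep(NA_real_, length(genes))
    for (gi in pass_kw) {
      if (all(!is.na(dunn_p[gi, ]))) {
        dp <- dunn_p[gi, ]
      } else {
        groups <- lapply(idx_by_cluster, function(ix) fc$values[gi, ix])
        dp <- vapply(seq_len(n_pairs), function(pi) {
          suppressWarnings(
            dunn_pairwise(groups, pair_tab[, pi])$p
          )
        }, numeric(1L))
        dunn_p[gi, ] <- dp
      }
      dq <- pmin(dp * n_pairs, 1)
      i <- assignment[gi]
      rel <- pair_tab[1L, ] == i | pair_tab[2L, ] == i
      dunn_q_min[gi] <- max(dq[rel])   # worst pair involving cluster i
      if (all(dq[rel] < alpha)) {
        sel[[i]] <- c(sel[[i]], genes[gi])
      }
    }
    res[[direction]] <- sel
    stats_rows[[direction]] <- data.frame(
      gene_id = genes[tested],
      direction = rep_len(direction, n_tested),
      cluster = assignment[tested],
      kw_statistic = kw_stat[tested],
      kw_q = q_kw[tested],
      dunn_q_worst = dunn_q_min[tested],
      stringsAsFactors = FALSE
    )
  }

  counts <- data.frame(
    cluster = seq_len(k),
    n_samples = lengths(idx_by_cluster),
    n_G_up = lengths(res$up),
    n_G_down = lengths(res$down)
  )
  structure(
    list(sample_cluster = sample_cluster, up_assignment = up_assignment,
         down_assignment = down_assignment, G_up = res$up, G_down = res$down,
         per_gene_stats = do.call(rbind, stats_rows), counts = counts,
         alpha = alpha, k = k),
    class = "cluster_assignment"
  )
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf("cluster_assignment (k = %d):\n", x$k))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
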