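#' Welch's unequal-variance two-sample t test
#'
#' Two-sided Welch t with Welch-Satterthwaite degrees of freedom. When both
#' samples are constant with equal means the statistic is undefined and
#' `t = 0, p = 1` is returned.
#'
#' @param x,y Numeric vectors, each with at least 2 values.
#' @param pooled Use the classical pooled-variance t instead of Welch.
#' @return List with `t`, `p`, `df` and `mean_diff` (`mean(x) - mean(y)`).
#' @export
welch_t_test <- function(x, y, pooled = FALSE) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("both samples need at least 2 values", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, p = 1, df = NA_real_, mean_diff = 0))
    }
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0, df = NA_real_,
                mean_diff = mean(x) - mean(y)))
  }
  tt <- stats::t.test(x, y, var.equal = pooled)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = mean(x) - mean(y))
}

#' Differentially expressed gene modules per sample cluster
#'
#' Collects every gene that survived the cluster filtering (union of the
#' `G_up` / `G_down` sets over clusters and directions) and, for each
#' sample cluster i, tests each collected gene between that cluster's
#' patients and all control samples on the normalised expression scale
#' (controls have no fold-change column, so the pre-fold-change matrix is
#' used). P-values are Bonferroni-adjusted over the genes tested within the
#' cluster; survivors join `M_up[[i]]` when patients exceed controls on
#' average and `M_down[[i]]` otherwise.
#'
#' @param ds The normalised [expression_dataset()] (patients and controls)
#'   the fold-change matrix was derived from.
#' @param assignment A `cluster_assignment` from [select_cluster_genes()].
#' @param alpha Significance level (default 0.05).
#' @param pooled Use pooled-variance t tests instead of Welch.
#' @return Object of class `deg_modules` with fields `M_up`, `M_down`
#'   (gene-id vectors per cluster), `per_gene_per_cluster` (data frame of t,
#'   q and mean difference) and `counts`.
#' @export
build_deg_modules <- function(ds, assignment, alpha = 0.05, pooled = FALSE) {
  tested_genes <- unique(c(unlist(assignment$G_up), unlist(assignment$G_down)))
  if (!length(tested_genes)) stop("no genes to test", call. = FALSE)
  ctl <- which(ds$group == "control")
  if (!length(ctl)) stop("no control samples", call. = FALSE)
  pat <- which(ds$group == "patient")
  if (length(pat) != length(assignment$sample_cluster)) {
    stop("patient count does not match the cluster assignment", call. = FALSE)
  }
  gi <- match(tested_genes, ds$gene_ids)
  if (anyNA(gi)) {
    stop("filtered genes missing from the dataset: ",
         paste(tested_genes[is.na(gi)][1:5], collapse = ", "), call. = FALSE)
  }
  k <- assignment$k
  n_tests <- length(tested_genes)
  M_up <- vector("list", k); M_down <- vector("list", k)
  rows <- vector("list", k)
  ctl_vals <- ds$values[gi, ctl, drop = FALSE]
  for (i in seq_len(k)) {
    cl_pat <- pat[assignment$sample_cluster == i]
    pv <- ds$values[gi, cl_pat, drop = FALSE]
    tt <- lapply(seq_len(n_tests), function(g) {
      welch_t_test(pv[g, ], ctl_vals[g, ], pooled = pooled)
    })
    p <- vapply(tt, `[[`, numeric(1L), "p")
    md <- vapply(tt, `[[`, numeric(1L), "mean_diff")
    q <- pmin(p * n_tests, 1)
    sig <- q < alpha
    M_up[[i]] <- tested_genes[sig & md > 0]
    M_down[[i]] <- tested_genes[sig & md < 0]
    rows[[i]] <- data.frame(
      gene_id = tested_genes, cluster = i,
      t = vapply(tt, `[[`, numeric(1L), "t"),
      q = q, mean_diff = md, stringsAsFactors = FALSE
    )
  }
  counts <- data.frame(
    cluster = seq_len(k),
    n_samples = as.vector(table(factor(assignment$sample_cluster,
                                       levels = seq_len(k)))),
    n_M_up = lengths(M_up),
    n_M_down = lengths(M_down)
  )
  structure(
    list(M_up = M_up, M_down = M_down,
         per_gene_per_cluster = do.call(rbind, rows), counts = counts,
         tested_genes = tested_genes, alpha = alpha, k = k),
    class = "deg_modules"
  )
}

#' @export
print.deg_modules <- function(x, ...) {
  cat(sprintf("deg_modules (k = %d):\n", x$k))
  print(x$counts, row.names = FALSE)
  invisible(x)
}
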