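#' Connectivity matrix of a cluster assignment
#'
#' Binary samples-by-samples matrix with entry (i, j) = 1 iff samples i and
#' j carry the same cluster label (diagonal all 1).
#'
#' @param assignment Integer vector of cluster labels.
#' @return A 0/1 symmetric matrix.
#' @export
connectivity_matrix <- function(assignment) {
  if (!length(assignment)) stop("empty assignment", call. = FALSE)
  outer(assignment, assignment, `==`) * 1
}

#' Consensus matrix and cophenetic coefficient of one factorization run
#'
#' Averages the connectivity matrices of every recorded iteration of a
#' convex NMF run: the (i, j) entry of the consensus matrix is the fraction
#' of iterations in which samples i and j were co-assigned.
#'
#' @param fit A [convex_nmf_fit()].
#' @param burn_in Iterations dropped from the head of the trace (default 0).
#' @return Object of class `consensus_result` with fields `consensus`,
#'   `cophenetic`, `k`, `n_runs_averaged` (here the number of iterations
#'   averaged).
#' @export
consensus_from_trace <- function(fit, burn_in = 0L) {
  trace <- fit$assignment_trace
  if (is.null(trace) || !nrow(trace)) stop("empty assignment trace", call. = FALSE)
  if (burn_in >= nrow(trace)) burn_in <- 0L
  rows <- seq.int(burn_in + 1L, nrow(trace))
  n <- ncol(trace)
  acc <- matrix(0, n, n)
  for (r in rows) acc <- acc + outer(trace[r, ], trace[r, ], `==`)
  consensus_result(acc / length(rows), fit$k, length(rows))
}

#' Consensus across the final assignments of several runs
#'
#' The restart-level (Brunet-style) variant: one connectivity matrix per
#' fitted run, from its final assignment, averaged over runs.
#'
#' @param fits List of [convex_nmf_fit()] objects on the same samples.
#' @return A `consensus_result`.
#' @export
consensus_from_fits <- function(fits) {
  if (!length(fits)) stop("no fits supplied", call. = FALSE)
  finals <- lapply(fits, function(f) f$assignment_trace[f$n_iter, ])
  n <- length(finals[[1L]])
  acc <- matrix(0, n, n)
  for (a in finals) acc <- acc + outer(a, a, `==`)
  consensus_result(acc / length(finals), fits[[1L]]$k, length(finals))
}

#' Argmax rank with NA scores excluded and ties to the smallest rank
#' @noRd
choose_rank <- function(ks, scores) {
  ok <- !is.na(scores)
  if (!any(ok)) stop("all restarts degenerate at every rank", call. = FALSE)
  ks[which.max(replace(scores, !ok, -Inf))]
}

#' @noRd
consensus_result <- function(consensus, k, n_runs) {
  structure(
    list(consensus = consensus, cophenetic = cophenetic_coefficient(consensus),
         k = k, n_runs_averaged = n_runs),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: k = %d, %d runs averaged, cophenetic = %s\n",
              x$k, x$n_runs_averaged, format(x$cophenetic)))
  invisible(x)
}

#' Cophenetic correlation coefficient of a consensus matrix
#'
#' Turns the consensus matrix C into the dissimilarity D = 1 - C (the
#' ones-matrix minus C, so frequently co-clustered pairs are close), builds
#' an average-linkage hierarchical clustering of D, and returns the Pearson
#' correlation between the pairwise entries of D and the cophenetic
#' distances of the dendrogram. Values near 1 indicate that the co-clustering
#' pattern is stable (close to ultrametric). When either vector has zero
#' variance (e.g. a constant off-diagonal consensus) the coefficient is
#' undefined and `NA_real_` is returned.
#'
#' @param consensus Symmetric numeric matrix with entries in [0, 1] and unit
#'   diagonal.
#' @return Correlation in [-1, 1], or `NA_real_` in the degenerate case.
#' @export
cophenetic_coefficient <- function(consensus) {
  consensus <- as.matrix(consensus)
  if (nrow(consensus) != ncol(consensus) ||
      max(abs(consensus - t(consensus))) > 1e-8) {
    stop("consensus matrix must be symmetric", call. = FALSE)
  }
  if (min(consensus) < -1e-12 || max(consensus) > 1 + 1e-12) {
    stop("consensus entries must lie in [0, 1]", call. = FALSE)
  }
  d <- stats::as.dist(1 - consensus)
  if (length(d) < 2L) return(NA_real_)
  hc <- stats::hclust(d, method = "average")
  cd <- stats::cophenetic(hc)
  if (stats::sd(d) == 0 || stats::sd(cd) == 0) return(NA_real_)
  if (isTRUE(all(d == cd))) return(1)   # exactly ultrametric consensus
  stats::cor(as.vector(d), as.vector(cd))
}

#' Select the factorization rank by mean cophenetic correlation
#'
#' For every rank k in `k_min..k_max`, runs `n_restarts` seeded convex NMF
#' fits and scores the rank by cophenetic correlation. With the default
#' `consensus = "restarts"` one consensus matrix per rank is built from the
#' final assignment of each restart (restart-to-restart stability, the
#' standard consensus-clustering protocol); with `consensus = "iterations"`
#' each run contributes the cophenetic coefficient of its own
#' iteration-averaged consensus and the rank is scored by the mean over
#' restarts. The chosen rank maximises the score; undefined (degenerate)
#' coefficients are excluded, and exact ties go to the smallest rank. The
#' returned `best_fit` is the restart at the chosen rank whose own
#' iteration-consensus cophenetic is largest.
#'
#' @param A Numeric fold-change matrix (genes x patients).
#' @param k_min,k_max Rank range (`k_min >= 2`; a warning is issued if the
#'   chosen rank is below 3, since the downstream Dunn filtering needs at
#'   least 3 clusters).
#' @param n_restarts Restarts per rank.
#' @param max_iter,tol,burn_in,consensus See [run_config()].
#' @param seed Master seed; restart seeds are derived from it.
#' @return Object of class `rank_selection` with fields
#'   `per_k_mean_cophenetic`, `chosen_k`, `best_fit`, `per_k_fits`
#'   (cophenetic values per restart) and, for the restart-level variant,
#'   `per_k_consensus`.
#' @export
select_rank <- function(A, k_min = 2L, k_max = 6L, n_restarts = 10L,
                        max_iter = 200L, tol = 1e-6, seed = 1L,
                        consensus = c("restarts", "iterations"),
                        burn_in = 0L) {
  consensus <- match.arg(consensus)
  if (k_min < 2L) stop("k_min must be >= 2", call. = FALSE)
  if (k_max < k_min) stop("k_max must be >= k_min", call. = FALSE)
  ks <- seq.int(k_min, k_max)
  seeds <- matrix(derive_seeds(seed, length(ks) * n_restarts),
                  nrow = length(ks))
  mean_coph <- stats::setNames(numeric(length(ks)), ks)
  per_k_coph <- stats::setNames(vector("list", length(ks)), ks)
  best_fit <- NULL; best_coph <- -Inf; chosen_k <- NA_integer_
  for (ki in seq_along(ks)) {
    k <- ks[ki]
    fits <- lapply(seq_len(n_restarts), function(r) {
      convex_nmf_fit(A, k, max_iter = max_iter, tol = tol,
                     seed = seeds[ki, r])
    })
    run_coph <- vapply(fits, function(f) {
      consensus_from_trace(f, burn_in)$cophenetic
    }, numeric(1L))
    if (consensus == "iterations") {
      per_k_coph[[ki]] <- run_coph
      ok <- !is.na(run_coph)
      mean_coph[ki] <- if (any(ok)) mean(run_coph[ok]) else NA_real_
    } else {
      per_k_coph[[ki]] <- run_coph
      mean_coph[ki] <- consensus_from_fits(fits)$cophenetic
    }
    better <- !is.na(mean_coph[ki]) &&
      (is.na(chosen_k) || mean_coph[ki] > best_coph)
    if (better) {
      chosen_k <- k
      best_coph <- mean_coph[ki]
      ok <- !is.na(run_coph)
      best_fit <- if (any(ok)) {
        fits[[which.max(replace(run_coph, !ok, -Inf))]]
      } else fits[[1L]]
    }
  }
  chosen_k <- choose_rank(ks, mean_coph)   # equals the incremental argmax
  if (chosen_k < 3L) {
    warning("chosen rank ", chosen_k,
            " is below 3; Kruskal-Wallis/Dunn gene filtering needs >= 3 clusters")
  }
  structure(
    list(per_k_mean_cophenetic = mean_coph, chosen_k = chosen_k,
         best_fit = best_fit, per_k_cophenetic = per_k_coph,
         consensus = consensus, seed = seed),
    class = "rank_selection"
  )
}

#' @export
print.rank_selection <- function(x, ...) {
  cat("rank_selection: chosen k =", x$chosen_k, "\n")
  print(round(x$per_k_mean_cophenetic, 4))
  invisible(x)
}
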