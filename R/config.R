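#' Pipeline run configuration
#'
#' Collects every tunable of the end-to-end pipeline in one validated object.
#' Defaults follow the study protocol the pipeline implements: rank search
#' over k = 2..10 with 10 random restarts per rank, significance level 0.05
#' with Bonferroni correction throughout, zero-initialised logistic
#' regression at a fixed learning rate under 10-fold cross-validation, and
#' 100 random-gene baseline panels.
#'
#' @param k_min,k_max Rank search range (integers, `2 <= k_min <= k_max`).
#' @param n_restarts Random restarts per rank (>= 1).
#' @param max_iter Maximum multiplicative-update iterations per fit.
#' @param tol Relative objective-change convergence tolerance.
#' @param alpha Significance level for all tests.
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @param learning_rate Gradient-descent step size for logistic regression.
#' @param n_folds Cross-validation folds.
#' @param epochs Gradient-descent epochs.
#' @param baseline_reps Random-gene baseline repetitions.
#' @param consensus Consensus construction: `"restarts"` (default) averages
#'   one final connectivity matrix per restart (restart-to-restart
#'   stability, the standard consensus-clustering protocol);
#'   `"iterations"` averages the connectivity matrices over the iterations
#'   of each run (one cophenetic value per restart, then averaged).
#' @param burn_in Iterations excluded from the head of the connectivity
#'   trace when `consensus = "iterations"`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(k_min = 2L, k_max = 10L, n_restarts = 10L,
                       max_iter = 200L, tol = 1e-6, alpha = 0.05,
                       seed = 1L, learning_rate = 0.05, n_folds = 10L,
                       epochs = 500L, baseline_reps = 100L,
                       consensus = c("restarts", "iterations"),
                       burn_in = 0L) {
  consensus <- match.arg(consensus)
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (is.na(k_min) || is.na(k_max) || k_min < 2L || k_min > k_max) {
    stop("invalid rank range: need 2 <= k_min <= k_max", call. = FALSE)
  }
  if (n_restarts < 1L) stop("n_restarts must be >= 1", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (tol < 0) stop("tol must be non-negative", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (n_folds < 2L) stop("n_folds must be >= 2", call. = FALSE)
  if (epochs < 0L) stop("epochs must be >= 0", call. = FALSE)
  if (baseline_reps < 2L) stop("baseline_reps must be >= 2", call. = FALSE)
  if (burn_in < 0L) stop("burn_in must be >= 0", call. = FALSE)
  structure(
    list(k_min = k_min, k_max = k_max, n_restarts = as.integer(n_restarts),
         max_iter = as.integer(max_iter), tol = tol, alpha = alpha,
         seed = as.integer(seed), learning_rate = learning_rate,
         n_folds = as.integer(n_folds), epochs = as.integer(epochs),
         baseline_reps = as.integer(baseline_reps), consensus = consensus,
         burn_in = as.integer(burn_in)),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, x[[nm]]))
  invisible(x)
}
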