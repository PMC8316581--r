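#' Positive and negative parts of a matrix
#'
#' Splits `B` into the element-wise nonnegative matrices
#' `B_plus = (|B| + B) / 2` and `B_minus = (|B| - B) / 2`, so that
#' `B = B_plus - B_minus`.
#'
#' @param B Numeric matrix.
#' @return List with components `plus` and `minus`.
#' @export
positive_negative_parts <- function(B) {
  a <- abs(B)
  list(plus = (a + B) / 2, minus = (a - B) / 2)
}

#' Convex non-negative matrix factorization by multiplicative updates
#'
#' Factorizes a (possibly mixed-sign) genes-by-samples matrix `A` as
#' `A ~ A F t(H)` with element-wise nonnegative `F` (samples x k, convex
#' combination weights over samples) and `H` (samples x k, per-sample
#' cluster coefficients). The basis `W = A F` therefore lives in the column
#' space of the data. `F` and `H` are updated alternately with the
#' multiplicative square-root rules driven by the positive and negative
#' parts of the Gram matrix `t(X) X` (X = A), which only ever touch `A`
#' through that cached Gram matrix:
#' \deqn{H_{ik} \leftarrow H_{ik}\sqrt{\frac{[(X^TX)^+F]_{ik}+[HF^T(X^TX)^-F]_{ik}}
#'   {[(X^TX)^-F]_{ik}+[HF^T(X^TX)^+F]_{ik}}}}
#' \deqn{F_{ik} \leftarrow F_{ik}\sqrt{\frac{[(X^TX)^+H]_{ik}+[(X^TX)^-FH^TH]_{ik}}
#'   {[(X^TX)^-H]_{ik}+[(X^TX)^+FH^TH]_{ik}}}}
#' Each full update cannot increase the squared Frobenius reconstruction
#' error, which is recorded per iteration together with the per-sample
#' argmax cluster assignment from the rows of `H`.
#'
#' @param A Numeric matrix (genes x samples), e.g. the `values` of a
#'   fold-change matrix.
#' @param k Factorization rank (number of clusters), `1 <= k <= ncol(A)`.
#' @param max_iter Maximum iterations (default 200).
#' @param tol Relative objective-change stopping tolerance (default 1e-6).
#' @param seed Seed for the uniform(0, 1) initialisation of `F` and `H`
#'   (a 1e-4 floor keeps all entries strictly positive).
#' @param init `"uniform"` (default) or `"kmeans"`, which seeds `H` from a
#'   k-means partition of the sample columns (F from the partition
#'   indicator) before the multiplicative updates.
#' @return An object of class `convex_nmf_fit` with fields `F`, `H`, `W`
#'   (= `A F`), `objective_trace`, `assignment_trace` (iterations x samples
#'   matrix of cluster labels), `k`, `seed`, `n_iter`, `converged`.
#' @export
convex_nmf_fit <- function(A, k, max_iter = 200L, tol = 1e-6, seed = 1L,
                           init = c("uniform", "kmeans")) {
  init <- match.arg(init)
  A <- as.matrix(A)
  if (!all(is.finite(A))) stop("input matrix has non-finite entries", call. = FALSE)
  n <- ncol(A)
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  if (max_iter < 1L) stop("max_iter must be >= 1", call. = FALSE)

  G <- crossprod(A)                       # t(X) X, samples x samples, cached
  parts <- positive_negative_parts(G)
  Gp <- parts$plus; Gn <- parts$minus
  trG <- sum(diag(G))
  floor_den <- 1e-12

  fh <- with_seed(seed, {
    if (init == "kmeans") {
      km <- stats::kmeans(t(A), centers = k, nstart = 5L)
      Hm <- matrix(0, n, k)
      Hm[cbind(seq_len(n), km$cluster)] <- 1
      sz <- pmax(colSums(Hm), 1)
      list(F = sweep(Hm, 2L, sz, "/") + 0.01, H = Hm + 0.2)
    } else {
      list(F = pmax(matrix(stats::runif(n * k), n, k), 1e-4),
           H = pmax(matrix(stats::runif(n * k), n, k), 1e-4))
    }
  })
  Fm <- fh$F; Hm <- fh$H

  objective <- function(Fm, Hm) {
    GF <- G %*% Fm
    trG - 2 * sum(GF * Hm) + sum(crossprod(Fm, G %*% Fm) * crossprod(Hm))
  }

  obj_trace <- numeric(max_iter)
  assign_trace <- matrix(NA_integer_, max_iter, n)
  prev <- objective(Fm, Hm)
  n_iter <- 0L
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    GpF <- Gp %*% Fm; GnF <- Gn %*% Fm
    FtGpF <- crossprod(Fm, GpF); FtGnF <- crossprod(Fm, GnF)
    Hm <- Hm * sqrt((GpF + Hm %*% FtGnF) /
                    (GnF + Hm %*% FtGpF + floor_den))
    HtH <- crossprod(Hm)
    GpH <- Gp %*% Hm; GnH <- Gn %*% Hm
    # GpF / GnF still hold (X^T X)^{+/-} F for the current F: only H has
    # been updated since they were formed
    Fm <- Fm * sqrt((GpH + GnF %*% HtH) /
                    (GnH + GpF %*% HtH + floor_den))
    n_iter <- it
    obj <- objective(Fm, Hm)
    obj_trace[it] <- obj
    assign_trace[it, ] <- argmax_rows(Hm)
    if (is.finite(prev) && abs(prev - obj) <= tol * max(abs(prev), 1e-300)) {
      converged <- TRUE
      break
    }
    prev <- obj
  }
  structure(
    list(F = Fm, H = Hm, W = A %*% Fm,
         objective_trace = obj_trace[seq_len(n_iter)],
         assignment_trace = assign_trace[seq_len(n_iter), , drop = FALSE],
         k = k, seed = seed, n_iter = n_iter, converged = converged),
    class = "convex_nmf_fit"
  )
}

#' @export
print.convex_nmf_fit <- function(x, ...) {
  cat(sprintf(
    "convex_nmf_fit: k = %d, %d iterations (%s), objective %.6g\n",
    x$k, x$n_iter, if (x$converged) "converged" else "max_iter",
    x$objective_trace[x$n_iter]))
  invisible(x)
}
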