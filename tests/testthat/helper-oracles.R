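# Independent brute-force oracles used to cross-check the package's
# statistics. They deliberately avoid the code paths (and where possible the
# base functions) the implementation uses.

# mid-ranks computed by sorting, not rank()
bf_midranks <- function(x) {
  o <- order(x)
  r <- numeric(length(x))
  i <- 1L
  while (i <= length(x)) {
    j <- i
    while (j < length(x) && x[o[j + 1L]] == x[o[i]]) j <- j + 1L
    r[o[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  r
}

# Kruskal-Wallis H with tie correction, chi-square p on k-1 df
bf_kruskal <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- bf_midranks(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, function(v) length(v) * mean(v)^2)) - 3 * (N + 1)
  ties <- table(x)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H <- H / corr
  list(statistic = H, p = pchisq(H, length(groups) - 1L, lower.tail = FALSE))
}

# Dunn pairwise z from pooled mid-ranks
bf_dunn <- function(groups, pair) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- bf_midranks(x)
  ties <- table(x)
  s2 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  i <- pair[1L]; j <- pair[2L]
  z <- (mean(r[g == i]) - mean(r[g == j])) /
    sqrt(s2 * (1 / sum(g == i) + 1 / sum(g == j)))
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# Welch t from first principles
bf_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# upper-tail hypergeometric by direct enumeration with choose()
bf_hyper_upper <- function(ov, query, set, universe) {
  if (ov == 0) return(1)
  i <- seq.int(ov, min(query, set))
  sum(choose(set, i) * choose(universe - set, query - i)) /
    choose(universe, query)
}

# AUC by enumerating positive-negative pairs
bf_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# classical one-way ANOVA from sums of squares
bf_anova <- function(groups) {
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  gm <- mean(x)
  ssb <- sum(tapply(x, g, function(v) length(v) * (mean(v) - gm)^2))
  ssw <- sum(tapply(x, g, function(v) sum((v - mean(v))^2)))
  df1 <- length(groups) - 1L
  df2 <- length(x) - length(groups)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

# explicit UPGMA agglomeration + dendrogram walk for cophenetic distances,
# then a hand-rolled Pearson correlation
bf_cophenetic <- function(consensus) {
  D <- 1 - consensus
  n <- nrow(D)
  members <- as.list(seq_len(n))
  d <- D
  diag(d) <- Inf
  active <- rep(TRUE, n)
  coph <- matrix(0, n, n)
  sizes <- rep(1L, n)
  for (step in seq_len(n - 1L)) {
    idx <- which(active)
    sub <- d[idx, idx, drop = FALSE]
    m <- which(sub == min(sub), arr.ind = TRUE)[1L, ]
    i <- idx[min(m)]; j <- idx[max(m)]
    h <- d[i, j]
    for (a in members[[i]]) for (b in members[[j]]) {
      coph[a, b] <- h; coph[b, a] <- h
    }
    # average linkage update into slot i
    for (k in idx) {
      if (k == i || k == j) next
      d[i, k] <- (sizes[i] * d[i, k] + sizes[j] * d[j, k]) /
        (sizes[i] + sizes[j])
      d[k, i] <- d[i, k]
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    active[j] <- FALSE
  }
  ut <- upper.tri(D)
  x <- D[ut]; y <- coph[ut]
  sx <- sqrt(sum((x - mean(x))^2)); sy <- sqrt(sum((y - mean(y))^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  sum((x - mean(x)) * (y - mean(y))) / (sx * sy)
}

# random valid consensus matrix: average of a few random co-clusterings
random_consensus <- function(n, n_parts = 6L) {
  acc <- matrix(0, n, n)
  for (i in seq_len(n_parts)) {
    lab <- sample(1:3, n, replace = TRUE)
    acc <- acc + outer(lab, lab, `==`)
  }
  acc / n_parts
}
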