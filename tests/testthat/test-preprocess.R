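test_that("duplicate gene rows merge to their per-sample mean", {
  ds <- expression_dataset(
    matrix(c(1, 3, 3, 5, 7, 8), nrow = 3, byrow = TRUE),
    gene_ids = c("g1", "g1", "g2"),
    sample_ids = c("s1", "s2"),
    group = c("patient", "control")
  )
  m <- merge_duplicate_genes(ds)
  expect_identical(m$gene_ids, c("g1", "g2"))
  expect_equal(unname(m$values["g1", ]), c(2, 4))

  # no duplicates: identity
  expect_equal(merge_duplicate_genes(tiny_dataset())$values,
               tiny_dataset()$values)

  # random triples against a column-wise mean oracle
  set.seed(1)
  v <- matrix(rnorm(9 * 4), 9, 4)
  ds <- expression_dataset(v, rep(c("a", "b", "c"), each = 3),
                           sprintf("s%d", 1:4),
                           rep(c("patient", "control"), 2))
  m <- merge_duplicate_genes(ds)
  for (i in 1:3) {
    expect_equal(unname(m$values[i, ]),
                 colMeans(v[(3 * i - 2):(3 * i), , drop = FALSE]))
  }
})

test_that("gene filtering keeps order and rejects empty intersections", {
  ds <- random_dataset(20, 6, 3, seed = 2)
  expect_equal(filter_genes(ds, ds$gene_ids)$values, ds$values)
  expect_error(filter_genes(ds, c("nope")), "no genes")
  set.seed(3)
  keep <- sample(ds$gene_ids, 10)
  f <- filter_genes(ds, keep)
  expect_identical(f$gene_ids, ds$gene_ids[ds$gene_ids %in% keep])
})

test_that("merge and filter commute when the keep list covers duplicates", {
  set.seed(4)
  ds <- expression_dataset(matrix(rnorm(8 * 3), 8, 3),
                           rep(c("a", "b", "c", "d"), 2),
                           sprintf("s%d", 1:3),
                           c("patient", "patient", "control"))
  keep <- c("a", "c")
  r1 <- filter_genes(merge_duplicate_genes(ds), keep)
  r2 <- merge_duplicate_genes(filter_genes(ds, keep))
  expect_identical(r1$gene_ids, r2$gene_ids)
  expect_equal(r1$values, r2$values)
})

test_that("batch adjustment equalises per-gene batch means", {
  set.seed(5)
  n_g <- 15; n_s <- 12
  v <- matrix(rnorm(n_g * n_s, mean = 8), n_g, n_s)
  batch <- rep(c("b1", "b2"), each = 6)
  delta <- 1.7
  v[, batch == "b2"] <- v[, batch == "b2"] + delta
  ds <- expression_dataset(v, sprintf("g%d", 1:n_g), sprintf("s%d", 1:n_s),
                           rep(c("patient", "control"), 6), batch = batch)
  adj <- remove_batch_effect(ds)
  for (gi in 1:n_g) {
    m1 <- mean(adj$values[gi, batch == "b1"])
    m2 <- mean(adj$values[gi, batch == "b2"])
    expect_lt(abs(m1 - m2), 1e-10)
  }
  # grand mean preserved per gene
  expect_equal(rowMeans(adj$values), rowMeans(ds$values))

  expect_error(remove_batch_effect(tiny_dataset()), "no batch")
  ds1 <- expression_dataset(v, sprintf("g%d", 1:n_g), sprintf("s%d", 1:n_s),
                            rep(c("patient", "control"), 6),
                            batch = rep("b1", n_s))
  expect_error(remove_batch_effect(ds1), "2 batches")
})

test_that("log2 fold change matches its defining formula", {
  ds <- expression_dataset(
    matrix(c(8, 2, 2,
             4, 4, 4), nrow = 2, byrow = TRUE),
    gene_ids = c("g1", "g2"),
    sample_ids = c("p1", "c1", "c2"),
    group = c("patient", "control", "control")
  )
  fc <- log2_fold_change(ds)
  expect_equal(unname(fc$values["g1", "p1"]), 2)   # log2(8/2)
  expect_equal(unname(fc$values["g2", "p1"]), 0)   # patient equals control mean
  expect_identical(fc$patient_ids, "p1")

  # random positive 20x10 dataset against element-wise recomputation
  set.seed(6)
  ds <- random_dataset(20, 10, 6, seed = 6)
  fc <- log2_fold_change(ds)
  ctl <- ds$values[, ds$group == "control", drop = FALSE]
  for (gi in 1:20) {
    for (pj in 1:6) {
      expect_equal(fc$values[gi, pj],
                   log2(ds$values[gi, pj] / mean(ctl[gi, ])))
    }
  }
})

test_that("nonpositive values and missing controls are hard errors", {
  ds <- tiny_dataset()
  ds$values[2, 1] <- -1
  expect_error(log2_fold_change(ds), "g2.*s1|nonpositive")
  ds2 <- expression_dataset(matrix(1:4, 2), c("g1", "g2"), c("s1", "s2"),
                            c("patient", "patient"))
  expect_error(log2_fold_change(ds2), "no control")
})

test_that("fold-change TSV export restores on reread", {
  fc <- log2_fold_change(random_dataset(10, 8, 5, seed = 7))
  p <- withr::local_tempfile(fileext = ".tsv")
  cmp <- withr::local_tempfile(fileext = ".tsv")
  write_fold_change(fc, p, cmp)
  tab <- read.table(p, header = TRUE, sep = "\t", check.names = FALSE)
  expect_equal(as.matrix(tab[, -1]),
               unname(fc$values)[, , drop = FALSE], ignore_attr = TRUE)
})
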