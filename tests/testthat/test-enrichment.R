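test_that("hypergeometric upper tail matches exhaustive enumeration", {
  expect_equal(hypergeom_upper_tail(0, 10, 5, 50), 1)
  # P(X >= 1) with universe 10, set 5, query 2: 1 - C(5,2)/C(10,2) = 7/9
  expect_equal(hypergeom_upper_tail(1, 2, 5, 10), 7 / 9, tolerance = 1e-12)

  set.seed(30)
  for (rep in 1:200) {
    u <- sample(5:50, 1)
    s <- sample(1:u, 1)
    q <- sample(1:u, 1)
    ov <- sample(0:min(s, q), 1)
    expect_equal(hypergeom_upper_tail(ov, q, s, u),
                 bf_hyper_upper(ov, q, s, u), tolerance = 1e-12)
  }
  expect_error(hypergeom_upper_tail(3, 2, 5, 10), "inconsistent")
  expect_error(hypergeom_upper_tail(1, 8, 5, 7), "inconsistent")
})

test_that("enrichment p-values are monotone in the overlap", {
  p <- vapply(0:5, function(ov) hypergeom_upper_tail(ov, 10, 5, 100),
              numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("growing the universe with unrelated genes shrinks the p-value", {
  p <- vapply(c(20, 40, 80, 160), function(u) {
    hypergeom_upper_tail(3, 5, 8, u)
  }, numeric(1))
  expect_true(all(diff(p) < 0))
})

test_that("collection enrichment applies Bonferroni over the sets tested", {
  uni <- sprintf("g%03d", 1:100)
  col <- gene_set_collection(
    list(S1 = uni[1:10], S2 = uni[11:30], S3 = uni[31:35]),
    universe = uni
  )
  res <- enrich_collection(uni[1:10], col)
  expect_equal(res$adjusted_p, pmin(res$p * 3, 1))
  expect_equal(res$set[which.min(res$p)], "S1")
  expect_true(res$enriched[res$set == "S1"])
  expect_equal(res$overlap[res$set == "S1"], 10)
  expect_error(enrich_collection(c("zz"), col), "disjoint")

  # genes outside the universe are ignored on both sides
  res2 <- enrich_collection(c(uni[1:10], "outside"), col)
  expect_equal(res2$query_size[1], 10)
})

test_that("reference pathway derivation recovers a list's own set", {
  uni <- sprintf("g%03d", 1:200)
  col <- gene_set_collection(
    list(A = uni[1:15], B = uni[16:40], C = uni[41:60]),
    universe = uni
  )
  expect_true("A" %in% derive_reference_pathways(uni[1:15], col))
  expect_error(derive_reference_pathways(character(0), col), "empty")
})

test_that("pair selection follows the two-stage counting on a toy study", {
  uni <- sprintf("g%02d", 1:50)
  col <- gene_set_collection(list(S = "g02"), universe = uni)
  mods <- function(up1) {
    structure(list(k = 1, M_up = list(up1), M_down = list(character(0))),
              class = "deg_modules")
  }
  ps <- select_related_pair(mods(c("g01", "g02")), mods(c("g02", "g03")),
                            col, refA = "g02", refB = "g02")
  expect_equal(ps$chosen_pair, c(1, 1))
  expect_equal(ps$candidate_genes$gene_id, "g02")
  expect_equal(ps$candidate_genes$direction, "up")

  # empty intersections everywhere: explicit no-pair result
  ps0 <- select_related_pair(mods("g01"), mods("g03"), col,
                             refA = "g02", refB = "g02")
  expect_null(ps0$chosen_pair)
  expect_equal(nrow(ps0$candidate_genes), 0)
})

test_that("planted paired study drives pair selection to the shared pair", {
  study <- small_study(31, 32)
  # oracle modules: hand the planted truth to the pairing stage
  mk <- function(truth) {
    structure(list(k = 3, M_up = truth$up_modules,
                   M_down = truth$down_modules), class = "deg_modules")
  }
  ps <- select_related_pair(mk(study$truth_a), mk(study$truth_b),
                            study$collection, study$ref_genes_a,
                            study$ref_genes_b)
  expect_equal(ps$chosen_pair, c(study$truth_a$shared_cluster,
                                 study$truth_b$shared_cluster))
  expect_setequal(ps$candidate_genes$gene_id,
                  study$shared_candidates$gene_id)
  # stage tables cover every cluster/direction combination
  expect_equal(nrow(ps$stageA_counts), 2 * 3 * 2)
  expect_equal(nrow(ps$stageB_counts), 3 * 3 * 2)
})

test_that("decoy reference lists yield few enriched pathways", {
  study <- small_study(33, 34)
  set.seed(35)
  decoys <- sample(study$collection$universe, 30)
  paths <- derive_reference_pathways(decoys, study$collection)
  expect_lte(length(paths), 2)
})

test_that("candidate overlap test is an exact hypergeometric tail", {
  expect_equal(candidate_overlap_test(c("a", "b"), c("c", "d"), 100), 1)
  p <- candidate_overlap_test(c("a", "b"), c("a", "b", "c"), 10)
  expect_equal(p, bf_hyper_upper(2, 2, 3, 10), tolerance = 1e-12)
  expect_error(candidate_overlap_test(letters[1:5], letters[6:10], 8),
               "background")
  set.seed(36)
  ids <- sprintf("x%04d", 1:1000)
  for (rep in 1:20) {
    cand <- sample(ids, 40); ref <- sample(ids, 60)
    expect_equal(candidate_overlap_test(cand, ref, 1000),
                 bf_hyper_upper(length(intersect(cand, ref)), 40, 60, 1000),
                 tolerance = 1e-12)
  }
})
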