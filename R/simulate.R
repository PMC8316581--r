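#' Design of a simulated disease expression study
#'
#' Describes one disease arm of a paired two-disease simulation: patients
#' fall into `k_true` latent clusters; each cluster owns an up- and a
#' down-regulated gene module whose members are shifted by `+/- effect_size`
#' (log2 units) in that cluster's patients; i.i.d. Gaussian noise
#' (`noise_sd`, clipped at 4 standard deviations) is added everywhere;
#' controls carry baseline plus noise only. Per-gene baselines are drawn
#' once from N(8, 1) on the log2 scale and floored at 4, which together
#' with the noise clipping keeps every value strictly positive, so log2
#' fold changes are always defined.
#'
#' A `shared_candidate_size`-gene subset is planted with the same direction
#' in the `shared_pair` cluster of both diseases (by convention the first
#' genes of the universe, split between the up and down module of that
#' cluster), giving the paired study a known cross-disease signal.
#'
#' @param n_genes Number of genes in the universe.
#' @param k_true Number of latent patient clusters (>= 2).
#' @param patients_per_cluster Integer vector of cluster sizes (recycled to
#'   `k_true`).
#' @param n_controls Number of control samples.
#' @param effect_size Planted shift in log2 units (>= 0; 0 gives a null
#'   design with no signal).
#' @param noise_sd Noise standard deviation in log2 units (> 0).
#' @param module_size Genes per cluster per direction.
#' @param shared_candidate_size Size of the planted cross-disease candidate
#'   set (<= module_size).
#' @param shared_pair Length-2 integer vector: the shared cluster index in
#'   disease A and in disease B.
#' @param batch_offset Optional additive offset applied to a random half of
#'   the samples (with batch labels recorded); `NULL` for no batch.
#' @param seed Seed for all draws of this arm.
#' @return A validated list of class `simulation_design`.
#' @export
simulation_design <- function(n_genes = 1000L, k_true = 3L,
                              patients_per_cluster = 30L, n_controls = 30L,
                              effect_size = 2.0, noise_sd = 0.5,
                              module_size = 40L,
                              shared_candidate_size = 25L,
                              shared_pair = c(1L, 1L),
                              batch_offset = NULL, seed = 1L) {
  k_true <- as.integer(k_true)
  if (k_true < 2L) stop("k_true must be >= 2", call. = FALSE)
  patients_per_cluster <- rep_len(as.integer(patients_per_cluster), k_true)
  if (any(patients_per_cluster < 1L)) {
    stop("every cluster needs at least one patient", call. = FALSE)
  }
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (noise_sd <= 0) stop("noise_sd must be > 0", call. = FALSE)
  if (shared_candidate_size > module_size) {
    stop("shared_candidate_size must not exceed module_size", call. = FALSE)
  }
  if (2L * k_true * module_size > n_genes) {
    stop("module sizes x clusters exceed the gene universe", call. = FALSE)
  }
  if (length(shared_pair) != 2L || any(shared_pair < 1L) ||
      any(shared_pair > k_true)) {
    stop("shared_pair must name a valid cluster in each disease", call. = FALSE)
  }
  structure(
    list(n_genes = as.integer(n_genes), k_true = k_true,
         patients_per_cluster = patients_per_cluster,
         n_controls = as.integer(n_controls), effect_size = effect_size,
         noise_sd = noise_sd, module_size = as.integer(module_size),
         shared_candidate_size = as.integer(shared_candidate_size),
         shared_pair = as.integer(shared_pair),
         batch_offset = batch_offset, seed = as.integer(seed)),
    class = "simulation_design"
  )
}

#' @noRd
gene_universe <- function(n_genes) sprintf("g%05d", seq_len(n_genes))

#' Planted shared candidate genes of a design
#'
#' By construction the first `shared_candidate_size` genes of the universe:
#' the first half planted upregulated, the rest downregulated, in the
#' shared cluster of both diseases.
#'
#' @param design A [simulation_design()].
#' @return Data frame with `gene_id` and `direction`.
#' @export
shared_candidate_genes <- function(design) {
  s <- design$shared_candidate_size
  ids <- gene_universe(design$n_genes)[seq_len(s)]
  n_up <- ceiling(s / 2)
  data.frame(gene_id = ids,
             direction = rep(c("up", "down"), c(n_up, s - n_up)),
             stringsAsFactors = FALSE)
}

#' Generate one simulated disease dataset with ground truth
#'
#' See [simulation_design()] for the generative model. The disease tag
#' selects the half of the (non-candidate) gene pool the disease-specific
#' module genes are drawn from (`"A"` lower half, `"B"` upper half, any
#' other tag the whole pool), so the two arms of a paired study share no
#' module genes beyond the planted candidates.
#'
#' @param design A [simulation_design()].
#' @param disease_tag Label used in sample identifiers and pool selection.
#' @return List with `dataset` (an [expression_dataset()] with an `age`
#'   covariate) and `truth` (class `ground_truth`: `sample_cluster`,
#'   `up_modules`, `down_modules`, `shared_candidates`).
#' @export
generate_disease_dataset <- function(design, disease_tag = "A") {
  genes <- gene_universe(design$n_genes)
  s <- design$shared_candidate_size
  shared <- shared_candidate_genes(design)
  pool <- setdiff(genes, shared$gene_id)
  half <- floor(length(pool) / 2)
  pool <- switch(disease_tag,
                 A = pool[seq_len(half)],
                 B = pool[seq.int(half + 1L, length(pool))],
                 pool)
  k <- design$k_true
  ms <- design$module_size
  need <- 2L * k * ms - s
  if (need > length(pool)) {
    stop("gene pool too small for the requested modules", call. = FALSE)
  }

  with_seed(design$seed, {
    picks <- sample(pool, need)
    ptr <- 0L
    take <- function(n) {
      out <- picks[ptr + seq_len(n)]
      ptr <<- ptr + n
      out
    }
    cstar <- design$shared_pair[if (disease_tag == "B") 2L else 1L]
    up_modules <- vector("list", k); down_modules <- vector("list", k)
    for (cl in seq_len(k)) {
      if (cl == cstar) {
        sh_up <- shared$gene_id[shared$direction == "up"]
        sh_dn <- shared$gene_id[shared$direction == "down"]
        up_modules[[cl]] <- c(sh_up, take(ms - length(sh_up)))
        down_modules[[cl]] <- c(sh_dn, take(ms - length(sh_dn)))
      } else {
        up_modules[[cl]] <- take(ms)
        down_modules[[cl]] <- take(ms)
      }
    }

    n_pat <- sum(design$patients_per_cluster)
    n <- n_pat + design$n_controls
    sample_cluster <- rep(seq_len(k), design$patients_per_cluster)
    mu <- pmax(stats::rnorm(design$n_genes, mean = 8, sd = 1), 4)
    noise <- matrix(stats::rnorm(design$n_genes * n, sd = design$noise_sd),
                    design$n_genes, n)
    clip <- 4 * design$noise_sd
    noise <- pmin(pmax(noise, -clip), clip)
    vals <- mu + noise
    for (cl in seq_len(k)) {
      cols <- which(sample_cluster == cl)
      up_idx <- match(up_modules[[cl]], genes)
      dn_idx <- match(down_modules[[cl]], genes)
      vals[up_idx, cols] <- vals[up_idx, cols] + design$effect_size
      vals[dn_idx, cols] <- vals[dn_idx, cols] - design$effect_size
    }

    sample_ids <- c(sprintf("%s_P%03d", disease_tag, seq_len(n_pat)),
                    sprintf("%s_C%03d", disease_tag,
                            seq_len(design$n_controls)))
    group <- rep(c("patient", "control"), c(n_pat, design$n_controls))
    batch <- NULL
    if (!is.null(design$batch_offset)) {
      shifted <- sample(n, floor(n / 2))
      vals[, shifted] <- vals[, shifted] + design$batch_offset
      batch <- rep("b1", n); batch[shifted] <- "b2"
    }
    age <- round(stats::rnorm(n, mean = 70, sd = 5), 1)

    ds <- expression_dataset(vals, genes, sample_ids, group, batch = batch,
                             covariates = data.frame(age = age))
    truth <- structure(
      list(sample_cluster = sample_cluster, up_modules = up_modules,
           down_modules = down_modules, shared_candidates = shared,
           shared_cluster = cstar, disease_tag = disease_tag),
      class = "ground_truth"
    )
    list(dataset = ds, truth = truth)
  })
}

#' Build a gene-set collection around planted modules
#'
#' One set per planted module (all module members plus ~15% random
#' out-of-module genes, so at least 80% of each set comes from its module)
#' plus `n_decoys` uniformly drawn decoy sets. The universe is the full
#' simulated gene universe.
#'
#' @param truths A `ground_truth` or list of them (one per disease).
#' @param n_genes Size of the simulated gene universe.
#' @param n_decoys Number of decoy sets.
#' @param set_size_range Length-2 integer range of decoy set sizes.
#' @param seed Seed.
#' @return A [gene_set_collection()]; set names are
#'   `MOD_<tag>_c<cluster>_<direction>` and `DECOY_<i>`.
#' @export
generate_gene_sets <- function(truths, n_genes, n_decoys = 30L,
                               set_size_range = c(15L, 50L), seed = 1L) {
  if (inherits(truths, "ground_truth")) truths <- list(truths)
  genes <- gene_universe(n_genes)
  if (max(set_size_range) > n_genes) {
    stop("set size exceeds the gene universe", call. = FALSE)
  }
  with_seed(seed, {
    sets <- list()
    for (tr in truths) {
      for (cl in seq_along(tr$up_modules)) {
        for (direction in c("up", "down")) {
          mod <- if (direction == "up") tr$up_modules[[cl]] else tr$down_modules[[cl]]
          extra <- sample(setdiff(genes, mod),
                          max(1L, round(0.15 * length(mod))))
          sets[[sprintf("MOD_%s_c%d_%s", tr$disease_tag, cl, direction)]] <-
            c(mod, extra)
        }
      }
    }
    for (i in seq_len(n_decoys)) {
      sz <- sample(seq.int(set_size_range[1L], set_size_range[2L]), 1L)
      sets[[sprintf("DECOY_%03d", i)]] <- sample(genes, sz)
    }
    gene_set_collection(sets, universe = genes)
  })
}

#' Generate a paired two-disease study
#'
#' Two disease arms with a common gene universe and a planted
#' same-direction candidate set in the `shared_pair` clusters, a gene-set
#' collection whose module sets capture the planted signal, and reference
#' gene lists (planted candidates plus uniformly drawn decoy genes) under
#' which the planted pair is the unique maximiser of reference-pathway
#' overlap.
#'
#' @param designA,designB [simulation_design()]s; `shared_pair` and
#'   `shared_candidate_size` must agree.
#' @param n_decoy_sets Decoy sets in the collection.
#' @param set_size_range Decoy set size range.
#' @param ref_decoy_genes Decoy genes added to each reference list.
#' @return List with `dataset_a`, `dataset_b`, `truth_a`, `truth_b`,
#'   `collection`, `ref_genes_a`, `ref_genes_b`, `shared_candidates`.
#' @export
generate_paired_study <- function(designA = simulation_design(seed = 1L),
                                  designB = simulation_design(seed = 2L),
                                  n_decoy_sets = 30L,
                                  set_size_range = c(15L, 50L),
                                  ref_decoy_genes = 25L) {
  if (!identical(designA$shared_pair, designB$shared_pair)) {
    stop("designs disagree on shared_pair", call. = FALSE)
  }
  if (designA$shared_candidate_size != designB$shared_candidate_size) {
    stop("designs disagree on shared_candidate_size", call. = FALSE)
  }
  if (designA$n_genes != designB$n_genes) {
    stop("designs must share one gene universe", call. = FALSE)
  }
  armA <- generate_disease_dataset(designA, "A")
  armB <- generate_disease_dataset(designB, "B")
  aux_seeds <- derive_seeds(designA$seed, 3L)
  collection <- generate_gene_sets(list(armA$truth, armB$truth),
                                   designA$n_genes, n_decoy_sets,
                                   set_size_range, seed = aux_seeds[1L])
  shared <- armA$truth$shared_candidates$gene_id
  genes <- gene_universe(designA$n_genes)
  ref_a <- with_seed(aux_seeds[2L],
                     c(shared, sample(setdiff(genes, shared), ref_decoy_genes)))
  ref_b <- with_seed(aux_seeds[3L],
                     c(shared, sample(setdiff(genes, shared), ref_decoy_genes)))
  list(dataset_a = armA$dataset, dataset_b = armB$dataset,
       truth_a = armA$truth, truth_b = armB$truth,
       collection = collection, ref_genes_a = ref_a, ref_genes_b = ref_b,
       shared_candidates = armA$truth$shared_candidates)
}
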