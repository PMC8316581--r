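#' Run the full cross-disease subtyping pipeline
#'
#' Executes every stage on two disease studies: preparation (duplicate
#' merging, optional protein-coding filter, batch adjustment, log2 fold
#' change), convex NMF rank selection by mean cophenetic correlation,
#' sample/gene cluster assignment with Kruskal-Wallis/Dunn filtering,
#' per-cluster DEG modules against controls, enrichment-based selection of
#' the related cluster pair with candidate-gene extraction, and
#' cross-validated logistic-regression evaluation of the candidate panel
#' against random-gene baselines. Per-stage tables and a decision log are
#' written under `out`.
#'
#' @param config A [run_config()] (or a list of its arguments).
#' @param inputs Named list of file paths: `expr_a`, `annot_a`, `expr_b`,
#'   `annot_b`, `gmt`, `ref_genes_a`, `ref_genes_b`, optional
#'   `coding_genes`.
#' @param out Output directory (created if missing).
#' @return Invisibly, a list with all stage results (`prep_a`, `prep_b`,
#'   `rank_a`, `rank_b`, `clusters_a`, `clusters_b`, `deg_a`, `deg_b`,
#'   `pairing`, `overlap_p`, `cv`, `baseline`, `anova_a`, `out`).
#' @export
run_pipeline <- function(config = run_config(), inputs, out) {
  if (!inherits(config, "run_config")) config <- do.call(run_config, config)
  req <- c("expr_a", "annot_a", "expr_b", "annot_b", "gmt",
           "ref_genes_a", "ref_genes_b")
  miss <- setdiff(req, names(inputs))
  if (length(miss)) {
    stage_stop("config", "missing inputs: ", paste(miss, collapse = ", "))
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out, "log.txt")
  logf <- function(...) cat(sprintf(...), "\n", sep = "", file = log_path,
                            append = TRUE)
  cat("", file = log_path)
  logf("seed: %d", config$seed)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) stage_stop(name, conditionMessage(e)))
  }

  # --- io ------------------------------------------------------------
  dat <- stage("io", {
    coding <- if (!is.null(inputs$coding_genes)) read_gene_list(inputs$coding_genes)
    list(a = read_expression_matrix(inputs$expr_a, inputs$annot_a),
         b = read_expression_matrix(inputs$expr_b, inputs$annot_b),
         collection = read_gene_sets_gmt(inputs$gmt),
         ref_a = read_gene_list(inputs$ref_genes_a),
         ref_b = read_gene_list(inputs$ref_genes_b),
         coding = coding)
  })

  # --- preprocess ----------------------------------------------------
  prep <- stage("preprocess", {
    list(a = preprocess_dataset(dat$a, dat$coding),
         b = preprocess_dataset(dat$b, dat$coding))
  })
  for (d in c("a", "b")) {
    logf("disease %s: %d genes, %d patients, %d controls", d,
         length(prep[[d]]$dataset$gene_ids), n_patients(prep[[d]]$dataset),
         sum(prep[[d]]$dataset$group == "control"))
  }

  # --- rank selection ------------------------------------------------
  seeds <- derive_seeds(config$seed, 6L)
  rank <- stage("factorize", {
    lapply(stats::setNames(c("a", "b"), c("a", "b")), function(d) {
      select_rank(prep[[d]]$fold_change$values,
                  k_min = config$k_min, k_max = config$k_max,
                  n_restarts = config$n_restarts,
                  max_iter = config$max_iter, tol = config$tol,
                  seed = seeds[if (d == "a") 1L else 2L],
                  consensus = config$consensus, burn_in = config$burn_in)
    })
  })
  for (d in c("a", "b")) {
    logf("disease %s: chosen k = %d (mean cophenetic: %s)", d,
         rank[[d]]$chosen_k,
         paste(sprintf("k%s=%.4f", names(rank[[d]]$per_k_mean_cophenetic),
                       rank[[d]]$per_k_mean_cophenetic), collapse = " "))
    utils::write.table(
      data.frame(k = names(rank[[d]]$per_k_mean_cophenetic),
                 mean_cophenetic = rank[[d]]$per_k_mean_cophenetic),
      file.path(out, sprintf("per_k_cophenetic_%s.tsv", d)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- clustering ----------------------------------------------------
  # the Kruskal-Wallis/Dunn filter needs >= 3 clusters; when the cophenetic
  # optimum is k = 2 the factorization is redone at the smallest usable rank
  clus_fit <- stage("cluster", {
    lapply(stats::setNames(c("a", "b"), c("a", "b")), function(d) {
      if (rank[[d]]$chosen_k >= 3L) return(rank[[d]]$best_fit)
      logf("disease %s: chosen k = %d is below 3; clustering at k = 3 instead",
           d, rank[[d]]$chosen_k)
      suppressWarnings(select_rank(
        prep[[d]]$fold_change$values, k_min = 3L, k_max = 3L,
        n_restarts = config$n_restarts, max_iter = config$max_iter,
        tol = config$tol, seed = seeds[if (d == "a") 5L else 6L],
        consensus = config$consensus, burn_in = config$burn_in))$best_fit
    })
  })
  clus <- stage("cluster", {
    lapply(stats::setNames(c("a", "b"), c("a", "b")), function(d) {
      fit <- clus_fit[[d]]
      select_cluster_genes(prep[[d]]$fold_change,
                           assign_samples(fit),
                           assign_genes(fit, "max"),
                           assign_genes(fit, "min"),
                           alpha = config$alpha)
    })
  })
  for (d in c("a", "b")) {
    logf("disease %s cluster gene counts (KW Bonferroni over %d genes/direction, Dunn over %d pairs/gene):",
         d, sum(!is.na(clus[[d]]$up_assignment)),
         clus[[d]]$k * (clus[[d]]$k - 1) / 2)
    utils::write.table(clus[[d]]$counts,
                       file.path(out, sprintf("cluster_counts_%s.tsv", d)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(clus[[d]]$per_gene_stats,
                       file.path(out, sprintf("gene_clusters_%s.tsv", d)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = prep[[d]]$fold_change$patient_ids,
                 cluster = clus[[d]]$sample_cluster),
      file.path(out, sprintf("sample_clusters_%s.tsv", d)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # --- deg modules ---------------------------------------------------
  deg <- stage("deg", {
    lapply(stats::setNames(c("a", "b"), c("a", "b")), function(d) {
      build_deg_modules(prep[[d]]$dataset, clus[[d]], alpha = config$alpha)
    })
  })
  for (d in c("a", "b")) {
    utils::write.table(deg[[d]]$counts,
                       file.path(out, sprintf("deg_counts_%s.tsv", d)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    logf("disease %s DEG counts written (Bonferroni over %d genes/cluster)",
         d, length(deg[[d]]$tested_genes))
  }

  # --- enrichment pairing --------------------------------------------
  measured <- intersect(prep$a$dataset$gene_ids, prep$b$dataset$gene_ids)
  universe <- intersect(measured, dat$collection$universe)
  logf("enrichment universe: %d genes (measured intersection x collection universe)",
       length(universe))
  pairing <- stage("pair", {
    select_related_pair(deg$a, deg$b, dat$collection, dat$ref_a, dat$ref_b,
                        alpha = config$alpha, universe = universe)
  })
  utils::write.table(pairing$stageA_counts,
                     file.path(out, "pair_stageA_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pairing$stageB_counts,
                     file.path(out, "pair_stageB_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pairing$candidate_genes,
                     file.path(out, "candidate_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  overlap_p <- NA_real_
  if (!is.null(pairing$chosen_pair)) {
    logf("chosen pair: A cluster %d, B cluster %d; %d candidate genes",
         pairing$chosen_pair[1L], pairing$chosen_pair[2L],
         nrow(pairing$candidate_genes))
    ref_common <- intersect(dat$ref_a, dat$ref_b)
    if (length(ref_common)) {
      overlap_p <- stage("pair", candidate_overlap_test(
        pairing$candidate_genes$gene_id, ref_common, length(measured)))
      logf("candidate/reference overlap p = %.6g (background %d)",
           overlap_p, length(measured))
    }
  } else {
    logf("no related pair found")
  }

  # --- validation ----------------------------------------------------
  cv <- NULL; baseline <- NULL
  if (!is.null(pairing$chosen_pair) && nrow(pairing$candidate_genes) > 0L) {
    cv <- stage("validate", cross_validated_auc(
      prep$a$dataset, pairing$candidate_genes$gene_id,
      n_folds = config$n_folds, learning_rate = config$learning_rate,
      epochs = config$epochs, seed = seeds[3L]))
    baseline <- stage("validate", random_gene_baseline(
      prep$a$dataset, panel_size = length(cv$gene_panel),
      reps = config$baseline_reps, n_folds = config$n_folds,
      learning_rate = config$learning_rate, epochs = config$epochs,
      seed = seeds[4L], candidate_auc = cv$mean_auc))
    utils::write.table(
      data.frame(fold = seq_along(cv$per_fold_auc), auc = cv$per_fold_auc),
      file.path(out, "cv_auc.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(rep = seq_along(baseline$baseline_aucs),
                 auc = baseline$baseline_aucs),
      file.path(out, "baseline_auc.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    logf("candidate panel mean AUC %.4f; baseline mean %.4f (p = %.4g, %d reps)",
         cv$mean_auc, baseline$mean_baseline_auc, baseline$p,
         config$baseline_reps)
  }

  anova_a <- NULL
  if (!is.null(prep$a$dataset$covariates) &&
      "age" %in% colnames(prep$a$dataset$covariates)) {
    pat <- prep$a$dataset$group == "patient"
    anova_a <- stage("validate", covariate_anova(
      prep$a$dataset$covariates$age[pat], clus$a$sample_cluster))
    logf("age ANOVA across disease-A clusters: F = %.4f, p = %.4g",
         anova_a$F, anova_a$p)
  }

  summary <- list(
    chosen_k = list(a = rank$a$chosen_k, b = rank$b$chosen_k),
    chosen_pair = pairing$chosen_pair,
    n_candidate_genes = nrow(pairing$candidate_genes),
    candidate_overlap_p = overlap_p,
    candidate_mean_auc = if (!is.null(cv)) cv$mean_auc,
    baseline_mean_auc = if (!is.null(baseline)) baseline$mean_baseline_auc,
    baseline_comparison_p = if (!is.null(baseline)) baseline$p,
    age_anova = anova_a, seed = config$seed
  )
  jsonlite::write_json(summary, file.path(out, "summary.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  invisible(list(prep_a = prep$a, prep_b = prep$b, rank_a = rank$a,
                 rank_b = rank$b, clusters_a = clus$a, clusters_b = clus$b,
                 deg_a = deg$a, deg_b = deg$b, pairing = pairing,
                 overlap_p = overlap_p, cv = cv, baseline = baseline,
                 anova_a = anova_a, out = out, summary = summary))
}

#' Write a simulated paired study to disk in pipeline input formats
#'
#' @param study Result of [generate_paired_study()].
#' @param dir Output directory (created if missing).
#' @return Named list of file paths suitable as `inputs` for
#'   [run_pipeline()].
#' @export
write_study_inputs <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_expression_matrix(study$dataset_a, p("expr_a.tsv"), p("annot_a.tsv"))
  write_expression_matrix(study$dataset_b, p("expr_b.tsv"), p("annot_b.tsv"))
  write_gene_sets_gmt(study$collection, p("sets.gmt"))
  write_gene_list(study$ref_genes_a, p("ref_genes_a.txt"))
  write_gene_list(study$ref_genes_b, p("ref_genes_b.txt"))
  utils::write.table(
    data.frame(sample_id = study$dataset_a$sample_ids[
                 study$dataset_a$group == "patient"],
               cluster = study$truth_a$sample_cluster),
    p("truth_sample_clusters_a.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  list(expr_a = p("expr_a.tsv"), annot_a = p("annot_a.tsv"),
       expr_b = p("expr_b.tsv"), annot_b = p("annot_b.tsv"),
       gmt = p("sets.gmt"), ref_genes_a = p("ref_genes_a.txt"),
       ref_genes_b = p("ref_genes_b.txt"))
}
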