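#' Upper-tail hypergeometric probability
#'
#' P(X >= overlap) when `query_size` genes are drawn without replacement
#' from a universe of `universe_size` genes containing `set_size` marked
#' ones; computed in log space via the hypergeometric distribution
#' function.
#'
#' @param overlap Observed overlap count.
#' @param query_size Query gene-set size.
#' @param set_size Pathway (marked) gene-set size.
#' @param universe_size Background size.
#' @return The upper-tail p-value.
#' @export
hypergeom_upper_tail <- function(overlap, query_size, set_size, universe_size) {
  if (overlap < 0 || query_size < 0 || set_size < 0 ||
      overlap > min(query_size, set_size) ||
      max(query_size, set_size) > universe_size) {
    stop("inconsistent hypergeometric counts", call. = FALSE)
  }
  if (overlap == 0) return(1)
  exp(stats::phyper(overlap - 1, set_size, universe_size - set_size,
                    query_size, lower.tail = FALSE, log.p = TRUE))
}

#' Hypergeometric enrichment of a query against a gene-set collection
#'
#' Every set (and the query) is first intersected with the background
#' universe; raw upper-tail p-values are Bonferroni-adjusted over the
#' number of sets tested.
#'
#' @param query Character vector of gene identifiers.
#' @param collection A [gene_set_collection()].
#' @param alpha Significance level for the `enriched` flag (default 0.05).
#' @param universe Optional background overriding `collection$universe`
#'   (e.g. the measured genes of a dataset).
#' @return Object of class `enrichment_result`: a data frame with one row
#'   per set (`set`, `overlap`, `set_size`, `query_size`, `universe_size`,
#'   `p`, `adjusted_p`, `enriched`), ordered as in the collection.
#' @export
enrich_collection <- function(query, collection, alpha = 0.05,
                              universe = NULL) {
  if (!length(query)) stop("empty query", call. = FALSE)
  uni <- unique(as.character(universe %||% collection$universe))
  q <- unique(intersect(query, uni))
  if (!length(q)) stop("query disjoint from the universe", call. = FALSE)
  n_sets <- length(collection$sets)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- intersect(collection$sets[[nm]], uni)
    ov <- length(intersect(q, s))
    p <- if (length(s)) {
      hypergeom_upper_tail(ov, length(q), length(s), length(uni))
    } else 1
    data.frame(set = nm, overlap = ov, set_size = length(s),
               query_size = length(q), universe_size = length(uni),
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- pmin(out$p * n_sets, 1)
  out$enriched <- out$adjusted_p < alpha
  class(out) <- c("enrichment_result", class(out))
  out
}

#' Derive reference pathways from a disease gene list
#'
#' Names of the collection's sets significantly enriched for the reference
#' genes — the pathway-level signature of a disease gene list.
#'
#' @inheritParams enrich_collection
#' @param ref_genes Character vector of disease-related gene identifiers.
#' @return Character vector of enriched set names.
#' @export
derive_reference_pathways <- function(ref_genes, collection, alpha = 0.05,
                                      universe = NULL) {
  if (!length(ref_genes)) stop("empty reference gene list", call. = FALSE)
  res <- enrich_collection(ref_genes, collection, alpha = alpha,
                           universe = universe)
  res$set[res$enriched]
}

#' Select the related cluster pair between two diseases
#'
#' Two-stage pathway bookkeeping over the DEG modules of diseases A and B:
#'
#' Stage A: each module `M_i^+` / `M_i^-` of one disease is enriched
#' against the collection and its enriched pathways are intersected with
#' the reference pathways of the *other* disease (derived from that
#' disease's reference gene list) — per-cluster evidence that a subgroup of
#' one disease carries the other disease's pathway signature.
#'
#' Stage B: for every cluster pair (i in A, j in B) and direction, the
#' same-direction common genes `M_i ∩ M_j` are enriched and the result is
#' intersected with the pathways of the joint reference list (refA ∩ refB).
#' The chosen pair maximises the stage-B up+down count; ties are broken by
#' the summed stage-A counts of the two clusters, then by lowest indices.
#' Candidate genes are the same-direction intersections of the chosen
#' pair's modules.
#'
#' @param modsA,modsB `deg_modules` for diseases A and B.
#' @param collection A [gene_set_collection()].
#' @param refA,refB Character vectors of disease-related reference genes.
#' @param alpha Significance level (default 0.05).
#' @param universe Optional background (defaults to the collection's).
#' @return Object of class `pair_selection` with fields `stageA_counts`,
#'   `stageB_counts` (data frames), `chosen_pair` (c(i, j) or NULL when no
#'   pair has evidence), `candidate_genes` (data frame `gene_id`,
#'   `direction`) and the reference pathway sets used.
#' @export
select_related_pair <- function(modsA, modsB, collection, refA, refB,
                                alpha = 0.05, universe = NULL) {
  ref_path_A <- derive_reference_pathways(refA, collection, alpha, universe)
  ref_path_B <- derive_reference_pathways(refB, collection, alpha, universe)
  ref_joint <- intersect(refA, refB)
  ref_path_joint <- if (length(ref_joint)) {
    derive_reference_pathways(ref_joint, collection, alpha, universe)
  } else character(0L)

  enriched_names <- function(genes) {
    if (!length(genes)) return(character(0L))
    ok <- length(intersect(genes, universe %||% collection$universe)) > 0L
    if (!ok) return(character(0L))
    res <- enrich_collection(genes, collection, alpha = alpha,
                             universe = universe)
    res$set[res$enriched]
  }

  stageA <- function(mods, other_ref_paths, disease) {
    rows <- list()
    for (i in seq_len(mods$k)) {
      for (direction in c("up", "down")) {
        genes <- if (direction == "up") mods$M_up[[i]] else mods$M_down[[i]]
        en <- enriched_names(genes)
        rows[[length(rows) + 1L]] <- data.frame(
          disease = disease, cluster = i, direction = direction,
          n_enriched = length(en),
          n_common_with_ref = length(intersect(en, other_ref_paths)),
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows)
  }
  stageA_counts <- rbind(stageA(modsA, ref_path_B, "A"),
                         stageA(modsB, ref_path_A, "B"))

  stageB_rows <- list()
  for (i in seq_len(modsA$k)) {
    for (j in seq_len(modsB$k)) {
      for (direction in c("up", "down")) {
        common <- if (direction == "up") {
          intersect(modsA$M_up[[i]], modsB$M_up[[j]])
        } else {
          intersect(modsA$M_down[[i]], modsB$M_down[[j]])
        }
        en <- enriched_names(common)
        stageB_rows[[length(stageB_rows) + 1L]] <- data.frame(
          cluster_a = i, cluster_b = j, direction = direction,
          n_common_genes = length(common), n_enriched = length(en),
          n_common_with_ref = length(intersect(en, ref_path_joint)),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  stageB_counts <- do.call(rbind, stageB_rows)

  pair_score <- stats::aggregate(n_common_with_ref ~ cluster_a + cluster_b,
                                 data = stageB_counts, FUN = sum)
  a_cnt <- stats::aggregate(n_common_with_ref ~ cluster,
                            data = stageA_counts[stageA_counts$disease == "A", ],
                            FUN = sum)
  b_cnt <- stats::aggregate(n_common_with_ref ~ cluster,
                            data = stageA_counts[stageA_counts$disease == "B", ],
                            FUN = sum)
  pair_score$stageA <- a_cnt$n_common_with_ref[pair_score$cluster_a] +
    b_cnt$n_common_with_ref[pair_score$cluster_b]

  chosen_pair <- NULL
  candidate_genes <- data.frame(gene_id = character(0L),
                                direction = character(0L),
                                stringsAsFactors = FALSE)
  if (any(pair_score$n_common_with_ref > 0)) {
    ord <- order(-pair_score$n_common_with_ref, -pair_score$stageA,
                 pair_score$cluster_a, pair_score$cluster_b)
    top <- pair_score[ord[1L], ]
    chosen_pair <- c(top$cluster_a, top$cluster_b)
    up <- intersect(modsA$M_up[[chosen_pair[1L]]],
                    modsB$M_up[[chosen_pair[2L]]])
    dn <- intersect(modsA$M_down[[chosen_pair[1L]]],
                    modsB$M_down[[chosen_pair[2L]]])
    candidate_genes <- data.frame(
      gene_id = c(up, dn),
      direction = rep(c("up", "down"), c(length(up), length(dn))),
      stringsAsFactors = FALSE
    )
  }
  structure(
    list(stageA_counts = stageA_counts, stageB_counts = stageB_counts,
         chosen_pair = chosen_pair, candidate_genes = candidate_genes,
         ref_path_A = ref_path_A, ref_path_B = ref_path_B,
         ref_path_joint = ref_path_joint, alpha = alpha),
    class = "pair_selection"
  )
}

#' @export
print.pair_selection <- function(x, ...) {
  if (is.null(x$chosen_pair)) {
    cat("pair_selection: no related pair (all overlap counts zero)\n")
  } else {
    cat(sprintf("pair_selection: chosen pair (A cluster %d, B cluster %d), %d candidate genes\n",
                x$chosen_pair[1L], x$chosen_pair[2L],
                nrow(x$candidate_genes)))
  }
  invisible(x)
}

#' Significance of the candidate / reference gene overlap
#'
#' Upper-tail hypergeometric probability of the observed overlap between
#' the candidate genes and a reference gene set on a background of
#' `background_size` genes.
#'
#' @param candidates Character vector of candidate gene identifiers.
#' @param ref_common Character vector of reference gene identifiers.
#' @param background_size Background universe size (must be at least
#'   `length(union(candidates, ref_common))`).
#' @return The p-value.
#' @export
candidate_overlap_test <- function(candidates, ref_common, background_size) {
  candidates <- unique(candidates); ref_common <- unique(ref_common)
  if (background_size < length(union(candidates, ref_common))) {
    stop("background smaller than the union of the two gene sets", call. = FALSE)
  }
  hypergeom_upper_tail(length(intersect(candidates, ref_common)),
                       length(candidates), length(ref_common),
                       background_size)
}
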