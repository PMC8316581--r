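#' Merge rows that share a gene identifier
#'
#' Duplicate identifiers (e.g. several probes mapped to one gene) are
#' collapsed to their per-sample arithmetic mean. Gene order follows the
#' first occurrence of each identifier.
#'
#' @param ds An [expression_dataset()].
#' @return An [expression_dataset()] with unique gene identifiers.
#' @export
merge_duplicate_genes <- function(ds) {
  if (!anyDuplicated(ds$gene_ids)) return(ds)
  keep <- unique(ds$gene_ids)
  grp <- factor(ds$gene_ids, levels = keep)
  merged <- rowsum(ds$values, grp, reorder = FALSE) /
    as.vector(table(grp))
  expression_dataset(merged, keep, ds$sample_ids, ds$group,
                     batch = ds$batch, covariates = ds$covariates)
}

#' Restrict a dataset to a gene list
#'
#' Keeps only genes present in `keep` (e.g. a protein-coding gene list),
#' preserving the dataset's original gene order.
#'
#' @param ds An [expression_dataset()].
#' @param keep Character vector of gene identifiers to retain.
#' @return The filtered [expression_dataset()].
#' @export
filter_genes <- function(ds, keep) {
  idx <- which(ds$gene_ids %in% keep)
  if (!length(idx)) {
    stop("no genes of the dataset are in the keep list", call. = FALSE)
  }
  expression_dataset(ds$values[idx, , drop = FALSE], ds$gene_ids[idx],
                     ds$sample_ids, ds$group, batch = ds$batch,
                     covariates = ds$covariates)
}

#' Equalise per-gene batch means
#'
#' A no-covariate linear batch adjustment: for every gene, each sample's
#' value is shifted by the grand mean minus its batch mean, so after
#' adjustment all batch means of a gene coincide (with the grand mean
#' preserved). This corresponds to fitting gene ~ batch and removing the
#' batch term.
#'
#' @param ds An [expression_dataset()] with batch labels (>= 2 batches, each
#'   with >= 2 samples).
#' @return The adjusted [expression_dataset()] (batch labels retained).
#' @export
remove_batch_effect <- function(ds) {
  if (is.null(ds$batch)) stop("dataset has no batch labels", call. = FALSE)
  b <- factor(ds$batch)
  if (nlevels(b) < 2L) stop("need at least 2 batches", call. = FALSE)
  sizes <- table(b)
  if (any(sizes < 2L)) {
    stop("batch with fewer than 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "), call. = FALSE)
  }
  # genes x batches matrix of batch means
  bm <- t(rowsum(t(ds$values), b)) / rep(as.vector(sizes),
                                         each = nrow(ds$values))
  grand <- rowMeans(ds$values)
  adj <- ds$values - bm[, as.integer(b), drop = FALSE] + grand
  expression_dataset(adj, ds$gene_ids, ds$sample_ids, ds$group,
                     batch = ds$batch, covariates = ds$covariates)
}

#' Log2 fold-change matrix of patients against the control mean
#'
#' For gene i and patient j the normalised value is
#' `y_ij = log2(patient_ij / normal_i)` where `normal_i` is the arithmetic
#' mean of gene i over the control samples, taken on the stored expression
#' scale. All patient values and control means must be strictly positive.
#'
#' @param ds An [expression_dataset()] with at least one patient and one
#'   control.
#' @return An object of class `fold_change_matrix` with fields `values`
#'   (genes x patients), `gene_ids`, `patient_ids` and `control_means`.
#' @export
log2_fold_change <- function(ds) {
  pat <- which(ds$group == "patient")
  ctl <- which(ds$group == "control")
  if (!length(ctl)) stop("no control samples", call. = FALSE)
  if (!length(pat)) stop("no patient samples", call. = FALSE)
  pv <- ds$values[, pat, drop = FALSE]
  if (any(pv <= 0)) {
    bad <- which(pv <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("nonpositive expression value at gene '%s', sample '%s'",
                 ds$gene_ids[bad[1L]], ds$sample_ids[pat][bad[2L]]),
         call. = FALSE)
  }
  cm <- rowMeans(ds$values[, ctl, drop = FALSE])
  if (any(cm <= 0)) {
    stop("nonpositive control mean for gene '",
         ds$gene_ids[which(cm <= 0)[1L]], "'", call. = FALSE)
  }
  y <- log2(pv) - log2(cm)
  structure(
    list(values = y, gene_ids = ds$gene_ids,
         patient_ids = ds$sample_ids[pat], control_means = cm),
    class = "fold_change_matrix"
  )
}

#' @export
print.fold_change_matrix <- function(x, ...) {
  cat(sprintf("fold_change_matrix: %d genes x %d patients\n",
              length(x$gene_ids), length(x$patient_ids)))
  invisible(x)
}

#' Write a fold-change matrix (with a sidecar control-means TSV)
#' @param fc A `fold_change_matrix`.
#' @param path Output TSV for the matrix.
#' @param control_means_path Output TSV for the per-gene control means.
#' @return Invisibly, `fc`.
#' @export
write_fold_change <- function(fc, path, control_means_path) {
  tab <- data.frame(gene_id = fc$gene_ids,
                    format(fc$values, digits = 17, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE)
  colnames(tab) <- c("gene_id", fc$patient_ids)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cm <- data.frame(gene_id = fc$gene_ids,
                   control_mean = format(fc$control_means, digits = 17,
                                         trim = TRUE, scientific = FALSE))
  utils::write.table(cm, control_means_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(fc)
}

#' Run the full preparation chain on a raw dataset
#'
#' merge duplicates -> optional protein-coding filter -> optional batch
#' adjustment -> log2 fold change.
#'
#' @param ds An [expression_dataset()].
#' @param coding_genes Optional gene list to restrict to.
#' @return List with the prepared `dataset` (normalised expression including
#'   controls) and the patient `fold_change` matrix.
#' @export
preprocess_dataset <- function(ds, coding_genes = NULL) {
  ds <- merge_duplicate_genes(ds)
  if (!is.null(coding_genes)) ds <- filter_genes(ds, coding_genes)
  if (!is.null(ds$batch) && length(unique(ds$batch)) > 1L) {
    ds <- remove_batch_effect(ds)
  }
  list(dataset = ds, fold_change = log2_fold_change(ds))
}
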