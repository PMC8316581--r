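#' Expression dataset container
#'
#' Bundles a genes-by-samples expression matrix (log-scale intensities) with
#' per-sample annotation: a patient/control group label, an optional batch
#' label and optional numeric covariates (for example age in years).
#'
#' @param values Numeric matrix, genes in rows and samples in columns.
#' @param gene_ids Character vector of row identifiers.
#' @param sample_ids Character vector of column identifiers (unique).
#' @param group Character vector per sample, values in `"patient"` /
#'   `"control"`.
#' @param batch Optional character vector of per-sample batch labels.
#' @param covariates Optional data frame of per-sample numeric covariates
#'   (one row per sample, in sample order).
#'
#' @return An object of class `expression_dataset` with fields `values`,
#'   `gene_ids`, `sample_ids`, `group`, `batch`, `covariates`.
#' @export
expression_dataset <- function(values, gene_ids, sample_ids, group,
                               batch = NULL, covariates = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  group <- as.character(group)
  if (nrow(values) != length(gene_ids)) {
    stop("row count does not match the number of gene ids", call. = FALSE)
  }
  if (ncol(values) != length(sample_ids)) {
    stop("column count does not match the number of sample ids", call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (length(group) != length(sample_ids)) {
    stop("group labels do not match the number of samples", call. = FALSE)
  }
  if (!all(group %in% c("patient", "control"))) {
    stop("group labels must be 'patient' or 'control'", call. = FALSE)
  }
  if (!is.null(batch)) {
    batch <- as.character(batch)
    if (length(batch) != length(sample_ids)) {
      stop("batch labels do not match the number of samples", call. = FALSE)
    }
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(sample_ids)) {
      stop("covariate rows do not match the number of samples", call. = FALSE)
    }
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(
    list(values = values, gene_ids = gene_ids, sample_ids = sample_ids,
         group = group, batch = batch, covariates = covariates),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d samples (%d patients, %d controls)\n",
              length(x$gene_ids), length(x$sample_ids),
              sum(x$group == "patient"), sum(x$group == "control")))
  if (!is.null(x$batch)) {
    cat("batches:", paste(sort(unique(x$batch)), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Number of patient samples in a dataset
#' @param ds An `expression_dataset`.
#' @return Integer count.
#' @export
n_patients <- function(ds) sum(ds$group == "patient")

#' Subset an expression dataset by sample index
#' @noRd
subset_samples <- function(ds, idx) {
  expression_dataset(
    ds$values[, idx, drop = FALSE], ds$gene_ids, ds$sample_ids[idx],
    ds$group[idx],
    batch = if (!is.null(ds$batch)) ds$batch[idx],
    covariates = if (!is.null(ds$covariates)) ds$covariates[idx, , drop = FALSE]
  )
}

#' Read an expression matrix and its sample annotation
#'
#' The matrix file is a TSV with a header row of sample identifiers and the
#' gene identifier in the first column. The annotation file is a TSV with
#' columns `sample_id`, `group` and optionally `batch` plus any number of
#' numeric covariate columns; every sample in the matrix must be annotated.
#'
#' @param path Path to the expression TSV.
#' @param annotation_path Path to the sample annotation TSV.
#' @return An [expression_dataset()].
#' @export
read_expression_matrix <- function(path, annotation_path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           quote = "", comment.char = "")
  if (ncol(tab) < 2L) stop("expression matrix has no sample columns", call. = FALSE)
  gene_ids <- tab[[1L]]
  sample_ids <- colnames(tab)[-1L]
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample ids in matrix header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(tab[-1L], as.numeric, numeric(nrow(tab)))
  )
  vals <- matrix(vals, nrow = nrow(tab),
                 dimnames = list(gene_ids, sample_ids))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric expression value at gene '%s', sample '%s'",
                 gene_ids[bad[1L]], sample_ids[bad[2L]]), call. = FALSE)
  }

  ann <- utils::read.table(annotation_path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE,
                           quote = "", comment.char = "")
  if (!all(c("sample_id", "group") %in% colnames(ann))) {
    stop("annotation must contain 'sample_id' and 'group' columns", call. = FALSE)
  }
  missing <- setdiff(sample_ids, ann$sample_id)
  if (length(missing)) {
    stop("samples absent from annotation: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(ann$sample_id, sample_ids)
  if (length(unknown)) {
    stop("annotation contains unknown samples: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ann <- ann[match(sample_ids, ann$sample_id), , drop = FALSE]
  covar_cols <- setdiff(colnames(ann), c("sample_id", "group", "batch"))
  expression_dataset(
    vals, gene_ids, sample_ids, ann$group,
    batch = if ("batch" %in% colnames(ann)) as.character(ann$batch),
    covariates = if (length(covar_cols)) ann[, covar_cols, drop = FALSE]
  )
}

#' Write an expression dataset as matrix + annotation TSVs
#'
#' Values are written at full precision so a read/write cycle is loss-free.
#'
#' @param ds An [expression_dataset()].
#' @param path Output path for the expression TSV.
#' @param annotation_path Output path for the annotation TSV.
#' @return Invisibly, `ds`.
#' @export
write_expression_matrix <- function(ds, path, annotation_path) {
  mat <- data.frame(gene_id = ds$gene_ids,
                    format(ds$values, digits = 17, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE)
  colnames(mat) <- c("gene_id", ds$sample_ids)
  utils::write.table(mat, path, sep = "\t", quote = FALSE, row.names = FALSE)
  ann <- data.frame(sample_id = ds$sample_ids, group = ds$group,
                    stringsAsFactors = FALSE)
  if (!is.null(ds$batch)) ann$batch <- ds$batch
  if (!is.null(ds$covariates)) ann <- cbind(ann, ds$covariates)
  utils::write.table(ann, annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(ds)
}

#' Gene-set collection container
#'
#' @param sets Named list of character vectors (gene identifiers).
#' @param universe Character vector of background gene identifiers; defaults
#'   to the union of all set members.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("every gene set must be named", call. = FALSE)
  }
  if (anyDuplicated(names(sets))) {
    stop("duplicate gene-set names: ",
         paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", "),
         call. = FALSE)
  }
  if (any(lengths(sets) == 0L)) stop("empty gene set", call. = FALSE)
  sets <- lapply(sets, as.character)
  universe <- as.character(universe %||% unique(unlist(sets, use.names = FALSE)))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, `name TAB description TAB member...`.
#'
#' @param path Path to the GMT file.
#' @param universe Optional background gene vector overriding the default
#'   (union of all members).
#' @return A [gene_set_collection()].
#' @export
read_gene_sets_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty GMT file", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short)) {
    stop("GMT line ", short[1L], " has fewer than 3 fields", call. = FALSE)
  }
  nm <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(parts, function(p) unique(p[-c(1L, 2L)]))
  names(sets) <- nm
  gene_set_collection(sets, universe = universe)
}

#' Write a gene-set collection as GMT
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return Invisibly, `collection`.
#' @export
write_gene_sets_gmt <- function(collection, path, descriptions = NULL) {
  nm <- names(collection$sets)
  desc <- descriptions %||% rep("na", length(nm))
  lines <- vapply(seq_along(nm), function(i) {
    paste(c(nm[i], desc[i], collection$sets[[i]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(collection)
}

#' Read a plain-text gene list (one identifier per line)
#'
#' Blank lines are ignored; identifiers are de-duplicated preserving first
#' occurrence.
#'
#' @param path Path to the list file.
#' @return Character vector of unique identifiers.
#' @export
read_gene_list <- function(path) {
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids)]
  if (!length(ids)) stop("empty gene list: ", path, call. = FALSE)
  unique(ids)
}

#' Write a gene list, one identifier per line
#' @param genes Character vector.
#' @param path Output path.
#' @return Invisibly, `genes`.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(as.character(genes), path)
  invisible(genes)
}
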