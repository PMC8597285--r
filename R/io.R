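# Reading, validation, binarization and subsetting of dependency matrices,
# gene sets and cell-line annotations.
#
# Matrices are gene-major throughout: rows are genes, columns are models
# (cell lines / screens). Quantitative matrices hold scaled fitness scores
# (more negative = stronger loss of fitness upon knock-out); binary matrices
# hold dependency calls (1 = the model is dependent on the gene).

#' Validate a quantitative dependency matrix
#'
#' A quantitative dependency matrix is a numeric matrix of scaled fitness
#' scores with unique gene row names and unique model column names, at least
#' 2 genes and 2 models. Cells are finite numbers or `NA` (missing).
#'
#' @param scores Numeric matrix, genes in rows, models in columns.
#' @return The validated matrix, invisibly classed for dispatch.
#' @export
validate_quantitative_matrix <- function(scores) {
  if (!is.matrix(scores) || !is.numeric(scores)) {
    stop("quantitative dependency matrix must be a numeric matrix")
  }
  if (nrow(scores) < 2L || ncol(scores) < 2L) {
    stop("quantitative dependency matrix needs at least 2 genes and 2 models")
  }
  if (is.null(rownames(scores)) || is.null(colnames(scores))) {
    stop("quantitative dependency matrix needs gene row names and model column names")
  }
  if (anyDuplicated(rownames(scores))) stop("duplicated gene identifiers")
  if (anyDuplicated(colnames(scores))) stop("duplicated model identifiers")
  if (any(is.infinite(scores))) stop("scores must be finite or NA")
  invisible(scores)
}

#' Validate a binary dependency matrix
#'
#' A binary dependency matrix holds dependency calls strictly in \{0, 1\}
#' (no missing values), with unique gene and model identifiers, at least one
#' gene and two models.
#'
#' @param calls Numeric/integer matrix of 0/1 calls.
#' @return The validated matrix, invisibly.
#' @export
validate_binary_matrix <- function(calls) {
  if (!is.matrix(calls) || !is.numeric(calls)) {
    stop("binary dependency matrix must be a numeric matrix")
  }
  if (nrow(calls) < 1L || ncol(calls) < 2L) {
    stop("binary dependency matrix needs at least 1 gene and 2 models")
  }
  if (is.null(rownames(calls)) || is.null(colnames(calls))) {
    stop("binary dependency matrix needs gene row names and model column names")
  }
  if (anyDuplicated(rownames(calls))) stop("duplicated gene identifiers")
  if (anyDuplicated(colnames(calls))) stop("duplicated model identifiers")
  if (anyNA(calls) || !all(calls == 0 | calls == 1)) {
    stop("non-binary value in dependency matrix (cells must be 0 or 1)")
  }
  invisible(calls)
}

read_delim_matrix <- function(path, delimiter, gene_column) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': file does not exist", path))
  df <- data.table::fread(path, sep = delimiter, header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  if (is.numeric(gene_column)) {
    if (gene_column < 1 || gene_column > ncol(df)) {
      stop("gene_column index out of range")
    }
    gene_col_idx <- as.integer(gene_column)
  } else {
    gene_col_idx <- match(gene_column, colnames(df))
    if (is.na(gene_col_idx)) {
      stop(sprintf("gene column '%s' not found in '%s'", gene_column, path))
    }
  }
  genes <- as.character(df[[gene_col_idx]])
  vals <- df[, -gene_col_idx, drop = FALSE]
  if (ncol(vals) < 2L) stop("dependency matrix needs at least 2 model columns")
  not_num <- !vapply(vals, is.numeric, logical(1))
  if (any(not_num)) {
    stop(sprintf("non-numeric cell(s) in column(s): %s",
                 paste(colnames(vals)[not_num], collapse = ", ")))
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  m
}

#' Read a quantitative dependency matrix from delimited text
#'
#' The first row holds model identifiers; one column (`gene_column`) holds
#' gene symbols. Duplicate gene rows are collapsed by arithmetic mean (as is
#' common in integrated dataset releases); missing cells stay `NA`.
#'
#' @param path Path to a CSV/TSV file.
#' @param delimiter Field delimiter (default `","`).
#' @param gene_column Name or index of the gene-symbol column (default 1).
#' @return A validated quantitative dependency matrix.
#' @export
read_quantitative_matrix <- function(path, delimiter = ",", gene_column = 1L) {
  m <- read_delim_matrix(path, delimiter, gene_column)
  genes <- rownames(m)
  if (anyDuplicated(genes)) {
    n_dup <- sum(duplicated(genes))
    keep_order <- unique(genes)
    sums <- rowsum(m, group = genes, na.rm = TRUE)
    counts <- rowsum((!is.na(m)) * 1, group = genes)
    avg <- sums / counts
    avg[counts == 0] <- NA_real_
    m <- avg[keep_order, , drop = FALSE]
    message(sprintf("collapsed %d duplicated gene row(s) by mean", n_dup))
  }
  validate_quantitative_matrix(m)
  m
}

#' Read a binary dependency matrix from delimited text
#'
#' Cells must parse to 0/1; duplicated gene symbols are an error (binary
#' calls are not averageable).
#'
#' @inheritParams read_quantitative_matrix
#' @return A validated binary dependency matrix.
#' @export
read_binary_matrix <- function(path, delimiter = ",", gene_column = 1L) {
  m <- read_delim_matrix(path, delimiter, gene_column)
  if (anyDuplicated(rownames(m))) {
    stop("duplicated gene symbols in binary dependency matrix")
  }
  validate_binary_matrix(m)
  m
}

#' Binarize a quantitative dependency matrix
#'
#' A gene/model cell is called dependent (1) when its scaled fitness score is
#' strictly below `threshold`. Missing scores are treated as non-essential
#' (0); their count is reported via a message.
#'
#' @param qm Quantitative dependency matrix.
#' @param threshold Finite significance threshold on the scaled fitness score
#'   (default -0.5, the conventional cut for significant essentiality).
#' @return A binary dependency matrix of the same shape.
#' @export
binarize <- function(qm, threshold = -0.5) {
  validate_quantitative_matrix(qm)
  if (!is.numeric(threshold) || length(threshold) != 1L || !is.finite(threshold)) {
    stop("threshold must be a single finite number")
  }
  n_missing <- sum(is.na(qm))
  calls <- (qm < threshold) * 1
  calls[is.na(calls)] <- 0
  if (n_missing > 0) {
    message(sprintf("binarize: %d missing score(s) treated as non-essential", n_missing))
  }
  storage.mode(calls) <- "integer"
  calls
}

#' Read a cell-line annotation table
#'
#' Expects delimited text with columns `model_id` and `tissue` (and optionally
#' `cancer_type`).
#'
#' @param path Path to the annotation CSV/TSV.
#' @param delimiter Field delimiter (default `","`).
#' @return A data.frame with columns `model_id`, `tissue` and, when present,
#'   `cancer_type`.
#' @export
read_model_annotation <- function(path, delimiter = ",") {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': file does not exist", path))
  df <- data.table::fread(path, sep = delimiter, header = TRUE,
                          data.table = FALSE, check.names = FALSE)
  validate_model_annotation(df)
  df
}

#' Validate a cell-line annotation table
#'
#' @param annotation data.frame with `model_id` and `tissue` columns.
#' @return The annotation, invisibly.
#' @export
validate_model_annotation <- function(annotation) {
  if (!is.data.frame(annotation) ||
      !all(c("model_id", "tissue") %in% colnames(annotation))) {
    stop("annotation must be a data.frame with columns 'model_id' and 'tissue'")
  }
  if (anyDuplicated(annotation$model_id)) stop("duplicated model_id in annotation")
  bad <- is.na(annotation$model_id) | annotation$model_id == "" |
    is.na(annotation$tissue) | annotation$tissue == ""
  if (any(bad)) stop("annotation contains empty model ids or tissue labels")
  invisible(annotation)
}

#' Restrict a dependency matrix to the models of one tissue
#'
#' Columns are restricted to the models annotated with `tissue`; gene order is
#' preserved. Models present in the matrix but absent from the annotation are
#' dropped from every tissue subset, with a warning.
#'
#' @param m Binary or quantitative dependency matrix.
#' @param annotation Cell-line annotation (see [read_model_annotation()]).
#' @param tissue Tissue-lineage (or cancer-type) label to keep.
#' @return A matrix of the same kind with the matching columns only.
#' @export
subset_by_tissue <- function(m, annotation, tissue) {
  validate_model_annotation(annotation)
  if (!tissue %in% annotation$tissue) {
    stop(sprintf("unknown tissue '%s' (not present in annotation)", tissue))
  }
  unannotated <- setdiff(colnames(m), annotation$model_id)
  if (length(unannotated) > 0) {
    warning(sprintf("%d model(s) in the matrix are missing from the annotation and were dropped: %s",
                    length(unannotated),
                    paste(utils::head(unannotated, 5), collapse = ", ")))
  }
  wanted <- annotation$model_id[annotation$tissue == tissue]
  keep <- colnames(m) %in% wanted
  if (!any(keep)) {
    stop(sprintf("no model in the matrix is annotated with tissue '%s'", tissue))
  }
  m[, keep, drop = FALSE]
}

#' Read a gene set from plain text
#'
#' One symbol per line; duplicates are removed (original and de-duplicated
#' counts are reported).
#'
#' @param path Path to the gene-list file.
#' @param header Logical; drop the first line as a header (default `FALSE`).
#' @return Character vector of unique gene symbols.
#' @export
read_gene_set <- function(path, header = FALSE) {
  if (!file.exists(path)) stop(sprintf("cannot read '%s': file does not exist", path))
  lines <- trimws(readLines(path, warn = FALSE))
  if (header && length(lines) > 0) lines <- lines[-1]
  lines <- lines[lines != ""]
  if (length(lines) == 0) stop(sprintf("empty gene set file '%s'", path))
  members <- unique(lines)
  if (length(members) < length(lines)) {
    message(sprintf("gene set '%s': %d symbols, %d after de-duplication",
                    basename(path), length(lines), length(members)))
  }
  members
}

#' Write a gene set as plain text, one symbol per line
#'
#' @param genes Character vector of gene symbols.
#' @param path Output path.
#' @export
write_gene_set <- function(genes, path) {
  assert_gene_set(genes)
  writeLines(genes, path)
  invisible(path)
}

#' Write a dependency matrix as delimited text
#'
#' Inverse of [read_quantitative_matrix()] / [read_binary_matrix()]: one
#' gene-id column followed by one column per model.
#'
#' @param m Dependency matrix (binary or quantitative).
#' @param path Output path.
#' @param delimiter Field delimiter (default `","`).
#' @param gene_column Name for the gene-id column (default `"gene"`).
#' @export
write_dependency_matrix <- function(m, path, delimiter = ",", gene_column = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df)[1] <- gene_column
  data.table::fwrite(df, path, sep = delimiter)
  invisible(path)
}

#' Download a dependency dataset to a local cache
#'
#' Thin convenience fetcher for public dependency-matrix releases; it simply
#' downloads `url` into `destdir` unless the file is already cached. Requires
#' network access and is never needed for the package's own analyses or tests.
#'
#' @param url URL of the file to download.
#' @param destdir Local cache directory (created if missing).
#' @param overwrite Re-download even if the cached file exists.
#' @return Path to the cached file.
#' @export
fetch_dependency_data <- function(url, destdir = "depmap-cache", overwrite = FALSE) {
  if (!dir.exists(destdir)) dir.create(destdir, recursive = TRUE)
  dest <- file.path(destdir, basename(url))
  if (overwrite || !file.exists(dest)) {
    utils::download.file(url, dest, mode = "wb")
  }
  dest
}
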