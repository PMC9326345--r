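# Readers and writers for the plain-text interchange formats: TSV
# matrices (genes x samples and proportion tables), GMT gene sets, and
# MTX + sidecar TSVs for single-cell references.

#' Read a genes x samples expression matrix from TSV
#'
#' Expected layout: header row of sample ids, first column gene ids,
#' tab-separated numeric cells. Ragged rows and non-numeric cells raise a
#' parse error citing the 1-based file line; duplicated gene ids are
#' collapsed by mean with a warning.
#'
#' @param path file path
#' @return numeric matrix with gene rownames and sample colnames
#' @export
read_expression_tsv <- function(path) {
  lines <- readLines(path)
  .assert(length(lines) >= 2, "expression TSV needs a header and data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  samples <- header[-1]
  parts <- strsplit(lines[-1], "\t", fixed = TRUE)
  widths <- lengths(parts)
  bad <- which(widths != length(header))
  if (length(bad) > 0) {
    stop(sprintf("ragged row at line %d (%d fields, expected %d)",
                 bad[1] + 1L, widths[bad[1]], length(header)))
  }
  ids <- vapply(parts, `[[`, character(1), 1)
  cells <- matrix(unlist(lapply(parts, `[`, -1)), nrow = length(parts),
                  byrow = TRUE)
  values <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(values)) {
    bad_cell <- which(is.na(values) & cells != "NA", arr.ind = TRUE)
    if (nrow(bad_cell) > 0) {
      stop(sprintf("non-numeric cell '%s' at line %d",
                   cells[bad_cell[1, , drop = FALSE]], bad_cell[1, 1] + 1L))
    }
  }
  rownames(values) <- ids
  colnames(values) <- samples
  if (anyDuplicated(ids)) {
    warning("duplicated gene ids collapsed by mean")
    values <- rowsum(values, ids) / as.vector(table(ids)[sort(unique(ids))])
  }
  values
}

#' Write a genes x samples matrix to TSV
#'
#' @param mat matrix with gene rownames and sample colnames
#' @param path output path
#' @param id_column name of the first (gene id) column
#' @export
write_expression_tsv <- function(mat, path, id_column = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a proportion table from TSV (first column sample id)
#'
#' @param path file path
#' @param method method name to record on the table
#' @return a [proportion_table()]
#' @export
read_proportions_tsv <- function(path, method = "file") {
  m <- read_expression_tsv(path)
  drift <- max(abs(rowSums(m) - 1))
  if (drift > 1e-6) {
    warning(sprintf("proportion rows deviate from the simplex by up to %.2g; renormalized",
                    drift))
  }
  proportion_table(m / rowSums(m), method = method)
}

#' Write a proportion table to TSV
#'
#' @param props a [proportion_table()]
#' @param path output path
#' @export
write_proportions_tsv <- function(props, path) {
  write_expression_tsv(unclass(props), path, id_column = "sample_id")
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene ids. Lines with fewer than three fields raise an error with
#' the line number; duplicated genes within a set are removed with a
#' warning; an empty file yields an empty list with a warning.
#'
#' @param path file path
#' @return named list of [gene_set()] objects
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    warning("empty GMT file")
    return(list())
  }
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop(sprintf("GMT line %d has %d field(s); need name, description and >= 1 gene",
                   i, length(fields)))
    }
    sets[[fields[1]]] <- gene_set(fields[1], fields[-(1:2)],
                                  description = fields[2])
  }
  sets
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of [gene_set()]s or gene-id vectors
#' @param path output path
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm) {
    s <- gene_sets[[nm]]
    genes <- if (inherits(s, "gene_set")) s$genes else s
    desc <- if (inherits(s, "gene_set")) s$description else ""
    if (!nzchar(desc)) desc <- "na"
    paste(c(nm, desc, genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a single-cell reference as MTX plus sidecar TSVs
#'
#' Emits `counts.mtx` (coordinate MatrixMarket, genes x cells),
#' `genes.tsv` and `cells.tsv` (cell id + cell type label).
#'
#' @param ref an `sc_reference`
#' @param dir output directory (created if missing)
#' @export
write_reference_mtx <- function(ref, dir) {
  stopifnot(inherits(ref, "sc_reference"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- Matrix::Matrix(t(ref$counts), sparse = TRUE)   # genes x cells
  Matrix::writeMM(m, file.path(dir, "counts.mtx"))
  writeLines(ref$gene_ids, file.path(dir, "genes.tsv"))
  utils::write.table(
    data.frame(cell_id = rownames(ref$counts), cell_type = ref$cell_types),
    file.path(dir, "cells.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a single-cell reference written by [write_reference_mtx()]
#'
#' @param dir directory containing `counts.mtx`, `genes.tsv`, `cells.tsv`
#' @return an `sc_reference`
#' @export
read_reference_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "counts.mtx")))
  genes <- readLines(file.path(dir, "genes.tsv"))
  cells <- utils::read.table(file.path(dir, "cells.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  counts <- t(m)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(cells$cell_id, genes)
  .assert(all(counts >= 0), "reference counts must be non-negative")
  .assert(!anyDuplicated(genes), "gene ids must be unique")
  structure(list(counts = counts, cell_types = cells$cell_type,
                 gene_ids = genes), class = "sc_reference")
}

#' Write a signature matrix to TSV
#'
#' Layout: first column gene id, header of cell-type names, plus trailing
#' `logFC` and `top_type` columns so the file round-trips including the
#' metadata needed for fraction subsetting.
#'
#' @param sig a `signature_matrix`
#' @param path output path
#' @export
write_signature_tsv <- function(sig, path) {
  df <- data.frame(gene_id = sig$gene_ids, sig$values,
                   logFC = sig$logfc, top_type = sig$top_type,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a signature matrix written by [write_signature_tsv()]
#'
#' @param path file path
#' @return a `signature_matrix`
#' @export
read_signature_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("gene_id", "logFC", "top_type")
  types <- setdiff(colnames(df), meta)
  values <- as.matrix(df[, types, drop = FALSE])
  rownames(values) <- df$gene_id
  structure(list(values = values, gene_ids = df$gene_id, cell_types = types,
                 logfc = stats::setNames(df$logFC, df$gene_id),
                 top_type = stats::setNames(df$top_type, df$gene_id)),
            class = "signature_matrix")
}
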