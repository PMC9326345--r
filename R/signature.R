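# Signature-matrix construction from a labeled single-cell reference:
# per-gene marker statistics, threshold-based marker selection, the
# correlation-inflection rule for the cell-type-exclusivity (SecondFC)
# cutoff, and logFC-ranked fraction subsetting.

#' Per-gene marker statistics from a single-cell reference
#'
#' For each gene, with per-type mean CPM profiles m_t and pseudocount 1:
#' `logFC` is the log2 fold change of the highest-expressing type over the
#' mean of the remaining types; `SecondFC` is the linear fold change of the
#' highest over the second-highest type; `logCPM` is log2 of the mean
#' expression across types; `frac_expressed_in_top` is the fraction of
#' cells of the top type with a non-zero count.
#'
#' @param ref an `sc_reference`
#' @return data.frame (class `marker_stats`) with columns `gene_id`,
#'   `logFC`, `logCPM`, `SecondFC`, `top_type`, `frac_expressed_in_top`
#' @export
compute_marker_stats <- function(ref) {
  stopifnot(inherits(ref, "sc_reference"))
  M <- celltype_mean_cpm(ref)
  K <- ncol(M)
  if (K < 2) stop("marker statistics need at least two cell types")
  top <- max.col(M, ties.method = "first")
  idx <- cbind(seq_len(nrow(M)), top)
  m1 <- M[idx]
  M2 <- M
  M2[idx] <- -Inf
  m2 <- apply(M2, 1, max)
  mean_others <- (rowSums(M) - m1) / (K - 1)
  eps <- 1
  stats_df <- data.frame(
    gene_id = rownames(M),
    logFC = log2((m1 + eps) / (mean_others + eps)),
    logCPM = log2(rowMeans(M) + eps),
    SecondFC = (m1 + eps) / (m2 + eps),
    top_type = colnames(M)[top],
    stringsAsFactors = FALSE
  )
  expressed <- vapply(colnames(M), function(t) {
    colMeans(ref$counts[ref$cell_types == t, , drop = FALSE] > 0)
  }, numeric(nrow(M)))
  stats_df$frac_expressed_in_top <- expressed[idx]
  rownames(stats_df) <- stats_df$gene_id
  class(stats_df) <- c("marker_stats", "data.frame")
  stats_df
}

#' Select marker genes by the four-threshold rule
#'
#' A gene is kept iff `logFC >= logfc_min`, `logCPM >= logcpm_min`,
#' `SecondFC >= secondfc_min` and `frac_expressed_in_top >=
#' min_frac_expressed`; it is assigned to its highest-expressing type.
#'
#' @param stats a [compute_marker_stats()] result
#' @param logfc_min,logcpm_min,secondfc_min,min_frac_expressed thresholds
#' @return named list of marker gene-id vectors per cell type (types with
#'   zero survivors are kept as empty entries with a warning); error if all
#'   types come out empty
#' @export
select_markers <- function(stats, logfc_min = 1, logcpm_min = 1,
                           secondfc_min = 1.5, min_frac_expressed = 0.30) {
  stopifnot(inherits(stats, "marker_stats"))
  keep <- stats$logFC >= logfc_min & stats$logCPM >= logcpm_min &
    stats$SecondFC >= secondfc_min &
    stats$frac_expressed_in_top >= min_frac_expressed
  types <- sort(unique(stats$top_type))
  sel <- lapply(types, function(t) stats$gene_id[keep & stats$top_type == t])
  names(sel) <- types
  empty <- types[lengths(sel) == 0]
  if (length(empty) == length(types)) {
    stop("no marker gene survives the thresholds for any cell type")
  }
  if (length(empty) > 0) {
    warning("no markers selected for cell type(s): ",
            paste(empty, collapse = ", "))
  }
  sel
}

#' Build a signature matrix from selected markers
#'
#' Entry (g, t) is the mean CPM of gene g over the cells of type t,
#' restricted to the selected marker genes.
#'
#' @param ref an `sc_reference`
#' @param markers named list of marker gene ids per cell type (from
#'   [select_markers()]) or a plain character vector
#' @param stats optional precomputed [compute_marker_stats()] (recomputed
#'   when missing; per-gene logFC is carried for fraction subsetting)
#' @return object of class `signature_matrix`: list with `values`
#'   (markers x types matrix), `gene_ids`, `cell_types`, `logfc` and
#'   `top_type` (named by gene)
#' @export
build_signature <- function(ref, markers, stats = NULL) {
  stopifnot(inherits(ref, "sc_reference"))
  if (is.list(markers)) {
    genes <- unique(unlist(markers, use.names = FALSE))
    assign_type <- rep(names(markers), lengths(markers))
    names(assign_type) <- unlist(markers, use.names = FALSE)
  } else {
    genes <- unique(as.character(markers))
    assign_type <- NULL
  }
  if (length(genes) == 0) stop("marker list is empty")
  missing <- setdiff(genes, ref$gene_ids)
  if (length(missing) > 0) {
    stop("marker gene(s) absent from the reference: ",
         paste(missing, collapse = ", "))
  }
  if (is.null(stats)) stats <- compute_marker_stats(ref)
  M <- celltype_mean_cpm(ref)
  values <- M[genes, , drop = FALSE]
  if (is.null(assign_type)) {
    assign_type <- stats::setNames(stats[genes, "top_type"], genes)
  }
  structure(list(values = values, gene_ids = genes,
                 cell_types = colnames(values),
                 logfc = stats::setNames(stats[genes, "logFC"], genes),
                 top_type = assign_type[genes]),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("signature matrix: %d marker genes x %d cell types\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Mean pairwise Pearson correlation between signature columns
#'
#' Pairs involving a constant (zero-variance) column are undefined and
#' excluded; if every pair is undefined an error is raised.
#'
#' @param sig a `signature_matrix`
#' @return mean correlation over defined unordered column pairs
#' @export
avg_celltype_correlation <- function(sig) {
  stopifnot(inherits(sig, "signature_matrix"))
  V <- sig$values
  if (ncol(V) < 2 || nrow(V) < 2) stop("need >= 2 cell types and >= 2 genes")
  sds <- apply(V, 2, stats::sd)
  ok <- which(sds > 0)
  if (length(ok) < 2) stop("all column pairs have undefined correlation")
  cm <- stats::cor(V[, ok, drop = FALSE])
  mean(cm[upper.tri(cm)])
}

#' Choose the SecondFC threshold by the correlation-plateau rule
#'
#' For each candidate threshold, markers are selected and the average
#' between-type correlation of the resulting signature computed. As the
#' threshold rises the signature columns decorrelate; the chosen threshold
#' is the smallest candidate whose forward decrease to the next candidate
#' falls below `plateau_tol` (the curve's inflection into its plateau),
#' falling back to the last candidate when the curve stays steep. A
#' candidate that empties the marker set truncates the scan with a warning.
#'
#' @param ref an `sc_reference`
#' @param candidate_thresholds increasing SecondFC candidates (>= 3)
#' @param plateau_tol plateau tolerance on the forward decrease
#' @param logfc_min,logcpm_min,min_frac_expressed the other selection
#'   thresholds, held fixed during the scan
#' @return object of class `threshold_scan`: list with `thresholds`,
#'   `avg_correlation` and `chosen_threshold`
#' @export
choose_secondfc_threshold <- function(ref, candidate_thresholds = seq(1, 8, by = 0.5),
                                      plateau_tol = 0.05, logfc_min = 1,
                                      logcpm_min = 1, min_frac_expressed = 0.30) {
  .assert(length(candidate_thresholds) >= 3, "need at least three candidates")
  .assert(!is.unsorted(candidate_thresholds, strictly = TRUE),
          "candidates must be strictly increasing")
  stats <- compute_marker_stats(ref)
  cors <- numeric(0)
  used <- numeric(0)
  for (th in candidate_thresholds) {
    sel <- tryCatch(
      suppressWarnings(select_markers(stats, logfc_min, logcpm_min, th,
                                      min_frac_expressed)),
      error = function(e) NULL)
    if (is.null(sel) || sum(lengths(sel)) < 2) {
      warning(sprintf("scan truncated at SecondFC = %g (marker set emptied)", th))
      break
    }
    sig <- build_signature(ref, sel, stats = stats)
    cors <- c(cors, avg_celltype_correlation(sig))
    used <- c(used, th)
  }
  if (length(used) == 0) stop("no candidate threshold yields a usable signature")
  chosen <- used[length(used)]
  if (length(used) >= 2) {
    dec <- cors[-length(cors)] - cors[-1]
    hit <- which(dec < plateau_tol)
    if (length(hit) > 0) chosen <- used[hit[1]]
  }
  structure(list(thresholds = used, avg_correlation = cors,
                 chosen_threshold = chosen),
            class = "threshold_scan")
}

#' Keep the top logFC-ranked fraction of markers, per cell type
#'
#' Within each cell type, `ceil(fraction * n_markers)` genes of highest
#' logFC are kept (ties broken by gene id, lexicographic), so every type
#' retains at least one marker; the matrix is rebuilt on the union.
#'
#' @param sig a `signature_matrix`
#' @param fraction value in (0, 1]
#' @return the subsetted `signature_matrix`
#' @export
subset_top_fraction <- function(sig, fraction) {
  stopifnot(inherits(sig, "signature_matrix"))
  .assert(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  keep <- unlist(lapply(unique(sig$top_type), function(t) {
    genes <- names(sig$top_type)[sig$top_type == t]
    o <- order(-sig$logfc[genes], genes)
    genes[o][seq_len(ceiling(fraction * length(genes)))]
  }), use.names = FALSE)
  keep <- sig$gene_ids[sig$gene_ids %in% keep]   # preserve original order
  structure(list(values = sig$values[keep, , drop = FALSE], gene_ids = keep,
                 cell_types = sig$cell_types, logfc = sig$logfc[keep],
                 top_type = sig$top_type[keep]),
            class = "signature_matrix")
}
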