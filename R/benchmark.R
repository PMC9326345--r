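# Evaluation framework for deconvolution: correlation with true
# proportions (PCC_P), reconstruction correlations on the fraction and the
# full signature (PCC_T1 / PCC_T2), marker-fraction scans, and
# average-rank stability across benchmark tests.

#' Pearson correlation between estimated and true proportions (PCC_P)
#'
#' Tables are aligned by sample and cell-type id and the correlation is
#' computed over all flattened entries. Per-cell-type correlations are
#' attached as attribute `per_type` for diagnostics.
#'
#' @param estimated,truth [proportion_table()] objects with matching ids
#' @return correlation in [-1, 1]
#' @export
pcc_proportions <- function(estimated, truth) {
  .assert(setequal(rownames(estimated), rownames(truth)),
          "sample ids of the two tables differ")
  .assert(setequal(colnames(estimated), colnames(truth)),
          "cell-type ids of the two tables differ")
  E <- unclass(estimated)[rownames(truth), colnames(truth), drop = FALSE]
  Tm <- unclass(truth)
  if (stats::sd(Tm) == 0) stop("true proportions are constant; PCC_P undefined")
  if (stats::sd(E) == 0) stop("estimated proportions are constant; PCC_P undefined")
  r <- stats::cor(as.vector(E), as.vector(Tm))
  per_type <- vapply(colnames(Tm), function(t) {
    if (stats::sd(Tm[, t]) == 0 || stats::sd(E[, t]) == 0) NA_real_
    else stats::cor(E[, t], Tm[, t])
  }, numeric(1))
  attr(r, "per_type") <- per_type
  r
}

#' Reconstruction correlation between predicted and observed bulk (PCC_T)
#'
#' Predicts bulk expression as T-hat = C P' on the chosen signature's genes
#' and correlates it with the observed bulk restricted to those genes.
#' Mode `"T1"` uses the fraction-restricted signature actually used for
#' deconvolution; mode `"T2"` uses the full-marker signature. The default
#' statistic is the per-sample correlation averaged over samples; set
#' `flatten = TRUE` for a single correlation over all entries.
#'
#' @param sig_used fraction-restricted `signature_matrix`
#' @param sig_full full-marker `signature_matrix`
#' @param estimated a [proportion_table()]
#' @param bulk genes x samples matrix
#' @param mode `"T1"` or `"T2"`
#' @param flatten compute one flattened correlation instead of a
#'   per-sample mean
#' @return correlation in [-1, 1]
#' @export
pcc_transcripts <- function(sig_used, sig_full, estimated, bulk,
                            mode = c("T1", "T2"), flatten = FALSE) {
  mode <- match.arg(mode)
  sig <- if (mode == "T1") sig_used else sig_full
  stopifnot(inherits(sig, "signature_matrix"))
  missing <- setdiff(sig$gene_ids, rownames(bulk))
  if (length(missing) > 0) {
    stop("bulk is missing signature gene(s): ", paste(missing, collapse = ", "))
  }
  P <- unclass(estimated)[colnames(bulk), sig$cell_types, drop = FALSE]
  That <- sig$values %*% t(P)
  Obs <- bulk[sig$gene_ids, , drop = FALSE]
  if (flatten) return(stats::cor(as.vector(That), as.vector(Obs)))
  mean(vapply(seq_len(ncol(Obs)), function(s) stats::cor(That[, s], Obs[, s]),
              numeric(1)))
}

#' Marker-fraction benchmark scan
#'
#' For each method and each top-logFC marker fraction: subset the full
#' signature, deconvolve the cohort, and record PCC_P, PCC_T1 (fraction
#' signature) and PCC_T2 (full signature). A failed (method, fraction)
#' cell is recorded as NA with a warning, never fabricated.
#'
#' @param ref an `sc_reference` used to build the full signature
#' @param bulk genes x samples matrix
#' @param truth true [proportion_table()]
#' @param methods character vector of solver names
#' @param fractions marker fractions in (0, 1]
#' @param test label stored in the `test` column (for multi-test ranking)
#' @param secondfc_min,logfc_min,logcpm_min,min_frac_expressed marker
#'   selection thresholds for the full signature
#' @return data.frame (class `benchmark_records`) with columns `test`,
#'   `method`, `fraction`, `pcc_p`, `pcc_t1`, `pcc_t2`
#' @export
run_fraction_scan <- function(ref, bulk, truth,
                              methods = c("nnls", "ols", "rlr", "nusvr"),
                              fractions = seq(0.05, 1, by = 0.05),
                              test = "test1", secondfc_min = 1.5,
                              logfc_min = 1, logcpm_min = 1,
                              min_frac_expressed = 0.30) {
  .assert(all(fractions > 0 & fractions <= 1), "fractions must lie in (0,1]")
  stats_df <- compute_marker_stats(ref)
  sel <- select_markers(stats_df, logfc_min, logcpm_min, secondfc_min,
                        min_frac_expressed)
  sig_full <- build_signature(ref, sel, stats = stats_df)
  rows <- list()
  for (f in fractions) {
    sig_f <- subset_top_fraction(sig_full, f)
    for (m in methods) {
      rec <- tryCatch({
        est <- deconvolve_cohort(sig_f, bulk, m)
        c(pcc_p = as.numeric(pcc_proportions(est, truth)),
          pcc_t1 = pcc_transcripts(sig_f, sig_full, est, bulk, "T1"),
          pcc_t2 = pcc_transcripts(sig_f, sig_full, est, bulk, "T2"))
      }, error = function(e) {
        warning(sprintf("scan cell (%s, %.2f) failed: %s", m, f,
                        conditionMessage(e)))
        c(pcc_p = NA_real_, pcc_t1 = NA_real_, pcc_t2 = NA_real_)
      })
      rows[[length(rows) + 1]] <- data.frame(
        test = test, method = m, fraction = f,
        pcc_p = rec[["pcc_p"]], pcc_t1 = rec[["pcc_t1"]],
        pcc_t2 = rec[["pcc_t2"]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("benchmark_records", "data.frame")
  out
}

#' Average-rank stability of methods over a fraction window
#'
#' Within every (test, fraction) cell of the window, methods are ranked by
#' descending PCC_P (rank 1 = best, ties share the mean rank); each
#' method's ranks are averaged over cells.
#'
#' @param records a [run_fraction_scan()] result (or any data.frame with
#'   columns `test`, `method`, `fraction`, `pcc_p`)
#' @param fraction_window inclusive `[low, high]` window on the fraction
#' @return list with `ranks` (long data.frame of per-cell ranks) and
#'   `average_rank` (named numeric, ascending = better)
#' @export
rank_methods <- function(records, fraction_window = c(0.25, 1.0)) {
  df <- records[records$fraction >= fraction_window[1] &
                  records$fraction <= fraction_window[2], , drop = FALSE]
  if (nrow(df) == 0) stop("no records inside the fraction window")
  methods <- sort(unique(df$method))
  cells <- unique(df[, c("test", "fraction")])
  rank_rows <- list()
  for (i in seq_len(nrow(cells))) {
    sub <- df[df$test == cells$test[i] & df$fraction == cells$fraction[i], ]
    missing <- setdiff(methods, sub$method)
    if (length(missing) > 0 || anyNA(sub$pcc_p)) {
      bad <- union(missing, sub$method[is.na(sub$pcc_p)])
      stop(sprintf("missing PCC_P for method(s) %s at (test=%s, fraction=%g)",
                   paste(bad, collapse = ", "), cells$test[i], cells$fraction[i]))
    }
    r <- rank(-sub$pcc_p, ties.method = "average")
    rank_rows[[i]] <- data.frame(test = cells$test[i],
                                 fraction = cells$fraction[i],
                                 method = sub$method, rank = r,
                                 stringsAsFactors = FALSE)
  }
  ranks <- do.call(rbind, rank_rows)
  avg <- tapply(ranks$rank, ranks$method, mean)
  avg <- stats::setNames(as.numeric(avg), names(avg))
  list(ranks = ranks, average_rank = avg[order(avg)])
}
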