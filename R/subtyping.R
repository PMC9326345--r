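# Unsupervised subtype discovery: binned mean-dispersion HVG selection,
# NMF consensus clustering with cophenetic-coefficient rank selection,
# and integrated multi-cell-type profiles.

#' Select highly variable genes by binned mean-dispersion statistics
#'
#' Per gene, mean and dispersion (variance / mean) of the log1p values are
#' computed; genes are cut into `n_bins` equal-frequency bins by mean and
#' the dispersion z-scored within each bin. Kept genes satisfy
#' `mean > mean_cutoff` and scaled dispersion `> dispersion_cutoff`.
#'
#' @param expr genes x samples matrix (linear scale; log1p applied
#'   internally)
#' @param mean_cutoff,dispersion_cutoff,n_bins selection parameters
#' @return character vector of gene ids; attribute `stats` carries the
#'   per-gene mean / dispersion table
#' @export
select_hvgs <- function(expr, mean_cutoff = 0.5, dispersion_cutoff = 1,
                        n_bins = 20) {
  .assert(n_bins >= 2, "n_bins must be >= 2")
  expr <- as.matrix(expr)
  L <- log1p(expr)
  mu <- rowMeans(L)
  v <- rowSums((L - mu)^2) / (ncol(L) - 1)
  ok <- v > 0 & mu > 0
  if (sum(ok) < n_bins) stop("too few genes with non-zero variance")
  disp <- ifelse(ok, v / mu, NA_real_)
  z <- rep(NA_real_, length(mu))
  r <- rank(mu[ok], ties.method = "first")
  bin <- ceiling(r / (sum(ok) / n_bins))
  zo <- disp[ok]
  for (b in unique(bin)) {
    ix <- bin == b
    s <- stats::sd(zo[ix])
    z[which(ok)[ix]] <- if (!is.finite(s) || s == 0) 0 else
      (zo[ix] - mean(zo[ix])) / s
  }
  keep <- which(ok & mu > mean_cutoff & z > dispersion_cutoff)
  if (length(keep) == 0) {
    stop("no highly variable gene selected; lower the cutoffs")
  }
  out <- rownames(expr)[keep]
  attr(out, "stats") <- data.frame(gene = rownames(expr), mean = mu,
                                   dispersion = disp, scaled_dispersion = z,
                                   row.names = NULL)
  out
}

# one multiplicative-update Frobenius NMF run
.nmf_once <- function(X, k, max_iter = 2000, tol = 1e-5) {
  f <- nrow(X); s <- ncol(X)
  eps <- 1e-9
  W <- matrix(stats::runif(f * k, 0.1, 1), f, k)
  H <- matrix(stats::runif(k * s, 0.1, 1), k, s)
  obj_prev <- Inf
  converged <- FALSE
  for (i in seq_len(max_iter)) {
    H <- H * (crossprod(W, X)) / (crossprod(W) %*% H + eps)
    W <- W * (X %*% t(H)) / (W %*% tcrossprod(H) + eps)
    if (i %% 10 == 0 || i == max_iter) {
      obj <- sum((X - W %*% H)^2)
      # tol is a per-iteration relative decrease; the objective is only
      # evaluated every 10 iterations
      if (is.finite(obj_prev) &&
          abs(obj_prev - obj) <= 10 * tol * max(obj_prev, eps)) {
        converged <- TRUE
        break
      }
      obj_prev <- obj
    }
  }
  list(labels = max.col(t(H), ties.method = "first"), converged = converged)
}

#' NMF consensus clustering
#'
#' Runs `n_runs` multiplicative-update Frobenius NMF factorizations with
#' seeded random non-negative initializations; per run, each sample is
#' assigned to the coefficient row with the largest loading. Run-wise
#' connectivity matrices are averaged into a consensus matrix; final
#' labels come from average-linkage hierarchical clustering of
#' 1 - consensus cut at k, and the cophenetic coefficient is the Pearson
#' correlation between the consensus distances and the dendrogram's
#' cophenetic distances. Rows with negative entries (z-scored input) are
#' shifted by their minimum to zero before factorization.
#'
#' @param expr_scaled features x samples matrix
#' @param k number of clusters (2 <= k < n_samples)
#' @param n_runs factorization restarts
#' @param seed RNG seed
#' @param max_iter,tol multiplicative-update stopping rule; runs that do
#'   not converge are discarded with a warning (error if more than half)
#' @return object of class `consensus_result`: list with `k`, `consensus`,
#'   `cophenetic_cc`, `labels`, `n_runs`, `n_converged`, `seed`
#' @export
nmf_consensus <- function(expr_scaled, k, n_runs = 30, seed = 1,
                          max_iter = 2000, tol = 1e-5) {
  X <- as.matrix(expr_scaled)
  .assert(k >= 2 && k < ncol(X), "need 2 <= k < number of samples")
  if (any(X < 0)) {
    X <- X - apply(X, 1, min)   # per-feature min-shift to non-negativity
  }
  S <- ncol(X)
  set.seed(seed)
  consensus <- matrix(0, S, S)
  n_ok <- 0L
  for (r in seq_len(n_runs)) {
    run <- .nmf_once(X, k, max_iter, tol)
    if (!run$converged) {
      warning(sprintf("NMF run %d did not converge; discarded", r))
      next
    }
    conn <- outer(run$labels, run$labels, "==") * 1
    consensus <- consensus + conn
    n_ok <- n_ok + 1L
  }
  if (n_ok < n_runs / 2) stop("more than half of the NMF runs failed to converge")
  consensus <- consensus / n_ok
  dimnames(consensus) <- list(colnames(X), colnames(X))
  d <- stats::as.dist(1 - consensus)
  hc <- stats::hclust(d, method = "average")
  labels <- stats::cutree(hc, k = k)
  cc <- if (stats::sd(d) == 0) {
    warning("consensus distances are constant; cophenetic coefficient undefined")
    NA_real_
  } else {
    stats::cor(d, stats::cophenetic(hc))
  }
  structure(list(k = k, consensus = consensus, cophenetic_cc = cc,
                 labels = labels, n_runs = n_runs, n_converged = n_ok,
                 seed = seed),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("NMF consensus: k = %d, cophenetic = %.4f (%d/%d runs)\n",
              x$k, x$cophenetic_cc, x$n_converged, x$n_runs))
  invisible(x)
}

#' Choose the number of clusters from the cophenetic curve
#'
#' The cophenetic coefficient typically stays flat from k = 2 and then
#' drops; the chosen k is the largest one reached before the drop, i.e.
#' the largest k such that every cc(j), j <= k, stays within `drop_tol`
#' of cc at the smallest k. If the curve never drops the maximum of the
#' range is returned with a warning.
#'
#' @param cc_by_k named numeric vector of cophenetic coefficients, names
#'   are the (contiguous) k values
#' @param drop_tol tolerated decrease relative to the first k
#' @return chosen k (integer)
#' @export
choose_k <- function(cc_by_k, drop_tol = 0.05) {
  .assert(length(cc_by_k) > 0, "empty cophenetic map")
  ks <- as.integer(names(cc_by_k))
  .assert(!anyNA(ks), "names of cc_by_k must be the k values")
  o <- order(ks)
  ks <- ks[o]; cc <- as.numeric(cc_by_k)[o]
  base <- cc[1]
  ok <- cumsum(cc < base - drop_tol) == 0
  if (all(ok)) {
    warning("cophenetic coefficient never drops; returning the largest k")
    return(ks[length(ks)])
  }
  ks[max(which(ok))]
}

#' Integrated multi-cell-type expression profile
#'
#' For every requested cell type, highly variable genes are selected from
#' its genes x samples slice of the cube; the slices are concatenated as
#' feature rows (ids namespaced `celltype:gene`) and each feature row is
#' z-scored. Cell types contributing no HVGs are omitted with a warning.
#' Genes carrying missing values in a slice are dropped from that slice.
#'
#' @param cube a `celltype_cube` (see [impute_celltype_expression()])
#' @param cell_types cell types to integrate
#' @param mean_cutoff,dispersion_cutoff,n_bins passed to [select_hvgs()]
#' @return features x samples matrix of z-scored expression
#' @export
build_integrated_profile <- function(cube, cell_types, mean_cutoff = 0.5,
                                     dispersion_cutoff = 1, n_bins = 20) {
  stopifnot(inherits(cube, "celltype_cube"))
  .assert(all(cell_types %in% dimnames(cube)[[2]]),
          "requested cell type absent from the cube")
  blocks <- list()
  for (t in cell_types) {
    slice <- cube[, t, ]
    complete <- stats::complete.cases(slice)
    slice <- slice[complete, , drop = FALSE]
    hvg <- tryCatch(
      select_hvgs(slice, mean_cutoff, dispersion_cutoff, n_bins),
      error = function(e) character(0))
    if (length(hvg) == 0) {
      warning(sprintf("cell type '%s' contributes no HVGs; omitted", t))
      next
    }
    block <- log1p(slice[hvg, , drop = FALSE])
    mu <- rowMeans(block)
    sdv <- apply(block, 1, stats::sd)
    keep <- sdv > 0
    block <- (block[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
    rownames(block) <- paste(t, hvg[keep], sep = ":")
    blocks[[t]] <- block
  }
  if (length(blocks) == 0) stop("no cell type contributed any HVG")
  do.call(rbind, blocks)
}

#' Scan dispersion cutoffs for the most stable clustering
#'
#' Rebuilds the integrated profile for each dispersion cutoff, scans k
#' over `k_range`, picks k by [choose_k()], and keeps the cutoff whose
#' chosen-k cophenetic coefficient is largest (ties broken toward the
#' larger cutoff, i.e. fewer features).
#'
#' @param cube a `celltype_cube`
#' @param cell_types cell types to integrate
#' @param cutoffs dispersion cutoffs to try
#' @param k_range contiguous candidate k values
#' @param n_runs,seed,drop_tol passed to [nmf_consensus()] / [choose_k()]
#' @param mean_cutoff,n_bins passed to [select_hvgs()]
#' @return list with `best_cutoff`, `best_k`, `best_cc` and the full
#'   `scan` data.frame
#' @export
tune_dispersion_cutoff <- function(cube, cell_types,
                                   cutoffs = seq(1, 2.5, by = 0.1),
                                   k_range = 2:6, n_runs = 20, seed = 1,
                                   drop_tol = 0.05, mean_cutoff = 0.5,
                                   n_bins = 20) {
  rows <- list()
  for (cut in cutoffs) {
    prof <- tryCatch(
      suppressWarnings(build_integrated_profile(cube, cell_types, mean_cutoff,
                                                cut, n_bins)),
      error = function(e) NULL)
    if (is.null(prof) || nrow(prof) < 2) next
    cc <- vapply(k_range, function(k) {
      nmf_consensus(prof, k, n_runs = n_runs, seed = seed)$cophenetic_cc
    }, numeric(1))
    names(cc) <- k_range
    k_star <- choose_k(cc, drop_tol)
    rows[[length(rows) + 1]] <- data.frame(
      cutoff = cut, k = k_star, cc = cc[[as.character(k_star)]],
      n_features = nrow(prof))
  }
  if (length(rows) == 0) stop("no cutoff yields a usable profile")
  scan <- do.call(rbind, rows)
  best <- scan[order(-scan$cc, -scan$cutoff), ][1, ]
  list(best_cutoff = best$cutoff, best_k = best$k, best_cc = best$cc,
       scan = scan)
}
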