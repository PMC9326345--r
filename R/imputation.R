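# Per-sample, per-cell-type expression imputation from bulk profiles and
# estimated proportions, with marker-enrichment validation. The two-stage
# surrogate is exactly testable: a cohort-level non-negative regression
# gives per-type baseline profiles, and each sample's residual is
# re-allocated to cell types where the fitted signal sits, so the
# proportion-weighted sum of the imputed profiles reproduces the bulk
# value wherever no clipping or missingness was triggered.

#' Impute per-sample cell-type-level expression
#'
#' Stage 1 fits, for every gene g, non-negative coefficients
#' \eqn{\beta_{g,t}} of the bulk values on the proportion columns (over
#' samples). Stage 2 allocates each sample's residual
#' \eqn{r_{g,s} = b_{g,s} - \sum_t p_{s,t}\beta_{g,t}} to cell types,
#' \eqn{x_{g,t,s} = \max(0, \beta_{g,t} + r_{g,s} w_{g,t,s} / p_{s,t})}.
#' The allocation weight names, per gene, the cell type whose abundance
#' best explains the absolute log-residual across samples (largest
#' positive correlation, with evidence pooled over modules of genes with
#' correlated residual patterns) and attributes the whole residual to it; genes
#' whose residuals carry no proportion structure fall back to weights
#' proportional to the fitted signal \eqn{p_{s,t}\beta_{g,t}}, and to a
#' uniform split over types with positive proportion when that is zero
#' too. Types with proportion below `min_prop` in a sample are set to
#' missing there (low-abundance profiles are unreliable). By construction
#' \eqn{\sum_t p_{s,t} x_{g,t,s} = b_{g,s}} wherever no clipping or
#' missingness was triggered.
#'
#' The residual-driver attribution is what lets a case-restricted,
#' cell-type-restricted expression shift surface in the correct type:
#' a weight proportional to the fitted signal alone provably spreads any
#' such shift across all types in equal relative measure (see the methods
#' vignette).
#'
#' @param bulk genes x samples matrix
#' @param props a [proportion_table()] with rows matching the bulk samples
#' @param min_prop missingness threshold on the per-sample proportion
#' @param alloc_tmin evidence threshold (t-statistic of the best per-type
#'   correlation) below which a gene's residual is split proportionally
#'   to the fitted signal instead of attributed to a single driver type;
#'   keeps plain-noise genes from becoming spuriously variable in one
#'   arbitrary cell type's profile
#' @return 3-d array (class `celltype_cube`) of genes x cell types x
#'   samples; attribute `beta` holds the stage-1 coefficients and
#'   attribute `alloc` the residual-allocation coefficients
#' @export
impute_celltype_expression <- function(bulk, props, min_prop = 0.005,
                                       allocation = c("driver", "proportional"),
                                       alloc_tmin = 3) {
  allocation = match.arg(allocation)
  bulk <- as.matrix(bulk)
  P <- unclass(props)
  .assert(setequal(colnames(bulk), rownames(P)),
          "bulk samples and proportion rows must match")
  P <- P[colnames(bulk), , drop = FALSE]
  S <- nrow(P); K <- ncol(P); G <- nrow(bulk)
  if (S <= K) {
    stop(sprintf("under-determined stage 1: %d samples for %d cell types", S, K))
  }
  beta <- matrix(0, G, K, dimnames = list(rownames(bulk), colnames(P)))
  alloc <- beta
  resid <- matrix(0, G, S)
  fitted <- matrix(0, G, S)
  for (g in seq_len(G)) {
    beta[g, ] <- nnls_solve(P, bulk[g, ])
    fitted[g, ] <- drop(P %*% beta[g, ])
    resid[g, ] <- bulk[g, ] - fitted[g, ]
  }
  # Which cell type drives each gene's residual? Gene-wise multiplicative
  # noise is homoscedastic on the log scale, so the absolute log-residual
  # of an undistorted gene is flat in the proportions, whereas a cell-type-
  # restricted distortion makes it grow with that type's abundance. Genes
  # are first grouped into modules of correlated residual patterns (a
  # coordinated distortion, e.g. one pathway shifted through one cell
  # type, hits many genes at once) and the evidence is pooled within each
  # module before naming the driver: the strongest positive per-type
  # correlation, attributed winner-take-all because any split allocation
  # leaks a shared, systematically signed component into every other
  # type, which would defeat cell-type-level group comparisons.
  Lsigned <- log(pmax(bulk, 1e-12)) - log(pmax(fitted, 1e-12))
  L <- abs(Lsigned)
  sdl <- apply(L, 1, stats::sd)
  sds <- apply(Lsigned, 1, stats::sd)
  sdp <- apply(P, 2, stats::sd)
  informative <- which(sdl > 0 & sds > 0)
  if (allocation == "driver" && length(informative) > 1 &&
      any(sdp > 0) && S > 2) {
    # modules form on the signed residual pattern (coherent across the
    # genes of one distorted pathway); driver evidence pools the absolute
    # pattern, whose correlation with the driver's abundance survives the
    # sign flip between elevated and depressed samples
    Zs <- Lsigned[informative, , drop = FALSE]
    Zs <- (Zs - rowMeans(Zs)) / sds[informative]
    modules <- stats::cutree(
      stats::hclust(stats::as.dist(1 - stats::cor(t(Zs))), method = "average"),
      h = 0.75)
    Z <- L[informative, , drop = FALSE]
    Z <- (Z - rowMeans(Z)) / sdl[informative]
    Pv <- P[, sdp > 0, drop = FALSE]
    for (m in unique(modules)) {
      rows <- which(modules == m)
      pooled <- colMeans(Z[rows, , drop = FALSE])
      if (stats::sd(pooled) == 0) next
      C <- drop(suppressWarnings(stats::cor(pooled, Pv)))
      C[!is.finite(C)] <- -Inf
      tstat <- C * sqrt(S - 2) / sqrt(pmax(1 - C^2, 1e-12))
      j <- which.max(tstat)
      if (tstat[j] >= alloc_tmin) {
        alloc[informative[rows], match(colnames(Pv)[j], colnames(P))] <- tstat[j]
      }
    }
  }
  cube <- array(NA_real_, dim = c(G, K, S),
                dimnames = list(rownames(bulk), colnames(P), rownames(P)))
  for (s in seq_len(S)) {
    p <- P[s, ]
    signal <- sweep(alloc, 2, p, "*")                  # p_t * a_t
    tot <- rowSums(signal)
    fallback <- tot == 0
    if (any(fallback)) {
      fb <- sweep(beta[fallback, , drop = FALSE], 2, p, "*")
      signal[fallback, ] <- fb
      tot[fallback] <- rowSums(fb)
    }
    W <- signal / ifelse(tot > 0, tot, 1)
    still_zero <- tot == 0
    if (any(still_zero)) {
      pos <- p > 0
      W[still_zero, ] <- matrix(rep(pos / sum(pos), each = sum(still_zero)),
                                nrow = sum(still_zero))
    }
    X <- beta + (resid[, s] * W) / rep(pmax(p, 1e-300), each = G)
    X <- pmax(X, 0)
    X[, p < min_prop] <- NA_real_
    cube[, , s] <- X
  }
  structure(cube, class = "celltype_cube", beta = beta, alloc = alloc,
            min_prop = min_prop)
}

#' Marker-enrichment validation of an imputed cube
#'
#' Profiles are averaged over samples per cell type; for every pair of
#' (imputed profile, marker set) a one-sided rank-sum test asks whether
#' the marker genes sit higher than the remaining genes in that profile.
#' The matrix of -log10 p-values is z-scored by rows (profiles), so a
#' biologically sound cube lights up its diagonal.
#'
#' @param cube a `celltype_cube`
#' @param markers named list of marker gene-id vectors (one per cell type
#'   or any gene sets of interest)
#' @return matrix (class `enrichment_heatmap`) of row-scaled -log10 p,
#'   profiles x marker sets; attribute `raw_p` keeps the unscaled p-values
#' @export
validate_marker_enrichment <- function(cube, markers) {
  stopifnot(inherits(cube, "celltype_cube"))
  .assert(is.list(markers) && length(markers) > 0 && !is.null(names(markers)),
          "markers must be a non-empty named list")
  genes <- dimnames(cube)[[1]]
  for (nm in names(markers)) {
    if (length(intersect(markers[[nm]], genes)) == 0) {
      stop(sprintf("marker set '%s' shares no genes with the cube", nm))
    }
  }
  avg <- apply(cube, c(1, 2), mean, na.rm = TRUE)
  types <- colnames(avg)
  P <- matrix(NA_real_, nrow = length(types), ncol = length(markers),
              dimnames = list(types, names(markers)))
  for (t in types) {
    prof <- avg[, t]
    prof <- prof[is.finite(prof)]
    for (nm in names(markers)) {
      inset <- names(prof) %in% markers[[nm]]
      if (!any(inset) || all(inset)) next
      P[t, nm] <- suppressWarnings(
        stats::wilcox.test(prof[inset], prof[!inset],
                           alternative = "greater")$p.value)
    }
  }
  L <- -log10(pmax(P, .Machine$double.xmin))
  scaled <- L
  degenerate <- logical(nrow(L))
  for (i in seq_len(nrow(L))) {
    s <- stats::sd(L[i, ], na.rm = TRUE)
    if (!is.finite(s) || s == 0) {
      scaled[i, ] <- 0
      degenerate[i] <- TRUE
    } else {
      scaled[i, ] <- (L[i, ] - mean(L[i, ], na.rm = TRUE)) / s
    }
  }
  structure(scaled, class = "enrichment_heatmap", raw_p = P,
            degenerate_rows = rownames(L)[degenerate])
}

#' Robust per-cell-type two-group test of a gene set's imputed activity
#'
#' For each cell type, every gene of the set is converted to its quantile
#' rank across samples within that type's imputed slice (tied ranks
#' averaged, so genes imputed as constant sit at 0.5 for every sample);
#' each sample is summarized by the median quantile rank over the set,
#' and the two groups are compared by a rank-sum test. The median-over-
#' genes summary has a high breakdown point, so the handful of genes
#' whose residual the imputation attributes to the wrong cell type
#' cannot flag an unaffected type (see the methods vignette).
#'
#' @param cube a `celltype_cube`
#' @param genes gene ids of the set (or a [gene_set()])
#' @param labels two-level grouping per sample
#' @param alternative passed to [stats::wilcox.test()] with the first
#'   factor level as the first sample (default `"greater"`: activity
#'   higher in the first level)
#' @return data.frame with `cell_type`, `statistic`, `p`
#' @export
compare_celltype_activation <- function(cube, genes, labels,
                                        alternative = "greater") {
  stopifnot(inherits(cube, "celltype_cube"))
  if (inherits(genes, "gene_set")) genes <- genes$genes
  labels <- droplevels(as.factor(labels))
  .assert(nlevels(labels) == 2, "exactly two groups required")
  present <- intersect(genes, dimnames(cube)[[1]])
  if (length(present) == 0) stop("no set gene present in the cube")
  types <- dimnames(cube)[[2]]
  res <- lapply(types, function(t) {
    X <- cube[present, t, , drop = TRUE]
    if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(present, dimnames(cube)[[3]]))
    S <- ncol(X)
    Q <- t(apply(X, 1, function(row) {
      if (all(is.na(row))) return(rep(NA_real_, S))
      rank(row, na.last = "keep") / sum(!is.na(row))
    }))
    m <- apply(Q, 2, stats::median, na.rm = TRUE)
    if (all(is.na(m)) || stats::sd(m, na.rm = TRUE) == 0) {
      return(data.frame(cell_type = t, statistic = NA_real_, p = 1))
    }
    w <- suppressWarnings(
      stats::wilcox.test(m[labels == levels(labels)[1]],
                         m[labels == levels(labels)[2]],
                         alternative = alternative))
    data.frame(cell_type = t, statistic = unname(w$statistic), p = w$p.value)
  })
  do.call(rbind, res)
}
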