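# Cohort-level statistics: group-wise proportion comparisons, the
# DEG-filtered linear-SVM classification stage, and clinical-feature
# association tests for discovered clusters.

#' Compare cell-type proportions between two groups
#'
#' Per cell type, a two-sided rank-sum test between the groups, with
#' Benjamini-Hochberg adjustment across cell types. Proportions that are
#' constant in both groups get p = 1.
#'
#' @param props a [proportion_table()]
#' @param labels two-level grouping, one label per sample (matched to the
#'   table's row order)
#' @return data.frame with `cell_type`, `statistic`, `p`, `p_adj`
#' @export
compare_group_proportions <- function(props, labels) {
  labels <- droplevels(as.factor(labels))
  .assert(nlevels(labels) == 2, "exactly two groups required")
  .assert(length(labels) == nrow(props), "one label per sample required")
  .assert(all(table(labels) >= 2), "need >= 2 samples per group")
  P <- unclass(props)
  res <- lapply(colnames(P), function(t) {
    x <- P[labels == levels(labels)[1], t]
    y <- P[labels == levels(labels)[2], t]
    if (stats::sd(c(x, y)) == 0) {
      return(data.frame(cell_type = t, statistic = NA_real_, p = 1))
    }
    w <- suppressWarnings(stats::wilcox.test(x, y))
    data.frame(cell_type = t, statistic = unname(w$statistic), p = w$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Select differentially expressed genes on log-scale expression
#'
#' Genes passing the expression filter (row mean above `logcpm_min`) are
#' tested with a per-gene Welch two-sample t-test on the log values;
#' Benjamini-Hochberg-adjusted p-values below `alpha` define the DEG set.
#' (A location test on log intensities stands in for a count-model fit,
#' since microarray-style and imputed inputs are continuous.)
#'
#' @param expr genes x samples matrix, log scale
#' @param labels two-level grouping per sample
#' @param logcpm_min expression filter on the row mean
#' @param alpha adjusted-p cutoff
#' @return character vector of DEG ids; attribute `table` holds the full
#'   per-gene test table (gene, statistic, p, p_adj)
#' @export
select_degs <- function(expr, labels, logcpm_min = 1, alpha = 0.05) {
  labels <- droplevels(as.factor(labels))
  .assert(nlevels(labels) == 2, "exactly two groups required")
  expr <- as.matrix(expr)
  keep <- rowMeans(expr) > logcpm_min
  if (!any(keep)) stop("no gene passes the expression filter")
  sub <- expr[keep, , drop = FALSE]
  tt <- row_welch_t(sub, which(labels == levels(labels)[1]),
                    which(labels == levels(labels)[2]))
  tt$p_adj <- stats::p.adjust(tt$p, method = "BH")
  degs <- rownames(sub)[tt$p_adj < alpha]
  attr(degs, "table") <- data.frame(gene = rownames(sub),
                                    statistic = tt$statistic,
                                    p = tt$p, p_adj = tt$p_adj,
                                    row.names = NULL)
  degs
}

#' SVM configuration
#'
#' @param cost_grid regularization costs searched by cross-validation
#' @param n_folds cross-validation folds on the training set
#' @param train_fraction fraction of samples in the (stratified) training
#'   split
#' @param logcpm_min,de_alpha DEG-selection parameters (training set only)
#' @param fallback_n_genes number of smallest-p genes used when no gene
#'   clears the adjusted-p cutoff (keeps null-label runs defined)
#' @param seed RNG seed controlling split and fold assignment
#' @return object of class `svm_config`
#' @export
svm_config <- function(cost_grid = seq(0.2, 2, by = 0.2), n_folds = 5,
                       train_fraction = 0.8, logcpm_min = 4, de_alpha = 0.05,
                       fallback_n_genes = 50, seed = 1) {
  .assert(all(cost_grid > 0), "costs must be positive")
  .assert(train_fraction > 0 && train_fraction < 1,
          "train_fraction must be in (0,1)")
  structure(list(cost_grid = cost_grid, n_folds = as.integer(n_folds),
                 train_fraction = train_fraction, logcpm_min = logcpm_min,
                 de_alpha = de_alpha, fallback_n_genes = fallback_n_genes,
                 seed = as.integer(seed)),
            class = "svm_config")
}

# L2-regularized squared-hinge linear SVM solved in the primal. The data
# term is averaged over samples (not summed), which makes the fitted
# decision function invariant under duplicating every sample at fixed
# cost; see the methods vignette for the contrast with the summed form.
.linear_svm_fit <- function(X, y, cost) {
  n <- nrow(X); d <- ncol(X)
  obj <- function(theta) {
    w <- theta[1:d]; b <- theta[d + 1]
    m <- pmax(0, 1 - y * (drop(X %*% w) + b))
    0.5 * sum(w^2) + cost * mean(m^2)
  }
  grad <- function(theta) {
    w <- theta[1:d]; b <- theta[d + 1]
    m <- pmax(0, 1 - y * (drop(X %*% w) + b))
    c(w - (2 * cost / n) * drop(crossprod(X, y * m)),
      -(2 * cost / n) * sum(y * m))
  }
  fit <- stats::optim(numeric(d + 1), obj, grad, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-10))
  list(w = fit$par[1:d], b = fit$par[d + 1])
}

.stratified_split <- function(labels, fraction) {
  idx_train <- unlist(lapply(levels(labels), function(lv) {
    ix <- which(labels == lv)
    sample(ix, max(1, round(fraction * length(ix))))
  }))
  sort(idx_train)
}

.stratified_folds <- function(labels, n_folds) {
  fold <- integer(length(labels))
  for (lv in levels(labels)) {
    ix <- sample(which(labels == lv))
    fold[ix] <- rep_len(seq_len(n_folds), length(ix))
  }
  fold
}

#' Train and evaluate a linear SVM classifier
#'
#' Samples are split into a stratified train/test partition. DEGs are
#' selected on the training set only (falling back to the
#' `fallback_n_genes` smallest-p genes when the adjusted cutoff selects
#' none); features are z-scored with training statistics. The cost is
#' chosen by mean ROC-AUC over stratified cross-validation folds (ties
#' broken toward the smallest cost), the model refit on the full training
#' set, and the held-out ROC-AUC reported.
#'
#' @param expr genes x samples matrix, log scale
#' @param labels two-level grouping per sample
#' @param cfg an [svm_config()]
#' @return list with `best_cost`, `test_auc`, `roc` (data.frame of fpr /
#'   tpr), `cv_auc` (per-cost mean CV AUC), `genes` (features used) and
#'   the index vectors of the split
#' @export
train_eval_svm <- function(expr, labels, cfg = svm_config()) {
  stopifnot(inherits(cfg, "svm_config"))
  labels <- droplevels(as.factor(labels))
  .assert(nlevels(labels) == 2, "exactly two classes required")
  expr <- as.matrix(expr)
  set.seed(cfg$seed)
  idx_train <- .stratified_split(labels, cfg$train_fraction)
  idx_test <- setdiff(seq_along(labels), idx_train)
  y_train <- droplevels(labels[idx_train])
  y_test <- labels[idx_test]
  if (nlevels(y_train) < 2 || length(unique(y_test)) < 2) {
    stop("both classes must be present in train and test after the split")
  }
  degs <- select_degs(expr[, idx_train, drop = FALSE], y_train,
                      cfg$logcpm_min, cfg$de_alpha)
  if (length(degs) == 0) {
    tab <- attr(degs, "table")
    degs <- tab$gene[order(tab$p)][seq_len(min(cfg$fallback_n_genes, nrow(tab)))]
  }
  Xall <- t(expr[degs, , drop = FALSE])
  mu <- colMeans(Xall[idx_train, , drop = FALSE])
  sdv <- apply(Xall[idx_train, , drop = FALSE], 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xall <- sweep(sweep(Xall, 2, mu), 2, sdv, "/")
  pos <- levels(labels)[1]
  yy <- ifelse(labels == pos, 1, -1)

  n_folds <- min(cfg$n_folds, min(table(y_train)))
  if (n_folds < 2) stop("too few samples per class for cross-validation")
  folds <- .stratified_folds(y_train, n_folds)
  cv_auc <- vapply(cfg$cost_grid, function(cost) {
    aucs <- vapply(seq_len(n_folds), function(f) {
      tr <- idx_train[folds != f]; va <- idx_train[folds == f]
      if (length(unique(yy[va])) < 2 || length(unique(yy[tr])) < 2) {
        return(NA_real_)
      }
      fit <- .linear_svm_fit(Xall[tr, , drop = FALSE], yy[tr], cost)
      rank_auc(drop(Xall[va, , drop = FALSE] %*% fit$w) + fit$b, yy[va] == 1)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best_cost <- cfg$cost_grid[which.max(cv_auc)]   # which.max: first = smallest
  fit <- .linear_svm_fit(Xall[idx_train, , drop = FALSE], yy[idx_train],
                         best_cost)
  scores <- drop(Xall[idx_test, , drop = FALSE] %*% fit$w) + fit$b
  test_auc <- rank_auc(scores, yy[idx_test] == 1)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  roc <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(scores[yy[idx_test] == 1] >= t),
                 numeric(1)),
    fpr = vapply(thr, function(t) mean(scores[yy[idx_test] == -1] >= t),
                 numeric(1)))
  list(best_cost = best_cost, test_auc = test_auc, roc = roc,
       cv_auc = stats::setNames(cv_auc, cfg$cost_grid), genes = degs,
       train_index = idx_train, test_index = idx_test,
       model = fit, positive_class = pos)
}

#' Test clinical-feature association with sample clusters
#'
#' Numeric features: one-way ANOVA across clusters plus all-pairs Welch
#' t-tests with Benjamini-Hochberg correction. Categorical features:
#' chi-square test (no continuity correction) on the cluster x category
#' contingency table. Features with a single distinct value are skipped
#' with a warning. ANOVA / chi-square p-values are additionally
#' BH-adjusted across features (`p_adj`).
#'
#' @param clusters cluster label per sample
#' @param clinical_table data.frame of features (rows = samples, same
#'   order as `clusters`); numeric columns are ANOVA-tested, everything
#'   else chi-square-tested
#' @return list with `table` (tidy data.frame: feature, test, statistic,
#'   p, p_adj) and `pairwise` (named list of symmetric matrices of
#'   FDR-adjusted pairwise p-values for numeric features)
#' @export
test_clinical_association <- function(clusters, clinical_table) {
  clusters <- droplevels(as.factor(clusters))
  .assert(nlevels(clusters) >= 2, "need at least two clusters")
  .assert(nrow(clinical_table) == length(clusters),
          "one cluster label per clinical row required")
  rows <- list()
  pairwise <- list()
  for (feat in colnames(clinical_table)) {
    x <- clinical_table[[feat]]
    if (length(unique(x[!is.na(x)])) < 2) {
      warning(sprintf("feature '%s' has a single distinct value; skipped", feat))
      next
    }
    if (is.numeric(x)) {
      fit <- stats::aov(x ~ clusters)
      an <- summary(fit)[[1]]
      stat <- an[["F value"]][1]
      p <- an[["Pr(>F)"]][1]
      if (!is.finite(p)) {
        # zero residual variance: perfect separation if the means differ
        means <- tapply(x, clusters, mean)
        if (stats::sd(means) > 0) {
          stat <- Inf
          p <- 0
        } else {
          p <- 1
        }
      }
      lv <- levels(clusters)
      pm <- matrix(NA_real_, length(lv), length(lv), dimnames = list(lv, lv))
      pairs <- utils::combn(lv, 2)
      praw <- apply(pairs, 2, function(pr) {
        a <- x[clusters == pr[1]]; b <- x[clusters == pr[2]]
        if (length(a) < 2 || length(b) < 2) return(NA_real_)
        tryCatch(stats::t.test(a, b)$p.value,
                 error = function(e) {
                   # both sides constant: certain if means differ, null if not
                   if (mean(a) != mean(b)) 0 else 1
                 })
      })
      padj <- stats::p.adjust(praw, method = "BH")
      for (j in seq_len(ncol(pairs))) {
        pm[pairs[1, j], pairs[2, j]] <- padj[j]
        pm[pairs[2, j], pairs[1, j]] <- padj[j]
      }
      pairwise[[feat]] <- pm
      rows[[feat]] <- data.frame(feature = feat, test = "anova",
                                 statistic = stat, p = p)
    } else {
      tab <- table(clusters, x)
      tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
      if (any(dim(tab) < 2)) {
        warning(sprintf("feature '%s' degenerates to one category; skipped", feat))
        next
      }
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      rows[[feat]] <- data.frame(feature = feat, test = "chi_square",
                                 statistic = unname(ct$statistic),
                                 p = ct$p.value)
    }
  }
  if (length(rows) == 0) stop("no testable clinical feature")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  list(table = out, pairwise = pairwise)
}
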