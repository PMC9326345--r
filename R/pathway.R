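# Rank-based per-sample pathway activity: the area under the gene-set
# recovery curve within the top-ranked fraction of genes (the AUCell
# statistic), plus two-group comparisons of the resulting scores.

#' Construct a gene set
#'
#' @param name set name
#' @param genes character vector of gene ids; duplicates are removed with
#'   a warning
#' @param description optional free-text description
#' @return object of class `gene_set`
#' @export
gene_set <- function(name, genes, description = "") {
  .assert(length(genes) > 0, "a gene set cannot be empty")
  if (anyDuplicated(genes)) {
    warning(sprintf("gene set '%s': duplicated genes removed", name))
    genes <- unique(genes)
  }
  structure(list(name = name, genes = as.character(genes),
                 description = description), class = "gene_set")
}

#' Rank-based activity score of a gene set in one expression profile
#'
#' Genes are ranked by descending expression (ties broken by gene id);
#' with `n_max = ceil(top_fraction * G)` and recovery curve
#' `R(i) = #\{set genes at rank <= i\}`, the score is
#' `sum_{i=1..n_max} R(i) / (n_max * min(|set|, n_max))`, i.e. the area
#' under the recovery curve normalized by its maximum. Set genes absent
#' from the profile are dropped with a warning; a score of 1 means the
#' whole set sits at the very top, 0 that no set gene reaches the window.
#' The score is invariant under any strictly monotone transform of the
#' expression values.
#'
#' @param expr_column named numeric vector of expression values
#' @param set a [gene_set()] (or plain character vector of gene ids)
#' @param top_fraction fraction of top-ranked genes forming the window
#' @return activity score in [0, 1]
#' @export
aucell_score <- function(expr_column, set, top_fraction = 0.05) {
  if (inherits(set, "gene_set")) set <- set$genes
  .assert(!is.null(names(expr_column)), "expression vector must be named")
  .assert(top_fraction > 0 && top_fraction <= 1, "top_fraction must be in (0,1]")
  present <- intersect(set, names(expr_column))
  if (length(present) == 0) {
    stop("no gene-set gene present in the expression profile")
  }
  if (length(present) < length(set)) {
    warning(sprintf("%d gene(s) of the set absent from the profile and dropped",
                    length(set) - length(present)))
  }
  G <- length(expr_column)
  ord <- order(-expr_column, names(expr_column))
  ranks <- match(present, names(expr_column)[ord])
  n_max <- ceiling(top_fraction * G)
  hits <- ranks[ranks <= n_max]
  if (length(hits) == 0) return(0)
  recovery <- cumsum(tabulate(hits, nbins = n_max))
  sum(recovery) / (n_max * min(length(present), n_max))
}

#' Activity scores for several gene sets across samples
#'
#' @param expr genes x samples matrix with gene-id rownames
#' @param gene_sets named list of [gene_set()]s (or gene-id vectors)
#' @param top_fraction see [aucell_score()]
#' @return samples x sets matrix of scores
#' @export
aucell_scores <- function(expr, gene_sets, top_fraction = 0.05) {
  expr <- as.matrix(expr)
  .assert(!is.null(rownames(expr)), "expression matrix must have gene rownames")
  if (is.null(names(gene_sets))) {
    names(gene_sets) <- vapply(gene_sets, function(s)
      if (inherits(s, "gene_set")) s$name else "set", character(1))
  }
  out <- vapply(gene_sets, function(s) {
    apply(expr, 2, function(col)
      aucell_score(stats::setNames(col, rownames(expr)), s, top_fraction))
  }, numeric(ncol(expr)))
  if (is.null(dim(out))) out <- matrix(out, nrow = ncol(expr),
                                       dimnames = list(colnames(expr),
                                                       names(gene_sets)))
  out
}

#' Two-group comparison of activity scores
#'
#' @param scores numeric vector of per-sample scores
#' @param labels two-level grouping (factor or character), >= 2 samples
#'   per group
#' @return list with `statistic`, `p.value` and `method` (two-sided
#'   rank-sum test)
#' @export
compare_groups <- function(scores, labels) {
  labels <- as.factor(labels)
  if (nlevels(droplevels(labels)) != 2) {
    stop("exactly two groups are required")
  }
  labels <- droplevels(labels)
  counts <- table(labels)
  if (any(counts < 2)) stop("need at least two samples per group")
  w <- suppressWarnings(
    stats::wilcox.test(scores[labels == levels(labels)[1]],
                       scores[labels == levels(labels)[2]]))
  p <- w$p.value
  if (!is.finite(p)) p <- 1   # all-tied scores carry no evidence
  list(statistic = unname(w$statistic), p.value = p,
       method = "two-sided Wilcoxon rank-sum")
}
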