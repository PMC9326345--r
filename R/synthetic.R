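# Synthetic-data generators: labeled single-cell references, pseudo-bulk
# mixtures with known proportions, and full case/control cohorts with
# planted subtype and clinical structure. These emulate the statistical
# shape of a multi-cell-type tissue (a placenta-like organ profiled by
# single-cell RNA-seq) mixed into bulk profiles measured on a different
# platform, so every downstream stage can be validated against ground truth.

#' Specification of a synthetic single-cell reference
#'
#' @param n_cell_types number of cell types (>= 2)
#' @param n_genes total number of genes
#' @param cells_per_type cells simulated per type
#' @param markers_per_type genes planted as markers of each type
#' @param marker_log2fc log2 elevation of a marker in its own type
#' @param baseline_log_mean,baseline_log_sd log-normal parameters of the
#'   per-gene baseline expression profile (natural-log scale)
#' @param count_depth expected total counts per cell (Poisson)
#' @param dropout_rate per-gene, per-cell Bernoulli zero-inflation rate,
#'   applied to the expression profile before depth normalization
#' @param seed RNG seed; generation is fully reproducible from it
#' @param cell_type_names optional character vector of type names
#' @return an object of class `reference_spec`
#' @export
reference_spec <- function(n_cell_types = 8, n_genes = 1000, cells_per_type = 50,
                           markers_per_type = 30, marker_log2fc = 3,
                           baseline_log_mean = 1, baseline_log_sd = 1,
                           count_depth = 2000, dropout_rate = 0.2, seed = 1,
                           cell_type_names = NULL) {
  .assert(n_cell_types >= 2, "need at least two cell types")
  .assert(markers_per_type * n_cell_types <= n_genes,
          "infeasible spec: more planted markers than genes")
  .assert(dropout_rate >= 0 && dropout_rate <= 1, "dropout_rate must be in [0,1]")
  .assert(count_depth > 0 && cells_per_type >= 1, "invalid depth or cell count")
  if (is.null(cell_type_names)) {
    cell_type_names <- paste0("T", seq_len(n_cell_types))
  }
  .assert(length(cell_type_names) == n_cell_types, "wrong number of cell type names")
  structure(list(
    n_cell_types = as.integer(n_cell_types), n_genes = as.integer(n_genes),
    cells_per_type = as.integer(cells_per_type),
    markers_per_type = as.integer(markers_per_type),
    marker_log2fc = marker_log2fc, baseline_log_mean = baseline_log_mean,
    baseline_log_sd = baseline_log_sd, count_depth = count_depth,
    dropout_rate = dropout_rate, seed = as.integer(seed),
    cell_type_names = cell_type_names
  ), class = "reference_spec")
}

#' Generate a labeled single-cell reference
#'
#' Per-gene baseline abundances are log-normal; each cell type elevates its
#' planted marker genes by `2^marker_log2fc`. A cell's counts are drawn from
#' a multinomial over its type's (dropout-thinned) profile at a
#' Poisson-distributed depth.
#'
#' @param spec a [reference_spec()]
#' @return object of class `sc_reference`: list with `counts`
#'   (cells x genes integer matrix), `cell_types` (label per cell),
#'   `gene_ids`. The planted marker assignment is attached as attribute
#'   `planted_markers` (named list of gene ids per type).
#' @export
generate_reference <- function(spec) {
  stopifnot(inherits(spec, "reference_spec"))
  set.seed(spec$seed)
  G <- spec$n_genes; K <- spec$n_cell_types; n <- spec$cells_per_type
  gene_ids <- sprintf("g%05d", seq_len(G))
  lambda <- stats::rlnorm(G, spec$baseline_log_mean, spec$baseline_log_sd)
  marker_idx <- matrix(sample.int(G, K * spec$markers_per_type), ncol = K)
  profiles <- matrix(lambda, nrow = G, ncol = K,
                     dimnames = list(gene_ids, spec$cell_type_names))
  for (t in seq_len(K)) {
    profiles[marker_idx[, t], t] <- profiles[marker_idx[, t], t] * 2^spec$marker_log2fc
  }
  n_cells <- K * n
  counts <- matrix(0L, nrow = n_cells, ncol = G,
                   dimnames = list(sprintf("c%05d", seq_len(n_cells)), gene_ids))
  cell_types <- rep(spec$cell_type_names, each = n)
  depths <- stats::rpois(n_cells, spec$count_depth)
  for (i in seq_len(n_cells)) {
    prof <- profiles[, match(cell_types[i], spec$cell_type_names)]
    if (spec$dropout_rate > 0) {
      keep <- stats::rbinom(G, 1L, 1 - spec$dropout_rate)
      if (any(keep == 1L)) prof <- prof * keep
    }
    counts[i, ] <- as.integer(stats::rmultinom(1, depths[i], prof))
  }
  planted <- lapply(seq_len(K), function(t) gene_ids[sort(marker_idx[, t])])
  names(planted) <- spec$cell_type_names
  structure(list(counts = counts, cell_types = cell_types, gene_ids = gene_ids),
            class = "sc_reference", planted_markers = planted, spec = spec)
}

#' @export
print.sc_reference <- function(x, ...) {
  cat(sprintf("single-cell reference: %d cells x %d genes, %d cell types\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$cell_types))))
  invisible(x)
}

#' Per-type mean CPM profiles of a reference
#'
#' @param ref an `sc_reference`
#' @return genes x cell types matrix of mean CPM
#' @export
celltype_mean_cpm <- function(ref) {
  stopifnot(inherits(ref, "sc_reference"))
  cpm <- cpm_normalize(ref$counts)
  types <- unique(ref$cell_types)
  M <- vapply(types, function(t) colMeans(cpm[ref$cell_types == t, , drop = FALSE]),
              numeric(ncol(cpm)))
  dimnames(M) <- list(ref$gene_ids, types)
  M
}

#' Generate pseudo-bulk mixtures with known proportions
#'
#' Bulk column s is \eqn{\sum_t p_{s,t} m_t \odot \exp(\epsilon)} with
#' \eqn{m_t} the per-type mean CPM profile of the reference,
#' \eqn{p_s \sim Dirichlet(concentration)} and i.i.d. Gaussian log-noise.
#' An optional per-gene multiplicative platform bias (shared by all samples,
#' applied after mixing) emulates a cross-platform reference/bulk pairing.
#'
#' @param ref an `sc_reference`
#' @param n_samples number of bulk samples
#' @param concentration Dirichlet concentration (length = number of types)
#' @param noise_log_sd standard deviation of the multiplicative log-normal
#'   noise (natural-log scale); 0 gives exactly linear mixtures
#' @param seed RNG seed
#' @param proportions optional fixed samples x types proportion matrix that
#'   bypasses Dirichlet sampling (rows must sum to 1)
#' @param platform_bias_sd log-sd of a per-gene fixed multiplicative bias
#' @return list with `bulk` (genes x samples) and `proportions`
#'   (a [proportion_table()] holding the true mixing weights)
#' @export
generate_mixtures <- function(ref, n_samples, concentration = NULL,
                              noise_log_sd = 0.2, seed = 1,
                              proportions = NULL, platform_bias_sd = 0) {
  stopifnot(inherits(ref, "sc_reference"))
  M <- celltype_mean_cpm(ref)
  K <- ncol(M)
  set.seed(seed)
  if (is.null(proportions)) {
    if (is.null(concentration)) concentration <- rep(3, K)
    .assert(length(concentration) == K,
            "concentration length must equal the number of cell types")
    if (any(concentration <= 0)) stop("Dirichlet concentration must be positive")
    P <- rdirichlet(n_samples, concentration)
  } else {
    P <- as.matrix(proportions)
    .assert(ncol(P) == K && nrow(P) == n_samples, "bad proportions dimensions")
    .assert(max(abs(rowSums(P) - 1)) < 1e-9, "proportion rows must sum to 1")
  }
  colnames(P) <- colnames(M)
  rownames(P) <- sprintf("s%04d", seq_len(n_samples))
  bulk <- M %*% t(P)
  if (noise_log_sd > 0) {
    bulk <- bulk * exp(matrix(stats::rnorm(length(bulk), 0, noise_log_sd),
                              nrow = nrow(bulk)))
  }
  if (platform_bias_sd > 0) {
    bulk <- bulk * exp(stats::rnorm(nrow(bulk), 0, platform_bias_sd))
  }
  colnames(bulk) <- rownames(P)
  list(bulk = bulk, proportions = proportion_table(P, method = "truth"))
}

#' Specification of a synthetic case/control cohort
#'
#' @param n_samples_per_group samples in each of the case and control arms
#' @param group_proportion_shift named numeric: difference of mean mixing
#'   proportion (case minus control) per shifted cell type; the complement
#'   is absorbed proportionally by the unshifted types
#' @param dirichlet_concentration control-group concentration vector (its
#'   normalized value is the control mean composition; the total sets the
#'   between-sample variability)
#' @param noise_log_sd multiplicative log-normal noise on bulk values
#' @param platform_bias_sd per-gene fixed multiplicative bias (log-sd)
#' @param n_subtypes number of planted case subtypes
#' @param subtype_pathway_genes list (one element per subtype) of lists with
#'   fields `cell_type`, `genes` (gene ids) and `log2fc`: that subtype's
#'   case samples up-scale those genes by 2^log2fc, only through the stated
#'   cell type's contribution, before summation
#' @param clinical_effect_size separation (in noise standard deviations)
#'   between consecutive subtype means of the planted numeric features
#' @param n_numeric_planted,n_numeric_null,n_categorical_planted,n_categorical_null
#'   how many clinical features of each kind to emit
#' @param seed RNG seed
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_samples_per_group = 60, group_proportion_shift = NULL,
                        dirichlet_concentration = NULL, noise_log_sd = 0.2,
                        platform_bias_sd = 0.3, n_subtypes = 1,
                        subtype_pathway_genes = NULL, clinical_effect_size = 2,
                        n_numeric_planted = 2, n_numeric_null = 2,
                        n_categorical_planted = 1, n_categorical_null = 1,
                        seed = 1) {
  .assert(n_samples_per_group >= 2, "need at least two samples per group")
  .assert(n_subtypes >= 1, "n_subtypes must be >= 1")
  if (!is.null(dirichlet_concentration) && any(dirichlet_concentration <= 0)) {
    stop("Dirichlet concentration must be strictly positive")
  }
  if (!is.null(subtype_pathway_genes)) {
    .assert(length(subtype_pathway_genes) == n_subtypes,
            "one pathway activation entry per subtype expected")
  }
  structure(list(
    n_samples_per_group = as.integer(n_samples_per_group),
    group_proportion_shift = group_proportion_shift,
    dirichlet_concentration = dirichlet_concentration,
    noise_log_sd = noise_log_sd, platform_bias_sd = platform_bias_sd,
    n_subtypes = as.integer(n_subtypes),
    subtype_pathway_genes = subtype_pathway_genes,
    clinical_effect_size = clinical_effect_size,
    n_numeric_planted = n_numeric_planted, n_numeric_null = n_numeric_null,
    n_categorical_planted = n_categorical_planted,
    n_categorical_null = n_categorical_null,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a full case/control cohort with planted structure
#'
#' Control samples mix cell types at Dirichlet-sampled proportions; the case
#' group's mean composition differs by `group_proportion_shift`. Case
#' samples are partitioned into `n_subtypes` blocks; each block's pathway
#' activation scales the stated genes through the stated cell type's
#' contribution before summation, so imputation can be checked against the
#' generating truth. Numeric clinical features separate subtype means by
#' `clinical_effect_size` noise-sd; categorical features have
#' subtype-dependent level frequencies; null features carry no signal.
#'
#' @param ref an `sc_reference`
#' @param spec a [cohort_spec()]
#' @return object of class `synthetic_cohort`: list with `bulk`
#'   (genes x samples, strictly positive), `true_proportions`
#'   ([proportion_table()]), `group` (factor case/control), `subtype`
#'   (integer per case sample, NA for controls), `clinical` (data.frame),
#'   and `provenance` (the generating specs and seed)
#' @export
generate_cohort <- function(ref, spec) {
  stopifnot(inherits(ref, "sc_reference"), inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  M <- celltype_mean_cpm(ref)
  types <- colnames(M)
  K <- length(types)
  conc <- spec$dirichlet_concentration
  # default: equal mean composition with the between-individual spread
  # typical of tissue cohorts (sd ~ 0.1-0.15 for a 4-8 type organ)
  if (is.null(conc)) conc <- rep(10 / K, K)
  .assert(length(conc) == K, "concentration length must match cell types")
  total <- sum(conc)
  m_ctrl <- stats::setNames(conc / total, types)
  m_case <- m_ctrl
  shift <- spec$group_proportion_shift
  if (!is.null(shift)) {
    .assert(!is.null(names(shift)) && all(names(shift) %in% types),
            "group_proportion_shift must be named by cell type")
    s <- stats::setNames(numeric(K), types)
    s[names(shift)] <- shift
    unshifted <- setdiff(types, names(shift))
    excess <- sum(s)
    if (length(unshifted) > 0 && abs(excess) > 0) {
      # absorb the net shift proportionally so shifted types keep their
      # exact stated displacement
      s[unshifted] <- -excess * m_ctrl[unshifted] / sum(m_ctrl[unshifted])
    }
    m_case <- m_ctrl + s
    if (any(m_case < 0) || abs(sum(m_case) - 1) > 1e-9) {
      stop("group_proportion_shift produces an invalid case composition")
    }
  }
  n <- spec$n_samples_per_group
  P <- rbind(rdirichlet(n, m_case * total), rdirichlet(n, m_ctrl * total))
  colnames(P) <- types
  rownames(P) <- sprintf("s%04d", seq_len(2 * n))
  group <- factor(rep(c("case", "control"), each = n),
                  levels = c("case", "control"))
  subtype <- rep(NA_integer_, 2 * n)
  subtype[group == "case"] <- rep_len(seq_len(spec$n_subtypes), n)

  G <- nrow(M)
  bulk <- matrix(0, nrow = G, ncol = 2 * n,
                 dimnames = list(rownames(M), rownames(P)))
  activations <- spec$subtype_pathway_genes
  for (s_i in seq_len(2 * n)) {
    Ms <- M
    if (!is.na(subtype[s_i]) && !is.null(activations)) {
      act <- activations[[subtype[s_i]]]
      if (!is.null(act)) {
        # a subtype may carry one activation or a list of them (shared
        # activations across subtypes give the cohort a hierarchy)
        if (!is.null(act$cell_type)) act <- list(act)
        for (a in act) {
          .assert(a$cell_type %in% types, "activation names an unknown cell type")
          gi <- match(a$genes, rownames(M))
          .assert(!anyNA(gi), "activation names genes absent from the reference")
          Ms[gi, a$cell_type] <- Ms[gi, a$cell_type] * 2^a$log2fc
        }
      }
    }
    bulk[, s_i] <- Ms %*% P[s_i, ]
  }
  if (spec$noise_log_sd > 0) {
    bulk <- bulk * exp(matrix(stats::rnorm(length(bulk), 0, spec$noise_log_sd),
                              nrow = G))
  }
  if (spec$platform_bias_sd > 0) {
    bulk <- bulk * exp(stats::rnorm(G, 0, spec$platform_bias_sd))
  }
  bulk <- pmax(bulk, 1e-6)   # strictly positive by contract

  clinical <- .make_clinical(group, subtype, spec)
  structure(list(bulk = bulk,
                 true_proportions = proportion_table(P, method = "truth"),
                 group = group, subtype = subtype, clinical = clinical,
                 provenance = list(reference_spec = attr(ref, "spec"),
                                   cohort_spec = spec, seed = spec$seed)),
            class = "synthetic_cohort")
}

# Clinical table: planted numeric features have subtype-specific means
# (consecutive subtypes separated by clinical_effect_size sd, unit noise);
# planted categorical features have subtype-dependent level frequencies.
# Controls and null features are pure noise.
.make_clinical <- function(group, subtype, spec) {
  n_all <- length(group)
  k <- spec$n_subtypes
  df <- data.frame(row.names = sprintf("s%04d", seq_len(n_all)))
  centered <- function(j) (j - (k + 1) / 2)
  for (f in seq_len(spec$n_numeric_planted)) {
    mu <- ifelse(is.na(subtype), 0, spec$clinical_effect_size * centered(subtype))
    df[[sprintf("num_planted_%d", f)]] <- mu + stats::rnorm(n_all)
  }
  for (f in seq_len(spec$n_numeric_null)) {
    df[[sprintf("num_null_%d", f)]] <- stats::rnorm(n_all)
  }
  for (f in seq_len(spec$n_categorical_planted)) {
    pr <- ifelse(is.na(subtype), 0.5,
                 0.15 + 0.7 * (subtype - 1) / max(1, k - 1))
    df[[sprintf("cat_planted_%d", f)]] <-
      factor(ifelse(stats::runif(n_all) < pr, "B", "A"))
  }
  for (f in seq_len(spec$n_categorical_null)) {
    df[[sprintf("cat_null_%d", f)]] <-
      factor(sample(c("A", "B"), n_all, replace = TRUE))
  }
  df$group <- group
  df
}
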