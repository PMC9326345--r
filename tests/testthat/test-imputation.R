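# Cell-type expression imputation: exactness in degenerate cases, the
# reconstruction identity, specificity of planted activations, and
# marker-enrichment validation.

test_that("a single cell type reproduces the bulk exactly", {
  bulk <- matrix(rexp(40, 0.01), 10, 4,
                 dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:4)))
  props <- proportion_table(matrix(1, 4, 1,
                                   dimnames = list(colnames(bulk), "only")))
  cube <- impute_celltype_expression(bulk, props)
  expect_equal(unname(cube[, 1, ]), unname(bulk), tolerance = 1e-9)
})

test_that("stage 1 recovers the generating profiles on noiseless data", {
  ref <- small_reference()
  M <- celltype_mean_cpm(ref)
  mix <- generate_mixtures(ref, 30, noise_log_sd = 0, seed = 61)
  cube <- impute_celltype_expression(mix$bulk, mix$proportions)
  beta <- attr(cube, "beta")
  rel <- abs(beta - M) / pmax(M, 1)
  expect_lt(max(rel), 1e-4)
  # residuals vanish, so the cube is flat across samples at beta
  expect_lt(max(abs(cube[, , 1] - beta), na.rm = TRUE), 1e-6)
})

test_that("the proportion-weighted cube reproduces the bulk", {
  ref <- small_reference()
  coh <- memo("imp_cohort", generate_cohort(ref, cohort_spec(
    n_samples_per_group = 20, noise_log_sd = 0.2, seed = 62)))
  cube <- impute_celltype_expression(coh$bulk, coh$true_proportions)
  P <- unclass(coh$true_proportions)
  expect_true(all(cube >= 0, na.rm = TRUE))
  worst <- 0
  for (s in seq_len(ncol(coh$bulk))) {
    X <- cube[, , s]
    ok <- rowSums(is.na(X)) == 0 & apply(X > 0, 1, all)  # no clip/missing
    err <- abs(X[ok, , drop = FALSE] %*% P[s, ] - coh$bulk[ok, s])
    worst <- max(worst, max(err / pmax(coh$bulk[ok, s], 1)))
  }
  expect_lt(worst, 1e-6)
})

test_that("imputation refuses under-determined cohorts", {
  bulk <- matrix(rexp(50), 10, 5,
                 dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:5)))
  P <- rdirichlet(5, rep(1, 5))
  dimnames(P) <- list(colnames(bulk), sprintf("T%d", 1:5))
  expect_error(impute_celltype_expression(bulk, proportion_table(P)),
               "under-determined")
})

test_that("a planted one-type activation surfaces only in that type", {
  ref <- memo("imp_ref4", generate_reference(reference_spec(
    n_cell_types = 4, n_genes = 400, cells_per_type = 30,
    markers_per_type = 20, seed = 4)))
  set.seed(5)
  act_genes <- sample(ref$gene_ids, 30)
  coh <- generate_cohort(ref, cohort_spec(
    n_samples_per_group = 60, n_subtypes = 1,
    subtype_pathway_genes = list(list(cell_type = "T2", genes = act_genes,
                                      log2fc = 1)),
    noise_log_sd = 0.2, platform_bias_sd = 0, seed = 301))
  cube <- impute_celltype_expression(coh$bulk, coh$true_proportions)
  res <- compare_celltype_activation(cube, act_genes, coh$group)
  expect_lt(res$p[res$cell_type == "T2"], 0.01)
  expect_true(all(res$p[res$cell_type != "T2"] > 0.05))
  # rank-based pathway scores on the imputed profiles agree
  sl <- cube[, "T2", ]
  sc <- aucell_scores(sl[stats::complete.cases(sl), ], list(act = act_genes),
                      top_fraction = 0.1)
  expect_lt(compare_groups(sc[, 1], coh$group)$p.value, 0.01)
})

test_that("low-abundance types are masked as missing", {
  bulk <- matrix(rexp(100, 0.01), 10, 10,
                 dimnames = list(sprintf("g%d", 1:10), sprintf("s%d", 1:10)))
  P <- matrix(rep(c(0.999, 0.001, 0), each = 10), nrow = 10,
              dimnames = list(colnames(bulk), c("big", "tiny", "zero")))
  cube <- impute_celltype_expression(bulk, proportion_table(P))
  expect_true(all(is.na(cube[, "tiny", ])))
  expect_true(all(is.na(cube[, "zero", ])))
  expect_false(anyNA(cube[, "big", ]))
})

test_that("marker enrichment lights up the diagonal on a faithful cube", {
  # hand-built cube: markers of each type are that profile's unique maxima
  genes <- sprintf("g%02d", 1:30)
  types <- c("A", "B", "C")
  markers <- list(A = genes[1:5], B = genes[6:10], C = genes[11:15])
  cube <- array(1, dim = c(30, 3, 4),
                dimnames = list(genes, types, sprintf("s%d", 1:4)))
  for (i in seq_along(types)) {
    cube[markers[[i]], i, ] <- 10
  }
  class(cube) <- "celltype_cube"
  heat <- validate_marker_enrichment(cube, markers)
  for (t in types) {
    expect_equal(names(which.max(heat[t, ])), t)
  }
  raw <- attr(heat, "raw_p")
  expect_true(all(diag(raw) < 0.01))
})

test_that("identical profiles carry no between-type contrast", {
  set.seed(64)
  genes <- sprintf("g%02d", 1:20)
  cube <- array(rep(rexp(20), times = 6), dim = c(20, 3, 2),
                dimnames = list(genes, c("A", "B", "C"), c("s1", "s2")))
  class(cube) <- "celltype_cube"
  heat <- validate_marker_enrichment(cube, list(A = genes[1:4], B = genes[5:8],
                                                C = genes[9:12]))
  raw <- attr(heat, "raw_p")
  # every marker set scores identically in every (identical) profile
  for (j in seq_len(ncol(raw))) {
    expect_equal(max(raw[, j]) - min(raw[, j]), 0)
  }
  # a single marker set leaves each row constant: scaling degenerates
  heat1 <- validate_marker_enrichment(cube, list(A = genes[1:4]))
  expect_true(all(heat1 == 0))
  expect_setequal(attr(heat1, "degenerate_rows"), c("A", "B", "C"))
})

test_that("null marker sets yield near-1 raw p-values", {
  set.seed(63)
  genes <- sprintf("g%02d", 1:50)
  cube <- array(rexp(50 * 2 * 3), dim = c(50, 2, 3),
                dimnames = list(genes, c("A", "B"), sprintf("s%d", 1:3)))
  # a set planted at the bottom of every profile
  cube[genes[1:5], , ] <- 1e-4
  class(cube) <- "celltype_cube"
  heat <- validate_marker_enrichment(cube, list(low = genes[1:5]))
  expect_true(all(attr(heat, "raw_p")[, "low"] > 0.9))
  expect_error(validate_marker_enrichment(cube, list(none = "nope")),
               "no genes")
})
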