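# Synthetic-data generators: planted-marker recovery, determinism,
# pseudo-bulk linearity, Dirichlet calibration, cohort structure.

test_that("planted markers carry the stated log2 fold change", {
  ref <- generate_reference(reference_spec(
    n_cell_types = 3, n_genes = 200, cells_per_type = 50,
    markers_per_type = 10, marker_log2fc = 3, seed = 1))
  expect_equal(dim(ref$counts), c(150, 200))
  st <- compute_marker_stats(ref)
  planted <- attr(ref, "planted_markers")
  for (t in names(planted)) {
    lf <- st[planted[[t]], ]
    expect_true(all(abs(lf$logFC - 3) < 0.5))
    expect_true(all(lf$top_type == t))
  }
})

test_that("zero marker effect yields no selectable marker", {
  ref <- generate_reference(reference_spec(
    n_cell_types = 3, n_genes = 200, cells_per_type = 50,
    markers_per_type = 10, marker_log2fc = 0, seed = 1))
  st <- compute_marker_stats(ref)
  expect_lt(max(st$logFC), 1)
  expect_error(select_markers(st), "no marker gene survives")
})

test_that("generation is deterministic given the spec seed", {
  spec <- reference_spec(n_cell_types = 2, n_genes = 80, cells_per_type = 10,
                         markers_per_type = 5, seed = 7)
  r1 <- generate_reference(spec)
  r2 <- generate_reference(spec)
  expect_identical(r1$counts, r2$counts)
  ref <- small_reference()
  m1 <- generate_mixtures(ref, 5, seed = 3)
  m2 <- generate_mixtures(ref, 5, seed = 3)
  expect_identical(m1$bulk, m2$bulk)
})

test_that("infeasible reference specs are rejected", {
  expect_error(reference_spec(n_cell_types = 5, n_genes = 20,
                              markers_per_type = 10), "infeasible")
  expect_error(reference_spec(dropout_rate = 1.5), "dropout")
  expect_error(reference_spec(n_cell_types = 1), "two cell types")
})

test_that("noiseless mixtures are exactly linear in the proportions", {
  ref <- small_reference()
  M <- celltype_mean_cpm(ref)
  K <- ncol(M)
  # vertex case: a one-hot proportion row reproduces the type profile
  P <- matrix(0, 3, K, dimnames = list(NULL, colnames(M)))
  P[1, 1] <- 1; P[2, 3] <- 1; P[3, K] <- 1
  mix <- generate_mixtures(ref, 3, noise_log_sd = 0, seed = 5, proportions = P)
  expect_equal(unname(mix$bulk[, 1]), unname(M[, 1]))
  expect_equal(unname(mix$bulk[, 3]), unname(M[, K]))
  # general case: bulk = M p, recoverable by NNLS to <= 1e-6
  mix2 <- generate_mixtures(ref, 6, noise_log_sd = 0, seed = 6)
  for (s in 1:6) {
    p_hat <- nnls_solve(M, mix2$bulk[, s])
    expect_lt(max(abs(p_hat - unclass(mix2$proportions)[s, ])), 1e-6)
  }
})

test_that("Dirichlet mixing matches its theoretical mean", {
  ref <- memo("tiny_ref", generate_reference(reference_spec(
    n_cell_types = 3, n_genes = 60, cells_per_type = 8, markers_per_type = 5,
    seed = 9)))
  conc <- c(2, 5, 3)
  mix <- generate_mixtures(ref, 2000, concentration = conc,
                           noise_log_sd = 0, seed = 10)
  emp <- colMeans(unclass(mix$proportions))
  expect_true(all(abs(emp - conc / sum(conc)) < 0.02))
  expect_simplex(unclass(mix$proportions))
})

test_that("non-positive concentrations are rejected", {
  ref <- memo("tiny_ref", generate_reference(reference_spec(
    n_cell_types = 3, n_genes = 60, cells_per_type = 8, markers_per_type = 5,
    seed = 9)))
  expect_error(generate_mixtures(ref, 2, concentration = c(1, 0, 1)),
               "positive")
})

test_that("cohort invariants hold and planted shifts are realized", {
  ref <- memo("tiny_ref5", generate_reference(reference_spec(
    n_cell_types = 5, n_genes = 80, cells_per_type = 8, markers_per_type = 5,
    seed = 11)))
  coh <- generate_cohort(ref, cohort_spec(
    n_samples_per_group = 60,
    group_proportion_shift = c(T2 = 0.10),
    noise_log_sd = 0.1, seed = 12))
  expect_simplex(unclass(coh$true_proportions))
  expect_true(all(coh$bulk > 0))
  expect_false(anyNA(coh$clinical$group))
  P <- unclass(coh$true_proportions)
  d <- mean(P[coh$group == "case", "T2"]) - mean(P[coh$group == "control", "T2"])
  expect_lt(abs(d - 0.10), 0.04)
  # downstream test flags the shifted type
  tests <- compare_group_proportions(coh$true_proportions, coh$group)
  expect_lt(tests$p_adj[tests$cell_type == "T2"], 0.01)
})

test_that("an infeasible proportion shift raises a parameter error", {
  ref <- memo("tiny_ref5", generate_reference(reference_spec(
    n_cell_types = 5, n_genes = 80, cells_per_type = 8, markers_per_type = 5,
    seed = 11)))
  expect_error(
    generate_cohort(ref, cohort_spec(group_proportion_shift = c(T1 = 0.9),
                                     seed = 1)),
    "invalid case composition")
})

test_that("null clinical effects stay null under ANOVA", {
  ref <- memo("tiny_ref3", generate_reference(reference_spec(
    n_cell_types = 3, n_genes = 50, cells_per_type = 6, markers_per_type = 4,
    seed = 13)))
  hits <- vapply(1:100, function(r) {
    coh <- generate_cohort(ref, cohort_spec(
      n_samples_per_group = 15, n_subtypes = 3, clinical_effect_size = 0,
      noise_log_sd = 0.1, seed = 500 + r))
    case <- coh$group == "case"
    p <- summary(stats::aov(coh$clinical$num_planted_1[case] ~
                              factor(coh$subtype[case])))[[1]][["Pr(>F)"]][1]
    p < 0.05
  }, logical(1))
  expect_gte(mean(!hits), 0.90)
})

test_that("zero group shift yields no significant proportion difference", {
  ref <- memo("tiny_ref5", generate_reference(reference_spec(
    n_cell_types = 5, n_genes = 80, cells_per_type = 8, markers_per_type = 5,
    seed = 11)))
  coh <- generate_cohort(ref, cohort_spec(n_samples_per_group = 30,
                                          noise_log_sd = 0.1, seed = 19))
  tests <- compare_group_proportions(coh$true_proportions, coh$group)
  expect_true(all(tests$p_adj > 0.05))
})

test_that("reference round-trips through MTX + sidecars", {
  ref <- memo("tiny_ref", generate_reference(reference_spec(
    n_cell_types = 3, n_genes = 60, cells_per_type = 8, markers_per_type = 5,
    seed = 9)))
  dir <- withr::local_tempdir()
  write_reference_mtx(ref, dir)
  back <- read_reference_mtx(dir)
  expect_equal(unname(back$counts), unname(ref$counts))
  expect_identical(back$cell_types, ref$cell_types)
  expect_identical(back$gene_ids, ref$gene_ids)
})
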