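# Solvers: exact recovery on identity and noiseless mixtures, the
# clipping / normalization contract, oracle agreement for NNLS, and the
# cohort-level invariances.

test_that("identity mixing is recovered by every solver", {
  C <- diag(2)
  dimnames(C) <- list(c("g1", "g2"), c("X", "Y"))
  sig <- raw_signature(C)
  bulk <- c(g1 = 0.3, g2 = 0.7)
  for (m in c("ols", "nnls", "rlr", "dwls")) {
    fit <- deconvolve_sample(sig, bulk, m)
    expect_equal(unname(fit$proportions), c(0.3, 0.7), tolerance = 1e-6)
  }
  # nu-SVR is excluded here: on a 2-gene identity signature the constant
  # vector lies in the signature's column span, so the SVR intercept
  # absorbs the mean and only the proportion difference is identified.
  # Its recovery is asserted on full-rank signatures below.
})

test_that("nnls matches the exact solution and the simplex-grid oracle", {
  C <- matrix(c(1, 0, 1, 0, 1, 1), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("X", "Y")))
  sig <- raw_signature(C)
  fit <- deconvolve_sample(sig, c(g1 = 0.2, g2 = 0.8, g3 = 1.0), "nnls")
  expect_equal(unname(fit$proportions), c(0.2, 0.8), tolerance = 1e-6)
  # 3-type random problems vs the exhaustive grid
  set.seed(41)
  for (i in 1:5) {
    C3 <- matrix(rexp(18), ncol = 3,
                 dimnames = list(sprintf("g%d", 1:6), c("A", "B", "C")))
    p_true <- as.vector(rdirichlet(1, c(1, 1, 1)))
    y <- drop(C3 %*% p_true)
    p_hat <- deconvolve_sample(raw_signature(C3),
                               stats::setNames(y, rownames(C3)),
                               "nnls")$proportions
    p_grid <- grid_search_oracle(C3, y)
    p_grid <- p_grid / sum(p_grid)
    expect_lt(max(abs(p_hat - p_grid)), 2e-3)
  }
})

test_that("negative raw coefficients are clipped then renormalized", {
  C <- matrix(c(1, 0, 2, 0, 1, 3), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("X", "Y")))
  y <- drop(C %*% c(1, -1))   # OLS coefficients are exactly [1, -1]
  fit <- deconvolve_sample(raw_signature(C), stats::setNames(y, rownames(C)),
                           "ols")
  expect_equal(unname(fit$raw), c(1, -1), tolerance = 1e-9)
  expect_equal(unname(fit$proportions), c(1, 0))
})

test_that("an all-negative fit falls back to uniform with a warning", {
  C <- matrix(c(1, 2, 3, 2, 4, 6.1), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("X", "Y")))
  y <- c(g1 = -1, g2 = -2, g3 = -3)
  expect_warning(fit <- deconvolve_sample(raw_signature(C), y, "nnls"),
                 "uniform")
  expect_equal(unname(fit$proportions), c(0.5, 0.5))
})

test_that("a pure-type bulk profile is assigned to its type by nu-SVR", {
  sig <- small_signature()
  for (k in c(1, 3)) {
    bulk <- stats::setNames(sig$values[, k], sig$gene_ids)
    fit <- deconvolve_sample(sig, bulk, "nusvr")
    expect_gte(fit$proportions[k], 0.95)
  }
})

test_that("rank-deficient signatures error under OLS with a hint", {
  C <- matrix(c(1, 2, 3, 2, 4, 6), ncol = 2,
              dimnames = list(c("g1", "g2", "g3"), c("X", "Y")))
  expect_error(deconvolve_sample(raw_signature(C),
                                 c(g1 = 1, g2 = 2, g3 = 3), "ols"),
               "nnls")
})

test_that("too few shared genes is an error", {
  sig <- small_signature()
  bulk <- stats::setNames(rexp(3), sig$gene_ids[1:3])
  expect_error(deconvolve_sample(sig, bulk, "nnls"), "shared genes")
})

test_that("noiseless cohorts are recovered almost exactly by all solvers", {
  ref <- small_reference()
  sig <- small_signature()
  mix <- generate_mixtures(ref, 12, noise_log_sd = 0, seed = 31)
  for (m in c("nnls", "ols", "rlr", "dwls")) {
    est <- deconvolve_cohort(sig, mix$bulk, m)
    expect_simplex(unclass(est))
    expect_lt(max(abs(unclass(est) - unclass(mix$proportions))), 1e-4)
  }
  est <- deconvolve_cohort(sig, mix$bulk, "nusvr")
  expect_lt(max(abs(unclass(est) - unclass(mix$proportions))), 0.02)
})

test_that("scaling and gene order do not change the estimates", {
  sig <- small_signature()
  mix <- memo("mix_noisy", generate_mixtures(small_reference(), 6,
                                             noise_log_sd = 0.2, seed = 32))
  for (m in c("nnls", "ols", "rlr")) {
    base <- deconvolve_cohort(sig, mix$bulk, m)
    scaled <- deconvolve_cohort(sig, mix$bulk * 1000, m)
    expect_equal(pt_values(base), pt_values(scaled), tolerance = 1e-5)
  }
  set.seed(33)
  perm <- sample(nrow(mix$bulk))
  shuffled <- deconvolve_cohort(sig, mix$bulk[perm, ], "nnls")
  expect_equal(pt_values(deconvolve_cohort(sig, mix$bulk, "nnls")),
               pt_values(shuffled), tolerance = 1e-10)
})

test_that("duplicated bulk gene ids are collapsed by mean with a warning", {
  sig <- small_signature()
  mix <- memo("mix_noisy", generate_mixtures(small_reference(), 6,
                                             noise_log_sd = 0.2, seed = 32))
  dup <- rbind(mix$bulk, mix$bulk[1:5, ])
  expect_warning(est <- deconvolve_cohort(sig, dup, "nnls"), "collapsed")
  expect_equal(pt_values(est),
               pt_values(deconvolve_cohort(sig, mix$bulk, "nnls")),
               tolerance = 1e-10)
})

test_that("solver configuration is validated", {
  expect_error(solver_config("nusvr", nu_grid = c(0, 0.5)), "nu_grid")
  expect_error(solver_config("rlr", huber_k = -1), "huber_k")
  expect_error(solver_config("bogus"), "arg")
})

test_that("proportion tables enforce the simplex and round-trip as TSV", {
  expect_error(proportion_table(matrix(c(0.6, 0.6), 1)), "sum to 1")
  expect_error(proportion_table(matrix(c(-0.2, 1.2), 1)), "non-negative")
  p <- proportion_table(matrix(c(0.25, 0.75, 0.5, 0.5), 2, byrow = TRUE,
                               dimnames = list(c("s1", "s2"), c("X", "Y"))),
                        method = "demo")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_proportions_tsv(p, path)
  back <- read_proportions_tsv(path)
  expect_equal(pt_values(back), pt_values(p), tolerance = 1e-12)
})
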