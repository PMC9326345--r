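# Marker statistics, threshold selection, signature construction and
# fraction subsetting, checked against hand-computed values on a
# reference whose CPM values are exact.

worked_ref <- function() {
  # per-type mean CPM: g1 = [8,2,2], g2 = [5,5,5], g3 = [10,0,0]
  exact_cpm_reference(list(
    A = c(g1 = 8, g2 = 5, g3 = 10),
    B = c(g1 = 2, g2 = 5, g3 = 0),
    C = c(g1 = 2, g2 = 5, g3 = 0)))
}

test_that("marker statistics match the closed-form worked examples", {
  st <- compute_marker_stats(worked_ref())
  expect_equal(st["g1", "logFC"], log2(9 / 3))
  expect_equal(st["g1", "SecondFC"], 3)
  expect_equal(st["g1", "logCPM"], log2(5))
  expect_equal(st["g1", "top_type"], "A")
  expect_equal(st["g2", "logFC"], 0)
  expect_equal(st["g2", "SecondFC"], 1)
  expect_equal(st["g3", "logFC"], log2(11))
  expect_equal(st["g3", "SecondFC"], 11)
  expect_true(all(st$SecondFC >= 1))
  expect_true(all(st$frac_expressed_in_top >= 0 & st$frac_expressed_in_top <= 1))
})

test_that("a single cell type has no marker contrast", {
  ref <- exact_cpm_reference(list(A = c(g1 = 5, g2 = 3)))
  expect_error(compute_marker_stats(ref), "two cell types")
})

test_that("the four-threshold rule selects exactly the qualifying genes", {
  st <- compute_marker_stats(worked_ref())
  sel <- suppressWarnings(
    select_markers(st, logfc_min = 1, logcpm_min = 1, secondfc_min = 1.5,
                   min_frac_expressed = 0))
  expect_setequal(unlist(sel, use.names = FALSE), c("g1", "g3"))
  expect_true(all(c("g1", "g3") %in% sel$A))
  # degenerate threshold empties the selection
  expect_error(select_markers(st, secondfc_min = Inf), "no marker gene")
  # vacuous thresholds keep every gene with a unique maximum
  sel_all <- suppressWarnings(
    select_markers(st, logfc_min = 0, logcpm_min = -Inf, secondfc_min = 1,
                   min_frac_expressed = 0))
  kept <- unlist(sel_all, use.names = FALSE)
  expect_true(all(c("g1", "g3") %in% kept))
})

test_that("raising the SecondFC threshold never enlarges the marker set", {
  ref <- small_reference()
  st <- compute_marker_stats(ref)
  sizes <- vapply(c(1, 1.5, 2, 3, 4), function(th) {
    sel <- tryCatch(suppressWarnings(select_markers(st, secondfc_min = th)),
                    error = function(e) list())
    sum(lengths(sel))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("signature entries are per-type mean CPM values", {
  # two cells of type A with CPM 2 and 4 for gene g -> entry 3
  ref <- exact_cpm_reference(list(
    A = list(c(g = 2, h = 10), c(g = 4, h = 10)),
    B = list(c(g = 1, h = 3), c(g = 1, h = 3))), cells_per_type = 2)
  sig <- build_signature(ref, list(A = "g", B = "h"))
  expect_equal(sig$values["g", "A"], 3)
  expect_equal(sig$values["h", "B"], 3)
  # a single cell per type reproduces that cell's CPM row
  ref1 <- exact_cpm_reference(list(A = c(g = 7, h = 1), B = c(g = 2, h = 9)))
  sig1 <- build_signature(ref1, c("g", "h"))
  expect_equal(unname(sig1$values["g", ]), c(7, 2))
  expect_error(build_signature(ref1, c("g", "nope")), "nope")
})

test_that("planted markers are assigned to their planted types", {
  ref <- generate_reference(reference_spec(
    n_cell_types = 3, n_genes = 200, cells_per_type = 50,
    markers_per_type = 10, marker_log2fc = 3, seed = 1))
  st <- compute_marker_stats(ref)
  sel <- select_markers(st)
  planted <- attr(ref, "planted_markers")
  recovered <- 0
  for (t in names(planted)) {
    recovered <- recovered + sum(planted[[t]] %in% sel[[t]])
  }
  expect_gte(recovered / sum(lengths(planted)), 0.90)
  sig <- build_signature(ref, sel, stats = st)
  for (t in names(planted)) {
    hit <- intersect(planted[[t]], sig$gene_ids)
    expect_true(all(colnames(sig$values)[max.col(sig$values[hit, , drop = FALSE])] == t))
  }
})

test_that("average between-type correlation follows hand arithmetic", {
  # identical columns correlate perfectly
  v <- matrix(c(1, 5, 3, 1, 5, 3), ncol = 2,
              dimnames = list(c("a", "b", "c"), c("X", "Y")))
  expect_equal(avg_celltype_correlation(raw_signature(v)), 1)
  # 3x3 identity: every pair correlates at -1/2
  id3 <- diag(3)
  dimnames(id3) <- list(c("a", "b", "c"), c("X", "Y", "Z"))
  expect_equal(avg_celltype_correlation(raw_signature(id3)), -0.5)
  # disjoint equal-magnitude support: negative mean correlation
  blocks <- rbind(c(4, 0), c(4, 0), c(0, 4), c(0, 4))
  dimnames(blocks) <- list(letters[1:4], c("X", "Y"))
  expect_lt(avg_celltype_correlation(raw_signature(blocks)), 0)
  # constant columns are excluded; all-undefined errors
  cst <- matrix(1, 3, 2, dimnames = list(letters[1:3], c("X", "Y")))
  expect_error(avg_celltype_correlation(raw_signature(cst)), "undefined")
})

test_that("the SecondFC scan chooses a plateau threshold and decorrelates", {
  ref <- small_reference()
  scan <- suppressWarnings(choose_secondfc_threshold(
    ref, candidate_thresholds = seq(1, 4, by = 0.5)))
  expect_true(scan$chosen_threshold %in% scan$thresholds)
  expect_true(all(scan$avg_correlation >= -1 & scan$avg_correlation <= 1))
  # empirically non-increasing correlation as the threshold rises
  expect_true(all(diff(scan$avg_correlation) <= 0.02))
})

test_that("fraction subsetting keeps the per-type logFC top and the identity", {
  sig <- small_signature()
  expect_identical(subset_top_fraction(sig, 1)$gene_ids, sig$gene_ids)
  # ceiling rule on a hand-built signature with 10 markers in one type
  v <- matrix(rep(c(5, 1), each = 12), ncol = 2,
              dimnames = list(sprintf("g%02d", 1:12), c("X", "Y")))
  lf <- stats::setNames(c(12:3, 2, 1), rownames(v))
  tt <- stats::setNames(c(rep("X", 10), "Y", "Y"), rownames(v))
  s <- raw_signature(v, logfc = lf, top_type = tt)
  sub <- subset_top_fraction(s, 0.25)
  expect_equal(sum(sub$top_type == "X"), 3)   # ceil(0.25 * 10)
  expect_equal(sum(sub$top_type == "Y"), 1)   # ceil(0.25 * 2)
  # brute-force oracle: the kept set is the per-type sorted top half
  sub5 <- subset_top_fraction(sig, 0.5)
  for (t in unique(sig$top_type)) {
    genes <- names(sig$top_type)[sig$top_type == t]
    ord <- genes[order(-sig$logfc[genes], genes)]
    want <- ord[seq_len(ceiling(0.5 * length(genes)))]
    expect_setequal(names(sub5$top_type)[sub5$top_type == t], want)
  }
  expect_error(subset_top_fraction(sig, 0), "fraction")
})

test_that("signature TSV round-trips", {
  sig <- small_signature()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature_tsv(sig, path)
  back <- read_signature_tsv(path)
  expect_equal(back$values, sig$values, tolerance = 1e-12)
  expect_equal(back$logfc, sig$logfc, tolerance = 1e-12)
  expect_identical(unname(back$top_type), unname(sig$top_type))
})
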