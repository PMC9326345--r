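# Shared fixtures. Everything is generated in code; heavier objects are
# built once per test run and memoised in the helper environment.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

# A reference whose per-type mean CPM values are known exactly: every cell
# has total counts 1e6, so CPM equals the raw counts.
exact_cpm_reference <- function(profiles, cells_per_type = 1) {
  # profiles: named list cell type -> named numeric vector of CPM values;
  # a filler gene absorbs the remaining depth
  types <- names(profiles)
  genes <- names(profiles[[1]])
  rows <- list()
  labels <- character(0)
  for (t in types) {
    for (i in seq_len(cells_per_type)) {
      v <- profiles[[t]]
      if (is.list(v)) v <- v[[i]]          # per-cell values when a list
      counts <- c(v, filler = 1e6 - sum(v))
      rows[[length(rows) + 1]] <- counts
      labels <- c(labels, t)
    }
  }
  counts <- do.call(rbind, rows)
  storage.mode(counts) <- "integer"
  rownames(counts) <- sprintf("cell%02d", seq_len(nrow(counts)))
  structure(list(counts = counts, cell_types = labels,
                 gene_ids = colnames(counts)),
            class = "sc_reference")
}

# small generated reference shared by several module tests
small_reference <- function() {
  memo("small_ref", generate_reference(
    reference_spec(n_cell_types = 5, n_genes = 600, cells_per_type = 40,
                   markers_per_type = 25, marker_log2fc = 3, seed = 2)))
}

small_signature <- function() {
  memo("small_sig", {
    ref <- small_reference()
    st <- compute_marker_stats(ref)
    build_signature(ref, select_markers(st), stats = st)
  })
}

# hand-rolled signature_matrix for solver unit tests
raw_signature <- function(values, logfc = NULL, top_type = NULL) {
  genes <- rownames(values)
  if (is.null(logfc)) logfc <- stats::setNames(rev(seq_along(genes)), genes)
  if (is.null(top_type)) {
    top_type <- stats::setNames(
      rep_len(colnames(values), length(genes)), genes)
  }
  structure(list(values = values, gene_ids = genes,
                 cell_types = colnames(values), logfc = logfc,
                 top_type = top_type),
            class = "signature_matrix")
}

# independent simplex-grid oracle for 3-type NNLS problems (step on the
# first two coordinates; third is the complement)
grid_search_oracle <- function(C, y, step = 1e-3) {
  g <- seq(0, 1, by = step)
  grid <- expand.grid(p1 = g, p2 = g)
  grid <- grid[grid$p1 + grid$p2 <= 1 + 1e-12, ]
  P <- cbind(grid$p1, grid$p2, 1 - grid$p1 - grid$p2)
  A <- crossprod(C)
  b2 <- drop(crossprod(C, y))
  # ||y - Cp||^2 = p'Ap - 2 b2'p + const
  score <- rowSums((P %*% A) * P) - 2 * drop(P %*% b2)
  P[which.min(score), ]
}

# independent brute-force recovery-curve integration for the AUCell score
aucell_oracle <- function(expr, set_genes, top_fraction) {
  G <- length(expr)
  ord <- names(expr)[order(-expr, names(expr))]
  n_max <- ceiling(top_fraction * G)
  present <- intersect(set_genes, names(expr))
  total <- 0
  for (i in seq_len(n_max)) {
    total <- total + sum(ord[seq_len(i)] %in% present)
  }
  total / (n_max * min(length(present), n_max))
}

expect_simplex <- function(props, tol = 1e-9) {
  expect_true(all(props >= -1e-12))
  expect_lt(max(abs(rowSums(props) - 1)), tol)
}

# proportion-table values stripped of method/raw attributes for comparison
pt_values <- function(p) {
  matrix(as.numeric(p), nrow(p), ncol(p), dimnames = dimnames(p))
}
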