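# Small shared numerical helpers.

#' Counts-per-million normalization of a cells x genes count matrix
#'
#' Each cell (row) is scaled to a library size of one million. Cells with
#' zero total counts are left as all-zero rows.
#'
#' @param counts non-negative cells x genes matrix
#' @return matrix of the same shape on the CPM scale
#' @keywords internal
cpm_normalize <- function(counts) {
  depth <- rowSums(counts)
  depth[depth == 0] <- 1
  counts / depth * 1e6
}

#' Dirichlet sampler
#'
#' @param n number of draws
#' @param alpha strictly positive concentration vector
#' @return n x length(alpha) matrix, rows on the simplex
#' @keywords internal
rdirichlet <- function(n, alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("Dirichlet concentration parameters must be strictly positive")
  }
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  sums <- rowSums(g)
  zero <- sums == 0          # numerically possible for very small alpha
  if (any(zero)) {
    g[zero, ] <- 1 / k
    sums[zero] <- 1
  }
  g / sums
}

#' Lawson-Hanson non-negative least squares
#'
#' Solves min ||A x - b||_2 subject to x >= 0 by the classical active-set
#' algorithm on the normal equations. Intended for the small systems that
#' arise in deconvolution (a handful of cell types).
#'
#' @param A design matrix (m x n)
#' @param b response vector (length m)
#' @param tol tolerance for dual feasibility and the zero test
#' @return non-negative coefficient vector of length ncol(A)
#' @export
nnls_solve <- function(A, b, tol = 1e-10) {
  A <- as.matrix(A)
  n <- ncol(A)
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  x <- numeric(n)
  passive <- logical(n)
  w <- Atb
  outer_max <- 10L * n + 10L
  it <- 0L
  while (any(!passive) && any(w[!passive] > tol) && it < outer_max) {
    it <- it + 1L
    cand <- which(!passive)
    j <- cand[which.max(w[cand])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      p <- which(passive)
      sub <- AtA[p, p, drop = FALSE]
      s[p] <- tryCatch(
        solve(sub, Atb[p]),
        error = function(e) {
          ridge <- 1e-10 * max(diag(sub), 1e-300)
          solve(sub + diag(ridge, length(p)), Atb[p])
        }
      )
      if (all(s[p] > tol)) {
        x <- s
        break
      }
      neg <- passive & s <= tol
      alpha <- min(x[neg] / (x[neg] - s[neg]))
      x <- x + alpha * (s - x)
      passive <- passive & x > tol
      x[!passive] <- 0
    }
    w <- Atb - drop(AtA %*% x)
  }
  x
}

#' Rank-based area under the ROC curve
#'
#' @param scores numeric decision values
#' @param positive logical vector, TRUE for the positive class
#' @return AUC in [0, 1]
#' @keywords internal
rank_auc <- function(scores, positive) {
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) stop("both classes needed to compute an AUC")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b cluster label vectors of equal length
#' @return ARI in [-1, 1]; 1 means identical partitions up to renaming
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' Vectorized Welch two-sample t-test on matrix rows
#'
#' @param x matrix (features x samples)
#' @param idx1,idx2 column indices of the two groups
#' @return data.frame with statistic, df and two-sided p per row
#' @keywords internal
row_welch_t <- function(x, idx1, idx2) {
  n1 <- length(idx1); n2 <- length(idx2)
  m1 <- rowMeans(x[, idx1, drop = FALSE])
  m2 <- rowMeans(x[, idx2, drop = FALSE])
  v1 <- rowSums((x[, idx1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((x[, idx2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  stat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(stat), df)
  # zero-variance rows: identical values -> no evidence; distinct means -> certain
  degenerate <- se2 == 0
  if (any(degenerate)) {
    p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
    stat[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 0, Inf)
    df[degenerate] <- n1 + n2 - 2
  }
  data.frame(statistic = stat, df = df, p = p, row.names = rownames(x))
}

# drop-in check used across constructors
.assert <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)
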