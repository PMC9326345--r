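# Proportion estimation: fit bulk ~ C p per sample under five solvers
# (OLS, NNLS, Huber robust regression, linear nu-SVR, dampened weighted
# least squares), then clip negatives and renormalize onto the simplex.

#' Construct a proportion table
#'
#' @param values samples x cell types matrix, non-negative, rows summing
#'   to 1 (within 1e-9)
#' @param method name of the producing method
#' @param raw optional matrix of raw (pre-clipping) coefficients
#' @return matrix of class `proportion_table` with attributes `method` and
#'   `raw`
#' @export
proportion_table <- function(values, method = "unknown", raw = NULL) {
  values <- as.matrix(values)
  .assert(all(values >= -1e-12), "proportions must be non-negative")
  .assert(max(abs(rowSums(values) - 1)) < 1e-9, "rows must sum to 1")
  structure(values, class = c("proportion_table", class(values)),
            method = method, raw = raw)
}

#' @export
print.proportion_table <- function(x, ...) {
  cat(sprintf("proportion table (%s): %d samples x %d cell types\n",
              attr(x, "method"), nrow(x), ncol(x)))
  print(utils::head(unclass(x), 5))
  invisible(x)
}

#' Solver configuration for deconvolution
#'
#' @param method one of `"nnls"`, `"ols"`, `"rlr"`, `"nusvr"`, `"dwls"`
#' @param nu_grid nu candidates for nu-SVR, all in (0, 1); the fit with
#'   the lowest reconstruction RMSE is kept
#' @param svr_cost regularization cost of the nu-SVR (linear kernel)
#' @param huber_k Huber tuning constant of the robust regression
#' @param dwls_damping_grid candidate weight-ratio caps for dampened WLS
#' @param standardize z-score signature columns and bulk vector before the
#'   nu-SVR fit (defaults to TRUE for nusvr, ignored otherwise)
#' @return object of class `solver_config`
#' @export
solver_config <- function(method = c("nnls", "ols", "rlr", "nusvr", "dwls"),
                          nu_grid = c(0.25, 0.5, 0.75), svr_cost = 1,
                          huber_k = 1.345, dwls_damping_grid = 2^(0:5),
                          standardize = TRUE) {
  method <- match.arg(method)
  .assert(all(nu_grid > 0 & nu_grid < 1), "nu_grid must lie in (0,1)")
  .assert(huber_k > 0, "huber_k must be positive")
  structure(list(method = method, nu_grid = nu_grid, svr_cost = svr_cost,
                 huber_k = huber_k, dwls_damping_grid = dwls_damping_grid,
                 standardize = standardize),
            class = "solver_config")
}

# ---- individual solvers (raw coefficients, no simplex projection) --------

.solve_ols <- function(C, y) {
  qr_C <- qr(C)
  if (qr_C$rank < ncol(C)) {
    stop("signature matrix is rank-deficient for OLS; consider nnls")
  }
  drop(qr.coef(qr_C, y))
}

# Huber M-estimation by iteratively reweighted least squares; the scale is
# re-estimated each iteration from the median absolute residual.
.solve_rlr <- function(C, y, k = 1.345, tol = 1e-6, max_iter = 100) {
  beta <- tryCatch(.solve_ols(C, y), error = function(e) nnls_solve(C, y))
  for (i in seq_len(max_iter)) {
    r <- y - drop(C %*% beta)
    s <- stats::median(abs(r)) / 0.6745
    if (!is.finite(s) || s < 1e-10) break
    w <- pmin(1, k * s / pmax(abs(r), 1e-300))
    sw <- sqrt(w)
    beta_new <- tryCatch(drop(qr.coef(qr(C * sw), y * sw)),
                         error = function(e) beta)
    if (anyNA(beta_new)) beta_new[is.na(beta_new)] <- 0
    if (max(abs(beta_new - beta)) < tol * max(1, max(abs(beta)))) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  beta
}

# Smoothed plus-function (Huberized hinge) used to make the nu-SVR primal
# differentiable; delta is the smoothing half-width.
.splus <- function(x, delta) {
  ifelse(x <= 0, 0, ifelse(x >= delta, x - delta / 2, x^2 / (2 * delta)))
}
.splus_grad <- function(x, delta) {
  ifelse(x <= 0, 0, ifelse(x >= delta, 1, x / delta))
}

# Linear nu-SVR solved in the primal over (w, b, eps): the problem has only
# K + 2 unknowns (one weight per cell type), so a quasi-Newton solve of the
# smoothed objective is fast and deterministic. The data term uses the
# libsvm scaling, 0.5 w'w + C (nu l eps + sum_i xi_i), so with hundreds of
# genes the loss dominates the regularizer and a noiseless linear mixture
# is recovered essentially exactly.
.fit_nusvr_once <- function(X, y, nu, cost, delta = 1e-3) {
  l <- nrow(X); K <- ncol(X)
  obj <- function(theta) {
    w <- theta[1:K]; b <- theta[K + 1]; eps <- theta[K + 2]
    r <- y - drop(X %*% w) - b
    e <- abs(r) - eps
    0.5 * sum(w^2) + cost * (nu * l * eps + sum(.splus(e, delta)))
  }
  grad <- function(theta) {
    w <- theta[1:K]; b <- theta[K + 1]; eps <- theta[K + 2]
    r <- y - drop(X %*% w) - b
    e <- abs(r) - eps
    g <- .splus_grad(e, delta)
    sg <- g * sign(r)
    c(w - cost * drop(crossprod(X, sg)),
      -cost * sum(sg),
      cost * nu * l - cost * sum(g))
  }
  theta0 <- c(numeric(K), 0, 0.01)
  fit <- stats::optim(theta0, obj, grad, method = "L-BFGS-B",
                      lower = c(rep(-Inf, K + 1), 0),
                      control = list(maxit = 500, factr = 1e7))
  list(w = fit$par[1:K], b = fit$par[K + 1], eps = fit$par[K + 2])
}

.solve_nusvr <- function(C, y, nu_grid, cost = 1, standardize = TRUE) {
  X <- C
  yy <- y
  if (standardize) {
    # one global center/scale for the whole signature (not per column):
    # a shared affine map keeps the fitted weights proportional to the
    # mixing proportions, which per-column scaling would distort
    sx <- stats::sd(as.vector(C))
    X <- (C - mean(C)) / (if (sx == 0) 1 else sx)
    sy <- stats::sd(y)
    yy <- if (sy == 0) y - mean(y) else (y - mean(y)) / sy
  }
  best <- NULL
  best_rmse <- Inf
  for (nu in nu_grid) {
    fit <- .fit_nusvr_once(X, yy, nu, cost)
    rmse <- sqrt(mean((yy - drop(X %*% fit$w) - fit$b)^2))
    if (rmse < best_rmse) {
      best_rmse <- rmse
      best <- fit
    }
  }
  best$w
}

# Dampened weighted least squares: iterate non-negative WLS with weights
# 1 / max(C p, delta)^2, weight ratios capped at the damping constant; the
# damping is picked by minimum (unweighted) reconstruction error.
.solve_dwls <- function(C, y, damping_grid = 2^(0:5), delta = 1e-6,
                        tol = 1e-6, max_iter = 100) {
  p0 <- nnls_solve(C, y)
  best <- p0
  best_err <- Inf
  for (d in damping_grid) {
    p <- p0
    for (i in seq_len(max_iter)) {
      fit <- drop(C %*% p)
      w <- 1 / pmax(fit, delta)^2
      w <- pmin(w / min(w), d)
      sw <- sqrt(w)
      p_new <- nnls_solve(C * sw, y * sw)
      if (max(abs(p_new - p)) < tol * max(1, max(abs(p)))) {
        p <- p_new
        break
      }
      p <- p_new
    }
    err <- sqrt(mean((y - drop(C %*% p))^2))
    if (err < best_err) {
      best_err <- err
      best <- p
    }
  }
  best
}

# ---- public API ----------------------------------------------------------

#' Estimate cell-type proportions for one bulk profile
#'
#' Genes are matched by exact id intersection between the signature and the
#' (named) bulk vector; duplicated bulk ids are collapsed by mean with a
#' warning. Raw solver coefficients are clipped at zero and renormalized to
#' the simplex; an all-zero raw vector falls back to uniform proportions
#' with a warning.
#'
#' @param sig a `signature_matrix`
#' @param bulk_column named numeric vector of bulk expression
#' @param cfg a [solver_config()] (or a method name)
#' @return list with `proportions` (named, on the simplex) and `raw`
#' @export
deconvolve_sample <- function(sig, bulk_column, cfg = solver_config("nnls")) {
  stopifnot(inherits(sig, "signature_matrix"))
  if (is.character(cfg)) cfg <- solver_config(cfg)
  .assert(!is.null(names(bulk_column)), "bulk vector must be named by gene id")
  if (anyDuplicated(names(bulk_column))) {
    warning("duplicated gene ids in bulk collapsed by mean")
    bulk_column <- tapply(bulk_column, names(bulk_column), mean)
  }
  shared <- intersect(sig$gene_ids, names(bulk_column))
  K <- length(sig$cell_types)
  if (length(shared) < K) {
    stop(sprintf("only %d shared genes for %d cell types", length(shared), K))
  }
  C <- sig$values[shared, , drop = FALSE]
  y <- as.numeric(bulk_column[shared])
  raw <- switch(cfg$method,
    ols = .solve_ols(C, y),
    nnls = nnls_solve(C, y),
    rlr = .solve_rlr(C, y, k = cfg$huber_k),
    nusvr = .solve_nusvr(C, y, cfg$nu_grid, cfg$svr_cost, cfg$standardize),
    dwls = .solve_dwls(C, y, cfg$dwls_damping_grid)
  )
  names(raw) <- sig$cell_types
  p <- pmax(raw, 0)
  if (sum(p) == 0) {
    warning("all raw coefficients non-positive; returning uniform proportions")
    p <- rep(1 / K, K)
    names(p) <- sig$cell_types
  } else {
    p <- p / sum(p)
  }
  list(proportions = p, raw = raw)
}

#' Estimate cell-type proportions for a bulk cohort
#'
#' Column-wise application of [deconvolve_sample()]; deterministic given
#' its inputs (no solver uses random initialization).
#'
#' @param sig a `signature_matrix`
#' @param bulk genes x samples matrix with gene-id rownames
#' @param cfg a [solver_config()] or method name
#' @return a [proportion_table()] (attribute `raw` holds the unclipped
#'   coefficients)
#' @export
deconvolve_cohort <- function(sig, bulk, cfg = solver_config("nnls")) {
  if (is.character(cfg)) cfg <- solver_config(cfg)
  bulk <- as.matrix(bulk)
  .assert(ncol(bulk) >= 1, "need at least one sample")
  .assert(!is.null(rownames(bulk)), "bulk must have gene-id rownames")
  if (anyDuplicated(rownames(bulk))) {
    warning("duplicated gene ids in bulk collapsed by mean")
    bulk <- rowsum(bulk, rownames(bulk)) /
      as.vector(table(rownames(bulk))[sort(unique(rownames(bulk)))])
  }
  samples <- colnames(bulk)
  if (is.null(samples)) samples <- sprintf("s%04d", seq_len(ncol(bulk)))
  P <- matrix(NA_real_, nrow = ncol(bulk), ncol = length(sig$cell_types),
              dimnames = list(samples, sig$cell_types))
  R <- P
  for (s in seq_len(ncol(bulk))) {
    fit <- tryCatch(
      deconvolve_sample(sig, stats::setNames(bulk[, s], rownames(bulk)), cfg),
      error = function(e) stop(sprintf("sample '%s': %s", samples[s],
                                       conditionMessage(e)), call. = FALSE))
    P[s, ] <- fit$proportions
    R[s, ] <- fit$raw
  }
  proportion_table(P, method = cfg$method, raw = R)
}
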