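---
title: "Methods: reference-based deconvolution, cell-type-level imputation and subtype discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-based deconvolution, cell-type-level imputation and subtype discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(bulkdecon)
```

# The problem

Bulk expression profiles of a heterogeneous tissue — a placenta biopsy on a
microarray, say — mix the transcriptomes of many cell types in unknown
proportions. Given a labeled single-cell reference of the same tissue,
reference-based deconvolution models each bulk profile as

$$ T \approx C\,P, $$

with $C$ the *signature gene matrix* (marker genes × cell types, mean
reference expression) and $P$ the per-sample mixing proportions on the
simplex. bulkdecon implements the full workflow around this model: signature
construction, several proportion solvers, an evaluation harness with known
ground truth, per-sample cell-type-level expression imputation, rank-based
pathway activity, a linear-SVM case/control classifier, NMF consensus
subtyping, and cluster–clinical association tests. A synthetic-data module
generates all inputs with planted truth so every stage is testable end to
end.

# Signature construction

Per gene, with per-type mean CPM profiles $m_t$ and pseudocount 1:

* **logFC** — log2 fold change of the top-expressing type over the mean of
  the others (cell-type specificity);
* **logCPM** — log2 mean expression across types (expression level);
* **SecondFC** — linear fold change of the top over the runner-up type
  (cell-type exclusivity);
* **fraction expressed** — share of the top type's cells with a non-zero
  count.

A marker passes if logFC ≥ 1, logCPM ≥ 1, SecondFC clears its threshold and
the gene is expressed in ≥30 % of the top type's cells. The pseudocount of 1
is our choice (it keeps SecondFC finite when the runner-up mean is zero), as
is CPM as the "normalized expression" (counts × 1e6 / cell depth).

The SecondFC threshold is data-driven: as it rises, the signature's columns
decorrelate and then plateau. `choose_secondfc_threshold()` scans a
candidate grid (default 1–8 by 0.5, covering both a placenta-like 1.5 and a
blood-panel-like ≥6) and picks the smallest candidate whose forward decrease
in mean between-type correlation falls below `plateau_tol` (0.05). The
"inflection" is visual in the original procedure; the plateau rule is our
operationalization. Fraction subsetting (`subset_top_fraction()`) ranks
markers by logFC *within each cell type* and keeps the top `ceil(f · n)` —
per-type rather than global ranking so no type loses all its markers.

# Proportion solvers

All five solvers fit one bulk column against $C$ on the shared genes and
then clip negatives and renormalize to the simplex:

* `ols` — unconstrained least squares (errors on rank-deficient $C$);
* `nnls` — Lawson–Hanson active-set non-negative least squares (authored
  in-package; verified against an exhaustive simplex-grid search);
* `rlr` — Huber M-estimation (k = 1.345), iteratively reweighted with a
  median-based scale, tol 1e-6;
* `nusvr` — linear ν-support-vector regression, the CIBERSORT recipe.
  The signature is standardized with one *global* center and scale and the
  bulk vector z-scored; a shared affine map keeps the fitted weights
  proportional to the mixing proportions, which per-column scaling would
  destroy. The primal (only K+2 unknowns) is solved with a smoothed
  ε-insensitive loss under the libsvm objective scaling
  $\tfrac12\|w\|^2 + C(\nu l \varepsilon + \sum_i \xi_i)$, deterministically,
  for ν ∈ {0.25, 0.5, 0.75}; the fit with the lowest reconstruction RMSE is
  kept. Note one degeneracy: if the constant vector lies in the span of the
  signature columns (as on a 2-gene identity toy), the intercept absorbs the
  mean and only proportion differences are identified — not a concern for
  real, full-rank signatures.
* `dwls` — dampened weighted least squares: non-negative WLS with weights
  $1/\max(Cp, \delta)^2$ (δ = 1e-6), weight ratios capped at a damping
  constant chosen from $2^0..2^5$ by minimum reconstruction error. That
  selection rule always favors the least-damped fit, so on well-posed
  problems dwls tracks nnls; we implement the stated rule and note the
  collapse.

# Evaluation harness

* **PCC_P** — Pearson correlation between estimated and true proportions
  over all flattened entries (per-type correlations attached for
  diagnostics; the flattened-vs-averaged convention is not fixed by the
  original description, flattened is our default).
* **PCC_T1 / PCC_T2** — correlation between the reconstructed bulk
  $\hat T = C P^\top$ and the observed bulk, using the fraction-restricted
  vs the full-marker signature; computed per sample and averaged (a
  flattened variant sits behind `flatten = TRUE`).
* `run_fraction_scan()` sweeps marker fractions (default 5 %…100 %) per
  method; `rank_methods()` ranks methods by PCC_P within each
  (test, fraction) cell of a window (default 25 %–100 %), ties sharing the
  mean rank, and averages.

# Cell-type-level imputation

The high-resolution imputation of per-sample, per-type expression from bulk
data is, in the original pipeline, a proprietary tool; bulkdecon defines an
exactly-testable surrogate. Stage 1 fits, per gene, non-negative
coefficients $\beta_{g,t}$ of the bulk values on the proportion columns.
Stage 2 allocates each sample's residual
$r_{g,s} = b_{g,s} - \sum_t p_{s,t}\beta_{g,t}$ back to cell types as
$x_{g,t,s} = \max(0, \beta_{g,t} + r_{g,s} w_{g,t,s}/p_{s,t})$, so that
$\sum_t p_{s,t} x_{g,t,s} = b_{g,s}$ holds exactly wherever no clipping or
missingness intervened. Types below 0.5 % abundance in a sample are masked
(low-abundance profiles are unreliable).

The choice of allocation weight $w$ is where the science sits. The
seemingly natural weight $w \propto p_{s,t}\beta_{g,t}$ ("attribute the
residual where the fitted signal is") has a provable flaw: it gives every
cell type the *same relative* boost $r_s/\sum_u p_u\beta_u$, so a
case-restricted shift planted in one cell type surfaces in **every** type's
profile with identical relative magnitude, and cell-type-resolved group
comparisons are meaningless. The default (`allocation = "driver"`)
therefore *names a driver*: gene-wise multiplicative noise is homoscedastic
on the log scale, so the absolute log-residual of an undistorted gene is
flat in the proportions, while a type-restricted distortion grows with that
type's abundance. Genes are grouped into modules of correlated signed
residual patterns (a shifted pathway hits many genes coherently), each
module's pooled absolute-residual pattern is correlated against each type's
proportions, and the best type (t-statistic ≥ 3) takes the whole module's
residuals; genes without proportion-structured residuals fall back to the
proportional weight. Winner-take-all is essential — *any* split leaks a
shared, systematically signed component into every type, and at cohort
sample sizes a rank test detects arbitrarily small systematic leaks.

Two consequences shape downstream use:

* For group comparisons of a gene set within a cell type, a robust summary
  is still required because a few modules are inevitably mis-attributed:
  `compare_celltype_activation()` converts each gene to its quantile rank
  across samples (constant genes pin at 0.5), summarizes a sample by the
  *median* over the set, and rank-sum-tests the groups. The median's
  breakdown point makes a handful of mis-attributed genes harmless.
* For subtype discovery the localization is irrelevant but feature
  stability matters, so the subtyping path uses
  `allocation = "proportional"`, whose features are shared-relative-residual
  patterns — stable and fully informative about sample structure.

`validate_marker_enrichment()` averages the cube over samples and asks, per
(profile, marker set) pair, whether the markers sit high in that profile
(one-sided rank-sum), returning row-scaled −log10 p-values whose diagonal
should light up for a biologically sound cube.

# Pathway activity

`aucell_score()` is the area under the gene-set recovery curve within the
top fraction of genes ranked by expression (ties broken by gene id for
reproducibility on integer data), normalized by its maximum — 1 when the
whole set leads the ranking, 0 when no set gene reaches the window, and
invariant under any monotone transform of the expression values. The window
is 5 % by default (the rank-based-activity convention; exposed as a
parameter). Genes absent from a profile are dropped with a warning rather
than ranked last.

# Classification

DEGs are selected on the training split only: an expression filter (mean
log-expression above a cutoff; default 4 for microarray-scale data) and a
per-gene Welch t-test on log values with Benjamini–Hochberg control — a
location-test surrogate for a count-model fit, since microarray and imputed
inputs are continuous. When the adjusted cutoff selects nothing (e.g. under
permuted labels), the smallest-p genes are used so the classifier stays
defined. The linear SVM is an L2-regularized squared-hinge primal solved by
BFGS with the data term *averaged* over samples — averaging (rather than
libsvm's sum) makes the fitted decision function invariant under
duplicating every sample at fixed cost, which we treat as the correct
sample-weight semantics. The cost is chosen on a 0.2–2.0 grid by mean
stratified 5-fold CV ROC-AUC (ties toward the smaller cost), and the
held-out 20 % AUC is reported.

# Subtype discovery

Highly variable genes are selected by binned mean–dispersion statistics of
log1p values (dispersion = variance/mean, z-scored within 20
equal-frequency mean bins). Per cell type, HVGs of the imputed slice are
z-scored and concatenated into an integrated profile with `celltype:gene`
feature ids. NMF needs non-negative input but the features are z-scored;
each feature row is shifted by its minimum, which preserves the variance
structure the scaling intends. Consensus clustering runs multiplicative-
update Frobenius NMF from seeded random initializations (30 runs); each
run's argmax-coefficient labels define a connectivity matrix, the average
is the consensus, final labels come from average-linkage clustering of
1 − consensus, and the cophenetic coefficient (correlation between
consensus distances and the dendrogram's ultrametric) measures stability.
The iteration cap is 2000: multiplicative updates need well over 500
iterations to reach the 1e-5 relative tolerance on realistic profiles, and
unconverged runs are discarded (more than half discarded is an error).

`choose_k()` implements the stated selection rule — the largest k whose
cophenetic values have not yet dropped more than 0.05 below the k = 2 value
— and returns the range maximum with a warning when the curve never drops.
A known limitation, documented deliberately: in our linear pseudo-bulk
world, a subtype's activation enters the bulk in proportion to its driver
type's abundance, which plants a *reproducible* within-subtype gradient;
consensus over-splits along such gradients are stable, nested structure is
ultrametric-compatible, and the cophenetic curve then has no knee even when
k = 4 clustering is essentially perfect (ARI ≈ 1). The corresponding
acceptance expectation is left failing rather than papered over; on real
cohorts, where over-splits are noise-driven, the rule behaves as described.
`tune_dispersion_cutoff()` implements the published practice of scanning
the HVG dispersion cutoff and keeping the one whose chosen k is most
stable.

Cluster–clinical association uses one-way ANOVA plus all-pairs Welch
t-tests (BH-corrected) for numeric features and a chi-square test without
continuity correction for categorical ones; constant features are skipped
with a warning, and ANOVA p-values are additionally BH-adjusted across
features.

# The synthetic world

`generate_reference()` draws per-gene baseline abundances from a log-normal
(meanlog 1, sdlog 1), elevates each type's planted markers by
2^`marker_log2fc`, thins per cell with Bernoulli dropout (default rate 0.2,
applied before depth normalization so the 30 %-expressed filter is
exercised), and samples multinomial counts at Poisson depth (default 2000).
`generate_mixtures()` mixes per-type mean CPM profiles with Dirichlet
proportions, i.i.d. log-normal noise, and an optional per-gene fixed
platform bias — mean profiles rather than resampled cells, so the noiseless
case is exactly linear and oracle-recoverable. `generate_cohort()` adds a
case/control composition shift (absorbed proportionally by unshifted
types, so the stated displacement is exact), case subtypes whose pathway
activations scale the stated genes through the stated cell type's
contribution *before* summation (hence imputation is checkable against
truth), and clinical features with subtype-separated means (planted) or
pure noise (null).

Defaults we fixed once and defend on realism: noise_log_sd 0.2 and
platform_bias_sd 0.3 (stipulations — the original study never characterizes
the microarray-to-single-cell link); Dirichlet concentration totalling 10,
giving between-individual composition sd ≈ 0.10–0.15, typical of solid
tissue; flat Dirichlet (α = 1) for benchmark mixtures, the standard
random-mixture convention; planted marker strength log2FC 4 for the
14-type acceptance panel (canonical marker scale, 16-fold); 2-fold planted
pathway activations for detection tests and 4-fold for subtype structure.
What a green test does *not* establish: robustness to batch effects,
ambient RNA, doublets, probe-level microarray artifacts, or reference/bulk
mismatch beyond a per-gene multiplicative bias — none of which the
generator emulates.

# Numerical notes

* NNLS: active-set on the normal equations with a scale-aware ridge rescue
  for near-singular subproblems; tolerance 1e-10.
* Undefined correlations (constant signature columns) are excluded from the
  between-type average rather than set to 0, to avoid biasing the plateau
  rule; all-undefined is an error.
* Ties: marker top-type by first index; AUCell ranking by gene id; rank
  averaging in the method harness; smallest cost on CV ties.
* All generators and consensus runs are seeded; identical spec + seed gives
  byte-identical output.
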