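# End-to-end orchestration on a synthetic cohort, a declarative config
# with seed resolution, and a small command-line front end.

.pipeline_defaults <- function() {
  list(
    seed = 1L,
    # synthetic reference
    n_cell_types = 5, n_genes = 600, cells_per_type = 40,
    markers_per_type = 25, marker_log2fc = 3, dropout_rate = 0.2,
    count_depth = 2000,
    # synthetic cohort
    n_samples_per_group = 30, noise_log_sd = 0.2, platform_bias_sd = 0.3,
    n_subtypes = 3, clinical_effect_size = 2, activation_log2fc = 1.5,
    activation_set_size = 30,
    # signature
    secondfc = "auto", logfc_min = 1, logcpm_min = 1,
    min_frac_expressed = 0.30,
    # deconvolution / benchmark
    method = "nnls", run_benchmark = TRUE,
    fractions = seq(0.25, 1, by = 0.25),
    benchmark_methods = c("nnls", "ols", "rlr"),
    # pathway / classification / subtyping
    top_fraction = 0.05, svm_logcpm_min = 1, k_range = 2:6, n_runs = 20,
    dispersion_cutoff = 1, run_subtyping = TRUE
  )
}

#' Build and validate a pipeline configuration
#'
#' Unknown keys are rejected; every random stage receives an explicit
#' sub-seed derived from the master `seed` during resolution, and the
#' resolved document is written alongside every run.
#'
#' @param ... overrides of the default configuration values
#' @return object of class `pipeline_config` (a named list)
#' @export
pipeline_config <- function(...) {
  defaults <- .pipeline_defaults()
  user <- list(...)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  cfg <- utils::modifyList(defaults, user)
  .assert(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
          "seed must be an integer")
  # per-stage sub-seeds, all kept within the 32-bit integer range
  base <- as.integer(cfg$seed) %% 1000000L
  cfg$stage_seeds <- list(reference = base * 13L + 1L,
                          cohort = base * 13L + 2L,
                          svm = base * 13L + 3L,
                          nmf = base * 13L + 4L)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full deconvolution workflow on a synthetic cohort
#'
#' Executes, in order: synthetic reference and cohort generation,
#' signature construction (with the automatic SecondFC inflection rule if
#' requested), cohort deconvolution, group-wise proportion comparison,
#' cell-type expression imputation (group-aware), marker-enrichment
#' validation, pathway activity scoring with group tests, the linear SVM
#' classification stage, integrated-profile NMF subtyping, and
#' clinical-feature association tests. Every stage writes its output as
#' TSV into `out_dir`, warnings are captured into a machine-readable log,
#' and the resolved configuration (with all sub-seeds) is stored as JSON.
#'
#' @param config a [pipeline_config()]
#' @param out_dir run directory (created; existing files overwritten)
#' @return invisibly, a list with the main in-memory stage results
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  note <- function(stage, msg) {
    log[[length(log) + 1]] <<- data.frame(stage = stage, message = msg)
  }
  with_stage <- function(stage, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e) {
        stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
             call. = FALSE)
      }),
      warning = function(w) {
        note(stage, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  cfg <- config
  jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)

  # --- synthetic data ---
  ref <- with_stage("synthetic", {
    spec <- reference_spec(
      n_cell_types = cfg$n_cell_types, n_genes = cfg$n_genes,
      cells_per_type = cfg$cells_per_type,
      markers_per_type = cfg$markers_per_type,
      marker_log2fc = cfg$marker_log2fc, dropout_rate = cfg$dropout_rate,
      count_depth = cfg$count_depth, seed = cfg$stage_seeds$reference)
    generate_reference(spec)
  })
  cohort <- with_stage("synthetic", {
    types <- unique(ref$cell_types)
    set.seed(cfg$stage_seeds$cohort)
    acts <- lapply(seq_len(cfg$n_subtypes), function(j) {
      list(cell_type = types[1 + (j - 1) %% length(types)],
           genes = sample(ref$gene_ids, cfg$activation_set_size),
           log2fc = cfg$activation_log2fc)
    })
    cspec <- cohort_spec(
      n_samples_per_group = cfg$n_samples_per_group,
      group_proportion_shift = stats::setNames(0.08, types[1]),
      noise_log_sd = cfg$noise_log_sd,
      platform_bias_sd = cfg$platform_bias_sd,
      n_subtypes = cfg$n_subtypes, subtype_pathway_genes = acts,
      clinical_effect_size = cfg$clinical_effect_size,
      seed = cfg$stage_seeds$cohort)
    generate_cohort(ref, cspec)
  })
  write_expression_tsv(cohort$bulk, file.path(out_dir, "bulk.tsv"))
  write_proportions_tsv(cohort$true_proportions,
                        file.path(out_dir, "true_proportions.tsv"))
  utils::write.table(
    data.frame(sample_id = rownames(cohort$clinical), cohort$clinical,
               subtype = cohort$subtype),
    file.path(out_dir, "clinical.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # --- signature ---
  sig <- with_stage("signature", {
    stats_df <- compute_marker_stats(ref)
    secondfc <- cfg$secondfc
    if (identical(secondfc, "auto")) {
      scan <- choose_secondfc_threshold(ref, logfc_min = cfg$logfc_min,
                                        logcpm_min = cfg$logcpm_min,
                                        min_frac_expressed = cfg$min_frac_expressed)
      secondfc <- scan$chosen_threshold
      utils::write.table(
        data.frame(threshold = scan$thresholds,
                   avg_correlation = scan$avg_correlation,
                   chosen = scan$thresholds == scan$chosen_threshold),
        file.path(out_dir, "secondfc_scan.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    }
    sel <- select_markers(stats_df, cfg$logfc_min, cfg$logcpm_min,
                          as.numeric(secondfc), cfg$min_frac_expressed)
    build_signature(ref, sel, stats = stats_df)
  })
  write_signature_tsv(sig, file.path(out_dir, "signature.tsv"))

  # --- deconvolution + group proportions ---
  props <- with_stage("deconvolution",
                      deconvolve_cohort(sig, cohort$bulk, cfg$method))
  write_proportions_tsv(props, file.path(out_dir, "proportions.tsv"))
  prop_tests <- with_stage("proportion_tests",
                           compare_group_proportions(props, cohort$group))
  utils::write.table(prop_tests, file.path(out_dir, "proportion_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # --- benchmark scan (optional) ---
  bench <- NULL
  if (isTRUE(cfg$run_benchmark)) {
    bench <- with_stage("benchmark", {
      rec <- run_fraction_scan(ref, cohort$bulk, cohort$true_proportions,
                               methods = cfg$benchmark_methods,
                               fractions = cfg$fractions)
      utils::write.table(rec, file.path(out_dir, "benchmark_records.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      rs <- rank_methods(rec)
      utils::write.table(
        data.frame(method = names(rs$average_rank),
                   average_rank = as.numeric(rs$average_rank)),
        file.path(out_dir, "method_ranks.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      list(records = rec, ranks = rs)
    })
  }

  # --- imputation + validation ---
  cube <- with_stage("imputation",
                     impute_celltype_expression(cohort$bulk, props))
  heat <- with_stage("marker_validation", {
    planted <- attr(ref, "planted_markers")
    validate_marker_enrichment(cube, planted)
  })
  utils::write.table(
    data.frame(profile = rownames(heat), unclass(heat), check.names = FALSE),
    file.path(out_dir, "marker_enrichment.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  # --- pathway activity on imputed profiles ---
  pathway <- with_stage("pathway", {
    acts <- cohort$provenance$cohort_spec$subtype_pathway_genes
    sets <- stats::setNames(
      lapply(seq_along(acts), function(j)
        gene_set(sprintf("planted_set_%d", j), acts[[j]]$genes)),
      sprintf("planted_set_%d", seq_along(acts)))
    write_gmt(sets, file.path(out_dir, "planted_sets.gmt"))
    types <- dimnames(cube)[[2]]
    rows <- list()
    for (t in types) {
      slice <- cube[, t, ]
      slice <- slice[stats::complete.cases(slice), , drop = FALSE]
      if (nrow(slice) < 20) next
      sc <- aucell_scores(slice, sets, cfg$top_fraction)
      for (nm in colnames(sc)) {
        cmp <- compare_groups(sc[, nm], cohort$group)
        rows[[length(rows) + 1]] <- data.frame(
          cell_type = t, gene_set = nm, statistic = cmp$statistic,
          p = cmp$p.value)
      }
    }
    out <- do.call(rbind, rows)
    utils::write.table(out, file.path(out_dir, "pathway_group_tests.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    out
  })

  # --- SVM classification on bulk ---
  svm <- with_stage("classification", {
    fit <- train_eval_svm(log2(cohort$bulk + 1), cohort$group,
                          svm_config(logcpm_min = cfg$svm_logcpm_min,
                                     seed = cfg$stage_seeds$svm))
    utils::write.table(fit$roc, file.path(out_dir, "svm_roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    fit
  })

  # --- subtyping + clinical association ---
  subtyping <- NULL
  if (isTRUE(cfg$run_subtyping)) {
    subtyping <- with_stage("subtyping", {
      case_idx <- which(cohort$group == "case")
      cube_case <- cube[, , case_idx, drop = FALSE]
      class(cube_case) <- "celltype_cube"
      prof <- build_integrated_profile(cube_case, dimnames(cube)[[2]],
                                       dispersion_cutoff = cfg$dispersion_cutoff)
      cc <- vapply(cfg$k_range, function(k)
        nmf_consensus(prof, k, n_runs = cfg$n_runs,
                      seed = cfg$stage_seeds$nmf)$cophenetic_cc, numeric(1))
      names(cc) <- cfg$k_range
      k_star <- choose_k(cc)
      cons <- nmf_consensus(prof, k_star, n_runs = cfg$n_runs,
                            seed = cfg$stage_seeds$nmf)
      utils::write.table(
        data.frame(k = as.integer(names(cc)), cophenetic = as.numeric(cc)),
        file.path(out_dir, "cophenetic_by_k.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      utils::write.table(
        data.frame(sample_id = names(cons$labels), cluster = cons$labels),
        file.path(out_dir, "subtype_labels.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
      assoc <- test_clinical_association(
        cons$labels,
        cohort$clinical[case_idx, setdiff(colnames(cohort$clinical), "group"),
                        drop = FALSE])
      utils::write.table(assoc$table,
                         file.path(out_dir, "clinical_association.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      list(k = k_star, cc_by_k = cc, consensus = cons, association = assoc)
    })
  }

  if (length(log) > 0) {
    utils::write.table(do.call(rbind, log), file.path(out_dir, "warnings.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(out_dir = out_dir, reference = ref, cohort = cohort,
                 signature = sig, proportions = props,
                 proportion_tests = prop_tests, benchmark = bench,
                 cube = cube, enrichment = heat, pathway = pathway,
                 svm = svm, subtyping = subtyping))
}

# ---- command-line front end ---------------------------------------------

.parse_flags <- function(argv) {
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    .assert(startsWith(a, "--"), sprintf("expected a --flag, got '%s'", a))
    key <- sub("^--", "", a)
    .assert(i + 1 <= length(argv), sprintf("flag --%s needs a value", key))
    out[[gsub("-", "_", key)]] <- argv[i + 1]
    i <- i + 2
  }
  out
}

.flag <- function(flags, name, default = NULL, required = FALSE) {
  if (!is.null(flags[[name]])) return(flags[[name]])
  if (required) stop(sprintf("missing required flag --%s", gsub("_", "-", name)))
  default
}

#' Command-line entry point
#'
#' Subcommands: `synth` (reference | cohort), `signature`, `deconv`,
#' `bench`, `impute`, `pathway`, `subtype`, `run`. Every random
#' subcommand requires `--seed`. Run `cli_main(character(0))` for usage.
#'
#' @param argv character vector of arguments (e.g. `commandArgs(TRUE)`)
#' @return exit status, invisibly
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: bulkdecon <command> [flags]",
    "  synth     --what reference|cohort --out DIR --seed N [generator flags]",
    "  signature --ref-dir DIR --out FILE [--secondfc value|auto]",
    "  deconv    --signature FILE --bulk FILE --method NAME --out FILE",
    "  bench     --ref-dir DIR --bulk FILE --truth FILE --methods a,b --out FILE",
    "  impute    --bulk FILE --props FILE --out-dir DIR",
    "  pathway   --expr FILE --gmt FILE --out FILE [--top-fraction F]",
    "  classify  --expr FILE --labels FILE --out FILE --seed N [--logcpm-min V]",
    "  subtype   --expr FILE --k-range lo:hi --n-runs N --seed N --out-dir DIR",
    "  run       --out DIR --seed N",
    sep = "\n")
  if (length(argv) == 0) {
    message(usage)
    return(invisible(1L))
  }
  cmd <- argv[1]
  flags <- .parse_flags(argv[-1])
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)
  switch(cmd,
    synth = {
      seed <- as.integer(.flag(flags, "seed", required = TRUE))
      what <- .flag(flags, "what", "reference")
      out <- .flag(flags, "out", required = TRUE)
      spec <- reference_spec(
        n_cell_types = as.integer(.flag(flags, "n_cell_types", 5)),
        n_genes = as.integer(.flag(flags, "n_genes", 600)),
        cells_per_type = as.integer(.flag(flags, "cells_per_type", 40)),
        markers_per_type = as.integer(.flag(flags, "markers_per_type", 25)),
        marker_log2fc = num(.flag(flags, "marker_log2fc", 3)),
        dropout_rate = num(.flag(flags, "dropout_rate", 0.2)),
        seed = seed)
      ref <- generate_reference(spec)
      if (what == "reference") {
        write_reference_mtx(ref, out)
      } else {
        cohort <- generate_cohort(ref, cohort_spec(
          n_samples_per_group = as.integer(.flag(flags, "n_samples_per_group", 30)),
          noise_log_sd = num(.flag(flags, "noise_log_sd", 0.2)),
          platform_bias_sd = num(.flag(flags, "platform_bias_sd", 0.3)),
          n_subtypes = as.integer(.flag(flags, "n_subtypes", 1)),
          seed = seed))
        dir.create(out, showWarnings = FALSE, recursive = TRUE)
        write_expression_tsv(cohort$bulk, file.path(out, "bulk.tsv"))
        write_proportions_tsv(cohort$true_proportions,
                              file.path(out, "true_proportions.tsv"))
        utils::write.table(
          data.frame(sample_id = rownames(cohort$clinical), cohort$clinical),
          file.path(out, "clinical.tsv"), sep = "\t", quote = FALSE,
          row.names = FALSE)
      }
    },
    signature = {
      ref <- read_reference_mtx(.flag(flags, "ref_dir", required = TRUE))
      stats_df <- compute_marker_stats(ref)
      secondfc <- .flag(flags, "secondfc", "1.5")
      if (secondfc == "auto") {
        secondfc <- choose_secondfc_threshold(ref)$chosen_threshold
      }
      sel <- select_markers(stats_df,
                            num(.flag(flags, "logfc_min", 1)),
                            num(.flag(flags, "logcpm_min", 1)),
                            as.numeric(secondfc),
                            num(.flag(flags, "min_frac_expressed", 0.3)))
      write_signature_tsv(build_signature(ref, sel, stats = stats_df),
                          .flag(flags, "out", required = TRUE))
    },
    deconv = {
      sig <- read_signature_tsv(.flag(flags, "signature", required = TRUE))
      bulk <- read_expression_tsv(.flag(flags, "bulk", required = TRUE))
      props <- deconvolve_cohort(sig, bulk, .flag(flags, "method", "nnls"))
      write_proportions_tsv(props, .flag(flags, "out", required = TRUE))
    },
    bench = {
      ref <- read_reference_mtx(.flag(flags, "ref_dir", required = TRUE))
      bulk <- read_expression_tsv(.flag(flags, "bulk", required = TRUE))
      truth <- read_proportions_tsv(.flag(flags, "truth", required = TRUE),
                                    method = "truth")
      methods <- strsplit(.flag(flags, "methods", "nnls"), ",")[[1]]
      fr <- .flag(flags, "fractions", "0.25:1:0.25")
      fr <- as.numeric(strsplit(fr, ":")[[1]])
      rec <- run_fraction_scan(ref, bulk, truth, methods = methods,
                               fractions = seq(fr[1], fr[2], by = fr[3]))
      utils::write.table(rec, .flag(flags, "out", required = TRUE),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    },
    impute = {
      bulk <- read_expression_tsv(.flag(flags, "bulk", required = TRUE))
      props <- read_proportions_tsv(.flag(flags, "props", required = TRUE))
      cube <- impute_celltype_expression(bulk, props)
      out <- .flag(flags, "out_dir", required = TRUE)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      for (t in dimnames(cube)[[2]]) {
        write_expression_tsv(cube[, t, ],
                             file.path(out, paste0("imputed_", t, ".tsv")))
      }
      writeLines(dimnames(cube)[[2]], file.path(out, "manifest.tsv"))
    },
    pathway = {
      expr <- read_expression_tsv(.flag(flags, "expr", required = TRUE))
      sets <- read_gmt(.flag(flags, "gmt", required = TRUE))
      sc <- aucell_scores(expr, sets, num(.flag(flags, "top_fraction", 0.05)))
      write_expression_tsv(sc, .flag(flags, "out", required = TRUE),
                           id_column = "sample_id")
    },
    classify = {
      expr <- read_expression_tsv(.flag(flags, "expr", required = TRUE))
      lab <- utils::read.table(.flag(flags, "labels", required = TRUE),
                               sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
      labels <- factor(lab[[2]][match(colnames(expr), lab[[1]])])
      fit <- train_eval_svm(expr, labels, svm_config(
        logcpm_min = num(.flag(flags, "logcpm_min", 4)),
        seed = as.integer(.flag(flags, "seed", required = TRUE))))
      out <- .flag(flags, "out", required = TRUE)
      utils::write.table(
        data.frame(best_cost = fit$best_cost, test_auc = fit$test_auc,
                   n_genes = length(fit$genes)),
        out, sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(fit$roc, paste0(out, ".roc.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    },
    subtype = {
      expr <- read_expression_tsv(.flag(flags, "expr", required = TRUE))
      kr <- as.integer(strsplit(.flag(flags, "k_range", "2:6"), ":")[[1]])
      seed <- as.integer(.flag(flags, "seed", required = TRUE))
      n_runs <- as.integer(.flag(flags, "n_runs", 20))
      out <- .flag(flags, "out_dir", required = TRUE)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      cc <- vapply(kr[1]:kr[2], function(k)
        nmf_consensus(expr, k, n_runs = n_runs, seed = seed)$cophenetic_cc,
        numeric(1))
      names(cc) <- kr[1]:kr[2]
      k_star <- choose_k(cc)
      cons <- nmf_consensus(expr, k_star, n_runs = n_runs, seed = seed)
      utils::write.table(data.frame(k = as.integer(names(cc)),
                                    cophenetic = as.numeric(cc)),
                         file.path(out, "cophenetic_by_k.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(data.frame(sample_id = names(cons$labels),
                                    cluster = cons$labels),
                         file.path(out, "labels.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_expression_tsv(cons$consensus, file.path(out, "consensus.tsv"),
                           id_column = "sample_id")
    },
    run = {
      run_pipeline(pipeline_config(
        seed = as.integer(.flag(flags, "seed", required = TRUE))),
        out_dir = .flag(flags, "out", required = TRUE))
    },
    {
      message(usage)
      return(invisible(1L))
    })
  invisible(0L)
}
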