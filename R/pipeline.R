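# End-to-end pipeline: simulate (optional) -> QC -> detection -> benchmark
# -> signature -> cross-platform -> covariates, writing every stage's table
# to a run directory.

#' Pipeline configuration
#'
#' @param out_dir Run directory (created if needed).
#' @param sim A [sim_config()] used to generate the study; alternatively set
#'   `tape_counts`/`meta`/`biopsy_counts`/`replicate_map`/`gold` to analyse
#'   existing data.
#' @param qc A [qc_config()].
#' @param grid Method grid, as [default_method_grid()].
#' @param contrast Contrast for the benchmark.
#' @param seed Integer master seed; the simulation substream derives from it.
#' @param tape_counts,meta,biopsy_counts,replicate_map,gold Optional
#'   pre-loaded inputs replacing the simulation.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, sim = sim_config(), qc = qc_config(),
                            grid = default_method_grid(),
                            contrast = "LS_vs_NL", seed = 1L,
                            tape_counts = NULL, meta = NULL,
                            biopsy_counts = NULL, replicate_map = NULL,
                            gold = NULL) {
  if (nrow(grid) == 0) stop("method grid is empty", call. = FALSE)
  structure(list(out_dir = out_dir, sim = sim, qc = qc, grid = grid,
                 contrast = contrast, seed = as.integer(seed),
                 tape_counts = tape_counts, meta = meta,
                 biopsy_counts = biopsy_counts, replicate_map = replicate_map,
                 gold = gold),
            class = "pipeline_config")
}

stage <- function(name, log, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes every stage in order and writes its tables under `out_dir`:
#' the simulated study (when no input data are supplied), `qc_report.tsv`,
#' `filtered_counts.tsv`, `detected_genes.txt`, `benchmark_accuracy.tsv`,
#' `intersections.tsv`, `signature.tsv`, `sample_correlation.tsv`,
#' `depth_association.tsv`, `group_comparison.tsv`, `layer_correlation.tsv`,
#' `total_count_lmm.tsv`, `signature_enrichment.tsv`, and `run_log.txt`
#' recording the seed, package version, and dropped samples/genes. A stage
#' failure stops the run with a stage-named error; earlier outputs remain.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(
    paste0("tapestrip ", as.character(utils::packageVersion("tapestrip"))),
    paste0("seed: ", config$seed),
    paste0("started: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  tsv <- function(x, name) utils::write.table(
    x, file.path(config$out_dir, name), sep = "\t", quote = FALSE,
    row.names = FALSE)

  simulated <- is.null(config$tape_counts)
  if (simulated) {
    simc <- config$sim
    simc$seed <- (config$seed * 1000L + 1L) %% .Machine$integer.max
    study <- stage("simulate", log, simulate_experiment(simc))
    write_sim_study(study, file.path(config$out_dir, "simulated_study"))
    tape <- study$tape$counts; meta <- study$tape$meta
    biopsy <- study$biopsy$counts; rep_map <- study$biopsy$replicate_map
    gold <- truth_gold_standard(study, config$contrast)
    annotation <- study$annotation
    sets <- study$gene_sets
  } else {
    tape <- config$tape_counts; meta <- config$meta
    biopsy <- config$biopsy_counts; rep_map <- config$replicate_map
    gold <- config$gold
    sets <- default_gene_sets()
    annotation <- gene_annotation(rownames(tape))
  }

  report <- stage("qc", log, score_sample_qc(tape, sets, config$qc))
  tsv(report, "qc_report.tsv")
  filtered <- stage("qc", log, filter_samples(tape, report))
  write_counts(filtered, file.path(config$out_dir, "filtered_counts.tsv"))
  log_lines <- c(log_lines,
                 paste0("samples dropped by QC: ", sum(!report$keep), " of ",
                        nrow(report)))

  detected <- stage("detect", log, detect_genes(filtered, annotation))
  writeLines(detected, file.path(config$out_dir, "detected_genes.txt"))
  log_lines <- c(log_lines, paste0("genes detected: ", length(detected)))
  if (length(detected) < 10) {
    stop("pipeline stage 'detect' failed: fewer than 10 detected genes",
         call. = FALSE)
  }
  meta_f <- meta[meta$sample_id %in% colnames(filtered), , drop = FALSE]
  bench_counts <- filtered[detected, , drop = FALSE]

  bench <- stage("benchmark", log,
                 run_benchmark(bench_counts, meta_f, gold, config$grid,
                               config$contrast, sets, full_counts = filtered))
  tsv(bench$accuracy, "benchmark_accuracy.tsv")
  tsv(bench$intersections, "intersections.tsv")
  if (length(bench$errors)) {
    log_lines <- c(log_lines, paste0("benchmark method failed: ",
                                     names(bench$errors), " (",
                                     unlist(bench$errors), ")"))
  }

  sig <- stage("signature", log, ensemble_signature(bench))
  tsv(sig, "signature.tsv")

  bx_avg <- stage("correlate", log, average_replicates(biopsy, rep_map))
  corr <- stage("correlate", log,
                per_sample_spearman(filtered, meta_f, bx_avg, detected))
  tsv(corr, "sample_correlation.tsv")
  depth <- stage("correlate", log, depth_association(corr))
  tsv(depth, "depth_association.tsv")
  grp <- stage("correlate", log, compare_groups(corr))
  tsv(grp, "group_comparison.tsv")
  layer <- stage("correlate", log,
                 layer_marker_correlation(filtered, meta_f, bx_avg, sets))
  tsv(layer, "layer_correlation.tsv")

  lmm <- stage("covariates", log, fit_total_count_lmm(meta_f, filtered, sets))
  tsv(lmm$anova, "total_count_lmm.tsv")

  enr <- if (nrow(sig) > 0 && any(sig$gene %in% detected)) {
    stage("enrich", log,
          fisher_enrichment(intersect(sig$gene, detected), sets, detected))
  } else NULL
  if (!is.null(enr)) tsv(enr, "signature_enrichment.tsv")

  log_lines <- c(log_lines,
                 paste0("signature genes: ", nrow(sig), " (",
                        attr(sig, "n_up"), " up / ", attr(sig, "n_down"),
                        " down)"),
                 paste0("finished: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S")))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(qc = report, detected = detected, benchmark = bench,
                 signature = sig, correlation = corr, depth = depth,
                 groups = grp, layers = layer, lmm = lmm, enrichment = enr,
                 gold = gold,
                 study = if (simulated) study else NULL))
}
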