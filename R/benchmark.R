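# Benchmark harness: cutoff grammar, accuracy against a gold standard,
# the method grid, upset-style intersections, and the ensemble signature.

#' Parse a DE cutoff
#'
#' Grammar mirrors the benchmark table: `"fc>2,p<0.05"`, `"fc>2,padj<0.05"`,
#' `"top5%"` (best 5% of genes by rank), `"top20up"` / `"top10up"` (best k
#' ranked upregulated genes).
#'
#' @param x Cutoff string.
#' @return A `de_cutoff` list with `type` in
#'   `fc_p`/`fc_padj`/`top_frac`/`top_k_up` and its thresholds.
#' @export
de_cutoff <- function(x) {
  x <- gsub(" ", "", tolower(x))
  if (grepl("^fc>([0-9.]+),(p|padj)<([0-9.]+)$", x)) {
    m <- regmatches(x, regexec("^fc>([0-9.]+),(p|padj)<([0-9.]+)$", x))[[1]]
    out <- list(type = if (m[3] == "p") "fc_p" else "fc_padj",
                fc = as.numeric(m[2]), alpha = as.numeric(m[4]))
  } else if (grepl("^top([0-9.]+)%$", x)) {
    frac <- as.numeric(sub("^top([0-9.]+)%$", "\\1", x)) / 100
    out <- list(type = "top_frac", frac = frac)
  } else if (grepl("^top([0-9]+)up$", x)) {
    k <- as.integer(sub("^top([0-9]+)up$", "\\1", x))
    out <- list(type = "top_k_up", k = k)
  } else {
    stop("unrecognised cutoff: ", x, call. = FALSE)
  }
  out$label <- x
  structure(out, class = "de_cutoff")
}

#' Apply a cutoff to a DE result
#'
#' `fc_p` keeps genes with `|log2fc| > log2(fc)` and `p < alpha` (strict
#' inequalities); `fc_padj` uses the BH-adjusted p; `top_frac` keeps the best
#' `frac` of genes by rank; `top_k_up` the best `k` ranked genes with
#' positive fold change. Rank-based cutoffs require a ranking engine
#' (one producing a DE probability).
#'
#' @param result A `de_result` tibble.
#' @param cutoff A [de_cutoff()] or cutoff string.
#' @return A tibble `gene`, `direction` (`up`/`down`), `log2fc`
#'   (class `deg_set`).
#' @export
apply_cutoff <- function(result, cutoff) {
  if (is.character(cutoff)) cutoff <- de_cutoff(cutoff)
  stopifnot(inherits(cutoff, "de_cutoff"))
  r <- result
  sel <- switch(
    cutoff$type,
    fc_p = !is.na(r$p) & abs(r$log2fc) > log2(cutoff$fc) & r$p < cutoff$alpha,
    fc_padj = !is.na(r$padj) & abs(r$log2fc) > log2(cutoff$fc) &
      r$padj < cutoff$alpha,
    top_frac = {
      if (!"prob" %in% names(r)) {
        stop("rank-based cutoff requires a ranking engine", call. = FALSE)
      }
      k <- ceiling(cutoff$frac * nrow(r))
      !is.na(r$rank) & r$rank <= k
    },
    top_k_up = {
      if (!"prob" %in% names(r)) {
        stop("rank-based cutoff requires a ranking engine", call. = FALSE)
      }
      up <- which(!is.na(r$log2fc) & r$log2fc > 0 & !is.na(r$rank))
      keep <- up[order(r$rank[up])][seq_len(min(cutoff$k, length(up)))]
      seq_len(nrow(r)) %in% keep
    })
  out <- tibble::tibble(gene = r$gene[sel],
                        direction = ifelse(r$log2fc[sel] > 0, "up", "down"),
                        log2fc = r$log2fc[sel])
  class(out) <- c("deg_set", class(out))
  out
}

#' Score a DEG set against a gold standard
#'
#' A called gene counts as correct iff it is in the gold standard with the
#' matching direction; accuracy is `100 * correct / called`, the precision of
#' the call set. An empty call set has undefined (missing) accuracy.
#'
#' @param degs A `deg_set` tibble (`gene`, `direction`).
#' @param gold A `gold_standard` tibble (`gene`, `direction`).
#' @return One-row tibble: `n_total`, `n_up`, `n_down`, `n_correct`,
#'   `n_correct_up`, `n_correct_down`, `accuracy` (percent).
#' @export
compute_accuracy <- function(degs, gold) {
  if (nrow(degs) == 0) {
    return(tibble::tibble(n_total = 0L, n_up = 0L, n_down = 0L,
                          n_correct = 0L, n_correct_up = 0L,
                          n_correct_down = 0L, accuracy = NA_real_))
  }
  in_gold <- degs$gene %in% gold$gene
  gdir <- gold$direction[match(degs$gene, gold$gene)]
  no_dir <- in_gold & is.na(gdir)
  if (any(no_dir)) {
    warning("gold standard lacks direction for ", sum(no_dir),
            " gene(s); direction check skipped for them")
  }
  correct <- in_gold & (is.na(gdir) | gdir == degs$direction)
  tibble::tibble(
    n_total = nrow(degs),
    n_up = sum(degs$direction == "up"),
    n_down = sum(degs$direction == "down"),
    n_correct = sum(correct),
    n_correct_up = sum(correct & degs$direction == "up"),
    n_correct_down = sum(correct & degs$direction == "down"),
    accuracy = 100 * sum(correct) / nrow(degs))
}

#' The default benchmark method grid
#'
#' Eleven normalization-by-engine-by-cutoff combinations covering the
#' benchmark table: NB-GLM LRT on RLE (adjusted p), TMM and TMMwsp (raw p),
#' the zero-inflation-weighted NB-GLM on TMM, a Wald-test NB-GLM on RLE,
#' voom with and without sample quality weights on TMM, the
#' mitochondrial-reference NB-GLM, and the non-parametric ranking at its
#' three published cutoffs.
#'
#' @return Tibble with columns `id`, `norm`, `engine`, `cutoff`.
#' @export
default_method_grid <- function() {
  tibble::tribble(
    ~id,                 ~norm,    ~engine,      ~cutoff,
    "RLE_nbglm_padj",    "rle",    "nbglm",      "fc>2,padj<0.05",
    "TMM_nbglm",         "tmm",    "nbglm",      "fc>2,p<0.05",
    "TMMwsp_nbglm",      "tmmwsp", "nbglm",      "fc>2,p<0.05",
    "ZIweights_nbglm",   "tmm",    "zi_nbglm",   "fc>2,p<0.05",
    "RLE_nbglm_wald",    "rle",    "nbglm_wald", "fc>2,p<0.05",
    "voom_TMM",          "tmm",    "voom",       "fc>2,p<0.05",
    "voomqw_TMM",        "tmm",    "voomqw",     "fc>2,p<0.05",
    "MTset_nbglm_padj",  "mt",     "nbglm",      "fc>2,padj<0.05",
    "NOIseq_top5pct",    "tmmwsp", "noiseq",     "top5%",
    "NOIseq_top20up",    "tmmwsp", "noiseq",     "top20up",
    "NOIseq_top10up",    "tmmwsp", "noiseq",     "top10up")
}

mt_offset <- function(counts, sets) {
  mt <- intersect(sets$MT_NORM, rownames(counts))
  if (length(mt) == 0) stop("no MT_NORM gene present", call. = FALSE)
  s <- colSums(counts[mt, , drop = FALSE])
  log(pmax(s, 0.5))  # floor guards samples with no mitochondrial reads
}

run_one_method <- function(counts, design, norm, engine, cutoff, sets,
                           full_counts = counts) {
  factors <- switch(norm,
    rle = rle_factors(counts),
    tmm = tmm_factors(counts),
    tmmwsp = tmm_factors(counts, singleton_pairing = TRUE),
    mt = none_factors(counts),
    none = none_factors(counts),
    stop("unknown normalization: ", norm, call. = FALSE))
  sub <- counts[, design$samples, drop = FALSE]
  res <- switch(engine,
    nbglm = ,
    nbglm_wald = ,
    zi_nbglm = {
      offs <- if (norm == "mt") mt_offset(full_counts, sets) else NULL
      disp <- estimate_dispersion(counts, design, factors)
      w <- if (engine == "zi_nbglm") zero_inflation_weights(sub, factors) else NULL
      nb_glm_test(counts, design, factors, disp, weights = w, offsets = offs,
                  test = if (engine == "nbglm_wald") "wald" else "lrt")
    },
    voom = voom_weighted_test(counts, factors, design),
    voomqw = voom_weighted_test(counts, factors, design, quality_weights = TRUE),
    noiseq = {
      expr <- log_cpm(sub, factors)
      noiseq_rank(expr, design$group[colnames(sub)], contrast = design$contrast)
    },
    stop("unknown engine: ", engine, call. = FALSE))
  list(result = res, degs = apply_cutoff(res, cutoff))
}

#' Run a method grid against a gold standard
#'
#' Executes every (normalization, engine, cutoff) combination on the same
#' post-QC count matrix, scores each call set against the gold standard, and
#' tabulates upset-style intersections of the true-positive sets. A failing
#' method is recorded with its error message and the remaining methods still
#' run. Fully deterministic given its inputs.
#'
#' @param counts Post-QC count matrix (detected genes x passing samples).
#' @param meta Sample metadata.
#' @param gold A `gold_standard` tibble.
#' @param grid Method grid, as from [default_method_grid()].
#' @param contrast Contrast to test.
#' @param sets Gene sets (for the mitochondrial reference offset).
#' @param full_counts Matrix holding all genes for the QC-passing samples;
#'   the mitochondrial reference offsets are computed from it, since the
#'   detection filter removes MT genes from `counts`. Defaults to `counts`.
#' @return A `benchmark_result`: `accuracy` tibble (one row per method),
#'   `deg_sets`, `tp_sets`, `intersections` tibble, `errors`, `gold`, `grid`.
#' @export
run_benchmark <- function(counts, meta, gold, grid = default_method_grid(),
                          contrast = "LS_vs_NL", sets = default_gene_sets(),
                          full_counts = counts) {
  stopifnot(nrow(grid) > 0)
  design <- design_spec(meta, contrast)
  deg_sets <- list(); tp_sets <- list(); errors <- list()
  acc <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    id <- grid$id[i]
    out <- tryCatch(
      run_one_method(counts, design, grid$norm[i], grid$engine[i],
                     grid$cutoff[i], sets, full_counts = full_counts),
      error = function(e) e)
    if (inherits(out, "error")) {
      errors[[id]] <- conditionMessage(out)
      acc[[i]] <- tibble::tibble(n_total = NA_integer_, n_up = NA_integer_,
                                 n_down = NA_integer_, n_correct = NA_integer_,
                                 n_correct_up = NA_integer_,
                                 n_correct_down = NA_integer_,
                                 accuracy = NA_real_)
      next
    }
    deg_sets[[id]] <- out$degs
    gdir <- gold$direction[match(out$degs$gene, gold$gene)]
    tp <- out$degs[!is.na(gdir) & gdir == out$degs$direction, , drop = FALSE]
    tp_sets[[id]] <- tp
    acc[[i]] <- compute_accuracy(out$degs, gold)
  }
  accuracy <- dplyr::bind_cols(grid, dplyr::bind_rows(acc))

  # upset-style intersections over true-positive sets
  union_genes <- unique(unlist(lapply(tp_sets, function(d) d$gene)))
  if (length(union_genes)) {
    membership <- vapply(tp_sets, function(d) union_genes %in% d$gene,
                         logical(length(union_genes)))
    membership <- matrix(membership, nrow = length(union_genes),
                         dimnames = list(union_genes, names(tp_sets)))
    pattern <- apply(membership, 1, function(z)
      paste(names(tp_sets)[z], collapse = "&"))
    intersections <- tibble::as_tibble(as.data.frame(table(pattern),
                                                     stringsAsFactors = FALSE))
    names(intersections) <- c("methods", "n_genes")
  } else {
    intersections <- tibble::tibble(methods = character(0), n_genes = integer(0))
  }

  structure(list(accuracy = accuracy, deg_sets = deg_sets, tp_sets = tp_sets,
                 intersections = intersections, errors = errors,
                 gold = gold, grid = grid, contrast = contrast),
            class = "benchmark_result")
}

#' Aggregate the ensemble disease signature
#'
#' The signature is the union over methods of each method's true positives
#' (called genes present in the gold standard with matching direction), with
#' per-gene provenance listing the contributing methods. The stricter
#' intersection-across-methods reading is available via `mode`.
#'
#' @param bench A `benchmark_result`.
#' @param mode `"union"` (default) or `"intersection"`.
#' @return A `signature_result` tibble: `gene`, `direction`, `n_methods`,
#'   `methods`; attributes `n_up`, `n_down`.
#' @export
ensemble_signature <- function(bench, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(inherits(bench, "benchmark_result"))
  tp <- bench$tp_sets
  all_tp <- dplyr::bind_rows(tp, .id = "method")
  if (nrow(all_tp) == 0) {
    warning("no true positives in any method; empty signature")
    out <- tibble::tibble(gene = character(0), direction = character(0),
                          n_methods = integer(0), methods = character(0))
  } else {
    out <- all_tp |>
      dplyr::group_by(.data$gene, .data$direction) |>
      dplyr::summarise(n_methods = dplyr::n(),
                       methods = paste(sort(unique(.data$method)), collapse = ","),
                       .groups = "drop") |>
      dplyr::arrange(.data$gene)
    if (mode == "intersection") {
      out <- out[out$n_methods == length(tp), , drop = FALSE]
      if (nrow(out) == 0) warning("intersection across all methods is empty")
    }
  }
  attr(out, "n_up") <- sum(out$direction == "up")
  attr(out, "n_down") <- sum(out$direction == "down")
  attr(out, "mode") <- mode
  class(out) <- c("signature_result", class(out))
  out
}
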