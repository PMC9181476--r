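# Four-criterion sample-level QC score and gene detection filtering for
# shallow tag-count libraries.

#' QC configuration
#'
#' Thresholds of the four-point sample scoring scheme. All four criteria are
#' strict inequalities; boundary values score 0.
#'
#' @param min_genes_detected A sample scores the sensitivity point when the
#'   number of genes with at least 1 count exceeds this (default 200).
#' @param min_edc_sum Signal point: summed raw counts over the `EDC_QC` panel
#'   must exceed this (default 100).
#' @param min_edc_fraction Purity point: the EDC sum as a fraction of the
#'   sample's total counts must exceed this (default 0.05).
#' @param max_mt_fraction Degradation point: the mitochondrial fraction of
#'   total counts must stay below this (default 0.15).
#' @param min_points_keep Samples with at least this many points are kept
#'   (default 3).
#' @return A `qc_config` list.
#' @export
qc_config <- function(min_genes_detected = 200, min_edc_sum = 100,
                      min_edc_fraction = 0.05, max_mt_fraction = 0.15,
                      min_points_keep = 3) {
  stopifnot(min_genes_detected > 0, min_edc_sum > 0,
            min_edc_fraction > 0, min_edc_fraction < 1,
            max_mt_fraction > 0, max_mt_fraction < 1)
  structure(list(min_genes_detected = min_genes_detected,
                 min_edc_sum = min_edc_sum,
                 min_edc_fraction = min_edc_fraction,
                 max_mt_fraction = max_mt_fraction,
                 min_points_keep = min_points_keep),
            class = "qc_config")
}

#' Score samples with the four-point QC scheme
#'
#' Each sample scores one point per fulfilled criterion, all computed on raw
#' counts: (c1) more than `min_genes_detected` genes with at least one count;
#' (c2) summed counts over the nine `EDC_QC` genes above `min_edc_sum`;
#' (c3) that EDC sum above `min_edc_fraction` of the sample's total counts;
#' (c4) mitochondrial counts below `max_mt_fraction` of the total. A sample
#' with zero total counts gets both fractions defined as 0, hence c3 FALSE and
#' c4 TRUE by convention.
#'
#' @param counts Validated count matrix.
#' @param sets `gene_sets` providing `EDC_QC`; mitochondrial genes are taken
#'   from `MT_NORM` plus any gene with an `MT-` prefix. Panel members missing
#'   from the matrix count as zero, with a warning.
#' @param config A [qc_config()].
#' @return A tibble, one row per sample, with the measured quantities,
#'   criterion flags `c1`..`c4`, the 0-4 `points`, and the `keep` flag.
#' @export
score_sample_qc <- function(counts, sets = default_gene_sets(),
                            config = qc_config()) {
  validate_counts(counts)
  edc <- sets$EDC_QC
  if (is.null(edc)) stop("gene sets must include EDC_QC", call. = FALSE)
  miss <- setdiff(edc, rownames(counts))
  if (length(miss)) {
    warning("EDC_QC genes absent from matrix (treated as zero): ",
            paste(miss, collapse = ", "))
  }
  mt_genes <- union(sets$MT_NORM,
                    rownames(counts)[startsWith(rownames(counts), "MT-")])
  edc_rows <- intersect(edc, rownames(counts))
  mt_rows <- intersect(mt_genes, rownames(counts))

  total <- colSums(counts)
  genes_detected <- colSums(counts >= 1)
  edc_sum <- if (length(edc_rows)) colSums(counts[edc_rows, , drop = FALSE]) else
    stats::setNames(rep(0, ncol(counts)), colnames(counts))
  mt_sum <- if (length(mt_rows)) colSums(counts[mt_rows, , drop = FALSE]) else
    stats::setNames(rep(0, ncol(counts)), colnames(counts))
  edc_fraction <- ifelse(total > 0, edc_sum / total, 0)
  mt_fraction <- ifelse(total > 0, mt_sum / total, 0)
  if (any(total == 0)) {
    message("samples with zero total counts: ",
            paste(colnames(counts)[total == 0], collapse = ", "))
  }

  c1 <- genes_detected > config$min_genes_detected
  c2 <- edc_sum > config$min_edc_sum
  c3 <- edc_fraction > config$min_edc_fraction
  c4 <- mt_fraction < config$max_mt_fraction
  points <- c1 + c2 + c3 + c4

  tibble::tibble(
    sample_id = colnames(counts),
    total_count = unname(total),
    genes_detected = unname(genes_detected),
    edc_sum = unname(edc_sum),
    edc_fraction = unname(edc_fraction),
    mt_fraction = unname(mt_fraction),
    c1 = unname(c1), c2 = unname(c2), c3 = unname(c3), c4 = unname(c4),
    points = unname(as.integer(points)),
    keep = unname(points >= config$min_points_keep))
}

#' Drop samples that failed QC
#'
#' @param counts Count matrix scored by [score_sample_qc()].
#' @param report The QC report tibble; must cover every sample of `counts`.
#' @return The matrix restricted to keep-flagged samples, column order
#'   preserved. Errors if no sample survives (the pipeline must not continue
#'   silently on an empty matrix).
#' @export
filter_samples <- function(counts, report) {
  validate_counts(counts)
  miss <- setdiff(colnames(counts), report$sample_id)
  if (length(miss)) {
    stop("QC report missing samples: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- report$keep[match(colnames(counts), report$sample_id)]
  if (!any(keep)) stop("no samples pass QC; nothing left to analyse", call. = FALSE)
  counts[, keep, drop = FALSE]
}

#' Detection filter for reliably expressed genes
#'
#' Keeps genes seen at `min_count` or more in at least `min_fraction` of the
#' (QC-passing) samples, then removes non-protein-coding and mitochondrial
#' genes. The default thresholds read "more than 1 count in 80% of samples"
#' literally: count >= 2 in >= 80% of samples.
#'
#' @param counts Count matrix (run [filter_samples()] first).
#' @param annotation Gene annotation tibble from [gene_annotation()]; genes
#'   absent from it are assumed protein-coding and non-mitochondrial.
#' @param min_count,min_fraction Detection thresholds.
#' @return Character vector of detected gene symbols.
#' @export
detect_genes <- function(counts, annotation = NULL,
                         min_count = 2, min_fraction = 0.80) {
  if (ncol(counts) == 0 || nrow(counts) == 0) {
    warning("empty count matrix; no genes detected")
    return(character(0))
  }
  validate_counts(counts)
  frac <- rowMeans(counts >= min_count)
  detected <- rownames(counts)[frac >= min_fraction]
  if (!is.null(annotation)) {
    ann <- annotation[match(detected, annotation$gene), ]
    coding <- is.na(ann$biotype) | ann$biotype == "protein_coding"
    mito <- !is.na(ann$is_mitochondrial) & ann$is_mitochondrial
    detected <- detected[coding & !mito]
  }
  detected <- detected[!startsWith(detected, "MT-")]
  detected
}
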