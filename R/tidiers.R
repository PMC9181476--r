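# broom-style tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a benchmark result
#'
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @return The per-method accuracy tibble.
#' @method tidy benchmark_result
#' @export
tidy.benchmark_result <- function(x, ...) x$accuracy

#' One-row summary of a benchmark result
#'
#' @param x A `benchmark_result`.
#' @param ... Unused.
#' @return Tibble with method counts, the best method and its accuracy, and
#'   the size of the union of true-positive sets.
#' @method glance benchmark_result
#' @export
glance.benchmark_result <- function(x, ...) {
  acc <- x$accuracy
  ok <- !is.na(acc$accuracy)
  best <- if (any(ok)) acc$id[ok][which.max(acc$accuracy[ok])] else NA_character_
  tibble::tibble(
    n_methods = nrow(acc),
    n_failed = length(x$errors),
    best_method = best,
    best_accuracy = if (any(ok)) max(acc$accuracy[ok]) else NA_real_,
    n_tp_union = length(unique(unlist(lapply(x$tp_sets, function(d) d$gene)))),
    contrast = x$contrast)
}

#' @method autoplot benchmark_result
#' @export
autoplot.benchmark_result <- function(object, ...) {
  acc <- object$accuracy
  acc <- acc[!is.na(acc$accuracy), , drop = FALSE]
  ggplot2::ggplot(acc, ggplot2::aes(
    x = stats::reorder(.data$id, .data$accuracy), y = .data$accuracy)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Accuracy (% of called DEGs in gold standard)",
                  title = paste("DE method benchmark,", object$contrast)) +
    ggplot2::theme_minimal()
}

#' Tidy the total-count mixed model
#'
#' @param x A `total_count_lmm`.
#' @param ... Unused.
#' @return The per-term likelihood-ratio table (`term`, `chisq`, `df`, `p`).
#' @method tidy total_count_lmm
#' @export
tidy.total_count_lmm <- function(x, ...) x$anova

#' One-row summary of the total-count mixed model
#'
#' @param x A `total_count_lmm`.
#' @param ... Unused.
#' @return Tibble with the sample size, log-likelihood, residual and
#'   random-intercept standard deviations, and the strongest term.
#' @method glance total_count_lmm
#' @export
glance.total_count_lmm <- function(x, ...) {
  if (inherits(x$fit, "merMod")) {
    vc <- as.data.frame(lme4::VarCorr(x$fit))
    sd_subject <- vc$sdcor[vc$grp == "subject_id"][1]
    sd_residual <- vc$sdcor[vc$grp == "Residual"][1]
  } else {
    sd_subject <- NA_real_
    sd_residual <- stats::sigma(x$fit)
  }
  tibble::tibble(
    n = nrow(x$data),
    logLik = as.numeric(stats::logLik(x$fit)),
    sd_subject = sd_subject,
    sd_residual = sd_residual,
    strongest_term = x$anova$term[which.min(x$anova$p)])
}

#' @method autoplot correlation_result
#' @export
autoplot.correlation_result <- function(object, ...) {
  d <- object[!is.na(object$rho), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = log10(.data$total_count), y = .data$rho,
                                  colour = .data$tissue_state)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(x = "log10 tape total counts", y = "Spearman rho",
                  colour = "Tissue state",
                  title = "Tape vs biopsy concordance by sequencing depth") +
    ggplot2::theme_minimal()
}

#' @method autoplot layer_correlation
#' @export
autoplot.layer_correlation <- function(object, ...) {
  d <- object[!is.na(object$rho), , drop = FALSE]
  d$layer <- factor(sub("^LAYER_", "", d$layer),
                    levels = c("CORNEUM", "GRANULOSUM", "SPINOSUM", "BASALE"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$layer, y = .data$rho)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, height = 0) +
    ggplot2::labs(x = "Epidermal layer (outermost to innermost)",
                  y = "Per-gene Spearman rho",
                  title = "Layer-marker concordance, tape vs biopsy") +
    ggplot2::theme_minimal()
}

#' QC score plot
#'
#' Bar chart of samples by QC points with the keep threshold marked.
#'
#' @param report Tibble from [score_sample_qc()].
#' @param min_points_keep Keep threshold to mark.
#' @return A ggplot object.
#' @export
plot_qc_scores <- function(report, min_points_keep = 3) {
  d <- dplyr::count(report, .data$points)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$points, levels = 0:4),
                                  y = .data$n)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = min_points_keep + 0.5, linetype = 2) +
    ggplot2::labs(x = "QC points", y = "Samples",
                  title = "Four-point sample QC score distribution") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a DE result
#'
#' @param result A `de_result` tibble.
#' @param fc,alpha Thresholds drawn as guides.
#' @return A ggplot object.
#' @export
plot_volcano <- function(result, fc = 2, alpha = 0.05) {
  d <- result[!is.na(result$p), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$log2fc, y = -log10(.data$p))) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = c(-log2(fc), log2(fc)), linetype = 2) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = unique(d$engine)[1]) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
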