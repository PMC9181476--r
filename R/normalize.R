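# Between-sample scaling factors (RLE, TMM, TMMwsp), log-CPM, and
# mitochondrial gene-set ratio normalization — native implementations.

norm_factor_tibble <- function(samples, lib_size, norm_factor, method,
                               size_factor = NULL) {
  out <- tibble::tibble(
    sample_id = samples,
    lib_size = unname(lib_size),
    norm_factor = unname(norm_factor),
    effective_lib_size = unname(lib_size * norm_factor),
    method = method)
  if (!is.null(size_factor)) out$size_factor <- unname(size_factor)
  class(out) <- c("norm_factors", class(out))
  out
}

geomean_rescale <- function(x) x / exp(mean(log(x)))

#' Relative-log-expression (median-of-ratios) scaling factors
#'
#' For each sample, the median over all-nonzero genes of the ratio of its
#' count to the gene's geometric mean across samples. The `size_factor`
#' column carries this median of ratios (geometric mean rescaled to 1); the
#' `norm_factor` column divides it by library size and rescales, the
#' convention under which a pure sequencing-depth change gives factors of 1
#' and the effective library size is `lib_size * norm_factor`.
#'
#' @param counts Count matrix with at least two samples.
#' @return A `norm_factors` tibble with columns `sample_id`, `lib_size`,
#'   `norm_factor`, `effective_lib_size`, `method`, `size_factor`.
#' @export
rle_factors <- function(counts) {
  validate_counts(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples", call. = FALSE)
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok)) {
    stop("no gene has nonzero counts in every sample; pre-filter the matrix ",
         "(e.g. with detect_genes) before RLE", call. = FALSE)
  }
  sub <- counts[ok, , drop = FALSE]
  gm <- exp(rowMeans(log(sub)))
  sf <- apply(sub / gm, 2, stats::median)
  sf <- geomean_rescale(sf)
  lib <- colSums(counts)
  nf <- geomean_rescale(sf / lib)
  norm_factor_tibble(colnames(counts), lib, nf, "RLE", size_factor = sf)
}

# Trimmed-mean-of-M-values factor of one sample against a reference column.
# With singleton_pairing, genes positive in exactly one of the two libraries
# are retained as pseudo-pairs (counts rank-matched largest-to-largest)
# instead of being discarded.
tmm_one <- function(obs, ref, n_obs, n_ref, logratio_trim, abs_trim,
                    singleton_pairing) {
  both <- obs > 0 & ref > 0
  o <- obs[both]; r <- ref[both]
  if (singleton_pairing) {
    only_obs <- sort(obs[obs > 0 & ref == 0], decreasing = TRUE)
    only_ref <- sort(ref[ref > 0 & obs == 0], decreasing = TRUE)
    k <- min(length(only_obs), length(only_ref))
    if (k > 0) {
      o <- c(o, only_obs[seq_len(k)])
      r <- c(r, only_ref[seq_len(k)])
    }
  }
  if (length(o) == 0) {
    warning("sample shares no usable gene with the reference; factor set to 1")
    return(1)
  }
  po <- o / n_obs; pr <- r / n_ref
  M <- log2(po / pr)
  A <- (log2(po) + log2(pr)) / 2
  # delta-method precision of M for weighting
  v <- (n_obs - o) / (n_obs * o) + (n_ref - r) / (n_ref * r)
  fin <- is.finite(M) & is.finite(A) & is.finite(v) & v > 0
  M <- M[fin]; A <- A[fin]; v <- v[fin]
  n <- length(M)
  if (n == 0) return(1)
  if (max(abs(M)) < 1e-6) return(1)
  loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
  loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
  keep <- rank(M, ties.method = "first") >= loM &
    rank(M, ties.method = "first") <= hiM &
    rank(A, ties.method = "first") >= loA &
    rank(A, ties.method = "first") <= hiA
  if (!any(keep)) return(1)
  f <- sum(M[keep] / v[keep]) / sum(1 / v[keep])
  2^f
}

#' Trimmed mean of M-values scaling factors (TMM and TMMwsp)
#'
#' The reference sample is the one whose 75th-percentile count proportion is
#' closest to the across-sample mean of that quantile. For each sample,
#' gene-wise log-ratios (M) and average log abundances (A) against the
#' reference are computed over genes positive in both libraries, doubly
#' trimmed (30% on M, 5% on A by default), and combined as a
#' precision-weighted mean; the factor is 2 to that mean, rescaled so factors
#' have geometric mean 1. With `singleton_pairing = TRUE` (the sparse-data
#' TMMwsp variant) genes positive in only one of the two libraries are kept
#' as rank-matched pseudo-pairs rather than discarded; on a zero-free matrix
#' the two variants coincide.
#'
#' @param counts Count matrix with at least two samples.
#' @param logratio_trim,abs_trim Two-sided trim fractions on M and A.
#' @param singleton_pairing Use the sparse-data singleton-pairing variant.
#' @return A `norm_factors` tibble (method `"TMM"` or `"TMMwsp"`).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05,
                        singleton_pairing = FALSE) {
  validate_counts(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample with zero total counts", call. = FALSE)
  q75 <- vapply(seq_len(ncol(counts)), function(j)
    stats::quantile(counts[, j], 0.75) / lib[j], numeric(1))
  ref_idx <- which.min(abs(q75 - mean(q75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    if (j == ref_idx) return(1)
    tmm_one(counts[, j], counts[, ref_idx], lib[j], lib[ref_idx],
            logratio_trim, abs_trim, singleton_pairing)
  }, numeric(1))
  f <- geomean_rescale(f)
  norm_factor_tibble(colnames(counts), lib, f,
                     if (singleton_pairing) "TMMwsp" else "TMM")
}

#' Unit scaling factors
#'
#' Library-size-only normalization: all factors 1.
#'
#' @param counts Count matrix.
#' @return A `norm_factors` tibble (method `"NONE"`).
#' @export
none_factors <- function(counts) {
  validate_counts(counts)
  lib <- colSums(counts)
  norm_factor_tibble(colnames(counts), lib, rep(1, ncol(counts)), "NONE")
}

#' Log2 counts per million on effective library sizes
#'
#' `log2((count + prior) / (effective_lib_size + 2 * prior) * 1e6)`.
#'
#' @param counts Count matrix.
#' @param factors A `norm_factors` tibble covering the samples; default unit
#'   factors.
#' @param prior_count Offset stabilising the log at zero counts.
#' @return A real matrix with the dimensions and dimnames of `counts` and
#'   attribute `scale = "logCPM"`.
#' @export
log_cpm <- function(counts, factors = none_factors(counts), prior_count = 0.5) {
  validate_counts(counts)
  idx <- match(colnames(counts), factors$sample_id)
  if (anyNA(idx)) stop("factors missing samples", call. = FALSE)
  eff <- factors$effective_lib_size[idx]
  if (any(eff <= 0)) stop("non-positive effective library size", call. = FALSE)
  out <- log2(sweep(counts + prior_count, 2, eff + 2 * prior_count, `/`) * 1e6)
  attr(out, "scale") <- "logCPM"
  out
}

#' Mitochondrial gene-set ratio normalization
#'
#' Each entry is divided by the sample's summed counts over the `MT_NORM`
#' reference set (the twelve mitochondrially encoded genes), treating that
#' set as a stable internal reference. Samples whose reference sum is zero
#' get missing values and are listed in the `failed_samples` attribute.
#'
#' @param counts Count matrix.
#' @param sets `gene_sets` providing `MT_NORM`.
#' @return A real matrix with attribute `scale = "ratio_MT"`.
#' @export
mt_ratio_normalize <- function(counts, sets = default_gene_sets()) {
  validate_counts(counts)
  mt <- intersect(sets$MT_NORM, rownames(counts))
  if (length(mt) == 0) stop("no MT_NORM gene present in matrix", call. = FALSE)
  mt_sum <- colSums(counts[mt, , drop = FALSE])
  out <- sweep(counts, 2, mt_sum, `/`)
  failed <- colnames(counts)[mt_sum == 0]
  if (length(failed)) {
    out[, failed] <- NA_real_
    warning("zero mitochondrial reference sum; entries set missing for: ",
            paste(failed, collapse = ", "))
  }
  attr(out, "scale") <- "ratio_MT"
  attr(out, "failed_samples") <- failed
  out
}
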