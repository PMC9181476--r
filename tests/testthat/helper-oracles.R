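# Fixture builders and independently coded oracles used across the suite.

mk_counts <- function(..., genes = NULL) {
  cols <- list(...)
  m <- do.call(cbind, cols)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(m)))
  rownames(m) <- genes
  if (is.null(names(cols))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  else colnames(m) <- names(cols)
  storage.mode(m) <- "integer"
  m
}

rand_counts <- function(n_genes, n_samples, mu = 50, size = 2, seed = 1,
                        min1 = FALSE) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = mu, size = size),
              nrow = n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  if (min1) m <- m + 1L
  storage.mode(m) <- "integer"
  m
}

mk_meta <- function(counts, tissue_state, subject_id = NULL, gender = NULL,
                    quarter = "Q1", region = "arm") {
  n <- ncol(counts)
  if (is.null(subject_id)) subject_id <- paste0("sub", seq_len(n))
  if (is.null(gender)) gender <- rep(c("F", "M"), length.out = n)
  tibble::tibble(sample_id = colnames(counts),
                 subject_id = subject_id,
                 tissue_state = rep(tissue_state, length.out = n),
                 gender = gender,
                 quarter = rep(quarter, length.out = n),
                 region = rep(region, length.out = n))
}

# paired LS/NL meta: samples ordered (LS_1..LS_k, NL_1..NL_k)
mk_paired_meta <- function(counts, k) {
  tibble::tibble(
    sample_id = colnames(counts),
    subject_id = rep(paste0("sub", seq_len(k)), 2),
    tissue_state = rep(c("LS", "NL"), each = k),
    gender = rep(rep(c("F", "M"), length.out = k), 2),
    quarter = "Q1", region = "arm")
}

# --- normalization oracles (explicit, loop-based) ------------------------

oracle_rle_size_factors <- function(m) {
  keep <- apply(m, 1, function(r) all(r > 0))
  sub <- m[keep, , drop = FALSE]
  gm <- apply(sub, 1, function(r) prod(r)^(1 / length(r)))
  sf <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) sf[j] <- median(sub[, j] / gm)
  sf / prod(sf)^(1 / length(sf))
}

oracle_tmm_factors <- function(m, logratio_trim = 0.30, abs_trim = 0.05) {
  lib <- colSums(m)
  f75 <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) f75[j] <- quantile(m[, j], 0.75) / lib[j]
  ref <- which.min(abs(f75 - mean(f75)))
  fac <- numeric(ncol(m))
  for (j in seq_len(ncol(m))) {
    if (j == ref) { fac[j] <- 1; next }
    o <- m[, j]; r <- m[, ref]
    use <- o > 0 & r > 0
    po <- o[use] / lib[j]; pr <- r[use] / lib[ref]
    M <- log2(po / pr)
    A <- 0.5 * log2(po * pr)
    w <- (lib[j] - o[use]) / (lib[j] * o[use]) +
      (lib[ref] - r[use]) / (lib[ref] * r[use])
    n <- length(M)
    # explicit sorted trim windows rather than rank arithmetic
    ordM <- order(M); ordA <- order(A)
    loM <- floor(n * logratio_trim) + 1; hiM <- n + 1 - loM
    loA <- floor(n * abs_trim) + 1; hiA <- n + 1 - loA
    keepM <- ordM[seq(loM, hiM)]
    keepA <- ordA[seq(loA, hiA)]
    keep <- intersect(keepM, keepA)
    if (max(abs(M)) < 1e-6 || length(keep) == 0) { fac[j] <- 1; next }
    fac[j] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  fac / prod(fac)^(1 / length(fac))
}

oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# two-sided Fisher p by exhaustive enumeration of the hypergeometric support
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# exhaustive double-loop NOIseq-style probability (no thinning)
oracle_noiseq_prob <- function(expr, groups, test, ref) {
  m_t <- rowMeans(expr[, groups == test, drop = FALSE])
  m_r <- rowMeans(expr[, groups == ref, drop = FALSE])
  M <- m_t - m_r
  D <- abs(2^m_t - 2^m_r)
  nM <- c(); nD <- c()
  for (g in c(test, ref)) {
    idx <- which(groups == g)
    for (a in seq_along(idx)) for (b in seq_along(idx)) if (a < b) {
      nM <- c(nM, expr[, idx[a]] - expr[, idx[b]])
      nD <- c(nD, abs(2^expr[, idx[a]] - 2^expr[, idx[b]]))
    }
  }
  out <- numeric(length(M))
  for (i in seq_along(M)) out[i] <- mean(abs(nM) < abs(M[i]) & nD < D[i])
  names(out) <- rownames(expr)
  out
}

# Build one QC test column over a fixed universe: one EDC carrier gene, one
# mitochondrial gene, and fillers soaking up the remaining total so the
# sample hits exact detection/signal/fraction targets.
qc_universe <- function(n_fillers = 400) {
  c("FLG", "MT-CO1", sprintf("f%03d", seq_len(n_fillers)))
}

build_qc_col <- function(n_detected, edc_sum, mt_sum, total,
                         genes = qc_universe()) {
  col <- setNames(integer(length(genes)), genes)
  col["FLG"] <- edc_sum
  col["MT-CO1"] <- mt_sum
  n_f <- n_detected - (edc_sum > 0) - (mt_sum > 0)
  rest <- total - edc_sum - mt_sum
  stopifnot(n_f > 0, rest >= n_f)
  base <- rest %/% n_f
  col[genes[3:(2 + n_f)]] <- base
  col[genes[3]] <- base + (rest - base * n_f)
  stopifnot(sum(col) == total, sum(col >= 1) == n_detected)
  col
}
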