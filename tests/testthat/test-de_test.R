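# Designs, dispersion estimation, the three DE engines, and ZI weights.

# two-group unpaired fixture: k per group, constant library sizes
two_group <- function(n_genes, k, mu_a, mu_b, size = 5, seed = 1,
                      deg_idx = integer(0)) {
  set.seed(seed)
  mu <- matrix(mu_a, n_genes, 2 * k)
  mu[deg_idx, (k + 1):(2 * k)] <- mu_b
  m <- matrix(rnbinom(length(mu), mu = mu, size = size), n_genes,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(2 * k))))
  storage.mode(m) <- "integer"
  meta <- mk_meta(m, tissue_state = rep(c("HC", "LS"), each = k))
  list(counts = m, meta = meta)
}

test_that("design construction enforces pairing and covariates", {
  m <- rand_counts(10, 6, seed = 1, min1 = TRUE)
  meta <- mk_paired_meta(m, 3)
  d <- design_spec(meta, "LS_vs_NL")
  expect_true(d$paired)
  expect_equal(d$coef, "stateLS")
  # subject blocking columns present
  expect_true(any(grepl("subject", colnames(d$design))))

  # one subject lacking its partner drops out
  meta2 <- meta[-1, ]
  d2 <- design_spec(meta2, "LS_vs_NL")
  expect_false("sub1" %in% unique(sub(".*sub", "sub", d2$samples)))

  expect_error(design_spec(meta[c(1, 4), ] , "LS_vs_NL"), ">= 2 subjects")
  expect_error(design_spec(meta, "LS_vs_XX"), "contrast")

  # unpaired contrast adjusts for gender
  fix <- two_group(5, 4, 50, 50)
  du <- design_spec(fix$meta, "LS_vs_HC")
  expect_false(du$paired)
  expect_true(any(grepl("gender", colnames(du$design))))
  expect_false(any(grepl("gender", colnames(
    design_spec(fix$meta, "LS_vs_HC", adjust = FALSE)$design))))
})

test_that("dispersion estimation recovers Poisson and NB truth", {
  fix_p <- two_group(400, 20, 60, 60, size = 1e8, seed = 2)
  d <- design_spec(fix_p$meta, "LS_vs_HC")
  f <- none_factors(fix_p$counts)
  disp_p <- estimate_dispersion(fix_p$counts, d, f)
  expect_lte(median(disp_p$dispersion), 0.05)

  fix_nb <- two_group(400, 20, 60, 60, size = 1 / 0.4, seed = 3)
  disp_nb <- estimate_dispersion(fix_nb$counts, design_spec(fix_nb$meta, "LS_vs_HC"),
                                 none_factors(fix_nb$counts))
  expect_gte(median(disp_nb$dispersion), 0.25)
  expect_lte(median(disp_nb$dispersion), 0.6)

  # constant gene: raw moment estimate collapses to zero
  cm <- fix_nb$counts
  cm[1, ] <- 50L
  disp_c <- estimate_dispersion(cm, design_spec(fix_nb$meta, "LS_vs_HC"),
                                none_factors(cm))
  expect_equal(disp_c$dispersion_raw[1], 0)
  expect_lt(disp_c$dispersion[1], disp_c$dispersion_trend[1] + 1e-12)
})

test_that("NB GLM recovers planted effects and flags degenerate genes", {
  # few DEGs among many genes (clean library offset), deep counts, modest
  # dispersion: the coefficient should sit within +/- 0.3 of the truth
  fix <- two_group(300, 20, 200, 800, size = 10, seed = 4, deg_idx = 1:3)
  fix$counts[6, ] <- 0L
  d <- design_spec(fix$meta, "LS_vs_HC")
  f <- none_factors(fix$counts)
  disp <- estimate_dispersion(fix$counts, d, f)
  res <- nb_glm_test(fix$counts, d, f, disp)

  expect_true(all(abs(res$log2fc[1:3] - 2) < 0.3))
  expect_true(all(res$p[1:3] < 1e-4))
  expect_equal(res$note[6], "all_zero")
  expect_true(is.na(res$p[6]))
  expect_true(all(res$padj >= res$p, na.rm = TRUE))
})

test_that("NB GLM type-I error is near nominal on null data", {
  fix <- two_group(500, 20, 50, 50, size = 2.5, seed = 5)
  d <- design_spec(fix$meta, "LS_vs_HC")
  f <- none_factors(fix$counts)
  disp <- estimate_dispersion(fix$counts, d, f)
  res <- nb_glm_test(fix$counts, d, f, disp)
  frac <- mean(res$p < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.10)
})

test_that("reversing a contrast negates log2FC and preserves p", {
  fix <- two_group(40, 6, 80, 160, size = 4, seed = 6, deg_idx = 1:4)
  meta <- mk_paired_meta(fix$counts, 6)
  f <- tmm_factors(fix$counts)
  d1 <- design_spec(meta, "LS_vs_NL")
  d2 <- design_spec(meta, "NL_vs_LS")
  disp <- estimate_dispersion(fix$counts, d1, f)
  r1 <- nb_glm_test(fix$counts, d1, f, disp)
  r2 <- nb_glm_test(fix$counts, d2, f, disp)
  expect_equal(r1$log2fc, -r2$log2fc, tolerance = 1e-6)
  expect_equal(r1$p, r2$p, tolerance = 1e-6)

  v1 <- voom_weighted_test(fix$counts, f, d1)
  v2 <- voom_weighted_test(fix$counts, f, d2)
  expect_equal(v1$log2fc, -v2$log2fc, tolerance = 1e-9)
  expect_equal(v1$p, v2$p, tolerance = 1e-9)

  e <- log_cpm(fix$counts, f)
  g <- meta$tissue_state
  n1 <- noiseq_rank(e, g, "LS_vs_NL")
  n2 <- noiseq_rank(e, g, "NL_vs_LS")
  expect_equal(n1$log2fc, -n2$log2fc)
  expect_equal(n1$prob, n2$prob)
})

test_that("engines are invariant to joint column/metadata permutation", {
  fix <- two_group(30, 5, 60, 120, size = 4, seed = 7, deg_idx = 1:3)
  perm <- sample(ncol(fix$counts))
  m2 <- fix$counts[, perm]
  meta2 <- fix$meta[perm, ]
  d1 <- design_spec(fix$meta, "LS_vs_HC")
  d2 <- design_spec(meta2, "LS_vs_HC")
  f1 <- tmm_factors(fix$counts); f2 <- tmm_factors(m2)
  r1 <- nb_glm_test(fix$counts, d1, f1, estimate_dispersion(fix$counts, d1, f1))
  r2 <- nb_glm_test(m2, d2, f2, estimate_dispersion(m2, d2, f2))
  expect_equal(r1$log2fc, r2$log2fc, tolerance = 1e-9)
  expect_equal(r1$p, r2$p, tolerance = 1e-9)
})

test_that("voom weights flatten under homoscedastic log-scale noise", {
  set.seed(8)
  n <- 200; k <- 8
  mu_g <- runif(n, 4, 10)                     # mean logCPM spread
  E <- matrix(rnorm(n * 2 * k, mean = mu_g, sd = 0.25), n)
  lib <- 1e6
  counts <- round(2^E * lib / 1e6)
  dimnames(counts) <- list(paste0("g", 1:n), paste0("s", 1:(2 * k)))
  storage.mode(counts) <- "integer"
  meta <- mk_meta(counts, rep(c("HC", "LS"), each = k))
  d <- design_spec(meta, "LS_vs_HC", adjust = FALSE)
  res <- voom_weighted_test(counts, none_factors(counts), d)
  w <- attr(res, "weights")
  expect_lt(sd(w) / mean(w), 0.10)
})

test_that("voom p-values are uniform under the null", {
  fix <- two_group(500, 10, 80, 80, size = 3, seed = 9)
  d <- design_spec(fix$meta, "LS_vs_HC")
  res <- voom_weighted_test(fix$counts, tmm_factors(fix$counts), d)
  ks <- suppressWarnings(ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("quality weights single out a noise-inflated sample", {
  set.seed(10)
  n <- 150; k <- 6
  E <- matrix(rnorm(n * 2 * k, mean = 8, sd = 0.3), n)
  E[, 3] <- rnorm(n, 8, 3)                    # one sample, 10x noise
  counts <- round(2^E * 1e6 / 1e6)
  dimnames(counts) <- list(paste0("g", 1:n), paste0("s", 1:(2 * k)))
  storage.mode(counts) <- "integer"
  meta <- mk_meta(counts, rep(c("HC", "LS"), each = k))
  d <- design_spec(meta, "LS_vs_HC", adjust = FALSE)
  res <- voom_weighted_test(counts, none_factors(counts), d,
                            quality_weights = TRUE)
  sw <- attr(res, "sample_weights")
  expect_equal(unname(which.min(sw)), 3)
})

test_that("ranking probabilities equal the exhaustive noise-pair oracle", {
  set.seed(11)
  e <- matrix(rnorm(50 * 8, mean = 6, sd = 1), 50,
              dimnames = list(paste0("g", 1:50), paste0("s", 1:8)))
  e[1:3, 5:8] <- e[1:3, 5:8] + 3
  g <- rep(c("NL", "LS"), each = 4)
  res <- noiseq_rank(e, g, "LS_vs_NL", n_noise_pairs = 1e9)
  oracle <- oracle_noiseq_prob(e, g, "LS", "NL")
  expect_equal(res$prob, unname(oracle[res$gene]), tolerance = 1e-12)
  # planted genes carry the top ranks; a flat gene ranks behind them
  expect_true(all(res$rank[1:3] <= 5))
  expect_error(noiseq_rank(e[, 1:5], c(rep("NL", 4), "LS")), ">= 2 samples")
})

test_that("strong planted effects reach the top-10 upregulated list", {
  hits <- vapply(1:10, function(seed) {
    fix <- two_group(200, 5, 50, 400, size = 8, seed = 100 + seed,
                     deg_idx = 1)
    groups <- rep(c("NL", "LS"), each = 5)   # elevated mean sits in LS
    e <- log_cpm(fix$counts, tmm_factors(fix$counts))
    res <- noiseq_rank(e, groups, "LS_vs_NL")
    degs <- apply_cutoff(res, "top10up")
    "g1" %in% degs$gene
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("zero-inflation weights separate dropout from NB zeros", {
  set.seed(12)
  n_s <- 120
  L <- round(10^runif(n_s, 3, 6))
  q <- 5e-4                                   # mu from 0.5 to 500
  y <- rnbinom(n_s, mu = q * L, size = 2)
  low <- which(L < 1e5)
  forced <- sample(low, length(low) / 2)
  nb_zero <- setdiff(which(y == 0), forced)
  y[forced] <- 0L
  m <- matrix(c(y, pmax(y, 1L)), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), paste0("s", 1:n_s)))
  storage.mode(m) <- "integer"
  f <- none_factors(m)
  f$lib_size <- L; f$effective_lib_size <- L
  W <- zero_inflation_weights(m, f)

  # nonzero observations keep weight exactly 1; zeros stay in (0, 1]
  expect_true(all(W[1, y > 0] == 1))
  expect_true(all(W > 0 & W <= 1))
  # the zero-free gene is untouched
  expect_true(all(W[2, ] == 1))
  # forced dropout zeros average lower weight than genuine NB zeros
  expect_lt(mean(W[1, forced]), mean(W[1, nb_zero]))
})
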