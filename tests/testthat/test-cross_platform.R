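# Replicate averaging, per-sample and per-gene Spearman concordance, depth
# association, and tissue-state comparison.

test_that("replicate averaging is the column mean, order-invariant", {
  m <- mk_counts(c(10L, 4L), c(20L, 8L), c(6L, 2L))
  colnames(m) <- c("r1", "r2", "r3")
  map <- tibble::tibble(replicate_id = c("r1", "r2", "r3"),
                        subject_id = c("A", "A", "B"))
  avg <- average_replicates(m, map)
  expect_equal(avg[, "A"], c(g1 = 15, g2 = 6))
  expect_equal(avg[, "B"], c(g1 = 6, g2 = 2))

  two_same <- average_replicates(m[, c("r1", "r1_b" = "r1")], map[1:2, ] |>
    dplyr::mutate(replicate_id = c("r1", "r1")))
  # identical replicates average to themselves
  expect_equal(unname(two_same[, "A"]), unname(m[, "r1"]))

  perm <- average_replicates(m[, c("r3", "r2", "r1")], map)
  expect_equal(perm[, colnames(avg)], avg)

  expect_error(average_replicates(m[, 1:2], map), "missing from matrix: r3")
})

cross_fixture <- function() {
  set.seed(20)
  genes <- paste0("g", 1:30)
  bx <- matrix(rpois(30 * 2, 200), 30, 2, dimnames = list(genes, c("A", "B")))
  bx[, "A"] <- as.integer(sample(seq(100L, 390L, by = 10L)))  # tie-free
  # tape sample t1: strictly monotone transform of subject A's profile
  t1 <- as.integer(round((bx[, "A"] / 10)^2))
  t2 <- as.integer(rpois(30, 40))
  t3 <- integer(30)                            # degenerate: all zero
  t4 <- as.integer(rpois(30, 40))              # subject without a biopsy
  tape <- cbind(t1 = t1, t2 = t2, t3 = t3, t4 = t4)
  rownames(tape) <- genes
  meta <- tibble::tibble(sample_id = c("t1", "t2", "t3", "t4"),
                         subject_id = c("A", "B", "B", "C"),
                         tissue_state = c("LS", "NL", "HC", "HC"),
                         gender = "F", quarter = "Q1", region = "arm")
  list(tape = tape, meta = meta, bx = bx, genes = genes)
}

test_that("per-sample Spearman handles monotone, degenerate, unmatched cases", {
  fx <- cross_fixture()
  corr <- per_sample_spearman(fx$tape, fx$meta, fx$bx, fx$genes)
  # monotone transform: perfect rank agreement
  expect_equal(corr$rho[corr$sample_id == "t1"], 1)
  # all-zero tape column: undefined, reported missing
  expect_true(is.na(corr$rho[corr$sample_id == "t3"]))
  expect_true(corr$matched[corr$sample_id == "t3"])
  # subject C has no biopsy: skipped and reported
  expect_false(corr$matched[corr$sample_id == "t4"])
  expect_true(is.na(corr$rho[corr$sample_id == "t4"]))

  # oracle equivalence on the random sample
  expect_equal(corr$rho[corr$sample_id == "t2"],
               oracle_spearman(fx$tape[, "t2"], fx$bx[, "B"]),
               tolerance = 1e-12)
})

test_that("depth association recovers an exact linear relation", {
  corr <- tibble::tibble(
    sample_id = paste0("s", 1:12),
    subject_id = paste0("p", 1:12),
    tissue_state = rep(c("LS", "NL", "HC"), 4),
    total_count = round(10^seq(3, 6, length.out = 12)),
    rho = NA_real_, p = NA_real_, matched = TRUE)
  corr$rho <- 0.1 + 0.2 * log10(corr$total_count)
  class(corr) <- c("correlation_result", class(corr))
  d <- suppressWarnings(depth_association(corr))  # exact fit warns
  expect_equal(d$slope[d$group == "pooled"], 0.2, tolerance = 1e-9)
  expect_lt(d$p[d$group == "pooled"], 1e-12)

  flat <- corr; flat$total_count <- 1000
  expect_error(depth_association(flat), "constant")
})

test_that("shuffled concordance shows no depth association", {
  set.seed(33)
  hits <- vapply(1:10, function(i) {
    corr <- tibble::tibble(
      sample_id = paste0("s", 1:20), subject_id = paste0("p", 1:20),
      tissue_state = "LS",
      total_count = round(10^runif(20, 3, 6)),
      rho = runif(20, -0.2, 0.6), p = NA_real_, matched = TRUE)
    class(corr) <- c("correlation_result", class(corr))
    depth_association(corr)$p[1] < 0.05
  }, logical(1))
  expect_lte(mean(hits), 0.3)
})

test_that("group comparison is a rank test with its invariances", {
  corr <- tibble::tibble(
    sample_id = paste0("s", 1:20), subject_id = paste0("p", 1:20),
    tissue_state = rep(c("LS", "HC"), each = 10),
    total_count = 1e4,
    rho = c(seq(0.5, 0.7, length.out = 10), seq(0.1, 0.3, length.out = 10)),
    p = NA_real_, matched = TRUE)
  class(corr) <- c("correlation_result", class(corr))
  g <- compare_groups(corr)
  # LS strictly above HC with n = 10 each: rank-sum tail below 1e-3
  expect_lt(g$p[g$contrast == "LS_vs_HC"], 0.001)
  # NL absent: that contrast is skipped
  expect_false(any(grepl("NL", g$contrast)))

  shifted <- corr; shifted$rho <- shifted$rho + 0.25
  class(shifted) <- class(corr)
  expect_equal(compare_groups(shifted)$p, g$p)

  same <- corr; same$rho <- rep(corr$rho[1:10], 2)
  class(same) <- class(corr)
  expect_gt(compare_groups(same)$p[1], 0.9)
})

test_that("layer correlation matches the rank oracle and reports absentees", {
  sets <- default_gene_sets()
  layer_genes <- unlist(sets[grep("^LAYER_", names(sets))])
  genes <- c(layer_genes[1:10], paste0("x", 1:5))
  set.seed(40)
  subjects <- paste0("p", 1:10)
  bx <- matrix(rpois(length(genes) * 10, 150), length(genes), 10,
               dimnames = list(genes, subjects))
  tape <- matrix(rpois(length(genes) * 10, 60), length(genes), 10,
                 dimnames = list(genes, paste0("t", 1:10)))
  tape[1, ] <- as.integer(bx[1, ] * 2L)      # marker equal up to scale: rho 1
  meta <- tibble::tibble(sample_id = colnames(tape), subject_id = subjects,
                         tissue_state = "LS", gender = "F", quarter = "Q1",
                         region = "arm")
  lc <- layer_marker_correlation(tape, meta, bx, sets)
  g1 <- layer_genes[1]
  expect_equal(lc$rho[lc$gene == g1], 1)
  # markers outside the fixture are reported missing, not dropped
  absent <- setdiff(layer_genes, genes)
  expect_true(all(absent %in% lc$gene))
  expect_true(all(!lc$present[lc$gene %in% absent]))

  g2 <- layer_genes[2]
  expect_equal(lc$rho[lc$gene == g2],
               oracle_spearman(tape[g2, ], bx[g2, ]), tolerance = 1e-12)
})

test_that("the pipeline's order is average-then-correlate, and it matters", {
  genes <- paste0("g", 1:10)
  set.seed(41)
  bx <- matrix(rpois(30, 100), 10, 3,
               dimnames = list(genes, c("A_r1", "A_r2", "A_r3")))
  bx[, 3] <- rev(bx[, 3])                      # discordant replicate
  map <- tibble::tibble(replicate_id = colnames(bx), subject_id = "A")
  tape_col <- matrix(rpois(10, 50), 10, 1, dimnames = list(genes, "t1"))
  meta <- tibble::tibble(sample_id = "t1", subject_id = "A",
                         tissue_state = "LS", gender = "F", quarter = "Q1",
                         region = "arm")
  avg_first <- per_sample_spearman(tape_col, meta,
                                   average_replicates(bx, map), genes)$rho
  corr_each <- vapply(1:3, function(j)
    oracle_spearman(tape_col[, 1], bx[, j]), numeric(1))
  expect_false(isTRUE(all.equal(avg_first, mean(corr_each))))
})

test_that("fold-change-space comparison runs on a paired fixture", {
  st <- simulate_experiment(sim_config(n_subjects_AD = 6, n_subjects_HC = 4,
                                       n_genes = 200, seed = 3))
  bx <- average_replicates(st$biopsy$counts, st$biopsy$replicate_map)
  det <- rownames(st$tape$counts)[rowSums(st$tape$counts >= 2) > 10]
  fc <- fold_change_correlation(st$tape$counts, st$tape$meta, bx, det)
  expect_true(is.finite(fc$rho))
  expect_equal(nrow(fc$fc), length(intersect(det, rownames(bx))))
})
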