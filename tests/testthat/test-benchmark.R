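# Cutoff grammar, accuracy scoring, the grid harness, and the signature.

mk_de_result <- function(n = 100, seed = 1, ranked = TRUE) {
  set.seed(seed)
  r <- tibble::tibble(
    gene = sprintf("g%03d", 1:n),
    log2fc = rnorm(n, 0, 1.5),
    statistic = rnorm(n),
    p = runif(n),
    padj = NA_real_)
  r$padj <- p.adjust(r$p, "BH")
  if (ranked) {
    r$prob <- runif(n)
    r$rank <- NA_integer_
    r$rank[order(-r$prob, -abs(r$log2fc), r$gene)] <- 1:n
  } else {
    r$rank <- NA_integer_
    r$rank[order(r$p, -abs(r$log2fc), r$gene)] <- 1:n
  }
  r$note <- NA_character_; r$engine <- if (ranked) "noiseq" else "nbglm"
  r$contrast <- "LS_vs_NL"
  class(r) <- c("de_result", class(r))
  r
}

test_that("cutoff grammar parses the benchmark table's cutoffs", {
  expect_equal(de_cutoff("fc>2,p<0.05")$type, "fc_p")
  expect_equal(de_cutoff("fc>2,padj<0.05")$type, "fc_padj")
  expect_equal(de_cutoff("top5%")$frac, 0.05)
  expect_equal(de_cutoff("top20up")$k, 20L)
  expect_error(de_cutoff("best10"), "unrecognised")
})

test_that("fold-change/p cutoffs use strict inequalities", {
  r <- mk_de_result(4, ranked = FALSE)
  r$log2fc <- c(1.2, 1.2, 0.9, -1.5)
  r$p <- c(0.01, 0.05, 0.01, 0.04)
  d <- apply_cutoff(r, "fc>2,p<0.05")
  expect_setequal(d$gene, c("g001", "g004"))      # p = 0.05 exactly excluded
  expect_equal(d$direction[d$gene == "g004"], "down")
})

test_that("top-k-up selects exactly the best-ranked upregulated genes", {
  r <- mk_de_result(100, seed = 3)
  d <- apply_cutoff(r, "top10up")
  up <- r[r$log2fc > 0, ]
  expected <- up$gene[order(up$rank)][1:10]
  expect_setequal(d$gene, expected)
  expect_equal(nrow(apply_cutoff(r, "top5%")), 5)

  flat <- mk_de_result(20, ranked = FALSE)
  expect_error(apply_cutoff(flat, "top10up"), "ranking engine")
})

test_that("accuracy matches the published record format", {
  gold <- tibble::tibble(gene = sprintf("G%02d", 1:20),
                         direction = rep("up", 20))
  degs <- tibble::tibble(gene = c(sprintf("G%02d", 1:7), "X1", "X2", "X3"),
                         direction = "up")
  a <- compute_accuracy(degs, gold)
  expect_equal(a$accuracy, 70.00)
  expect_equal(c(a$n_correct_up, a$n_correct_down), c(7L, 0L))

  disjoint <- tibble::tibble(gene = c("Y1", "Y2"), direction = "up")
  expect_equal(compute_accuracy(disjoint, gold)$accuracy, 0)

  subset_ok <- tibble::tibble(gene = c("G01", "G02"), direction = "up")
  expect_equal(compute_accuracy(subset_ok, gold)$accuracy, 100)

  # wrong direction is not correct
  flipped <- tibble::tibble(gene = "G01", direction = "down")
  expect_equal(compute_accuracy(flipped, gold)$accuracy, 0)

  empty <- tibble::tibble(gene = character(0), direction = character(0))
  expect_true(is.na(compute_accuracy(empty, gold)$accuracy))

  nodir <- gold; nodir$direction[1] <- NA
  expect_warning(a2 <- compute_accuracy(flipped, nodir), "direction")
  expect_equal(a2$accuracy, 100)
})

# small simulated study shared by the harness tests
bench_fixture <- function(seed = 7) {
  st <- simulate_experiment(sim_config(n_subjects_AD = 10, n_subjects_HC = 4,
                                       n_genes = 400, seed = seed))
  tape <- st$tape$counts
  rep <- suppressWarnings(score_sample_qc(tape, st$gene_sets))
  filt <- filter_samples(tape, rep)
  det <- detect_genes(filt, st$annotation)
  meta <- st$tape$meta[st$tape$meta$sample_id %in% colnames(filt), ]
  list(counts = filt[det, , drop = FALSE], full = filt, meta = meta,
       gold = truth_gold_standard(st, "LS_vs_NL"))
}

test_that("the harness runs a grid, scores it, and is deterministic", {
  fx <- bench_fixture()
  grid <- tibble::tribble(
    ~id, ~norm, ~engine, ~cutoff,
    "voom_TMM", "tmm", "voom", "fc>2,p<0.05",
    "NOIseq_top10up", "tmmwsp", "noiseq", "top10up")
  b1 <- suppressWarnings(run_benchmark(fx$counts, fx$meta, fx$gold, grid,
                                       full_counts = fx$full))
  b2 <- suppressWarnings(run_benchmark(fx$counts, fx$meta, fx$gold, grid,
                                       full_counts = fx$full))
  expect_equal(b1$accuracy, b2$accuracy)
  expect_equal(names(b1$deg_sets), grid$id)

  # single-method grid reduces to that method's records
  b3 <- suppressWarnings(run_benchmark(fx$counts, fx$meta, fx$gold, grid[1, ],
                                       full_counts = fx$full))
  expect_equal(b3$accuracy$accuracy, b1$accuracy$accuracy[1])

  # intersection counts sum to the union of true-positive sets
  expect_equal(sum(b1$intersections$n_genes),
               length(unique(unlist(lapply(b1$tp_sets, function(d) d$gene)))))
})

test_that("identical call sets put all intersection mass on the joint cell", {
  fx <- bench_fixture()
  grid <- tibble::tribble(
    ~id, ~norm, ~engine, ~cutoff,
    "m1", "tmm", "voom", "fc>2,p<0.05",
    "m2", "tmm", "voom", "fc>2,p<0.05")
  b <- suppressWarnings(run_benchmark(fx$counts, fx$meta, fx$gold, grid,
                                      full_counts = fx$full))
  expect_equal(b$deg_sets$m1, b$deg_sets$m2)
  if (nrow(b$intersections) > 0) {
    expect_equal(b$intersections$methods, "m1&m2")
  }
})

test_that("a failing method is recorded and the rest still run", {
  fx <- bench_fixture()
  grid <- tibble::tribble(
    ~id, ~norm, ~engine, ~cutoff,
    "bad", "rle", "nbglm", "fc>2,padj<0.05",
    "ok", "tmm", "voom", "fc>2,p<0.05")
  # sabotage RLE: inject a zero into every gene so no all-nonzero gene exists
  cm <- fx$counts
  for (i in seq_len(nrow(cm))) cm[i, (i %% ncol(cm)) + 1] <- 0L
  b <- suppressWarnings(run_benchmark(cm, fx$meta, fx$gold, grid,
                                      full_counts = fx$full))
  expect_match(b$errors$bad, "pre-filter")
  expect_false(is.na(b$accuracy$accuracy[2]) && is.null(b$deg_sets$ok))
})

test_that("the ensemble signature is the union of true positives", {
  bench <- structure(list(
    tp_sets = list(
      m1 = tibble::tibble(gene = c("A", "B"), direction = c("up", "up")),
      m2 = tibble::tibble(gene = c("B", "C"), direction = c("up", "down")))),
    class = "benchmark_result")
  sig <- ensemble_signature(bench)
  expect_setequal(sig$gene, c("A", "B", "C"))
  expect_equal(sig$n_methods[sig$gene == "B"], 2L)
  expect_equal(sig$methods[sig$gene == "B"], "m1,m2")
  expect_equal(attr(sig, "n_up"), 2L)
  expect_equal(attr(sig, "n_down"), 1L)

  inter <- ensemble_signature(bench, mode = "intersection")
  expect_equal(inter$gene, "B")

  empty <- structure(list(tp_sets = list(m1 = tibble::tibble(
    gene = character(0), direction = character(0)))),
    class = "benchmark_result")
  expect_warning(s0 <- ensemble_signature(empty), "empty")
  expect_equal(nrow(s0), 0)
})

test_that("signature from a simulated benchmark stays inside the gold standard", {
  fx <- bench_fixture(seed = 9)
  grid <- default_method_grid()[c(2, 6, 11), ]
  b <- suppressWarnings(run_benchmark(fx$counts, fx$meta, fx$gold, grid,
                                      full_counts = fx$full))
  sig <- ensemble_signature(b)
  expect_true(all(sig$gene %in% fx$gold$gene))
  gd <- fx$gold$direction[match(sig$gene, fx$gold$gene)]
  expect_equal(unname(sig$direction), unname(gd))
  expect_equal(tidy(b), b$accuracy)
  expect_s3_class(glance(b), "tbl_df")
})
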