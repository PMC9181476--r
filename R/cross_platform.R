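# Tape-vs-biopsy concordance: replicate averaging, per-sample Spearman
# correlation, depth association, tissue-state comparison, and epidermal
# layer marker correlation.

#' Average biopsy replicates per subject and site
#'
#' Column-wise arithmetic mean of each replicate group, taken before any
#' correlation is computed; singleton groups pass through. With a `site`
#' column in the map, groups are subject-by-site and output columns are
#' named `<subject>_<site>`; otherwise one column per subject.
#'
#' @param biopsy Biopsy count matrix (columns are replicate ids).
#' @param replicate_map Tibble with `replicate_id`, `subject_id`, and
#'   optionally `site`.
#' @return A real matrix with one column per replicate group.
#' @export
average_replicates <- function(biopsy, replicate_map) {
  miss <- setdiff(replicate_map$replicate_id, colnames(biopsy))
  if (length(miss)) {
    stop("replicates missing from matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- if ("site" %in% names(replicate_map)) {
    paste(replicate_map$subject_id, replicate_map$site, sep = "_")
  } else {
    replicate_map$subject_id
  }
  groups <- unique(key)
  out <- vapply(groups, function(g) {
    cols <- replicate_map$replicate_id[key == g]
    rowMeans(biopsy[, cols, drop = FALSE])
  }, numeric(nrow(biopsy)))
  out <- matrix(out, nrow = nrow(biopsy),
                dimnames = list(rownames(biopsy), groups))
  out
}

# resolve a tape sample's biopsy partner column: subject x site if present,
# else the subject's single column
biopsy_partner <- function(subject, state, cols) {
  key <- paste(subject, state, sep = "_")
  out <- ifelse(key %in% cols, key,
                ifelse(subject %in% cols, subject, NA_character_))
  out
}

#' Per-sample Spearman correlation between tape and averaged biopsy profiles
#'
#' For each tape sample, the Spearman rank correlation (average ranks at
#' ties) between its raw counts and its subject's replicate-averaged biopsy
#' values over a detected gene list, with a two-sided p-value. Tape samples
#' without a biopsy partner, or with constant values over the gene list, are
#' reported with missing correlation rather than dropped silently.
#'
#' @param tape Tape count matrix.
#' @param meta Tape sample metadata (`sample_id`, `subject_id`,
#'   `tissue_state`).
#' @param biopsy_avg Averaged biopsy matrix from [average_replicates()].
#' @param genes Gene list to correlate over (e.g. from [detect_genes()]).
#' @return A `correlation_result` tibble: per sample `rho`, `p`,
#'   `tissue_state`, `total_count`, `matched`; summary medians per state in
#'   the `summary` attribute.
#' @export
per_sample_spearman <- function(tape, meta, biopsy_avg, genes) {
  if (length(genes) == 0) stop("empty gene list", call. = FALSE)
  g <- intersect(genes, intersect(rownames(tape), rownames(biopsy_avg)))
  if (length(g) < 3) stop("fewer than 3 shared genes", call. = FALSE)
  rows <- lapply(colnames(tape), function(s) {
    subj <- meta$subject_id[match(s, meta$sample_id)]
    state <- meta$tissue_state[match(s, meta$sample_id)]
    tot <- sum(tape[, s])
    partner <- if (is.na(subj)) NA_character_ else
      biopsy_partner(subj, state, colnames(biopsy_avg))
    if (is.na(partner)) {
      return(tibble::tibble(sample_id = s, subject_id = subj,
                            tissue_state = state, total_count = tot,
                            rho = NA_real_, p = NA_real_, matched = FALSE))
    }
    x <- tape[g, s]; y <- biopsy_avg[g, partner]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      rho <- NA_real_; pv <- NA_real_
    } else {
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                             exact = FALSE))
      rho <- unname(ct$estimate); pv <- ct$p.value
    }
    tibble::tibble(sample_id = s, subject_id = subj, tissue_state = state,
                   total_count = tot, rho = rho, p = pv, matched = TRUE)
  })
  out <- dplyr::bind_rows(rows)
  summ <- out |>
    dplyr::filter(!is.na(.data$rho)) |>
    dplyr::group_by(.data$tissue_state) |>
    dplyr::summarise(median_rho = stats::median(.data$rho),
                     n = dplyr::n(), .groups = "drop")
  attr(out, "summary") <- summ
  class(out) <- c("correlation_result", class(out))
  out
}

#' Association between concordance and tape sequencing depth
#'
#' Linear regression of the per-sample Spearman rho on log10 tape total
#' counts, pooled and per tissue state.
#'
#' @param corr A `correlation_result`.
#' @return Tibble with `group` (`pooled` and each state), `slope`, `p`, `n`.
#' @export
depth_association <- function(corr) {
  d <- corr[!is.na(corr$rho) & corr$total_count > 0, , drop = FALSE]
  if (nrow(d) < 3) stop("need >= 3 matched samples", call. = FALSE)
  if (stats::sd(log10(d$total_count)) == 0) {
    stop("constant tape depth; association undefined", call. = FALSE)
  }
  fit_one <- function(dd, label) {
    if (nrow(dd) < 3 || stats::sd(log10(dd$total_count)) == 0) {
      return(tibble::tibble(group = label, slope = NA_real_, p = NA_real_,
                            n = nrow(dd)))
    }
    fit <- stats::lm(rho ~ log10(total_count), data = dd)
    sm <- summary(fit)$coefficients
    tibble::tibble(group = label, slope = sm[2, 1], p = sm[2, 4], n = nrow(dd))
  }
  dplyr::bind_rows(
    fit_one(d, "pooled"),
    dplyr::bind_rows(lapply(split(d, d$tissue_state), function(dd)
      fit_one(dd, dd$tissue_state[1]))))
}

#' Compare concordance between tissue states
#'
#' Two-sided rank-sum (Wilcoxon) comparison of the per-sample rho between
#' each pair of tissue states; `test = "t"` switches to Welch's t-test.
#'
#' @param corr A `correlation_result`.
#' @param test `"ranksum"` or `"t"`.
#' @return Tibble with `contrast`, `p`, `n1`, `n2`; pairs with a missing
#'   group are skipped.
#' @export
compare_groups <- function(corr, test = c("ranksum", "t")) {
  test <- match.arg(test)
  d <- corr[!is.na(corr$rho), , drop = FALSE]
  pairs <- list(c("LS", "NL"), c("LS", "HC"), c("NL", "HC"))
  rows <- lapply(pairs, function(pr) {
    x <- d$rho[d$tissue_state == pr[1]]
    y <- d$rho[d$tissue_state == pr[2]]
    if (length(x) < 2 || length(y) < 2) return(NULL)
    pv <- if (test == "ranksum") {
      stats::wilcox.test(x, y, exact = FALSE)$p.value
    } else {
      stats::t.test(x, y)$p.value
    }
    tibble::tibble(contrast = paste(pr, collapse = "_vs_"), p = pv,
                   n1 = length(x), n2 = length(y))
  })
  dplyr::bind_rows(rows)
}

#' Per-gene tape-vs-biopsy correlation for epidermal layer markers
#'
#' For each marker gene, the Spearman correlation of its tape counts against
#' its subject's averaged biopsy values across matched samples, grouped by
#' epidermal layer with per-layer median rho. Markers absent from either
#' matrix are reported with missing rho, never dropped silently.
#'
#' @param tape Tape count matrix.
#' @param meta Tape sample metadata.
#' @param biopsy_avg Averaged biopsy matrix.
#' @param layer_sets `gene_sets` whose names start with `LAYER_`; the sets
#'   must be disjoint.
#' @return A `layer_correlation` tibble: `gene`, `layer`, `rho`, `p`,
#'   `present`; per-layer medians in the `summary` attribute.
#' @export
layer_marker_correlation <- function(tape, meta, biopsy_avg,
                                     layer_sets = default_gene_sets()) {
  layers <- grep("^LAYER_", names(layer_sets), value = TRUE)
  if (length(layers) == 0) stop("no LAYER_* sets supplied", call. = FALSE)
  members <- unlist(layer_sets[layers])
  if (anyDuplicated(members)) {
    stop("layer sets overlap: ", members[duplicated(members)][1], call. = FALSE)
  }
  partner <- biopsy_partner(meta$subject_id, meta$tissue_state,
                            colnames(biopsy_avg))
  sm <- meta[!is.na(partner), , drop = FALSE]
  sm$partner <- partner[!is.na(partner)]
  rows <- lapply(layers, function(ly) {
    lapply(layer_sets[[ly]], function(g) {
      if (!g %in% rownames(tape) || !g %in% rownames(biopsy_avg)) {
        return(tibble::tibble(gene = g, layer = ly, rho = NA_real_,
                              p = NA_real_, present = FALSE))
      }
      x <- tape[g, sm$sample_id]
      y <- biopsy_avg[g, sm$partner]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        return(tibble::tibble(gene = g, layer = ly, rho = NA_real_,
                              p = NA_real_, present = TRUE))
      }
      ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                             exact = FALSE))
      tibble::tibble(gene = g, layer = ly, rho = unname(ct$estimate),
                     p = ct$p.value, present = TRUE)
    })
  })
  out <- dplyr::bind_rows(unlist(rows, recursive = FALSE))
  summ <- out |>
    dplyr::filter(!is.na(.data$rho)) |>
    dplyr::group_by(.data$layer) |>
    dplyr::summarise(median_rho = stats::median(.data$rho), n = dplyr::n(),
                     .groups = "drop")
  attr(out, "summary") <- summ
  class(out) <- c("layer_correlation", class(out))
  out
}

#' Fold-change-space concordance between platforms
#'
#' Optional comparison mode: per-gene lesional/non-lesional log2 ratios of
#' group means (with a pseudocount) computed on each platform, then
#' correlated across genes by Spearman.
#'
#' @param tape,biopsy_avg Count matrices (biopsy averaged per subject).
#' @param meta Tape metadata.
#' @param genes Gene list.
#' @param pseudo Pseudocount for the log-ratio.
#' @return A list with per-gene tibble `fc` and the Spearman `rho`/`p`.
#' @export
fold_change_correlation <- function(tape, meta, biopsy_avg, genes, pseudo = 0.5) {
  g <- intersect(genes, intersect(rownames(tape), rownames(biopsy_avg)))
  ls_s <- meta$sample_id[meta$tissue_state == "LS"]
  nl_s <- meta$sample_id[meta$tissue_state == "NL"]
  if (length(ls_s) == 0 || length(nl_s) == 0) {
    stop("need LS and NL tape samples", call. = FALSE)
  }
  tape_fc <- log2((rowMeans(tape[g, ls_s, drop = FALSE]) + pseudo) /
                  (rowMeans(tape[g, nl_s, drop = FALSE]) + pseudo))
  cols <- colnames(biopsy_avg)
  bx_ls <- grep("_LS$", cols, value = TRUE)
  bx_ref <- grep("_NL$", cols, value = TRUE)
  if (length(bx_ls) == 0) {       # subject-only map: AD vs control subjects
    bx_ls <- intersect(unique(meta$subject_id[meta$tissue_state == "LS"]), cols)
    bx_ref <- intersect(unique(meta$subject_id[meta$tissue_state == "HC"]), cols)
  }
  if (length(bx_ls) == 0 || length(bx_ref) == 0) {
    stop("need lesional and reference biopsy columns", call. = FALSE)
  }
  bx_fc <- log2((rowMeans(biopsy_avg[g, bx_ls, drop = FALSE]) + pseudo) /
                (rowMeans(biopsy_avg[g, bx_ref, drop = FALSE]) + pseudo))
  ct <- suppressWarnings(stats::cor.test(tape_fc, bx_fc, method = "spearman",
                                         exact = FALSE))
  list(fc = tibble::tibble(gene = g, tape_log2fc = unname(tape_fc),
                           biopsy_log2fc = unname(bx_fc)),
       rho = unname(ct$estimate), p = ct$p.value)
}
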