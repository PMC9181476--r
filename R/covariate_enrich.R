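# Mixed-effect modeling of total-count variation and Fisher-exact gene-set
# enrichment.

#' Mixed-effect model of total transcript counts
#'
#' Fits, by maximum likelihood, a random-intercept model of per-sample
#' library size on the QC-passing samples:
#' `log10(total_count + 1) ~ tissue_state + quarter + gender + hair_signature
#' + region + (1 | subject_id)`, where the hair signature covariate is the
#' log10 KRTAP fraction, `log10((KRTAP sum + 1) / (total + 1))` — a
#' depth-free measure of hair contamination (the raw KRTAP sum would carry
#' the sample's depth and regress the response on itself). Each fixed term
#' gets a
#' likelihood-ratio p-value against the nested model without it. Constant
#' (rank-deficient) terms are dropped with a warning; if no subject has
#' replicate samples the model still fits with the random-effect variance on
#' its boundary.
#'
#' @param meta Sample metadata with `total_count` (from [validate_meta()]).
#' @param counts Count matrix (for the KRTAP covariate).
#' @param sets `gene_sets` providing `KRTAP`.
#' @return A `total_count_lmm` object: the `lme4` fit, `anova` tibble
#'   (`term`, `chisq`, `df`, `p`), the model frame.
#' @export
fit_total_count_lmm <- function(meta, counts, sets = default_gene_sets()) {
  krtap <- intersect(sets$KRTAP, rownames(counts))
  hair <- if (length(krtap)) {
    log10((colSums(counts[krtap, meta$sample_id, drop = FALSE]) + 1) /
            (colSums(counts[, meta$sample_id, drop = FALSE]) + 1))
  } else {
    warning("no KRTAP genes in matrix; hair signature dropped")
    NULL
  }
  d <- data.frame(
    y = log10(meta$total_count + 1),
    tissue_state = factor(meta$tissue_state),
    quarter = factor(meta$quarter),
    gender = factor(meta$gender),
    region = factor(meta$region),
    subject_id = factor(meta$subject_id))
  if (!is.null(hair)) d$hair_signature <- unname(hair)

  terms <- c("tissue_state", "quarter", "gender",
             if (!is.null(hair)) "hair_signature", "region")
  constant <- vapply(terms, function(t)
    length(unique(d[[t]])) < 2, logical(1))
  if (any(constant)) {
    warning("dropping constant term(s): ",
            paste(terms[constant], collapse = ", "))
    terms <- terms[!constant]
  }
  if (length(terms) == 0) stop("no usable fixed terms", call. = FALSE)
  mixed <- any(duplicated(d$subject_id))
  if (!mixed) {
    warning("no subject has replicate samples; reducing to a fixed-effects model")
  }

  fit_model <- function(tt) {
    if (mixed) {
      form <- stats::as.formula(
        paste("y ~", paste(c(tt, "1"), collapse = " + "), "+ (1 | subject_id)"))
      lme4::lmer(form, data = d, REML = FALSE,
                 control = lme4::lmerControl(check.conv.singular = "ignore"))
    } else {
      stats::lm(stats::as.formula(
        paste("y ~", paste(c(tt, "1"), collapse = " + "))), data = d)
    }
  }
  fit <- fit_model(terms)
  full_ll <- stats::logLik(fit)

  rows <- lapply(terms, function(t) {
    rfit <- fit_model(setdiff(terms, t))
    df <- attr(full_ll, "df") - attr(stats::logLik(rfit), "df")
    chisq <- max(0, 2 * (as.numeric(full_ll) - as.numeric(stats::logLik(rfit))))
    tibble::tibble(term = t, chisq = chisq, df = df,
                   p = stats::pchisq(chisq, df = max(df, 1), lower.tail = FALSE))
  })
  anova_tbl <- dplyr::arrange(dplyr::bind_rows(rows), .data$p)

  structure(list(fit = fit, anova = anova_tbl, data = tibble::as_tibble(d),
                 terms = terms),
            class = "total_count_lmm")
}

#' Fisher-exact gene-set enrichment
#'
#' For each set, the 2x2 table of query membership by set membership over the
#' universe is tested two-sided with Fisher's exact test. The reported odds
#' ratio is the sample (cross-product) odds ratio, with 0.5 added to every
#' cell when any cell is zero (Haldane correction). q-values are BH across
#' sets.
#'
#' @param query Gene list (must be a subset of `universe`).
#' @param sets `gene_sets`; each set is intersected with the universe.
#' @param universe Background gene list.
#' @return An `enrichment_result` tibble: `set`, `overlap`, `set_size`,
#'   `query_size`, `odds_ratio`, `p`, `q`.
#' @export
fisher_enrichment <- function(query, sets, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  universe <- unique(universe)
  bad <- setdiff(query, universe)
  if (length(bad)) {
    stop("query genes outside universe: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  query <- unique(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    a <- length(intersect(query, s))                     # in query, in set
    b <- length(query) - a                               # in query, not set
    cc <- length(s) - a                                  # not query, in set
    dd <- length(universe) - a - b - cc
    tab <- matrix(c(a, b, cc, dd), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    or_tab <- if (any(tab == 0)) tab + 0.5 else tab
    or <- (or_tab[1, 1] * or_tab[2, 2]) / (or_tab[1, 2] * or_tab[2, 1])
    tibble::tibble(set = nm, overlap = a, set_size = length(s),
                   query_size = length(query), odds_ratio = or, p = p)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  class(out) <- c("enrichment_result", class(out))
  out
}
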