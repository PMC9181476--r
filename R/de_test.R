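# Differential-expression engines: design construction, NB dispersion
# estimation, NB-GLM likelihood-ratio testing, a voom-style
# precision-weighted moderated-t, a NOIseq-style non-parametric ranking,
# and per-observation zero-inflation weights.

#' Build a design for a tissue-state contrast
#'
#' Contrasts are `"<test>_vs_<ref>"` over the tissue states `HC`, `NL`, `LS`.
#' The lesional-vs-non-lesional contrast is paired: only subjects carrying
#' both states are kept and, with `adjust = TRUE`, subject enters the design
#' as a blocking factor. Unpaired contrasts adjust for gender instead. With
#' `adjust = FALSE` the nuisance term is dropped from the model.
#'
#' @param meta Sample metadata (from [validate_meta()] or the simulator).
#' @param contrast A string like `"LS_vs_NL"`.
#' @param adjust Include the nuisance covariate (subject or gender).
#' @return A `design_spec` list: `design` (full model matrix), `reduced`
#'   (without the state column), `coef` (tested column name), `samples`,
#'   `group` (state per sample), `contrast`, `paired`.
#' @export
design_spec <- function(meta, contrast = "LS_vs_NL", adjust = TRUE) {
  parts <- strsplit(contrast, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !all(parts %in% c("HC", "NL", "LS"))) {
    stop("contrast must be '<test>_vs_<ref>' over HC/NL/LS, got: ", contrast,
         call. = FALSE)
  }
  test_state <- parts[1]; ref_state <- parts[2]
  keep <- meta$tissue_state %in% parts
  m <- meta[keep, , drop = FALSE]
  paired <- setequal(parts, c("LS", "NL"))
  if (paired) {
    both <- intersect(m$subject_id[m$tissue_state == test_state],
                      m$subject_id[m$tissue_state == ref_state])
    if (length(both) < 2) {
      stop("paired contrast needs >= 2 subjects with both tissue states",
           call. = FALSE)
    }
    m <- m[m$subject_id %in% both, , drop = FALSE]
  }
  if (length(unique(m$tissue_state)) < 2) {
    stop("both contrast states must be present", call. = FALSE)
  }
  state <- factor(m$tissue_state, levels = c(ref_state, test_state))
  if (adjust && paired) {
    design <- stats::model.matrix(~ factor(subject_id) + state,
                                  data = cbind(m, state = state))
  } else if (adjust && length(unique(m$gender)) > 1) {
    design <- stats::model.matrix(~ factor(gender) + state,
                                  data = cbind(m, state = state))
  } else {
    design <- stats::model.matrix(~ state, data = data.frame(state = state))
  }
  coef_name <- paste0("state", test_state)
  if (qr(design)$rank < ncol(design)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  structure(list(design = design,
                 reduced = design[, colnames(design) != coef_name, drop = FALSE],
                 coef = coef_name,
                 samples = m$sample_id,
                 group = stats::setNames(m$tissue_state, m$sample_id),
                 contrast = contrast, paired = paired),
            class = "design_spec")
}

align_factors <- function(factors, samples) {
  idx <- match(samples, factors$sample_id)
  if (anyNA(idx)) stop("normalization factors missing samples", call. = FALSE)
  factors[idx, , drop = FALSE]
}

# Trigamma inverse by Newton iteration (for the moderated-t prior df).
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

#' Estimate per-gene negative-binomial dispersions
#'
#' Per gene, the dispersion maximising the Cox-Reid adjusted profile
#' likelihood of the NB-GLM (log link, effective-library-size offsets); the
#' adjustment term `-0.5 log det(X'WX)` compensates the downward bias a
#' plug-in estimate suffers when the design eats many degrees of freedom
#' (e.g. subject blocking). The raw estimates are then shrunk toward a
#' mean-dispersion trend, weighting the trend as `prior_df` extra residual
#' degrees of freedom, and clipped to `[1e-6, 10]`.
#'
#' @param counts Count matrix.
#' @param design A [design_spec()].
#' @param factors `norm_factors` for the design's samples.
#' @param prior_df Prior degrees of freedom of the trend shrinkage.
#' @return A tibble with `gene`, `dispersion_raw`, `dispersion_trend`,
#'   `dispersion` (shrunk, clipped), `mean_count`.
#' @export
estimate_dispersion <- function(counts, design, factors, prior_df = 10) {
  validate_counts(counts)
  stopifnot(inherits(design, "design_spec"))
  y <- counts[, design$samples, drop = FALSE]
  X <- design$design
  n <- ncol(y); p <- ncol(X)
  if (n - p < 1) stop("no residual degrees of freedom", call. = FALSE)
  f <- align_factors(factors, design$samples)
  off <- log(f$effective_lib_size)

  # Cox-Reid adjusted profile log-likelihood at a given dispersion
  apl <- function(yi, phi) {
    fam <- MASS::negative.binomial(theta = 1 / phi)
    fit <- suppressWarnings(stats::glm.fit(X, yi, family = fam, offset = off))
    mu <- pmax(fit$fitted.values, 1e-10)
    ll <- sum(stats::dnbinom(yi, mu = mu, size = 1 / phi, log = TRUE))
    w <- mu / (1 + phi * mu)
    R <- qr.R(qr(X * sqrt(w)))
    # det(X'WX) = det(R)^2, so -0.5 log det = -sum log |diag R|
    ll - sum(log(abs(diag(R))))
  }
  raw <- vapply(seq_len(nrow(y)), function(i) {
    yi <- y[i, ]
    if (all(yi == 0)) return(NA_real_)
    opt <- tryCatch(
      stats::optimize(function(lp) apl(yi, exp(lp)), c(log(1e-6), log(10)),
                      maximum = TRUE, tol = 0.01),
      error = function(e) NULL)
    if (is.null(opt)) return(NA_real_)
    # flat-likelihood genes pile at the lower boundary: report as ~0
    phi <- exp(opt$maximum)
    if (opt$maximum < log(1e-6) + 0.1) phi <- 0
    phi
  }, numeric(1))

  mean_count <- rowMeans(sweep(y, 2, exp(off - mean(off)), `/`))
  usable <- !is.na(raw) & mean_count > 0
  trend <- rep(stats::median(raw[usable], na.rm = TRUE), nrow(y))
  if (sum(usable) >= 10) {
    lo <- stats::lowess(log(mean_count[usable]),
                        log(pmax(raw[usable], 1e-6)), f = 0.5)
    trend[usable] <- exp(stats::approx(lo$x, lo$y,
                                       xout = log(mean_count[usable]),
                                       rule = 2, ties = mean)$y)
  }
  df_res <- n - p
  shrunk <- (prior_df * trend + df_res * ifelse(is.na(raw), trend, raw)) /
    (prior_df + df_res)
  shrunk <- pmin(pmax(shrunk, 1e-6), 10)
  tibble::tibble(gene = rownames(y), dispersion_raw = raw,
                 dispersion_trend = trend, dispersion = shrunk,
                 mean_count = unname(mean_count))
}

de_result_tibble <- function(gene, log2fc, statistic, p, note, engine, contrast,
                             prob = NULL) {
  padj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  padj[ok] <- stats::p.adjust(p[ok], method = "BH")
  out <- tibble::tibble(gene = unname(gene), log2fc = unname(log2fc),
                        statistic = unname(statistic), p = unname(p),
                        padj = padj)
  if (!is.null(prob)) out$prob <- unname(prob)
  # deterministic ranking: best statistic first, ties by |log2fc| then symbol
  key_stat <- if (!is.null(prob)) -prob else p
  ord <- order(key_stat, -abs(out$log2fc), out$gene, na.last = TRUE)
  out$rank <- NA_integer_
  out$rank[ord] <- seq_along(ord)
  out$note <- note
  out$engine <- engine
  out$contrast <- contrast
  class(out) <- c("de_result", class(out))
  out
}

#' Negative-binomial GLM likelihood-ratio test
#'
#' Per gene, a negative binomial log-linear model with a log effective
#' library-size offset (or a caller-supplied offset matrix, e.g. the log
#' mitochondrial reference sum for ratio normalization) is maximised at the
#' gene's estimated dispersion; the tissue-state coefficient is tested by a
#' 1-df likelihood-ratio test against the reduced model. `log2fc` is the
#' fitted coefficient on the log2 scale; p-values are BH-adjusted.
#'
#' @param counts Count matrix.
#' @param design A [design_spec()].
#' @param factors `norm_factors`; ignored when `offsets` is given.
#' @param dispersions Tibble from [estimate_dispersion()].
#' @param weights Optional gene x sample observation-weight matrix (e.g. from
#'   [zero_inflation_weights()]).
#' @param offsets Optional per-sample offset vector on the natural-log scale,
#'   replacing `log(effective_lib_size)`.
#' @param test `"lrt"` (1-df likelihood-ratio test, the default) or `"wald"`
#'   (coefficient z-test from the observed information).
#' @return A `de_result` tibble. All-zero genes are reported untestable
#'   (`note = "all_zero"`, missing p); non-converging fits are flagged.
#' @export
nb_glm_test <- function(counts, design, factors = NULL, dispersions,
                        weights = NULL, offsets = NULL,
                        test = c("lrt", "wald")) {
  test <- match.arg(test)
  validate_counts(counts)
  stopifnot(inherits(design, "design_spec"))
  y <- counts[, design$samples, drop = FALSE]
  X <- design$design
  Xr <- design$reduced
  coef_idx <- match(design$coef, colnames(X))
  if (is.null(offsets)) {
    if (is.null(factors)) stop("supply factors or offsets", call. = FALSE)
    f <- align_factors(factors, design$samples)
    off <- log(f$effective_lib_size)
  } else {
    off <- offsets[design$samples]
    if (anyNA(off)) stop("offsets missing samples", call. = FALSE)
  }
  disp <- dispersions$dispersion[match(rownames(y), dispersions$gene)]
  if (anyNA(disp)) stop("dispersions missing genes", call. = FALSE)
  W <- if (is.null(weights)) NULL else weights[rownames(y), design$samples, drop = FALSE]

  fit_one <- function(yi, wi, th) {
    full <- stats::glm.fit(X, yi, weights = wi, offset = off,
                           family = MASS::negative.binomial(theta = th))
    red <- stats::glm.fit(Xr, yi, weights = wi, offset = off,
                          family = MASS::negative.binomial(theta = th))
    list(full = full, red = red)
  }

  n_genes <- nrow(y)
  log2fc <- stat <- p <- rep(NA_real_, n_genes)
  note <- rep(NA_character_, n_genes)
  for (i in seq_len(n_genes)) {
    yi <- y[i, ]
    if (all(yi == 0)) { note[i] <- "all_zero"; next }
    wi <- if (is.null(W)) rep(1, length(yi)) else W[i, ]
    th <- 1 / disp[i]
    fits <- tryCatch(suppressWarnings(fit_one(yi, wi, th)), error = function(e) NULL)
    if (is.null(fits) || !fits$full$converged) {
      note[i] <- "non_convergence"
      next
    }
    log2fc[i] <- fits$full$coefficients[coef_idx] / log(2)
    if (test == "lrt") {
      lr <- fits$red$deviance - fits$full$deviance
      stat[i] <- lr
      p[i] <- stats::pchisq(pmax(lr, 0), df = 1, lower.tail = FALSE)
    } else {
      R <- qr.R(fits$full$qr)
      se <- tryCatch(sqrt(chol2inv(R)[coef_idx, coef_idx]),
                     error = function(e) NA_real_)
      z <- fits$full$coefficients[coef_idx] / se
      stat[i] <- z
      p[i] <- 2 * stats::pnorm(-abs(z))
    }
  }
  de_result_tibble(rownames(y), log2fc, stat, p, note,
                   if (test == "lrt") "nbglm" else "nbglm_wald",
                   design$contrast)
}

# Moment-based empirical-Bayes variance squeezing (moderated t machinery).
squeeze_var <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    d0 <- Inf
    s02 <- exp(emean)
  } else {
    d0 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  }
  post <- rep(NA_real_, length(s2))
  if (is.finite(d0)) {
    post[ok] <- (d0 * s02 + df * s2[ok]) / (d0 + df)
  } else {
    post[ok] <- s02
  }
  list(var_post = post, df_prior = d0, var_prior = s02)
}

#' Precision-weighted moderated-t test on log-CPM
#'
#' Gene-wise linear models on log-CPM with observation precision weights read
#' off a smoothed mean-variance trend: residual quarter-root standard
#' deviations are regressed on average log-CPM (locally weighted, span 0.5),
#' each observation's weight is the inverted fourth power of the trend at its
#' fitted log-CPM, and the weighted fits are tested with an empirical-Bayes
#' moderated t (prior df by method of moments on the log residual variances).
#' With `quality_weights = TRUE` a per-sample weight, the inverse of the
#' sample's mean squared standardized residual (geometric mean 1, two
#' refinement passes), multiplies the observation weights.
#'
#' @param counts Count matrix.
#' @param factors `norm_factors` (typically TMM).
#' @param design A [design_spec()].
#' @param quality_weights Estimate per-sample quality weights.
#' @param span Smoothing span of the mean-variance trend.
#' @param prior_count Prior count of the log-CPM transform.
#' @return A `de_result` tibble; the per-observation weights and any sample
#'   weights are attached as attributes `weights` and `sample_weights`.
#' @export
voom_weighted_test <- function(counts, factors, design, quality_weights = FALSE,
                               span = 0.5, prior_count = 0.5) {
  validate_counts(counts)
  stopifnot(inherits(design, "design_spec"))
  y <- counts[, design$samples, drop = FALSE]
  f <- align_factors(factors, design$samples)
  E <- log_cpm(y, f, prior_count = prior_count)
  X <- design$design
  n <- ncol(E); p <- ncol(X)
  if (n - p < 1) stop("no residual degrees of freedom", call. = FALSE)
  coef_idx <- match(design$coef, colnames(X))

  fit0 <- stats::lm.fit(X, t(E))
  res <- t(fit0$residuals)                       # genes x samples
  fitted0 <- t(fit0$fitted.values)
  s <- sqrt(rowSums(res^2) / (n - p))
  ybar <- rowMeans(E)

  ok <- s > 0
  if (sum(ok) < 10 || diff(range(ybar[ok])) < 1e-8) {
    warning("degenerate mean-variance trend; using constant variance")
    w <- matrix(1, nrow(E), n, dimnames = dimnames(E))
  } else {
    lo <- stats::lowess(ybar[ok], sqrt(s[ok]), f = span)
    pred <- function(x) {
      out <- stats::approx(lo$x, lo$y, xout = x, rule = 2, ties = mean)$y
      pmax(out, 1e-4)
    }
    w <- matrix(pred(as.vector(fitted0)), nrow(E), n, dimnames = dimnames(E))^-4
  }

  sample_w <- NULL
  if (quality_weights) {
    sample_w <- rep(1, n)
    for (it in 1:2) {
      wf <- sweep(w, 2, sample_w, `*`)
      # weighted per-gene fits to get standardized residuals
      z2 <- matrix(0, nrow(E), n)
      for (i in seq_len(nrow(E))) {
        fi <- stats::lm.wfit(X, E[i, ], w = wf[i, ])
        s2i <- sum(wf[i, ] * fi$residuals^2) / (n - p)
        if (s2i <= 0) s2i <- 1e-8
        z2[i, ] <- wf[i, ] * fi$residuals^2 / s2i
      }
      v <- colMeans(z2)
      v <- pmax(v, 1e-4)
      sample_w <- sample_w / v
      sample_w <- sample_w / exp(mean(log(sample_w)))
    }
    w <- sweep(w, 2, sample_w, `*`)
    names(sample_w) <- colnames(E)
  }

  beta <- se_unscaled <- s2 <- rep(NA_real_, nrow(E))
  for (i in seq_len(nrow(E))) {
    fi <- stats::lm.wfit(X, E[i, ], w = w[i, ])
    R <- qr.R(fi$qr)
    XtXinv <- chol2inv(R)
    beta[i] <- fi$coefficients[coef_idx]
    se_unscaled[i] <- sqrt(XtXinv[coef_idx, coef_idx])
    s2[i] <- sum(w[i, ] * fi$residuals^2) / (n - p)
  }
  sq <- squeeze_var(s2, n - p)
  df_total <- (n - p) + (if (is.finite(sq$df_prior)) sq$df_prior else 1e6)
  tstat <- beta / (sqrt(sq$var_post) * se_unscaled)
  pval <- 2 * stats::pt(-abs(tstat), df = df_total)

  out <- de_result_tibble(rownames(E), beta, tstat, pval,
                          rep(NA_character_, nrow(E)),
                          if (quality_weights) "voomqw" else "voom",
                          design$contrast)
  attr(out, "weights") <- w
  attr(out, "sample_weights") <- sample_w
  attr(out, "df_prior") <- sq$df_prior
  out
}

#' Non-parametric signal-vs-noise DE ranking
#'
#' For each gene, the signal is the pair (M, D): M is the difference of
#' group-mean log-CPM (a log2 fold change) and D the absolute difference of
#' the group means on the CPM scale. The noise distribution pools the same
#' statistics computed between all within-group sample pairs across all
#' genes. The DE probability of a gene is the fraction of noise pairs it
#' dominates (`|M_noise| < |M|` and `D_noise < D`); genes are ranked by
#' probability, ties broken by `|M|` then symbol.
#'
#' @param expr Log-CPM matrix (e.g. from [log_cpm()] on TMM factors).
#' @param groups Factor/character vector of group labels aligned with the
#'   columns of `expr`, two groups, each with at least two samples.
#' @param contrast Label stored in the result, `"<test>_vs_<ref>"`; M is
#'   test minus ref.
#' @param n_noise_pairs Cap on the pooled noise values (deterministic
#'   thinning keeps memory and time bounded).
#' @return A `de_result` tibble with `prob` and `rank`; `p`/`padj` are
#'   `1 - prob` and its BH adjustment, for interface uniformity only — the
#'   supported cutoffs for this engine are rank-based.
#' @export
noiseq_rank <- function(expr, groups, contrast = "LS_vs_NL",
                        n_noise_pairs = 20000) {
  if (ncol(expr) != length(groups)) stop("groups must match columns", call. = FALSE)
  parts <- strsplit(contrast, "_vs_", fixed = TRUE)[[1]]
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) != 2) stop("exactly two groups required", call. = FALSE)
  if (all(parts %in% lev)) { test <- parts[1]; ref <- parts[2] }
  else { test <- lev[1]; ref <- lev[2] }
  if (sum(groups == test) < 2 || sum(groups == ref) < 2) {
    stop("each group needs >= 2 samples to form within-group noise pairs",
         call. = FALSE)
  }

  m_test <- rowMeans(expr[, groups == test, drop = FALSE])
  m_ref <- rowMeans(expr[, groups == ref, drop = FALSE])
  M <- m_test - m_ref
  D <- abs(2^m_test - 2^m_ref)

  noise_M <- list(); noise_D <- list(); k <- 0
  for (g in c(test, ref)) {
    idx <- which(groups == g)
    for (a in seq_along(idx)) for (b in seq_along(idx)) if (a < b) {
      k <- k + 1
      xa <- expr[, idx[a]]; xb <- expr[, idx[b]]
      noise_M[[k]] <- xa - xb
      noise_D[[k]] <- abs(2^xa - 2^xb)
    }
  }
  nM <- abs(unlist(noise_M)); nD <- unlist(noise_D)
  if (length(nM) > n_noise_pairs) {
    pick <- round(seq(1, length(nM), length.out = n_noise_pairs))
    nM <- nM[pick]; nD <- nD[pick]
  }
  prob <- vapply(seq_along(M), function(i)
    mean(nM < abs(M[i]) & nD < D[i]), numeric(1))

  out <- de_result_tibble(rownames(expr), M, prob, 1 - prob,
                          rep(NA_character_, length(M)), "noiseq", contrast,
                          prob = prob)
  out
}

#' Per-observation zero-inflation weights
#'
#' Fits, gene by gene, a two-component mixture of a negative binomial and a
#' point mass at zero by EM, with the zero-inflation logit linear in the log
#' effective library size (sequencing depth as the sample-level covariate).
#' The weight of an observation is the posterior probability that it arose
#' from the NB component: 1 for every nonzero count, in (0, 1] for zeros.
#' Genes whose EM does not converge within `max_iter` iterations keep unit
#' weights and are flagged.
#'
#' @param counts Count matrix.
#' @param factors `norm_factors` covering the samples.
#' @param max_iter,tol EM stopping rule.
#' @return A gene x sample weight matrix with attribute `non_converged`
#'   (character vector of flagged genes).
#' @export
zero_inflation_weights <- function(counts, factors, max_iter = 100, tol = 1e-4) {
  validate_counts(counts)
  f <- align_factors(factors, colnames(counts))
  L <- f$effective_lib_size
  x <- log(L)
  W <- matrix(1, nrow(counts), ncol(counts), dimnames = dimnames(counts))
  flagged <- character(0)

  for (i in seq_len(nrow(counts))) {
    yi <- counts[i, ]
    zeros <- yi == 0
    if (!any(zeros)) next
    if (all(zeros)) next
    # moment initialisation ignoring inflation
    q <- sum(yi) / sum(L)
    mu <- q * L
    phi <- max((sum((yi - mu)^2) - sum(mu)) / sum(mu^2), 1e-4)
    a <- 0; b <- 0          # logit(pi) = a + b * x
    post <- rep(0, length(yi))
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      pi_d <- stats::plogis(a + b * x)
      p0 <- stats::dnbinom(0, mu = q * L, size = 1 / phi)
      new_post <- rep(0, length(yi))
      new_post[zeros] <- pi_d[zeros] /
        (pi_d[zeros] + (1 - pi_d[zeros]) * p0[zeros])
      delta <- max(abs(new_post - post))
      post <- new_post
      # M-step: weighted NB moments and logistic regression of dropout on depth
      wnb <- 1 - post
      q <- sum(wnb * yi) / sum(wnb * L)
      if (!is.finite(q) || q <= 0) break
      mu <- q * L
      phi <- max(sum(wnb * ((yi - mu)^2 - mu)) / sum(wnb * mu^2), 1e-4)
      fit <- tryCatch(
        suppressWarnings(stats::glm.fit(cbind(1, x), post,
                                        family = stats::quasibinomial())),
        error = function(e) NULL)
      if (is.null(fit)) break
      a <- fit$coefficients[1]; b <- fit$coefficients[2]
      if (!all(is.finite(c(a, b)))) break
      if (delta < tol) { converged <- TRUE; break }
    }
    if (converged) {
      W[i, ] <- 1 - post
      W[i, !zeros] <- 1
      W[i, ] <- pmin(pmax(W[i, ], 1e-6), 1)
    } else {
      flagged <- c(flagged, rownames(counts)[i])
    }
  }
  attr(W, "non_converged") <- flagged
  W
}
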