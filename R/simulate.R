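# Negative-binomial simulator of paired shallow tape-strip and deep biopsy
# libraries with planted differential expression and depth-dependent dropout.

#' Simulation configuration
#'
#' Defaults emulate the structure of a tape-strip BRB-seq study of
#' mild-to-moderate atopic dermatitis: 30 AD subjects each contributing one
#' lesional (LS) and one non-lesional (NL) tape sample, 30 healthy controls
#' (HC) contributing one sample each, tape library sizes spread log-uniformly
#' over 361..7.9e6 total counts, deep (~1e7) biopsy libraries with 2
#' replicates per subject, and dropout (extra zeros beyond the negative
#' binomial) rising as expected counts shrink.
#'
#' @param n_subjects_AD,n_subjects_HC Numbers of AD and HC subjects.
#' @param n_genes Size of the simulated gene universe (panel genes included).
#' @param frac_DEG Fraction of genes with a planted LS-vs-NL effect.
#' @param deg_high_frac Fraction of the planted DEGs drawn from the top
#'   decile of baseline expression rather than uniformly; emulates a disease
#'   signature dominated by highly expressed barrier genes, whose mostly
#'   upward shift moves library composition.
#' @param log2fc_range Interval the planted |log2 fold changes| are drawn from.
#' @param tape_libsize_range Tape total-count range. The base depth is drawn
#'   log-uniformly per subject (RNA yield is a property of the person and
#'   site), then jittered per sample.
#' @param tape_depth_jitter_sd Natural-log standard deviation of the
#'   per-sample depth jitter around the subject's base depth.
#' @param hairiness_sd Log-normal spread of a per-subject multiplier on the
#'   KRTAP (hair) panel, emulating between-person variation in hair
#'   contamination.
#' @param biopsy_libsize Mean biopsy library size.
#' @param biopsy_replicates Biopsy replicates per subject.
#' @param dispersion_meanlog,dispersion_sdlog Log-normal parameters of the
#'   per-gene NB dispersion.
#' @param zi_intercept,zi_slope Logistic dropout model for tape observations:
#'   an observation with NB mean mu is zeroed with probability
#'   `plogis(zi_intercept + u_j - zi_slope * log(mu))`, where `u_j` is the
#'   sample's degradation offset. `zi_slope = Inf` disables dropout entirely.
#' @param zi_sample_sd Standard deviation of the per-tape-sample degradation
#'   offsets `u_j` (normal, mean 0). RNA degradation varies strongly between
#'   tape samples; degraded samples lose transcripts at every expression
#'   level, not only where expected counts are small. 0 disables it.
#' @param subject_sd Standard deviation of per-subject random intercepts on
#'   the natural-log expression scale.
#' @param bio_gene_subject_sd Standard deviation of gene-by-subject
#'   biological effects on the natural-log scale, shared between a subject's
#'   tape and biopsy samples; this is the inter-individual expression
#'   variation that cross-platform per-gene correlations detect.
#' @param layer_bio_sd Larger gene-by-subject standard deviation for the
#'   epidermal layer marker panels: differentiation genes vary strongly
#'   between individuals, which is what makes their cross-platform
#'   correlation measurable at all.
#' @param state_libsize_multiplier Mean tape library-size multipliers for
#'   HC/NL/LS, giving the tissue-state effect on total counts.
#' @param quarter_effect_sd Standard deviation of per-quarter log library-size
#'   offsets (seasonal variation in RNA yield); 0 disables it.
#' @param layer_zi_offset Named additive offsets to `zi_intercept` for genes in
#'   the epidermal layer panels; the default makes dropout lowest for stratum
#'   corneum markers and highest for basale markers, the depth gradient a tape
#'   strip induces.
#' @param edc_ad_effect Plant upregulation in LS on the six EDC panel genes
#'   the disease signature names (FLG2, LORICRIN, S100A7, S100A8, SPRR2E,
#'   SPRR1B); their |log2FC| is drawn from `log2fc_range` like any other
#'   planted effect. The lesional epidermis shifts exactly these dominant
#'   barrier genes, which moves library composition.
#' @param frac_noncoding Fraction of non-panel genes labelled non-protein-coding
#'   in the annotation (exercises the biotype filter).
#' @param seed Integer seed; the same config and seed give identical output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_subjects_AD = 30, n_subjects_HC = 30,
                       n_genes = 3000, frac_DEG = 0.1,
                       deg_high_frac = 0.3,
                       log2fc_range = c(1, 3),
                       tape_libsize_range = c(361, 7.9e6),
                       tape_depth_jitter_sd = 0.25,
                       hairiness_sd = 0.5,
                       biopsy_libsize = 1e7,
                       biopsy_replicates = 2,
                       dispersion_meanlog = log(0.4), dispersion_sdlog = 0.5,
                       zi_intercept = 1.5, zi_slope = 1.0,
                       zi_sample_sd = 1.5,
                       subject_sd = 0.2,
                       bio_gene_subject_sd = 0.5,
                       layer_bio_sd = 1.5,
                       state_libsize_multiplier = c(HC = 1, NL = 1.5, LS = 2.5),
                       quarter_effect_sd = 0.1,
                       layer_zi_offset = c(LAYER_CORNEUM = -4, LAYER_GRANULOSUM = -2,
                                           LAYER_SPINOSUM = 2, LAYER_BASALE = 4),
                       edc_ad_effect = TRUE,
                       frac_noncoding = 0.1,
                       seed = 1L) {
  stopifnot(frac_DEG >= 0, frac_DEG <= 1,
            all(tape_libsize_range > 0), biopsy_libsize > 0,
            n_subjects_AD >= 1, n_subjects_HC >= 1, n_genes >= 1)
  structure(
    list(n_subjects_AD = n_subjects_AD, n_subjects_HC = n_subjects_HC,
         n_genes = n_genes, frac_DEG = frac_DEG,
         deg_high_frac = deg_high_frac, log2fc_range = log2fc_range,
         tape_libsize_range = tape_libsize_range,
         tape_depth_jitter_sd = tape_depth_jitter_sd,
         hairiness_sd = hairiness_sd,
         biopsy_libsize = biopsy_libsize, biopsy_replicates = biopsy_replicates,
         dispersion_meanlog = dispersion_meanlog,
         dispersion_sdlog = dispersion_sdlog,
         zi_intercept = zi_intercept, zi_slope = zi_slope,
         zi_sample_sd = zi_sample_sd,
         subject_sd = subject_sd,
         bio_gene_subject_sd = bio_gene_subject_sd,
         layer_bio_sd = layer_bio_sd,
         state_libsize_multiplier = state_libsize_multiplier,
         quarter_effect_sd = quarter_effect_sd,
         layer_zi_offset = layer_zi_offset,
         edc_ad_effect = edc_ad_effect,
         frac_noncoding = frac_noncoding,
         seed = as.integer(seed)),
    class = "sim_config")
}

# Panel genes carried into every simulated universe, with relative baseline
# expression multipliers: EDC very high in all skin, MT moderate, KRTAP
# variable, layer markers moderate.
panel_baseline_multiplier <- function(sets) {
  mult <- c(EDC_QC = 200, MT_NORM = 20, KRTAP = 5,
            LAYER_CORNEUM = 30, LAYER_GRANULOSUM = 20,
            LAYER_SPINOSUM = 15, LAYER_BASALE = 15)
  out <- unlist(lapply(names(mult), function(s) {
    stats::setNames(rep(mult[[s]], length(sets[[s]])), sets[[s]])
  }))
  out[!duplicated(names(out))]
}

#' Simulate a paired tape-strip / biopsy study
#'
#' Generative model: per-gene baseline means are log-normal with panel genes
#' elevated; a `frac_DEG` fraction of genes (plus, by default, six EDC panel
#' genes) gets a planted LS effect of `2^(+/- log2FC)`; gene-by-subject
#' biological effects are shared between a subject's tape and biopsy
#' samples; tape library sizes are log-uniform per subject over
#' `tape_libsize_range`, scaled by the tissue-state multiplier, a
#' per-quarter offset, and per-sample jitter; counts are negative binomial
#' with per-gene dispersion; tape observations are then zeroed with
#' probability `plogis(zi_intercept + u_j - zi_slope*log(mu))` (layer panels
#' shift the intercept, degraded samples shift `u_j`). Biopsy libraries are
#' deep, replicate-structured per subject and site, and free of the extra
#' zeros.
#'
#' @param config A [sim_config()].
#' @return A `sim_study` list with elements `tape` (`counts`, `meta`),
#'   `biopsy` (`counts`, `replicate_map`), `truth` (per-gene tibble with
#'   `is_DEG`, `log2fc`, `panel`, `biotype`), `annotation`, `gene_sets`, and
#'   the `config` used.
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  sets <- default_gene_sets()
  panel_mult <- panel_baseline_multiplier(sets)
  n_panel <- length(panel_mult)
  if (config$n_genes < n_panel + 10) {
    stop("n_genes (", config$n_genes, ") too small for the ", n_panel,
         " panel genes", call. = FALSE)
  }

  set.seed(config$seed)

  n_filler <- config$n_genes - n_panel
  genes <- c(names(panel_mult),
             sprintf("GENE%05d", seq_len(n_filler)))

  # (1) baseline relative means, panel genes elevated
  base <- stats::rlnorm(config$n_genes, meanlog = log(5), sdlog = 1.2)
  names(base) <- genes
  base[names(panel_mult)] <- base[names(panel_mult)] * panel_mult
  # KRTAP variability: extra per-gene spread for the hair signature
  krtap <- intersect(sets$KRTAP, genes)
  base[krtap] <- base[krtap] * stats::rlnorm(length(krtap), 0, 1)

  # (2) planted DEG effects on LS (filler genes only, so panel semantics stay)
  filler <- setdiff(genes, names(panel_mult))
  n_deg <- round(config$frac_DEG * config$n_genes)
  n_deg <- min(n_deg, length(filler))
  deg_genes <- character(0)
  if (n_deg > 0) {
    # stratified placement: part of the signature sits among the
    # highest-expressed genes (barrier-gene-dominated disease signal)
    high_pool <- filler[base[filler] >= stats::quantile(base[filler], 0.9)]
    n_high <- min(round(config$deg_high_frac * n_deg), length(high_pool))
    deg_high <- if (n_high > 0) sample(high_pool, n_high) else character(0)
    deg_rest <- sample(setdiff(filler, deg_high), n_deg - n_high)
    deg_genes <- c(deg_high, deg_rest)
  }
  log2fc <- stats::setNames(rep(0, config$n_genes), genes)
  if (n_deg > 0) {
    mag <- stats::runif(n_deg, config$log2fc_range[1], config$log2fc_range[2])
    sgn <- sample(c(-1, 1), n_deg, replace = TRUE, prob = c(0.2, 0.8))
    log2fc[deg_genes] <- sgn * mag
  }
  if (isTRUE(config$edc_ad_effect)) {
    edc_up <- intersect(c("FLG2", "LORICRIN", "S100A7", "S100A8",
                          "SPRR2E", "SPRR1B"), genes)
    log2fc[edc_up] <- stats::runif(length(edc_up), config$log2fc_range[1],
                                   config$log2fc_range[2])
    deg_genes <- c(deg_genes, edc_up)
  }

  disp <- stats::rlnorm(config$n_genes, config$dispersion_meanlog,
                        config$dispersion_sdlog)
  names(disp) <- genes

  # subjects and samples
  ad_ids <- sprintf("AD%03d", seq_len(config$n_subjects_AD))
  hc_ids <- sprintf("HC%03d", seq_len(config$n_subjects_HC))
  subj_int <- stats::rnorm(length(ad_ids) + length(hc_ids), 0, config$subject_sd)
  names(subj_int) <- c(ad_ids, hc_ids)
  subj_gender <- stats::setNames(
    sample(c("F", "M"), length(subj_int), replace = TRUE), names(subj_int))
  subj_quarter <- stats::setNames(
    sample(paste0("Q", 1:4), length(subj_int), replace = TRUE), names(subj_int))
  regions <- c("arm", "leg", "hand", "back of knee", "wrist", "elbow")
  region_p <- c(106, 11, 5, 5, 3, 2) / 132
  subj_region <- stats::setNames(
    sample(regions, length(subj_int), replace = TRUE, prob = region_p),
    names(subj_int))
  quarter_off <- stats::setNames(
    stats::rnorm(4, 0, config$quarter_effect_sd), paste0("Q", 1:4))

  meta <- tibble::tibble(
    sample_id = c(paste0(ad_ids, "_LS"), paste0(ad_ids, "_NL"),
                  paste0(hc_ids, "_HC")),
    subject_id = c(ad_ids, ad_ids, hc_ids),
    tissue_state = c(rep("LS", length(ad_ids)), rep("NL", length(ad_ids)),
                     rep("HC", length(hc_ids))))
  meta$gender <- subj_gender[meta$subject_id]
  meta$quarter <- subj_quarter[meta$subject_id]
  meta$region <- subj_region[meta$subject_id]

  # per-subject hair contamination multiplier on the KRTAP panel
  hair_factor <- stats::setNames(
    stats::rlnorm(length(subj_int), 0, config$hairiness_sd), names(subj_int))

  # gene-by-subject biological effects, shared between platforms
  bio <- matrix(stats::rnorm(config$n_genes * length(subj_int), 0,
                             config$bio_gene_subject_sd),
                nrow = config$n_genes,
                dimnames = list(genes, names(subj_int)))
  layer_genes <- intersect(
    unlist(sets[grep("^LAYER_", names(sets))]), genes)
  bio[layer_genes, ] <- matrix(
    stats::rnorm(length(layer_genes) * length(subj_int), 0,
                 config$layer_bio_sd),
    nrow = length(layer_genes))

  # (4) library sizes: subject-level base depth (RNA yield follows the
  # person/site), state multiplier, quarter offset, per-sample jitter
  lr <- log(config$tape_libsize_range)
  subj_depth <- stats::setNames(
    exp(stats::runif(length(subj_int), lr[1], lr[2])), names(subj_int))
  depth <- subj_depth[meta$subject_id] *
    config$state_libsize_multiplier[meta$tissue_state] *
    exp(quarter_off[meta$quarter]) *
    exp(stats::rnorm(nrow(meta), 0, config$tape_depth_jitter_sd))

  # per-gene dropout intercepts (layer panels shift the logit)
  zi_int <- stats::setNames(rep(config$zi_intercept, config$n_genes), genes)
  for (s in names(config$layer_zi_offset)) {
    zi_int[intersect(sets[[s]], genes)] <-
      config$zi_intercept + config$layer_zi_offset[[s]]
  }

  # expected relative expression per sample: baseline x subject x LS effect
  rel <- matrix(base, nrow = config$n_genes, ncol = nrow(meta),
                dimnames = list(genes, meta$sample_id))
  ls_cols <- meta$tissue_state == "LS"
  rel[, ls_cols] <- rel[, ls_cols] * 2^log2fc
  rel[krtap, ] <- rel[krtap, ] %*% diag(hair_factor[meta$subject_id])
  rel <- rel * exp(bio[, meta$subject_id])
  rel <- sweep(rel, 2, exp(subj_int[meta$subject_id]), `*`)
  rel <- sweep(rel, 2, colSums(rel), `/`)

  # (5) NB counts at the drawn depths
  mu_tape <- sweep(rel, 2, depth, `*`)
  tape <- matrix(
    stats::rnbinom(length(mu_tape), mu = mu_tape, size = rep(1 / disp, ncol(mu_tape))),
    nrow = config$n_genes, dimnames = dimnames(mu_tape))

  storage.mode(tape) <- "integer"

  # biopsy: replicates per subject and site (AD subjects contribute LS and
  # NL site biopsies, HC one site), deep, no dropout, no layer gradient
  n_rep <- config$biopsy_replicates
  site_tbl <- rbind(
    expand.grid(subject_id = ad_ids, site = c("LS", "NL"),
                stringsAsFactors = FALSE),
    data.frame(subject_id = hc_ids, site = "HC"))
  rep_map <- tibble::tibble(
    replicate_id = paste0(rep(paste(site_tbl$subject_id, site_tbl$site,
                                    sep = "_"), each = n_rep),
                          "_bx", seq_len(n_rep)),
    subject_id = rep(site_tbl$subject_id, each = n_rep),
    site = rep(site_tbl$site, each = n_rep))
  rel_bx <- matrix(base, nrow = config$n_genes, ncol = nrow(rep_map),
                   dimnames = list(genes, rep_map$replicate_id))
  # the disease effect sits on lesional-site biopsies only
  ls_rep <- rep_map$site == "LS"
  rel_bx[, ls_rep] <- rel_bx[, ls_rep] * 2^log2fc
  rel_bx[krtap, ] <- rel_bx[krtap, ] %*% diag(hair_factor[rep_map$subject_id])
  rel_bx <- rel_bx * exp(bio[, rep_map$subject_id])
  rel_bx <- sweep(rel_bx, 2, exp(subj_int[rep_map$subject_id]), `*`)
  rel_bx <- sweep(rel_bx, 2, colSums(rel_bx), `/`)
  depth_bx <- stats::rlnorm(nrow(rep_map), log(config$biopsy_libsize), 0.2)
  mu_bx <- sweep(rel_bx, 2, depth_bx, `*`)
  biopsy <- matrix(
    stats::rnbinom(length(mu_bx), mu = mu_bx, size = rep(1 / disp, ncol(mu_bx))),
    nrow = config$n_genes, dimnames = dimnames(mu_bx))
  storage.mode(biopsy) <- "integer"

  # (6) dropout on tape observations only: depth-dependent, plus a
  # per-sample degradation offset; drawn after the biopsy arm so the biopsy
  # stream is invariant to dropout settings
  if (is.finite(config$zi_slope)) {
    u <- stats::rnorm(nrow(meta), 0, config$zi_sample_sd)
    logit <- sweep(zi_int - config$zi_slope * log(pmax(mu_tape, 1e-8)),
                   2, u, `+`)
    p_drop <- stats::plogis(logit)
    drop <- matrix(stats::runif(length(p_drop)) < p_drop,
                   nrow = nrow(p_drop))
    tape[drop] <- 0L
    storage.mode(tape) <- "integer"
  }

  # annotation: panel genes protein-coding; a fraction of fillers non-coding
  panel_lookup <- stats::setNames(rep(NA_character_, config$n_genes), genes)
  for (s in names(sets)) panel_lookup[intersect(sets[[s]], genes)] <- s
  n_nc <- round(config$frac_noncoding * length(filler))
  nc_genes <- if (n_nc > 0) sample(setdiff(filler, deg_genes),
                                   min(n_nc, length(setdiff(filler, deg_genes))))
              else character(0)
  biotype <- ifelse(genes %in% nc_genes, "lncRNA", "protein_coding")
  annotation <- gene_annotation(genes, biotype = biotype)

  truth <- tibble::tibble(
    gene = genes,
    is_DEG = genes %in% deg_genes,
    log2fc = unname(log2fc),
    panel = unname(panel_lookup),
    biotype = biotype)

  meta <- validate_meta(meta, tape)

  structure(
    list(tape = list(counts = tape, meta = meta),
         biopsy = list(counts = biopsy, replicate_map = rep_map),
         truth = truth, annotation = annotation, gene_sets = sets,
         config = config),
    class = "sim_study")
}

#' Extract the planted gold-standard DEG set
#'
#' In simulation the planted truth replaces the biopsy-derived gold standard a
#' real study would use: the returned set is exactly the genes with a planted
#' effect, with direction `up`/`down` taken from the sign of the planted
#' log2 fold change of the test condition relative to the reference.
#'
#' @param study A `sim_study` from [simulate_experiment()].
#' @param contrast One of `"LS_vs_NL"`, `"LS_vs_HC"`, `"NL_vs_HC"`.
#' @return A tibble with columns `gene`, `direction`, `log2fc`
#'   (class `gold_standard`).
#' @export
truth_gold_standard <- function(study, contrast = c("LS_vs_NL", "LS_vs_HC", "NL_vs_HC")) {
  stopifnot(inherits(study, "sim_study"))
  contrast <- match.arg(contrast)
  truth <- study$truth
  # planted effects act on LS only: NL_vs_HC carries no planted signal
  if (contrast == "NL_vs_HC") {
    out <- truth[0, c("gene", "log2fc")]
  } else {
    out <- truth[truth$is_DEG, c("gene", "log2fc")]
  }
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  out <- out[, c("gene", "direction", "log2fc")]
  attr(out, "contrast") <- contrast
  class(out) <- c("gold_standard", class(out))
  out
}

#' Write a simulated study to a directory in the package's text formats
#'
#' @param study A `sim_study`.
#' @param dir Target directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(study$tape$counts, file.path(dir, "tape_counts.tsv"))
  write_counts(study$biopsy$counts, file.path(dir, "biopsy_counts.tsv"))
  utils::write.table(study$tape$meta, file.path(dir, "sample_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$biopsy$replicate_map,
                     file.path(dir, "replicate_map.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- study$config
  cfg_flat <- lapply(unclass(cfg), function(x)
    if (length(x) > 1) paste(names(x), x, sep = "=", collapse = ",") else x)
  jsonlite::write_json(cfg_flat, file.path(dir, "sim_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
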