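# Core containers: validated integer count matrices, sample metadata,
# gene annotation, and named gene sets (GMT).

#' Validate a gene-by-sample count matrix
#'
#' Checks the invariants assumed throughout the pipeline: a base integer (or
#' integer-valued numeric) matrix with unique gene symbols as rownames, unique
#' sample identifiers as colnames, and no negative or fractional entries.
#'
#' @param counts A numeric matrix, genes in rows, samples in columns.
#' @return The matrix, invisibly, with storage mode coerced to integer-valued
#'   numeric. Errors describe the first violated invariant.
#' @export
validate_counts <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix (genes x samples)", call. = FALSE)
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must carry gene symbols as rownames and sample ids as colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    dup <- rownames(counts)[duplicated(rownames(counts))][1]
    stop("duplicate gene symbol: ", dup, call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    dup <- colnames(counts)[duplicated(colnames(counts))][1]
    stop("duplicate sample id: ", dup, call. = FALSE)
  }
  if (anyNA(counts)) stop("counts contain NA", call. = FALSE)
  if (any(counts < 0)) stop("negative count entries are not allowed", call. = FALSE)
  if (any(counts != round(counts))) {
    stop("non-integer count entries are not allowed", call. = FALSE)
  }
  invisible(counts)
}

#' Read a count matrix from TSV or MatrixMarket files
#'
#' The TSV layout has gene symbols in a first column named `gene` and one
#' column per sample. The MatrixMarket (`mtx`) layout is the sparse coordinate
#' format with two sidecar files next to it, `<stem>.genes.txt` and
#' `<stem>.samples.txt`, holding one identifier per line (rows and columns of
#' the matrix respectively); entries absent from the triplet list are zeros.
#'
#' @param path Path to the `.tsv` or `.mtx` file.
#' @param format Either `"tsv"` or `"mtx"`; default guessed from the extension.
#' @return A validated integer count matrix.
#' @export
read_counts <- function(path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2 || names(tab)[1] != "gene") {
      stop("malformed count TSV header: first column must be 'gene'", call. = FALSE)
    }
    m <- as.matrix(tab[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric count entries in ", path, call. = FALSE)
    rownames(m) <- tab$gene
  } else {
    stem <- sub("\\.mtx$", "", path)
    genes_file <- paste0(stem, ".genes.txt")
    samples_file <- paste0(stem, ".samples.txt")
    if (!file.exists(genes_file) || !file.exists(samples_file)) {
      stop("mtx sidecar files missing: expected ", genes_file, " and ",
           samples_file, call. = FALSE)
    }
    sp <- Matrix::readMM(path)
    m <- as.matrix(sp)
    rownames(m) <- readLines(genes_file)
    colnames(m) <- readLines(samples_file)
  }
  validate_counts(m)
  m
}

#' Write a count matrix to TSV or MatrixMarket files
#'
#' Inverse of [read_counts()]; the MatrixMarket writer also emits the
#' `.genes.txt` / `.samples.txt` sidecars.
#'
#' @param counts Validated count matrix.
#' @param path Output path (`.tsv` or `.mtx`).
#' @param format `"tsv"` or `"mtx"`; default guessed from the extension.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, format = c("auto", "tsv", "mtx")) {
  format <- match.arg(format)
  validate_counts(counts)
  if (format == "auto") {
    format <- if (grepl("\\.mtx$", path)) "mtx" else "tsv"
  }
  if (format == "tsv") {
    tab <- data.frame(gene = rownames(counts), counts, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    stem <- sub("\\.mtx$", "", path)
    sp <- Matrix::Matrix(counts, sparse = TRUE)
    Matrix::writeMM(sp, path)
    writeLines(rownames(counts), paste0(stem, ".genes.txt"))
    writeLines(colnames(counts), paste0(stem, ".samples.txt"))
  }
  invisible(path)
}

#' Read named gene sets from a GMT file
#'
#' Standard MSigDB dialect: one set per line, tab-separated fields
#' `name`, `description`, then member gene symbols.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors (class `gene_sets`); the
#'   description lines are kept in the `"descriptions"` attribute.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("GMT line ", bad[1], " has fewer than 3 tab-separated fields",
         call. = FALSE)
  }
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene set name: ", nm[duplicated(nm)][1], call. = FALSE)
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "descriptions") <-
    stats::setNames(vapply(fields, `[[`, character(1), 2L), nm)
  class(sets) <- "gene_sets"
  sets
}

#' Bundled skin gene panels
#'
#' The default panels used by QC, normalization and the layer-correlation
#' analysis: `EDC_QC` (the nine epidermal differentiation complex genes of the
#' QC signal criterion), `MT_NORM` (the twelve mitochondrially encoded genes
#' of the ratio-normalization reference set), `KRTAP` (hair signature), and
#' four disjoint epidermal layer marker sets `LAYER_CORNEUM`,
#' `LAYER_GRANULOSUM`, `LAYER_SPINOSUM`, `LAYER_BASALE`.
#'
#' @return A `gene_sets` list, as from [read_gene_sets()].
#' @export
default_gene_sets <- function() {
  read_gene_sets(system.file("extdata", "skin_panels.gmt",
                             package = "tapestrip", mustWork = TRUE))
}

#' Build a gene annotation table
#'
#' @param genes Character vector of gene symbols (the gene universe).
#' @param biotype Character vector aligned with `genes`
#'   (`"protein_coding"` or anything else); default all protein-coding.
#' @param is_mitochondrial Optional logical flag; genes with an `MT-` prefix
#'   are flagged mitochondrial regardless, so annotation gaps are tolerated.
#' @return A tibble with columns `gene`, `biotype`, `is_mitochondrial`.
#' @export
gene_annotation <- function(genes, biotype = "protein_coding",
                            is_mitochondrial = FALSE) {
  tibble::tibble(
    gene = genes,
    biotype = rep_len(biotype, length(genes)),
    is_mitochondrial = rep_len(is_mitochondrial, length(genes)) |
      startsWith(genes, "MT-")
  )
}

#' Validate a sample metadata table against a count matrix
#'
#' @param meta Tibble with columns `sample_id`, `subject_id`, `tissue_state`
#'   (`HC`/`NL`/`LS`), `gender`, `quarter` (`Q1`..`Q4`), `region`.
#' @param counts Companion count matrix.
#' @return `meta` with a derived `total_count` column, sample order aligned to
#'   the matrix columns.
#' @export
validate_meta <- function(meta, counts) {
  need <- c("sample_id", "subject_id", "tissue_state", "gender", "quarter", "region")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata missing columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata", call. = FALSE)
  absent <- setdiff(colnames(counts), meta$sample_id)
  if (length(absent)) stop("samples missing from metadata: ",
                           paste(absent, collapse = ", "), call. = FALSE)
  bad_state <- setdiff(unique(meta$tissue_state), c("HC", "NL", "LS"))
  if (length(bad_state)) stop("unknown tissue_state: ",
                              paste(bad_state, collapse = ", "), call. = FALSE)
  hc_subjects <- unique(meta$subject_id[meta$tissue_state == "HC"])
  ad_subjects <- unique(meta$subject_id[meta$tissue_state %in% c("LS", "NL")])
  overlap <- intersect(hc_subjects, ad_subjects)
  if (length(overlap)) stop("subjects with both HC and LS/NL samples: ",
                            paste(overlap, collapse = ", "), call. = FALSE)
  meta <- meta[match(colnames(counts), meta$sample_id), , drop = FALSE]
  meta$total_count <- unname(colSums(counts))
  tibble::as_tibble(meta)
}
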