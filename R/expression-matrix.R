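#' Expression matrix container
#'
#' A lightweight S3 container for a (probes or genes) x samples expression
#' table together with the annotation the workflow needs: a probe-to-gene map
#' (possibly many-to-one before collapsing), a per-sample cohort/batch label,
#' and optionally a per-sample mean background level as reported by bead-array
#' scanners (required by [filter_probes()]).
#'
#' @param values numeric matrix, probes/genes in rows, samples in columns.
#'   Row and column names are used as probe and sample identifiers when
#'   `probe_ids`/`sample_ids` are not given.
#' @param probe_ids character vector of probe identifiers (unique).
#' @param gene_symbols character vector mapping each probe to a gene symbol;
#'   `NA` for unmapped probes. May be many-to-one.
#' @param sample_ids character vector of unique sample identifiers.
#' @param cohort factor or character, one cohort/batch label per sample.
#' @param background optional numeric vector, per-sample mean background level
#'   on the same (linear) scale as raw `values`.
#' @param log_scale logical, whether `values` are on log2 scale.
#'
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `probe_ids`, `gene_symbols`, `sample_ids`, `cohort`,
#'   `background`, `log_scale`.
#' @export
expression_matrix <- function(values,
                              probe_ids = rownames(values),
                              gene_symbols = NULL,
                              sample_ids = colnames(values),
                              cohort = NULL,
                              background = NULL,
                              log_scale = TRUE) {
  values <- as.matrix(values)
  if (is.null(probe_ids)) probe_ids <- paste0("probe", seq_len(nrow(values)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(ncol(values)))
  probe_ids <- as.character(probe_ids)
  sample_ids <- as.character(sample_ids)
  if (length(probe_ids) != nrow(values))
    stop("probe_ids length must equal nrow(values)")
  if (length(sample_ids) != ncol(values))
    stop("sample_ids length must equal ncol(values)")
  if (anyDuplicated(sample_ids))
    stop("duplicated sample IDs")
  if (anyDuplicated(probe_ids))
    stop("duplicated probe IDs")
  if (is.null(gene_symbols)) gene_symbols <- probe_ids
  gene_symbols <- as.character(gene_symbols)
  if (length(gene_symbols) != nrow(values))
    stop("gene_symbols length must equal nrow(values)")
  if (is.null(cohort)) cohort <- "cohort1"
  if (length(cohort) == 1) cohort <- rep(cohort, ncol(values))
  cohort <- factor(cohort)
  if (length(cohort) != ncol(values))
    stop("cohort length must equal ncol(values)")
  if (!is.null(background)) {
    background <- as.numeric(background)
    if (length(background) != ncol(values))
      stop("background length must equal ncol(values)")
  }
  rownames(values) <- probe_ids
  colnames(values) <- sample_ids
  structure(
    list(values = values, probe_ids = probe_ids, gene_symbols = gene_symbols,
         sample_ids = sample_ids, cohort = cohort, background = background,
         log_scale = isTRUE(log_scale)),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d probes x %d samples (%s scale)\n",
              nrow(x$values), ncol(x$values),
              if (x$log_scale) "log2" else "linear"))
  cat("cohorts:", paste(sprintf("%s (n=%d)", levels(x$cohort),
                                tabulate(x$cohort)), collapse = ", "), "\n")
  n_genes <- length(unique(stats::na.omit(x$gene_symbols)))
  cat(sprintf("mapped gene symbols: %d%s\n", n_genes,
              if (is.null(x$background)) "" else "; background available"))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Subset an ExpressionMatrix by probes and/or samples
#' @param x an `ExpressionMatrix`
#' @param i probe index (integer, logical or probe IDs)
#' @param j sample index (integer, logical or sample IDs)
#' @param ... ignored
#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  if (is.character(i)) i <- match(i, x$probe_ids)
  if (is.character(j)) j <- match(j, x$sample_ids)
  expression_matrix(
    x$values[i, j, drop = FALSE],
    probe_ids = x$probe_ids[i],
    gene_symbols = x$gene_symbols[i],
    sample_ids = x$sample_ids[j],
    cohort = droplevels(x$cohort[j]),
    background = if (!is.null(x$background)) x$background[j],
    log_scale = x$log_scale
  )
}

#' Write an expression matrix to TSV
#'
#' First column holds the probe/gene identifier, header row holds sample IDs.
#'
#' @param x an `ExpressionMatrix` or a plain matrix with dimnames
#' @param path output file
#' @export
write_expression_tsv <- function(x, path) {
  values <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  df <- data.frame(id = rownames(values), values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' @param path TSV with the identifier in the first column and one column per
#'   sample.
#' @param cohort optional cohort label(s) for the samples.
#' @param log_scale logical; if `NA` (default) the scale is auto-detected:
#'   values with maximum above 50 are treated as linear intensities and
#'   log2-transformed with a +1 offset is NOT applied (raw values kept,
#'   `log_scale = FALSE`); use [preprocess_cohort()] or transform explicitly.
#' @return an `ExpressionMatrix`
#' @export
read_expression_tsv <- function(path, cohort = NULL, log_scale = NA) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- as.character(df[[1]])
  if (is.na(log_scale)) log_scale <- max(values, na.rm = TRUE) <= 50
  expression_matrix(values, cohort = cohort, log_scale = log_scale)
}
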