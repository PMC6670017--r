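#' Filter probes by signal-over-background
#'
#' Keeps a probe if, in at least one cohort, at least one sample's raw signal
#' exceeds `background_factor` times that cohort's mean background level. When
#' several cohorts are supplied the returned matrices are restricted to the
#' intersection of surviving probes, ready for merging.
#'
#' @param cohorts a single `ExpressionMatrix` or a list of them, each carrying
#'   raw (linear-scale) values and a per-sample `background`.
#' @param background_factor multiple of the mean background a signal must
#'   exceed (default 2).
#' @param per_sample_background if `TRUE`, each sample's signal is compared to
#'   `background_factor` times its own background instead of the cohort-wide
#'   mean background.
#' @return an object of the same shape as the input (single matrix or list),
#'   restricted to surviving probes.
#' @export
filter_probes <- function(cohorts, background_factor = 2,
                          per_sample_background = FALSE) {
  single <- inherits(cohorts, "ExpressionMatrix")
  if (single) cohorts <- list(cohorts)
  stopifnot(all(vapply(cohorts, inherits, TRUE, "ExpressionMatrix")))
  keep_per_cohort <- lapply(cohorts, function(x) {
    if (is.null(x$background))
      stop("filter_probes requires a per-sample background level")
    if (per_sample_background) {
      thr <- matrix(background_factor * x$background, nrow = nrow(x$values),
                    ncol = ncol(x$values), byrow = TRUE)
      pass <- x$values > thr
    } else {
      pass <- x$values > background_factor * mean(x$background)
    }
    stats::setNames(rowSums(pass) > 0, x$probe_ids)
  })
  # a probe survives if it passes in >= 1 cohort; merging then uses the
  # probes present (and surviving) everywhere
  all_ids <- unique(unlist(lapply(cohorts, `[[`, "probe_ids")))
  passes_any <- rep(FALSE, length(all_ids))
  names(passes_any) <- all_ids
  for (kp in keep_per_cohort) passes_any[names(kp)] <- passes_any[names(kp)] | kp
  shared <- Reduce(intersect, lapply(cohorts, `[[`, "probe_ids"))
  surviving <- shared[passes_any[shared]]
  out <- lapply(cohorts, function(x) x[surviving, ])
  if (single) out[[1]] else out
}

#' Quantile-normalize the samples of an expression matrix
#'
#' Forces every sample (column) to share the same empirical distribution: the
#' across-sample mean of the order statistics. Ties receive the average of the
#' tied ranks' reference values. Applied within one cohort at a time; when the
#' matrix holds several cohorts, each is normalized separately (arrays are
#' normalized within their own study).
#'
#' @param x an `ExpressionMatrix` (or plain matrix) with at least 2 samples.
#' @return the normalized object, same class as the input.
#' @export
quantile_normalize <- function(x) {
  values <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  if (anyNA(values)) stop("missing values are not supported")
  if (ncol(values) < 2) stop("quantile normalization needs >= 2 samples")
  if (inherits(x, "ExpressionMatrix") && nlevels(x$cohort) > 1) {
    for (co in levels(x$cohort)) {
      j <- x$cohort == co
      values[, j] <- limma::normalizeQuantiles(values[, j, drop = FALSE],
                                               ties = TRUE)
    }
  } else {
    values <- limma::normalizeQuantiles(values, ties = TRUE)
  }
  if (inherits(x, "ExpressionMatrix")) {
    x$values <- values
    x
  } else {
    values
  }
}

#' Center each probe by its mean, within cohort
#'
#' Subtracts from every probe row its per-cohort mean. Because batch effects
#' are modeled as additive per-probe offsets shared by all samples of a
#' cohort, per-cohort centering removes them exactly; a probe constant within
#' a cohort becomes all-zero there.
#'
#' @param x an `ExpressionMatrix`, or a plain matrix (treated as one cohort).
#' @return the centered object, same class as the input.
#' @export
center_probes <- function(x) {
  values <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  cohort <- if (inherits(x, "ExpressionMatrix")) x$cohort
            else factor(rep("cohort1", ncol(values)))
  for (co in levels(cohort)) {
    j <- cohort == co
    values[, j] <- values[, j, drop = FALSE] -
      rowMeans(values[, j, drop = FALSE])
  }
  if (inherits(x, "ExpressionMatrix")) {
    x$values <- values
    x
  } else {
    values
  }
}

#' Collapse redundant probes to one row per gene
#'
#' For genes measured by several probes, keeps the probe with the highest
#' median expression (computed on the values as given, i.e. normalized but not
#' yet centered — a centered row's median carries no expression-level
#' information). Ties are broken by the lexicographically smallest probe ID.
#' Probes with no mapped gene symbol are dropped and their count reported in a
#' message.
#'
#' @param x an `ExpressionMatrix` with a probe-to-gene map.
#' @return an `ExpressionMatrix` with one row per gene, rownames set to gene
#'   symbols.
#' @export
collapse_probes <- function(x) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  mapped <- !is.na(x$gene_symbols) & nzchar(x$gene_symbols)
  n_dropped <- sum(!mapped)
  if (n_dropped > 0)
    message(n_dropped, " probes without a gene symbol dropped")
  meds <- apply(x$values, 1, stats::median)
  df <- data.frame(probe = x$probe_ids, gene = x$gene_symbols, med = meds,
                   stringsAsFactors = FALSE)[mapped, ]
  df <- df[order(df$gene, -df$med, df$probe), ]
  best <- df[!duplicated(df$gene), ]
  out <- x[match(best$probe, x$probe_ids), ]
  out$probe_ids <- best$probe
  out$gene_symbols <- best$gene
  rownames(out$values) <- best$gene
  out
}

#' Merge two gene-level cohorts
#'
#' Inner-join on gene symbol. In `mode = "join"` the log-scale values are
#' concatenated as-is (per-probe centering is expected to follow or precede).
#' In `mode = "median_scale"` — used when combining array intensities with
#' sequencing-derived abundances — each gene's values are divided by its
#' within-cohort median before joining (requires linear-scale values).
#'
#' @param a,b gene-level `ExpressionMatrix` objects (see [collapse_probes()]).
#' @param mode `"join"` or `"median_scale"`.
#' @return a merged `ExpressionMatrix` over the shared genes, with cohort
#'   labels preserved (prefixed by the argument if the labels collide).
#' @export
merge_cohorts <- function(a, b, mode = c("join", "median_scale")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "ExpressionMatrix"), inherits(b, "ExpressionMatrix"))
  ga <- rownames(a$values)
  gb <- rownames(b$values)
  if (anyDuplicated(ga) || anyDuplicated(gb))
    stop("cohorts must be collapsed to one row per gene before merging")
  shared <- intersect(ga, gb)
  if (length(shared) == 0) stop("no shared genes between cohorts")
  va <- a$values[match(shared, ga), , drop = FALSE]
  vb <- b$values[match(shared, gb), , drop = FALSE]
  if (mode == "median_scale") {
    scale_rows <- function(v) {
      med <- apply(v, 1, stats::median)
      if (any(med == 0)) stop("zero within-cohort median; cannot median-scale")
      v / med
    }
    va <- scale_rows(va)
    vb <- scale_rows(vb)
  }
  coh_a <- as.character(a$cohort)
  coh_b <- as.character(b$cohort)
  if (length(intersect(unique(coh_a), unique(coh_b))) > 0) {
    coh_a <- paste0("a.", coh_a)
    coh_b <- paste0("b.", coh_b)
  }
  sa <- a$sample_ids
  sb <- b$sample_ids
  if (length(intersect(sa, sb)) > 0) {
    sa <- paste0("a.", sa)
    sb <- paste0("b.", sb)
  }
  expression_matrix(cbind(va, vb),
                    probe_ids = shared, gene_symbols = shared,
                    sample_ids = c(sa, sb), cohort = c(coh_a, coh_b),
                    log_scale = a$log_scale && mode == "join")
}

#' Run the full preprocessing chain on one or more raw cohorts
#'
#' Convenience wrapper: optional log2 transform (auto-detected when the
#' maximum value exceeds 50, as linear bead intensities do), probe filtering
#' against background (skipped when no background is available), per-cohort
#' quantile normalization, probe collapse (on uncentered values), merging, and
#' per-cohort probe centering.
#'
#' @param cohorts a list of raw `ExpressionMatrix` objects (or a single one).
#' @param background_factor see [filter_probes()].
#' @param log2_transform `TRUE`, `FALSE`, or `NA` to auto-detect linear scale.
#' @return a merged, normalized, collapsed, centered `ExpressionMatrix`.
#' @export
preprocess_cohort <- function(cohorts, background_factor = 2,
                              log2_transform = NA) {
  if (inherits(cohorts, "ExpressionMatrix")) cohorts <- list(cohorts)
  has_bg <- all(!vapply(cohorts, function(x) is.null(x$background), TRUE))
  if (has_bg)
    cohorts <- filter_probes(cohorts, background_factor = background_factor)
  cohorts <- lapply(cohorts, function(x) {
    do_log <- if (is.na(log2_transform)) {
      !x$log_scale || max(x$values) > 50
    } else {
      log2_transform
    }
    if (do_log) {
      x$values <- log2(pmax(x$values, 1))
      x$log_scale <- TRUE
    }
    x <- quantile_normalize(x)
    collapse_probes(x)
  })
  merged <- Reduce(merge_cohorts, cohorts)
  center_probes(merged)
}
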