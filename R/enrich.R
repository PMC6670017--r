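#' Genes significantly up-regulated per subtype
#'
#' Mirrors the filter feeding enrichment analysis: a Kruskal-Wallis test
#' across all subtypes gates each gene (at unadjusted p < `fdr`; with small
#' groups the exact Kruskal-Wallis p-value has a floor that a multiplicity
#' adjustment would push past any strict cutoff), followed by a one-vs-rest
#' two-sided Mann-Whitney U test per subtype whose p-values are
#' Benjamini-Hochberg adjusted across genes; a gene is reported for a subtype
#' when its adjusted Mann-Whitney p falls below `fdr` and its median is higher
#' in that subtype than in the rest.
#'
#' @param x an `ExpressionMatrix` or genes x samples matrix.
#' @param labels per-sample subtype labels.
#' @param fdr adjusted-p cutoff (default 0.01).
#' @return named list (one per subtype) of data frames with `gene`, `p_mw`,
#'   `p_mw_adj`, sorted by ascending adjusted p.
#' @export
subtype_upregulated <- function(x, labels, fdr = 0.01) {
  values <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  labels <- factor(labels)
  if (length(labels) != ncol(values)) stop("labels length mismatch")
  if (any(table(labels) < 2)) stop("every class needs at least 2 samples")
  genes <- rownames(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))

  p_kw <- apply(values, 1, function(row) {
    stats::kruskal.test(row, labels)$p.value
  })
  kw_pass <- p_kw < fdr

  out <- lapply(levels(labels), function(cls) {
    in_cls <- labels == cls
    p_mw <- apply(values, 1, function(row) {
      suppressWarnings(
        stats::wilcox.test(row[in_cls], row[!in_cls])$p.value)
    })
    p_adj <- stats::p.adjust(p_mw, "BH")
    up <- apply(values[, in_cls, drop = FALSE], 1, stats::median) >
      apply(values[, !in_cls, drop = FALSE], 1, stats::median)
    sel <- which(kw_pass & p_adj < fdr & up)
    sel <- sel[order(p_adj[sel])]
    data.frame(gene = genes[sel], p_mw = unname(p_mw[sel]),
               p_mw_adj = unname(p_adj[sel]), stringsAsFactors = FALSE)
  })
  names(out) <- levels(labels)
  out
}

#' Read a gene-set collection in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1))
  sets
}

#' Write a gene-set collection in GMT format
#' @param sets named list of character vectors.
#' @param path output file.
#' @param description description field per set (recycled).
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], description[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation of gene sets in a query list
#'
#' For each set, the probability of observing at least the actual overlap
#' between the query and the set by chance, given the universe (one-sided
#' hypergeometric upper tail), with Benjamini-Hochberg adjustment across sets.
#' Query genes outside the universe are dropped with a message; set members
#' are intersected with the universe.
#'
#' @param query character vector of genes of interest (non-empty).
#' @param sets named list of gene sets (e.g. from [read_gmt()]).
#' @param universe background gene list.
#' @return data frame with `set`, `set_size`, `overlap`, `p_value`,
#'   `p_adjusted`, sorted by ascending p.
#' @export
overrepresentation <- function(query, sets, universe) {
  query <- unique(query)
  if (length(query) == 0) stop("empty query")
  universe <- unique(universe)
  dropped <- setdiff(query, universe)
  if (length(dropped) > 0) {
    message(length(dropped), " query genes outside the universe dropped")
    query <- intersect(query, universe)
    if (length(query) == 0) stop("no query genes left within the universe")
  }
  N <- length(universe)
  k <- length(query)
  rows <- lapply(names(sets), function(nm) {
    set <- intersect(unique(sets[[nm]]), universe)
    m <- length(set)
    ov <- length(intersect(query, set))
    # P(X >= ov), X ~ Hypergeometric(m, N - m, k)
    p <- stats::phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(set = nm, set_size = m, overlap = ov, p_value = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out[order(out$p_value), , drop = FALSE]
}

#' Read a directed interaction network from a 2-column TSV edge list
#'
#' Columns: regulator, target. Self-loops are removed unless `keep_self`.
#'
#' @param path TSV file (header optional, detected by non-matching first row
#'   being used as data when `header = FALSE`).
#' @param header whether the file has a header row.
#' @param keep_self keep self-loops.
#' @return data frame with columns `regulator`, `target`.
#' @export
read_network <- function(path, header = TRUE, keep_self = FALSE) {
  df <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  df <- df[, 1:2]
  names(df) <- c("regulator", "target")
  if (!keep_self) df <- df[df$regulator != df$target, , drop = FALSE]
  df
}

#' Network over-connectivity of upstream regulators
#'
#' For each candidate regulator in a directed network, tests whether its
#' targets are over-represented in the query list relative to the universe
#' (node-level hypergeometric: targets within the universe form the set, the
#' query the draw). Regulators with no targets in the universe are skipped.
#'
#' @param query character vector of genes (e.g. a subtype's up-regulated
#'   transcripts).
#' @param network data frame with `regulator` and `target` columns (see
#'   [read_network()]).
#' @param universe background gene list.
#' @return data frame with `regulator`, `n_targets` (within universe),
#'   `overlap`, `expected`, `ratio`, `p_value`, `p_adjusted`, sorted by
#'   ascending p.
#' @export
overconnectivity <- function(query, network, universe) {
  query <- intersect(unique(query), universe)
  if (length(query) == 0) stop("empty query within universe")
  N <- length(universe)
  k <- length(query)
  regs <- unique(network$regulator)
  rows <- lapply(regs, function(r) {
    targets <- intersect(unique(network$target[network$regulator == r]),
                         universe)
    m <- length(targets)
    if (m == 0) return(NULL)
    ov <- length(intersect(query, targets))
    expected <- m * k / N
    p <- stats::phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(regulator = r, n_targets = m, overlap = ov,
               expected = expected,
               ratio = if (expected > 0) ov / expected else NA_real_,
               p_value = p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) stop("no regulator has targets within the universe")
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
  out[order(out$p_value), , drop = FALSE]
}
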