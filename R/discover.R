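#' Principal component analysis with sevenfold cross-validated Q2
#'
#' Fits PCA by singular value decomposition on the column-centered data
#' (samples are observations, genes are variables) and assesses each
#' component's predictive relevance by element-wise deletion cross-validation:
#' matrix cells are assigned to `n_folds` deletion groups in a deterministic
#' diagonal ("venetian blinds") pattern, each group is deleted in turn, a
#' one-component NIPALS model tolerant of missing values is fit to the rest,
#' and the deleted cells are predicted. Q2 for component k is
#' `1 - PRESS_k / RSS_{k-1}` where `RSS_{k-1}` is the residual sum of squares
#' of the full-data model with k-1 components. A component is counted as
#' significant while its Q2 exceeds `q2_threshold`.
#'
#' @param x an `ExpressionMatrix` (genes x samples) or a samples x features
#'   matrix.
#' @param max_components number of components to extract (capped at
#'   `min(n, p)`).
#' @param n_folds cross-validation folds for Q2 (default 7).
#' @param q2_threshold significance threshold on Q2 (default 0).
#' @return an object of class `PcaModel`: list with `scores` (samples x
#'   components), `loadings` (features x components), `r2` (explained-variance
#'   fraction per component), `q2`, `n_significant`, `center` (feature means).
#' @export
fit_pca <- function(x, max_components = 10, n_folds = 7, q2_threshold = 0) {
  X <- if (inherits(x, "ExpressionMatrix")) t(x$values) else as.matrix(x)
  if (max_components < 1) stop("max_components must be >= 1")
  if (anyNA(X)) stop("missing values are not supported")
  center <- colMeans(X)
  X <- sweep(X, 2, center)
  k_max <- min(dim(X))
  k <- min(max_components, k_max)
  sv <- svd(X, nu = k, nv = k)
  d2 <- sv$d^2
  total_ss <- sum(d2)
  r2 <- d2[seq_len(k)] / total_ss
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v

  fold_of <- (outer(seq_len(nrow(X)), seq_len(ncol(X)), `+`)) %% n_folds
  q2 <- numeric(k)
  E <- X
  for (comp in seq_len(k)) {
    rss_prev <- sum(E^2)
    press <- 0
    for (f in seq_len(n_folds) - 1) {
      Edel <- E
      del <- fold_of == f
      Edel[del] <- NA
      cmp <- nipals_component(Edel)
      pred <- tcrossprod(cmp$t, cmp$p)
      press <- press + sum((E[del] - pred[del])^2)
    }
    q2[comp] <- 1 - press / rss_prev
    E <- E - tcrossprod(scores[, comp], loadings[, comp])
  }
  above <- which(q2 > q2_threshold)
  n_significant <- if (length(above)) max(above) else 0L

  rownames(scores) <- rownames(X)
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(loadings) <- colnames(X)
  colnames(loadings) <- paste0("PC", seq_len(k))
  structure(list(scores = scores, loadings = loadings, r2 = r2, q2 = q2,
                 n_significant = n_significant, center = center),
            class = "PcaModel")
}

# One NIPALS PCA component tolerant of missing values. Returns scores t and
# loadings p such that t %*% t(p) approximates X (centered input assumed).
nipals_component <- function(X, tol = 1e-9, max_iter = 500) {
  obs <- !is.na(X)
  X0 <- X
  X0[!obs] <- 0
  j0 <- which.max(colSums(X0^2))
  t <- X0[, j0]
  p <- numeric(ncol(X))
  for (it in seq_len(max_iter)) {
    # p_j = sum_i obs X_ij t_i / sum_i obs t_i^2
    num <- crossprod(X0, t)
    den <- crossprod(obs, t^2)
    p_new <- as.numeric(num / pmax(den, .Machine$double.eps))
    p_new <- p_new / sqrt(sum(p_new^2))
    num_t <- X0 %*% p_new
    den_t <- obs %*% p_new^2
    t_new <- as.numeric(num_t / pmax(den_t, .Machine$double.eps))
    if (sum((p_new - p)^2) < tol && it > 1) {
      t <- t_new
      p <- p_new
      break
    }
    t <- t_new
    p <- p_new
  }
  list(t = t, p = p)
}

#' @export
print.PcaModel <- function(x, ...) {
  cat(sprintf("PcaModel: %d components, %d significant (Q2 > 0)\n",
              ncol(x$scores), x$n_significant))
  cat("R2: ", paste(sprintf("%.3f", x$r2), collapse = " "), "\n")
  cat("Q2: ", paste(sprintf("%.3f", x$q2), collapse = " "), "\n")
  invisible(x)
}

#' Cluster samples with one of five algorithms
#'
#' Supported algorithms: hierarchical clustering with Ward linkage on
#' Euclidean (`ward_euclidean`) or Manhattan (`ward_manhattan`) distances,
#' `kmeans` (25 random starts), a one-dimensional batch self-organizing map
#' (`som`, k units in a line; samples labeled by their nearest unit), and
#' `affinity_propagation` (k emergent; see [affinity_propagation()]).
#'
#' @param data samples x features numeric matrix.
#' @param algorithm one of `"ward_euclidean"`, `"ward_manhattan"`, `"kmeans"`,
#'   `"som"`, `"affinity_propagation"`.
#' @param k number of clusters (ignored by affinity propagation).
#' @param seed integer seed controlling the stochastic algorithms.
#' @return integer label vector (1..k), with attributes `converged` (affinity
#'   propagation only) and `k_emergent` where applicable.
#' @export
cluster_samples <- function(data,
                            algorithm = c("ward_euclidean", "ward_manhattan",
                                          "kmeans", "som",
                                          "affinity_propagation"),
                            k = 3, seed = 1) {
  algorithm <- match.arg(algorithm)
  data <- as.matrix(data)
  n <- nrow(data)
  if (algorithm != "affinity_propagation") {
    if (is.null(k) || k < 1) stop("k is required for ", algorithm)
    if (k > n) stop("k cannot exceed the number of samples")
  }
  labels <- switch(
    algorithm,
    ward_euclidean = stats::cutree(
      stats::hclust(stats::dist(data), method = "ward.D2"), k = k),
    ward_manhattan = stats::cutree(
      stats::hclust(stats::dist(data, method = "manhattan"),
                    method = "ward.D2"), k = k),
    kmeans = {
      set.seed(seed)
      stats::kmeans(data, centers = k, nstart = 25, iter.max = 100)$cluster
    },
    som = {
      set.seed(seed)
      grid <- class::somgrid(xdim = k, ydim = 1, topo = "rectangular")
      fitted <- class::batchSOM(data, grid, radii = c(2, 1, 0.5, 0, 0))
      units <- as.integer(class::knn1(fitted$codes, data,
                                      seq_len(nrow(fitted$codes))))
      # relabel to consecutive integers (empty units possible)
      as.integer(factor(units))
    },
    affinity_propagation = {
      ap <- affinity_propagation(data, seed = seed)
      lab <- ap$labels
      attr(lab, "converged") <- ap$converged
      attr(lab, "k_emergent") <- ap$k
      lab
    }
  )
  unname_keep_attr(labels)
}

unname_keep_attr <- function(x) {
  at <- attributes(x)
  x <- as.integer(x)
  for (nm in setdiff(names(at), "names")) attr(x, nm) <- at[[nm]]
  x
}

#' Affinity propagation clustering
#'
#' Message-passing clustering of Frey & Dueck with negative squared Euclidean
#' distance similarities, preference set to the median similarity, damping
#' 0.9, and at most `max_iter` iterations. The number of clusters is emergent.
#' If the exemplar set has not been stable for `conv_iter` consecutive
#' iterations by `max_iter`, the result is flagged as non-converged rather
#' than forced.
#'
#' @param data samples x features matrix.
#' @param damping damping factor in (0.5, 1).
#' @param max_iter maximum number of message-passing iterations.
#' @param conv_iter iterations of unchanged exemplars required to declare
#'   convergence.
#' @param preference exemplar preference; default median of the off-diagonal
#'   similarities.
#' @param seed seed for the tiny symmetry-breaking noise added to the
#'   similarities.
#' @return list with `labels` (integer vector, 1..k), `exemplars`, `k`,
#'   `converged`, `iterations`.
#' @export
affinity_propagation <- function(data, damping = 0.9, max_iter = 1000,
                                 conv_iter = 100, preference = NULL,
                                 seed = 1) {
  data <- as.matrix(data)
  n <- nrow(data)
  S <- -as.matrix(stats::dist(data))^2
  set.seed(seed)
  off <- S[upper.tri(S) | lower.tri(S)]
  if (is.null(preference)) preference <- stats::median(off)
  diag(S) <- preference
  # tiny noise removes degeneracies (as in the reference implementation)
  S <- S + 1e-12 * abs(S) * matrix(stats::rnorm(n * n), n)

  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  last_ex <- NULL
  stable <- 0L
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    ex <- which(diag(A + R) > 0)
    if (!is.null(last_ex) && length(ex) > 0 && identical(ex, last_ex)) {
      stable <- stable + 1L
      if (stable >= conv_iter) {
        converged <- TRUE
        break
      }
    } else {
      stable <- 0L
    }
    last_ex <- ex
  }
  ex <- which(diag(A + R) > 0)
  if (length(ex) == 0) ex <- which.max(diag(A + R))
  assign <- apply(S[, ex, drop = FALSE], 1, which.max)
  assign[ex] <- seq_along(ex)
  list(labels = as.integer(assign), exemplars = ex, k = length(ex),
       converged = converged, iterations = it)
}

#' Grouping-preservation statistic between two clusterings
#'
#' Matches the clusters of `alternative` one-to-one to the clusters of
#' `reference` by maximum agreement (optimal assignment on the contingency
#' table, found by exhaustive permutation; cluster counts up to 8 are
#' supported) and returns the fraction of samples whose matched label agrees
#' with the reference. Invariant to relabeling of either argument.
#'
#' @param reference,alternative label vectors of equal length.
#' @param per_cluster if `TRUE`, also return the per-reference-cluster
#'   consistency fractions.
#' @return the overall preserved fraction, or (with `per_cluster = TRUE`) a
#'   list with `overall` and `per_cluster`.
#' @export
preservation <- function(reference, alternative, per_cluster = FALSE) {
  if (length(reference) != length(alternative))
    stop("label vectors must have equal length")
  tab <- table(reference, alternative)
  match_idx <- match_clusters(tab)
  agreed <- sum(tab[cbind(seq_len(nrow(tab)), match_idx)], na.rm = TRUE)
  overall <- agreed / length(reference)
  if (!per_cluster) return(overall)
  per <- vapply(seq_len(nrow(tab)), function(i) {
    if (is.na(match_idx[i])) 0 else tab[i, match_idx[i]] / sum(tab[i, ])
  }, numeric(1))
  names(per) <- rownames(tab)
  list(overall = overall, per_cluster = per)
}

# Optimal one-to-one assignment of contingency-table columns to rows,
# maximizing the total matched count. Exhaustive over permutations of the
# larger dimension (fine for the handful of clusters used here).
match_clusters <- function(tab) {
  r <- nrow(tab)
  c <- ncol(tab)
  k <- max(r, c)
  if (k > 8) stop("cluster matching supports at most 8 clusters")
  sq <- matrix(0, k, k)
  sq[seq_len(r), seq_len(c)] <- tab
  best <- NULL
  best_sum <- -1
  for (perm in all_permutations(k)) {
    s <- sum(sq[cbind(seq_len(k), perm)])
    if (s > best_sum) {
      best_sum <- s
      best <- perm
    }
  }
  idx <- best[seq_len(r)]
  idx[idx > c] <- NA
  idx
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (sub in all_permutations(k - 1)) {
      rest <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, rest[sub])
    }
  }
  out
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions (up to
#' relabeling), approximately 0 for independent ones.
#'
#' @param a,b label vectors of equal length.
#' @return numeric scalar.
#' @export
adjusted_rand <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)
  (sum_ij - expected) / (maximum - expected)
}

#' Discover molecular subtypes by PCA plus consensus clustering
#'
#' The reference solution is Ward/Euclidean hierarchical clustering of the
#' first `m_components` principal component scores cut at `k` clusters.
#' Alternative solutions are computed for each requested algorithm in each
#' requested input space (scores of the first 2 or 5 components, or all
#' genes), and their agreement with the reference is summarized by the
#' grouping-preservation statistic. Reference clusters are relabeled by
#' decreasing size (cluster 1 largest), mirroring the convention of naming the
#' dominant subtype first.
#'
#' @param x an `ExpressionMatrix` (preprocessed: normalized, collapsed,
#'   centered) or samples x genes matrix.
#' @param m_components number of PC scores for the reference clustering
#'   (default 2).
#' @param k number of clusters (default 3).
#' @param algorithms algorithms for the alternative solutions.
#' @param spaces input spaces for the alternative solutions; any of
#'   `"pc2"`, `"pc5"`, `"all_genes"`.
#' @param seed seed for the stochastic algorithms.
#' @param max_components components to extract in the PCA model.
#' @return an object of class `ClusterSolution`: list with `reference_labels`
#'   (integer vector named by sample), `alternative_labels` (named list),
#'   `preservation` (named numeric vector, one per alternative),
#'   `per_cluster_preservation`, `pca` (the [fit_pca()] model), `k`,
#'   `input_space`, `ap_converged` (named logical for affinity-propagation
#'   runs).
#' @export
discover_subtypes <- function(x, m_components = 2, k = 3,
                              algorithms = c("ward_euclidean",
                                             "ward_manhattan", "kmeans",
                                             "som", "affinity_propagation"),
                              spaces = c("pc2", "pc5", "all_genes"),
                              seed = 1, max_components = 10) {
  X <- if (inherits(x, "ExpressionMatrix")) t(x$values) else as.matrix(x)
  pca <- fit_pca(X, max_components = max(max_components, 5, m_components))
  get_space <- function(space) {
    switch(space,
           pc2 = pca$scores[, 1:2, drop = FALSE],
           pc5 = pca$scores[, 1:min(5, ncol(pca$scores)), drop = FALSE],
           all_genes = X,
           stop("unknown space: ", space))
  }
  ref_space <- pca$scores[, seq_len(m_components), drop = FALSE]
  ref <- cluster_samples(ref_space, "ward_euclidean", k = k, seed = seed)
  # relabel by decreasing cluster size, ties by first occurrence
  sizes <- sort(table(ref), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  ref <- as.integer(relabel[as.character(ref)])
  names(ref) <- rownames(X)

  alt <- list()
  pres <- numeric(0)
  per_cluster <- list()
  ap_conv <- logical(0)
  ref_space_tag <- paste0("pc", m_components)
  for (space in spaces) {
    dat <- get_space(space)
    for (algo in algorithms) {
      if (algo == "ward_euclidean" && space == ref_space_tag) next
      id <- paste(algo, space, sep = ".")
      lab <- cluster_samples(dat, algo, k = k, seed = seed)
      if (algo == "affinity_propagation") {
        ap_conv[id] <- isTRUE(attr(lab, "converged"))
        if (!ap_conv[id]) {
          alt[[id]] <- NULL
          pres[id] <- NA_real_
          next
        }
      }
      alt[[id]] <- as.integer(lab)
      p <- preservation(ref, lab, per_cluster = TRUE)
      pres[id] <- p$overall
      per_cluster[[id]] <- p$per_cluster
    }
  }
  structure(list(reference_labels = ref, alternative_labels = alt,
                 preservation = pres, per_cluster_preservation = per_cluster,
                 pca = pca, k = k, input_space = ref_space_tag,
                 ap_converged = ap_conv),
            class = "ClusterSolution")
}

#' @export
print.ClusterSolution <- function(x, ...) {
  cat(sprintf("ClusterSolution: k=%d on %s; n=%d samples\n", x$k,
              x$input_space, length(x$reference_labels)))
  cat("cluster sizes:", paste(tabulate(x$reference_labels, x$k),
                              collapse = "/"), "\n")
  if (length(x$preservation)) {
    cat("preservation:\n")
    for (nm in names(x$preservation)) {
      cat(sprintf("  %-35s %s\n", nm,
                  if (is.na(x$preservation[nm])) "not converged"
                  else sprintf("%.2f", x$preservation[nm])))
    }
  }
  invisible(x)
}
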