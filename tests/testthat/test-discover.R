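test_that("PCA explains a rank-1 matrix with one component and conserves R2", {
  set.seed(1)
  u <- rnorm(12)
  v <- rnorm(20)
  X <- tcrossprod(u, v)           # exact rank 1 after centering
  fit <- fit_pca(X, max_components = 5)
  expect_equal(fit$r2[1], 1, tolerance = 1e-12)

  Y <- matrix(rnorm(12 * 20), 12)
  fit2 <- fit_pca(Y, max_components = 12)
  expect_equal(sum(fit2$r2), 1, tolerance = 1e-12)
  # reconstruction with all components equals the input
  rec <- fit2$scores %*% t(fit2$loadings)
  expect_equal(rec + matrix(fit2$center, 12, 20, byrow = TRUE), Y,
               tolerance = 1e-10)
  expect_error(fit_pca(Y, max_components = 0), "max_components")
})

test_that("cross-validated Q2 finds exactly one significant component in rank-1 + noise", {
  set.seed(2)
  signal <- tcrossprod(rnorm(30, sd = 4), rnorm(40))
  X <- signal + matrix(rnorm(30 * 40, sd = 0.05), 30)
  fit <- fit_pca(X, max_components = 5)
  expect_gt(fit$q2[1], 0.9)
  expect_true(all(fit$q2[2:5] <= 0))
  expect_equal(fit$n_significant, 1L)
})

test_that("all five algorithms separate two well-separated blobs", {
  set.seed(3)
  blob <- rbind(matrix(rnorm(30, 0, 0.2), 15, 2),
                matrix(rnorm(30, 8, 0.2), 15, 2))
  truth <- rep(1:2, each = 15)
  for (algo in c("ward_euclidean", "ward_manhattan", "kmeans", "som")) {
    lab <- cluster_samples(blob, algo, k = 2, seed = 3)
    expect_equal(adjusted_rand(lab, truth), 1)
  }
  ap <- cluster_samples(blob, "affinity_propagation", seed = 3)
  expect_true(attr(ap, "converged"))
  expect_equal(adjusted_rand(as.integer(ap), truth), 1)
})

test_that("hierarchical clustering at k = n gives singletons and k > n errors", {
  set.seed(4)
  d <- matrix(rnorm(12), 6, 2)
  expect_equal(sort(cluster_samples(d, "ward_euclidean", k = 6)), 1:6)
  expect_error(cluster_samples(d, "kmeans", k = 7), "exceed")
})

test_that("Ward cut at k=3 matches brute-force minimum-variance agglomeration", {
  pts <- matrix(c(0, 0, 0.4, 0, 5, 5, 5.3, 5.2, 9, 0, 9.2, 0.3),
                6, 2, byrow = TRUE)
  # brute-force Ward: merge the pair of clusters with the smallest increase
  # in total within-cluster sum of squares, down to 3 clusters
  ess <- function(idx) {
    if (length(idx) == 1) return(0)
    sum(scale(pts[idx, , drop = FALSE], scale = FALSE)^2)
  }
  clusters <- as.list(1:6)
  while (length(clusters) > 3) {
    best <- NULL
    best_inc <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1)) {
      inc <- ess(c(clusters[[i]], clusters[[j]])) -
        ess(clusters[[i]]) - ess(clusters[[j]])
      if (inc < best_inc) {
        best_inc <- inc
        best <- c(i, j)
      }
    }
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[1]]])
    clusters[[best[1]]] <- NULL
  }
  brute <- integer(6)
  for (i in seq_along(clusters)) brute[clusters[[i]]] <- i
  lab <- cluster_samples(pts, "ward_euclidean", k = 3)
  expect_equal(adjusted_rand(lab, brute), 1)
})

test_that("preservation matches clusters optimally and handles moved samples", {
  ref <- c(1, 1, 1, 1, 2, 2, 2, 3, 3, 3)
  expect_equal(preservation(ref, ref), 1)
  # identical up to renaming
  renamed <- c(3, 3, 3, 3, 1, 1, 1, 2, 2, 2)
  expect_equal(preservation(ref, renamed), 1)
  expect_equal(preservation(renamed, ref), 1)
  # one sample moved between clusters
  moved <- renamed
  moved[5] <- 3
  expect_equal(preservation(ref, moved), 0.9)
  per <- preservation(ref, moved, per_cluster = TRUE)
  expect_equal(unname(per$per_cluster), c(1, 2 / 3, 1))
  expect_error(preservation(ref, ref[-1]), "equal length")
  # symmetric under relabeling of either argument
  set.seed(5)
  a <- sample(1:3, 40, replace = TRUE)
  b <- sample(1:3, 40, replace = TRUE)
  perm <- c(2, 3, 1)
  expect_equal(preservation(a, b), preservation(perm[a], b))
  expect_equal(preservation(a, b), preservation(a, perm[b]))
})

test_that("adjusted Rand index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(6)
  for (i in 1:5) {
    a <- sample(1:3, 30, replace = TRUE)
    b <- sample(1:4, 30, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand(1:10, 1:10), 1)
})

test_that("Ward on all PC scores equals Ward on the centered data", {
  set.seed(7)
  X <- matrix(rnorm(20 * 15), 20, 15)
  Xc <- sweep(X, 2, colMeans(X))
  pca <- fit_pca(X, max_components = 15)
  lab_pc <- cluster_samples(pca$scores, "ward_euclidean", k = 4)
  lab_raw <- cluster_samples(Xc, "ward_euclidean", k = 4)
  expect_equal(adjusted_rand(lab_pc, lab_raw), 1)
})

test_that("subtype discovery recovers planted subtypes with high preservation", {
  co <- small_cohort(seed = 7)
  pp <- preprocess_cohort(co$expression)
  sol <- discover_subtypes(pp, seed = 7)
  expect_gte(adjusted_rand(sol$reference_labels, co$truth), 0.9)
  # reference rerun = preservation 1
  expect_equal(preservation(sol$reference_labels,
                            cluster_samples(sol$pca$scores[, 1:2],
                                            "ward_euclidean", k = 3)), 1)
  # the four k-aware algorithms agree with the reference across spaces
  kaware <- grep("affinity", names(sol$preservation), invert = TRUE,
                 value = TRUE)
  expect_true(all(sol$preservation[kaware] >= 0.8))
  # affinity propagation either fails to converge or is reported as flagged
  expect_true(all(c("ap_converged") %in% names(sol)))
})

test_that("affinity propagation reports non-convergence instead of forcing labels", {
  set.seed(8)
  # adversarial: nearly equidistant points, very few iterations allowed
  d <- matrix(rnorm(40, sd = 1), 20, 2)
  ap <- affinity_propagation(d, max_iter = 3, conv_iter = 100)
  expect_false(ap$converged)
  expect_equal(ap$iterations, 3)
  expect_length(ap$labels, 20)
})
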