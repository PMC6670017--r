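test_that("marker selection reproduces the exact Mann-Whitney p on 3-vs-3 toys", {
  # hand-ordered values, tie-free: p must equal full enumeration over all
  # C(6,3)=20 rank splits
  x <- matrix(c(10, 9, 8, 1, 2, 3,
                5, 1, 4, 2, 6, 3), 2, 6, byrow = TRUE)
  rownames(x) <- c("gA", "gB")
  labels <- rep(c("T", "R"), each = 3)
  panel <- select_markers(x, labels, n_top = 5, fc_min = 1, log_scale = FALSE)
  got <- panel$T
  expect_equal(got$p_value[got$gene == "gA"],
               exact_mw_p(c(10, 9, 8), c(1, 2, 3)))
  if ("gB" %in% got$gene) {
    expect_equal(got$p_value[got$gene == "gB"],
                 exact_mw_p(c(5, 1, 4), c(2, 6, 3)))
  }
})

test_that("fold-change filter excludes flat genes and ranks by p then fold change", {
  set.seed(1)
  n <- 8
  labels <- rep(c("T", "R"), each = n)
  flat <- rep(5, 2 * n)
  up_big <- c(rep(9, n), rep(5, n)) + rnorm(2 * n, sd = 0.01)
  up_small <- c(rep(5.2, n), rep(5, n)) + rnorm(2 * n, sd = 0.01)
  x <- rbind(flat = flat, up_big = up_big, up_small = up_small)
  panel <- select_markers(x, labels, n_top = 10, fc_min = 1.5)
  expect_false("flat" %in% panel$T$gene)       # fold change 1.0 -> excluded
  expect_true("up_big" %in% panel$T$gene)
  expect_false("up_small" %in% panel$T$gene)   # 2^0.2 < 1.5 -> excluded
  expect_error(select_markers(x, c("T", rep("R", 2 * n - 1))), "2 samples")
})

test_that("panels hold n_top genes per subtype when enough pass the filter", {
  co <- small_cohort(seed = 9)
  pp <- preprocess_cohort(co$expression)
  panel <- select_markers(pp, co$truth, n_top = 20)
  for (s in c("A", "B", "C")) {
    expect_equal(nrow(panel[[s]]), 20)
    expect_false(any(duplicated(panel[[s]]$gene)))
    expect_true(all(diff(panel[[s]]$p_value) >= 0))       # sorted by p
    expect_true(all(panel[[s]]$median_fold_change >= 1.5))
    # planted markers dominate the panel
    expect_gt(mean(panel[[s]]$gene %in% co$marker_blocks[[s]]), 0.9)
  }
})

test_that("marker p-values are invariant to monotone transforms, fold changes are not", {
  set.seed(2)
  x <- matrix(rnorm(5 * 12, 8), 5, 12)
  rownames(x) <- paste0("g", 1:5)
  labels <- rep(c("T", "R"), each = 6)
  p1 <- select_markers(x, labels, n_top = 5, fc_min = 0)
  p2 <- select_markers(2 * x + 3, labels, n_top = 5, fc_min = 0)
  m1 <- p1$T[order(p1$T$gene), ]
  m2 <- p2$T[order(p2$T$gene), ]
  expect_equal(m1$p_value, m2$p_value, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(m1$median_fold_change,
                                m2$median_fold_change)))
})

test_that("OPLS-DA with zero orthogonal components equals a PLS oracle", {
  skip_if_not_installed("mixOmics")
  set.seed(3)
  n <- 24
  labels <- factor(rep(c("A", "B", "C"), each = 8))
  X <- matrix(rnorm(n * 10), n, 10) +
    outer(as.integer(labels), seq_len(10) %% 3 + 1) * 0.5
  colnames(X) <- paste0("g", 1:10)
  model <- fit_oplsda(X, labels, n_orthogonal = 0, n_predictive = 2)
  Y <- stats::model.matrix(~ labels - 1)
  oracle <- mixOmics::pls(X, Y, ncomp = 2, scale = FALSE, mode = "regression")
  pred_oracle <- predict(oracle, X)$predict[, , 2]
  pred_mine <- as.matrix(predict_class(model, X)[, model$classes])
  expect_lt(max(abs(pred_mine - pred_oracle)), 1e-8)
})

test_that("dummy Y columns sum to their class sizes", {
  labels <- factor(c("A", "A", "B", "C", "C", "C"))
  Y <- stats::model.matrix(~ labels - 1)
  expect_equal(unname(colSums(Y)), c(2, 1, 3))
})

test_that("training predictions on separable data respect the 0.35/0.65 rule", {
  co <- small_cohort(seed = 10)
  pp <- preprocess_cohort(co$expression)
  panel <- select_markers(pp, co$truth)
  X <- t(pp$values[panel_genes(panel), ])
  model <- fit_oplsda(X, co$truth)
  calls <- predict_class(model, X)
  correct <- mean(calls$call == as.character(co$truth))
  expect_gte(correct, 0.95)
  expect_lt(mean(calls$call == "intermediate"), 0.10)
})

test_that("predictive R2Y does not decrease with more orthogonal components", {
  co <- small_cohort(seed = 12)
  pp <- preprocess_cohort(co$expression)
  panel <- select_markers(pp, co$truth)
  X <- t(pp$values[panel_genes(panel), ])
  Y <- stats::model.matrix(~ factor(co$truth) - 1)
  Yc <- sweep(Y, 2, colMeans(Y))
  r2y <- vapply(0:2, function(q) {
    m <- fit_oplsda(X, co$truth, n_orthogonal = q)
    1 - sum((Yc - scale(m$fitted, scale = FALSE))^2) / sum(Yc^2)
  }, numeric(1))
  expect_true(all(diff(r2y) >= -1e-8))
})

test_that("the threshold rule maps predicted vectors to the documented calls", {
  classes <- c("A", "B", "C")
  expect_equal(class_call(c(0.9, 0.05, 0.05), classes)$call, "A")
  expect_equal(class_call(c(0.5, 0.5, 0.0), classes)$call, "intermediate")
  expect_equal(class_call(c(0.2, 0.2, 0.2), classes)$call, "unassigned")
  # two classes above the upper threshold: intermediate, flagged
  res <- class_call(c(0.7, 0.7, 0.0), classes)
  expect_equal(res$call, "intermediate")
  expect_match(res$note, "multiple")
  # exactly one above but another not below the lower threshold
  expect_equal(class_call(c(0.7, 0.4, 0.1), classes)$call, "intermediate")
})

test_that("constant marker columns are dropped with a warning", {
  set.seed(4)
  X <- cbind(matrix(rnorm(40), 20), const = rep(1, 20))
  colnames(X) <- c("g1", "g2", "gc")
  labels <- rep(c("A", "B"), each = 10)
  expect_warning(m <- fit_oplsda(X, labels, n_orthogonal = 0),
                 "constant")
  expect_false("gc" %in% m$genes)
})

test_that("prediction errors when too many marker genes are missing", {
  co <- small_cohort(seed = 10)
  pp <- preprocess_cohort(co$expression)
  panel <- select_markers(pp, co$truth, n_top = 10)
  X <- t(pp$values[panel_genes(panel), ])
  model <- fit_oplsda(X, co$truth, n_orthogonal = 0)
  n_half <- floor(ncol(X) / 2)
  expect_error(predict_class(model, X[, seq_len(n_half)]), "missing")
  # a single missing gene below the tolerance is imputed with a warning
  expect_warning(
    out <- predict_class(model, X[, -1], max_missing = 0.1),
    "imputed")
  expect_equal(nrow(out), nrow(X))
})

test_that("external validation recovers planted frequencies in a second batch", {
  co <- small_cohort(seed = 10)
  pp <- preprocess_cohort(co$expression)
  panel <- select_markers(pp, co$truth)
  X <- t(pp$values[panel_genes(panel), ])
  model <- fit_oplsda(X, co$truth)

  co2 <- small_cohort(seed = 77)
  pp2 <- preprocess_cohort(co2$expression)
  val <- external_validation(model, panel, pp2)
  planted <- as.vector(table(co2$truth)) / length(co2$truth)
  # binomial error at n=72: 3 standard errors per class
  se <- sqrt(planted * (1 - planted) / length(co2$truth))
  expect_true(all(abs(val$frequencies - planted) <= 3 * se + 0.02))
  # each subtype's marker block stays coherent (positively rank-correlated)
  expect_true(all(val$marker_correlation > 0.3))
})

test_that("validation on the training cohort reproduces training frequencies", {
  co <- small_cohort(seed = 10)
  pp <- preprocess_cohort(co$expression)
  panel <- select_markers(pp, co$truth)
  X <- t(pp$values[panel_genes(panel), ])
  model <- fit_oplsda(X, co$truth)
  calls_train <- predict_class(model, X)$call
  val <- external_validation(model, panel, pp)
  expect_equal(unname(val$frequencies),
               as.vector(table(factor(calls_train,
                                      model$classes))) / nrow(X))
})
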