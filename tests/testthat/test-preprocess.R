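test_that("probe filter keeps a probe iff it clears 2x mean background somewhere", {
  # 10-probe toy, enumerated by brute force against the rule
  set.seed(1)
  bg1 <- c(100, 120)          # cohort 1 mean background 110 -> threshold 220
  bg2 <- c(80, 80, 110)       # cohort 2 mean background 90  -> threshold 180
  v1 <- matrix(150, 10, 2)
  v2 <- matrix(150, 10, 3)
  probes <- paste0("p", 1:10)
  rownames(v1) <- rownames(v2) <- probes
  v1[1, 1] <- 500             # passes in cohort 1 only
  v2[2, 3] <- 300             # passes in cohort 2 only
  v1[3, ] <- c(250, 400)      # passes in cohort 1
  v2[3, ] <- 500              # and cohort 2
  v1[4, 2] <- 220             # exactly at threshold: NOT above
  a <- raw_cohort(v1, bg1, "c1")
  b <- raw_cohort(v2, bg2, "c2")

  brute <- probes[apply(cbind(v1 > 2 * mean(bg1), v2 > 2 * mean(bg2)), 1, any)]
  out <- filter_probes(list(a, b))
  expect_setequal(out[[1]]$probe_ids, brute)
  expect_setequal(out[[2]]$probe_ids, brute)
  expect_true(all(c("p1", "p2", "p3") %in% out[[1]]$probe_ids))
  expect_false("p4" %in% out[[1]]$probe_ids)

  expect_error(filter_probes(raw_cohort(v1, NULL)), "background")
})

test_that("per-sample background mode compares each sample to its own level", {
  v <- matrix(c(150, 150,
                250, 150), 2, 2, byrow = TRUE)
  rownames(v) <- c("p1", "p2")
  x <- raw_cohort(v, background = c(100, 1000))
  # cohort-mean background = 550 -> nothing passes
  expect_equal(nrow(filter_probes(x)$values), 0)
  # per-sample: sample 1 threshold 200 -> p2 passes there
  out <- filter_probes(x, per_sample_background = TRUE)
  expect_equal(out$probe_ids, "p2")
})

test_that("quantile normalization forces identical column order statistics", {
  m <- cbind(c(1, 3), c(2, 4))
  expect_equal(unname(quantile_normalize(m)), cbind(c(1.5, 3.5), c(1.5, 3.5)))

  same <- matrix(rep(c(5, 1, 3), 4), 3)
  expect_equal(quantile_normalize(same), same)

  set.seed(2)
  r <- matrix(rnorm(20), 5, 4)
  qn <- quantile_normalize(r)
  sorted <- apply(qn, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  # idempotent
  expect_equal(quantile_normalize(qn), qn, tolerance = 1e-12)
  # rank order within each column is preserved
  expect_equal(apply(qn, 2, rank), apply(r, 2, rank))

  r[2, 2] <- NA
  expect_error(quantile_normalize(r), "missing")
  expect_error(quantile_normalize(matrix(1:3, 3, 1)), ">= 2 samples")
})

test_that("per-cohort centering zeroes probe means and removes planted offsets", {
  expect_equal(unname(center_probes(matrix(c(1, 2, 3), 1))),
               matrix(c(-1, 0, 1), 1))
  expect_equal(unname(center_probes(matrix(5, 1, 4))), matrix(0, 1, 4))

  set.seed(3)
  base <- matrix(rnorm(50 * 8), 50, 8)
  offsets <- rnorm(50, sd = 3)
  batch2 <- base[, 5:8] + offsets
  x <- expression_matrix(cbind(base[, 1:4], batch2),
                         cohort = rep(c("b1", "b2"), each = 4))
  cx <- center_probes(x)
  for (co in c("b1", "b2")) {
    expect_lt(max(abs(rowMeans(cx$values[, cx$cohort == co]))), 1e-12)
  }
  # planted offsets are unrecoverable: centered batches differ only as the
  # centered base data do
  manual <- cbind(base[, 1:4] - rowMeans(base[, 1:4]),
                  base[, 5:8] - rowMeans(base[, 5:8]))
  expect_equal(unname(cx$values), manual, tolerance = 1e-12)
})

test_that("probe collapse keeps the highest-median probe per gene", {
  v <- matrix(c(5, 5, 5,
                7, 7, 7), 2, 3, byrow = TRUE)
  x <- expression_matrix(v, probe_ids = c("pA", "pB"),
                         gene_symbols = c("G1", "G1"))
  out <- collapse_probes(x)
  expect_equal(out$probe_ids, "pB")
  expect_equal(rownames(out$values), "G1")

  # 12-probe/5-gene toy vs brute-force per-gene argmax with tie-break
  set.seed(4)
  v <- matrix(rnorm(12 * 6, 8), 12, 6)
  v[7, ] <- v[8, ]  # exact tie within gene g4 -> lexicographically smaller probe
  probes <- sprintf("pr%02d", 1:12)
  genes <- c("g1", "g1", "g1", "g2", "g2", "g3", "g4", "g4", "g5", "g5",
             "g5", NA)
  x <- expression_matrix(v, probe_ids = probes, gene_symbols = genes)
  expect_message(out <- collapse_probes(x), "1 probes without")
  meds <- apply(v, 1, median)
  brute <- vapply(unique(na.omit(genes)), function(g) {
    idx <- which(!is.na(genes) & genes == g)
    idx <- idx[order(-meds[idx], probes[idx])]
    probes[idx[1]]
  }, character(1))
  expect_equal(sort(out$probe_ids), sort(unname(brute)))
  expect_equal(nrow(out$values), 5)
})

test_that("cohort merging inner-joins genes and median-scales when asked", {
  mk <- function(genes, vals, cohort) {
    expression_matrix(matrix(vals, length(genes), 3), probe_ids = genes,
                      gene_symbols = genes, cohort = cohort,
                      log_scale = FALSE)
  }
  a <- mk(c("g1", "g2", "g3", "g4"), 1:12, "c1")
  b <- mk(c("g2", "g3", "g4", "g5"), 13:24, "c2")
  m <- merge_cohorts(a, b)
  expect_equal(sort(rownames(m$values)), c("g2", "g3", "g4"))
  expect_equal(ncol(m$values), 6)

  disjoint <- mk(c("h1", "h2", "h3", "h4"), 1:12, "c2")
  expect_error(merge_cohorts(a, disjoint), "no shared genes")

  # identical cohort merged with itself in median mode: all medians become 1
  a2 <- mk(c("g1", "g2", "g3", "g4"), abs(rnorm(12)) + 1, "c1")
  m2 <- merge_cohorts(a2, a2, mode = "median_scale")
  meds <- apply(m2$values[, m2$cohort == levels(m2$cohort)[1]], 1, median)
  expect_equal(unname(meds), rep(1, 4))
})

test_that("preprocess_cohort removes batch structure from generator output", {
  co <- small_cohort(seed = 11)
  pp <- preprocess_cohort(co$expression)
  for (b in levels(pp$cohort)) {
    expect_lt(max(abs(rowMeans(pp$values[, pp$cohort == b]))), 1e-10)
  }
  expect_equal(nrow(pp$values), 300)
})
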