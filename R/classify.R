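#' Select subtype marker panels by rank test and fold change
#'
#' For each subtype, every gene is tested one-vs-rest with a two-sided
#' Mann-Whitney U test (exact p-values for small groups without ties, normal
#' approximation with tie correction otherwise, as `stats::wilcox.test`
#' provides). The fold change is the ratio of group medians on the linear
#' scale: log2 data are back-transformed before taking medians, so on centered
#' log2 data the fold change is `2^(median_subtype - median_rest)`. Only
#' up-regulated genes (fold change >= `fc_min`, subtype over rest) are
#' eligible; the `n_top` genes with the smallest p-values are kept, ties
#' broken by larger fold change then lexicographic gene ID.
#'
#' @param x an `ExpressionMatrix` (log2 values) or genes x samples matrix.
#' @param labels per-sample subtype labels (factor or vector).
#' @param n_top panel size per subtype (default 20).
#' @param fc_min minimum linear-scale median fold change (default 1.5).
#' @param log_scale whether the values are log2 (default taken from the
#'   object, `TRUE` for plain matrices).
#' @return an object of class `MarkerPanel`: a named list (one element per
#'   subtype) of data frames with columns `gene`, `p_value`,
#'   `median_fold_change`, sorted by ascending p; attribute `panel_size`.
#' @export
select_markers <- function(x, labels, n_top = 20, fc_min = 1.5,
                           log_scale = NULL) {
  values <- if (inherits(x, "ExpressionMatrix")) x$values else as.matrix(x)
  if (is.null(log_scale))
    log_scale <- if (inherits(x, "ExpressionMatrix")) x$log_scale else TRUE
  labels <- factor(labels)
  if (length(labels) != ncol(values))
    stop("labels length must equal the number of samples")
  if (any(table(labels) < 2))
    stop("every class needs at least 2 samples")
  genes <- rownames(values)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  linear <- if (log_scale) 2^values else values

  panels <- lapply(levels(labels), function(cls) {
    in_cls <- labels == cls
    p <- apply(values, 1, function(row) {
      suppressWarnings(
        stats::wilcox.test(row[in_cls], row[!in_cls])$p.value)
    })
    med_in <- apply(linear[, in_cls, drop = FALSE], 1, stats::median)
    med_out <- apply(linear[, !in_cls, drop = FALSE], 1, stats::median)
    fc <- med_in / med_out
    keep <- which(fc >= fc_min)
    ord <- keep[order(p[keep], -fc[keep], genes[keep])]
    sel <- utils::head(ord, n_top)
    data.frame(gene = genes[sel], p_value = unname(p[sel]),
               median_fold_change = unname(fc[sel]),
               stringsAsFactors = FALSE)
  })
  names(panels) <- levels(labels)
  structure(panels, class = c("MarkerPanel", "list"), panel_size = n_top)
}

#' Union of panel genes across subtypes
#' @param panel a [select_markers()] result.
#' @return character vector of unique marker genes.
#' @export
panel_genes <- function(panel) {
  unique(unlist(lapply(panel, `[[`, "gene"), use.names = FALSE))
}

# ---- OPLS-DA ---------------------------------------------------------------

# One multi-Y PLS component on centered X, Y: the weight vector is the
# dominant left singular vector of X'Y (the fixed point NIPALS iterates to),
# computed exactly by SVD.
pls_component <- function(X, Y) {
  w <- svd(crossprod(X, Y), nu = 1, nv = 0)$u[, 1]
  t <- as.numeric(X %*% w)
  ss_t <- sum(t^2)
  p <- as.numeric(crossprod(X, t)) / ss_t
  c_ <- as.numeric(crossprod(Y, t)) / ss_t
  list(w = as.numeric(w), t = t, p = p, c = c_)
}

# Plain multi-Y PLS (NIPALS, regression mode) with n_comp components.
fit_pls <- function(X, Y, n_comp) {
  n_var <- ncol(X)
  W <- P <- matrix(0, n_var, n_comp)
  C <- matrix(0, ncol(Y), n_comp)
  Tm <- matrix(0, nrow(X), n_comp)
  Xd <- X
  Yd <- Y
  for (a in seq_len(n_comp)) {
    cmp <- pls_component(Xd, Yd)
    W[, a] <- cmp$w
    P[, a] <- cmp$p
    C[, a] <- cmp$c
    Tm[, a] <- cmp$t
    Xd <- Xd - tcrossprod(cmp$t, cmp$p)
    Yd <- Yd - tcrossprod(cmp$t, cmp$c)
  }
  # regression coefficients: B = W (P'W)^-1 C'
  B <- W %*% solve(crossprod(P, W), t(C))
  list(W = W, P = P, C = C, scores = Tm, B = B)
}

#' Fit an OPLS-DA model for subtype classification
#'
#' Orthogonal projections to latent structures discriminant analysis: class
#' membership is dummy-coded as a zeros/ones matrix Y (one column per class).
#' Orthogonal components — systematic X variation uncorrelated with Y — are
#' extracted and removed first: each candidate PLS loading is deflated of its
#' projection onto the span of X'Y, normalized, and the resulting orthogonal
#' score is stripped from X. The predictive part is then an ordinary multi-Y
#' PLS regression on the filtered X with `n_predictive` components (default:
#' number of classes minus 1). The number of orthogonal components can be
#' fixed or chosen by sevenfold cross-validated Q2 over 0..`max_orthogonal`.
#'
#' Constant columns are dropped with a warning before fitting.
#'
#' @param X samples x genes matrix (marker panel columns), named columns.
#' @param labels per-sample class labels.
#' @param n_orthogonal `"auto"` (sevenfold CV) or a fixed count >= 0.
#' @param max_orthogonal cap for the automatic choice (default 3).
#' @param n_predictive number of predictive components.
#' @param thresholds lower/upper predicted-value cutoffs used at prediction
#'   time (defaults 0.35 and 0.65).
#' @return an object of class `OplsdaModel`.
#' @export
fit_oplsda <- function(X, labels, n_orthogonal = "auto", max_orthogonal = 3,
                       n_predictive = NULL,
                       thresholds = c(lower = 0.35, upper = 0.65)) {
  X <- as.matrix(X)
  labels <- factor(labels)
  if (nlevels(labels) < 2) stop("need at least 2 classes")
  if (nrow(X) != length(labels)) stop("X rows must match labels")
  stopifnot(thresholds[1] > 0, thresholds[1] < thresholds[2],
            thresholds[2] < 1)
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
  const <- apply(X, 2, function(v) max(v) - min(v) == 0)
  if (any(const)) {
    warning(sum(const), " constant columns dropped")
    X <- X[, !const, drop = FALSE]
  }
  Y <- stats::model.matrix(~ labels - 1)
  colnames(Y) <- levels(labels)
  if (is.null(n_predictive)) n_predictive <- nlevels(labels) - 1

  if (identical(n_orthogonal, "auto")) {
    q2 <- vapply(0:max_orthogonal, function(q) {
      oplsda_cv_q2(X, Y, q, n_predictive)
    }, numeric(1))
    n_orthogonal <- (0:max_orthogonal)[which.max(q2)]
  }

  x_center <- colMeans(X)
  y_center <- colMeans(Y)
  Xc <- sweep(X, 2, x_center)
  Yc <- sweep(Y, 2, y_center)
  core <- oplsda_core(Xc, Yc, n_orthogonal, n_predictive)

  structure(
    list(x_center = x_center, y_center = y_center,
         genes = colnames(X), classes = levels(labels),
         n_orthogonal = n_orthogonal, n_predictive = n_predictive,
         W_ortho = core$W_o, P_ortho = core$P_o,
         pls = core$pls, thresholds = thresholds,
         fitted = core$fitted),
    class = "OplsdaModel"
  )
}

# Orthogonal filtering + predictive PLS on centered data.
oplsda_core <- function(Xc, Yc, n_orthogonal, n_predictive) {
  n_var <- ncol(Xc)
  # orthonormal basis of the Y-correlated weight space
  Wy <- crossprod(Xc, Yc)
  Wy <- qr.Q(qr(Wy))[, seq_len(qr(Wy)$rank), drop = FALSE]
  W_o <- P_o <- matrix(0, n_var, 0)
  Xf <- Xc
  q_used <- 0
  for (q in seq_len(n_orthogonal)) {
    cmp <- pls_component(Xf, Yc)
    w_o <- cmp$p - Wy %*% crossprod(Wy, cmp$p)
    nrm <- sqrt(sum(w_o^2))
    if (nrm < 1e-10) break
    w_o <- w_o / nrm
    t_o <- Xf %*% w_o
    p_o <- crossprod(Xf, t_o) / sum(t_o^2)
    W_o <- cbind(W_o, w_o)
    P_o <- cbind(P_o, p_o)
    Xf <- Xf - tcrossprod(t_o, as.numeric(p_o))
    q_used <- q
  }
  pls <- fit_pls(Xf, Yc, n_predictive)
  fitted <- Xf %*% pls$B
  list(W_o = W_o, P_o = P_o, pls = pls, fitted = fitted, n_ortho = q_used)
}

# Remove the model's orthogonal components from (centered) new data.
ortho_filter <- function(Xc, W_o, P_o) {
  if (ncol(W_o) == 0) return(Xc)
  for (q in seq_len(ncol(W_o))) {
    t_o <- Xc %*% W_o[, q]
    Xc <- Xc - tcrossprod(t_o, P_o[, q])
  }
  Xc
}

# Sevenfold sample-wise CV of predicted Y for a given orthogonal count.
oplsda_cv_q2 <- function(X, Y, n_orthogonal, n_predictive, n_folds = 7) {
  n <- nrow(X)
  folds <- rep_len(seq_len(n_folds), n)
  press <- 0
  for (f in seq_len(n_folds)) {
    test <- folds == f
    if (sum(!test) < 3) next
    xc <- colMeans(X[!test, , drop = FALSE])
    yc <- colMeans(Y[!test, , drop = FALSE])
    Xc <- sweep(X[!test, , drop = FALSE], 2, xc)
    Yc <- sweep(Y[!test, , drop = FALSE], 2, yc)
    core <- tryCatch(oplsda_core(Xc, Yc, n_orthogonal, n_predictive),
                     error = function(e) NULL)
    if (is.null(core)) return(-Inf)
    Xt <- sweep(X[test, , drop = FALSE], 2, xc)
    Xt <- ortho_filter(Xt, core$W_o, core$P_o)
    pred <- sweep(Xt %*% core$pls$B, 2, yc, `+`)
    press <- press + sum((Y[test, , drop = FALSE] - pred)^2)
  }
  ss <- sum(sweep(Y, 2, colMeans(Y))^2)
  1 - press / ss
}

#' @export
print.OplsdaModel <- function(x, ...) {
  cat(sprintf(
    "OplsdaModel: %d classes (%s), %d genes, %d predictive + %d orthogonal components\n",
    length(x$classes), paste(x$classes, collapse = "/"), length(x$genes),
    x$n_predictive, x$n_orthogonal))
  cat(sprintf("thresholds: <%.2f out, >%.2f in\n", x$thresholds[1],
              x$thresholds[2]))
  invisible(x)
}

#' Predict class membership from an OPLS-DA model
#'
#' New samples are centered with the training means, stripped of the model's
#' orthogonal components, and regressed onto the class-value space. A sample
#' is assigned to a class iff exactly one predicted value exceeds the upper
#' threshold and all others fall below the lower threshold; it is
#' `intermediate` when any value lies between the thresholds (or more than one
#' exceeds the upper threshold, flagged in `note`); `unassigned` when all
#' values fall below the lower threshold.
#'
#' @param model an `OplsdaModel`.
#' @param X_new samples x genes matrix; columns are matched to the training
#'   genes by name. Missing genes beyond `max_missing` (fraction) raise an
#'   error; below that they are mean-imputed (training mean) with a warning.
#' @param max_missing maximum tolerated fraction of missing marker genes.
#' @return a data frame with one row per sample: predicted value per class,
#'   `call` in {class levels, `"intermediate"`, `"unassigned"`}, and `note`.
#' @export
predict_class <- function(model, X_new, max_missing = 0.1) {
  stopifnot(inherits(model, "OplsdaModel"))
  X_new <- as.matrix(X_new)
  if (is.null(colnames(X_new)))
    stop("X_new must have gene names as column names")
  missing <- setdiff(model$genes, colnames(X_new))
  if (length(missing) / length(model$genes) > max_missing)
    stop(sprintf("%d of %d marker genes missing (> %.0f%% allowed)",
                 length(missing), length(model$genes), 100 * max_missing))
  X <- matrix(NA_real_, nrow(X_new), length(model$genes),
              dimnames = list(rownames(X_new), model$genes))
  present <- intersect(model$genes, colnames(X_new))
  X[, present] <- X_new[, present]
  if (length(missing)) {
    warning(length(missing), " marker genes missing; imputed at training mean")
    X[, missing] <- matrix(model$x_center[missing], nrow(X), length(missing),
                           byrow = TRUE)
  }
  Xc <- sweep(X, 2, model$x_center)
  Xf <- ortho_filter(Xc, model$W_ortho, model$P_ortho)
  pred <- sweep(Xf %*% model$pls$B, 2, model$y_center, `+`)
  colnames(pred) <- model$classes
  calls <- class_call(pred, model$classes, model$thresholds)
  out <- data.frame(pred, call = calls$call, note = calls$note,
                    stringsAsFactors = FALSE, check.names = FALSE)
  rownames(out) <- rownames(X_new)
  out
}

#' Apply the predicted-value threshold rule
#'
#' A sample belongs to a class iff exactly one predicted class value exceeds
#' the upper threshold and every other value is below the lower threshold; a
#' value between the thresholds makes the sample `intermediate` (as does more
#' than one value above the upper threshold, which is additionally flagged);
#' all values below the lower threshold give `unassigned`.
#'
#' @param pred samples x classes matrix of predicted class values.
#' @param classes class names (defaults to `colnames(pred)`).
#' @param thresholds length-2 numeric, lower and upper cutoffs (defaults 0.35
#'   and 0.65).
#' @return list with character vectors `call` and `note`.
#' @export
class_call <- function(pred, classes = colnames(pred),
                       thresholds = c(lower = 0.35, upper = 0.65)) {
  pred <- rbind(pred)
  lo <- thresholds[1]
  hi <- thresholds[2]
  call <- character(nrow(pred))
  note <- character(nrow(pred))
  for (i in seq_len(nrow(pred))) {
    v <- pred[i, ]
    above <- v > hi
    below <- v < lo
    if (sum(above) == 1 && sum(below) == length(v) - 1) {
      call[i] <- classes[which(above)]
    } else if (sum(above) >= 2) {
      call[i] <- "intermediate"
      note[i] <- "multiple classes above upper threshold"
    } else if (all(below)) {
      call[i] <- "unassigned"
    } else {
      call[i] <- "intermediate"
    }
  }
  list(call = call, note = note)
}

#' Validate the classifier on an external cohort
#'
#' Applies [predict_class()] to a preprocessed external cohort and reports the
#' predicted class frequencies, the fraction of intermediate/unassigned
#' samples, and — as a marker-coherence check — the mean pairwise Spearman
#' correlation among each subtype's panel genes within the new cohort
#' (coherent marker blocks stay strongly positively correlated in an
#' independent cohort that contains the subtypes).
#'
#' @param model an `OplsdaModel`.
#' @param panel the `MarkerPanel` the model was trained on.
#' @param cohort an `ExpressionMatrix` (genes x samples, preprocessed and, if
#'   cross-platform, median-scaled) or samples x genes matrix.
#' @return list with `calls` (the [predict_class()] frame), `frequencies`
#'   (named fractions over assigned classes), `fraction_intermediate`,
#'   `fraction_unassigned`, and `marker_correlation` (named per subtype).
#' @export
external_validation <- function(model, panel, cohort) {
  X <- if (inherits(cohort, "ExpressionMatrix")) t(cohort$values)
       else as.matrix(cohort)
  calls <- predict_class(model, X)
  assigned <- calls$call %in% model$classes
  freq <- table(factor(calls$call[assigned], levels = model$classes))
  freq <- as.numeric(freq) / nrow(calls)
  names(freq) <- model$classes
  marker_cor <- vapply(names(panel), function(cls) {
    genes <- intersect(panel[[cls]]$gene, colnames(X))
    if (length(genes) < 2) return(NA_real_)
    cm <- stats::cor(X[, genes], method = "spearman")
    mean(cm[upper.tri(cm)])
  }, numeric(1))
  list(calls = calls, frequencies = freq,
       fraction_intermediate = mean(calls$call == "intermediate"),
       fraction_unassigned = mean(calls$call == "unassigned"),
       marker_correlation = marker_cor)
}
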