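#' Kaplan-Meier estimate with median survival
#'
#' Product-limit estimator (via `survival::survfit`) with cause-specific
#' censoring: deaths from other causes and subjects alive at follow-up enter
#' as censored. The median is the earliest time at which the estimated
#' survival drops to 0.5 or below, `NA` when the curve never reaches 0.5.
#'
#' @param time follow-up times (months from first ADT by convention), >= 0.
#' @param event 1 = event (prostate-cancer death), 0 = censored.
#' @return list with `time`, `surv`, `n_risk`, `n_event` (the step curve) and
#'   `median`.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop("negative follow-up times")
  if (length(time) != length(event)) stop("time/event length mismatch")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- suppressWarnings(min(fit$time[fit$surv <= 0.5]))
  if (!is.finite(med)) med <- NA_real_
  list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
       n_event = fit$n.event, median = med)
}

#' Log-rank test across groups
#'
#' Standard (unweighted) log-rank over pooled event times, two-group and
#' k-group forms, via `survival::survdiff`.
#'
#' @param time,event as in [km_estimate()].
#' @param group per-subject group labels (>= 2 non-empty groups).
#' @return list with `chisq`, `df`, `p_value`, and the observed/expected table.
#' @export
logrank_test <- function(time, event, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("need at least 2 non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1
  list(chisq = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Cox proportional hazards fit
#'
#' Partial-likelihood maximization with Breslow tie handling and Wald
#' confidence intervals. Non-convergence or quasi-separation (as signaled by
#' `survival::coxph`) is surfaced in the `flags` element rather than hidden.
#'
#' @param data data frame holding the model variables.
#' @param time_col,event_col column names of follow-up time and event
#'   indicator.
#' @param covariates character vector of covariate column names (e.g. the
#'   combinatory PSA/Ki67 group and Gleason score).
#' @param conf_level confidence level for the hazard-ratio intervals.
#' @return list with `hr` (data frame: term, hazard ratio, CI bounds, p) and
#'   `flags` (character vector of warnings, empty when clean), plus the
#'   underlying `coxph` fit.
#' @export
cox_fit <- function(data, time_col = "time_from_first_adt",
                    event_col = "event", covariates, conf_level = 0.95) {
  stopifnot(length(covariates) >= 1)
  n_events <- sum(data[[event_col]])
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(covariates, collapse = " + ")))
  flags <- character(0)
  fit <- withCallingHandlers(
    survival::coxph(fml, data = data, ties = "breslow"),
    warning = function(w) {
      flags <<- c(flags, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (n_events < length(stats::coef(fit)))
    flags <- c(flags, "fewer events than parameters")
  s <- summary(fit, conf.int = conf_level)
  hr <- data.frame(term = rownames(s$coefficients),
                   hr = s$conf.int[, "exp(coef)"],
                   lower = s$conf.int[, 3], upper = s$conf.int[, 4],
                   p_value = s$coefficients[, "Pr(>|z|)"],
                   row.names = NULL, stringsAsFactors = FALSE)
  list(hr = hr, flags = flags, fit = fit)
}

#' Group-comparison test battery
#'
#' The univariate toolkit the workflow uses on clinical variables: a
#' Kruskal-Wallis gate across all groups followed by pairwise two-sided
#' Mann-Whitney U tests (exact for small tie-free groups, normal approximation
#' with tie correction otherwise).
#'
#' @param values numeric vector.
#' @param groups group labels, same length.
#' @return list with `kruskal` (statistic, df, p) and `pairwise` (data frame
#'   of group pairs and Mann-Whitney p-values).
#' @export
compare_groups <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups)) stop("length mismatch")
  kw <- stats::kruskal.test(values, groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  pw <- data.frame(
    group1 = pairs[1, ], group2 = pairs[2, ],
    p_value = apply(pairs, 2, function(pr) {
      suppressWarnings(
        stats::wilcox.test(values[groups == pr[1]],
                           values[groups == pr[2]])$p.value)
    }),
    stringsAsFactors = FALSE)
  list(kruskal = list(statistic = unname(kw$statistic),
                      df = unname(kw$parameter), p_value = kw$p.value),
       pairwise = pw)
}

#' Paired Wilcoxon signed-rank test
#'
#' For paired observations (e.g. a marker scored in a metastasis and its
#' matched primary tumor).
#'
#' @param x,y paired numeric vectors of equal length.
#' @return list with `statistic` (V) and `p_value`.
#' @export
paired_wilcoxon <- function(x, y) {
  if (length(x) != length(y)) stop("paired test requires equal lengths")
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' Spearman rank correlation with p-value
#' @param x,y numeric vectors of equal length.
#' @return list with `rho` and `p_value`.
#' @export
spearman_cor <- function(x, y) {
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Chi-square test on a contingency table
#' @param tab a contingency table or matrix of counts.
#' @param correct continuity correction for 2x2 tables (default FALSE, plain
#'   Pearson chi-square).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
chisq_contingency <- function(tab, correct = FALSE) {
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}
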