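#' Immunoreactivity (IR) score
#'
#' The fraction of immunostained tumor epithelial cells is binned as
#' 0: 0%, 1: 1-25%, 2: 26-50%, 3: 51-75%, 4: 76-100%, and multiplied by the
#' staining intensity grade (0 negative, 1 weak, 2 moderate, 3 intense),
#' giving scores in 0-12. Vectorized; monotone non-decreasing in both
#' arguments.
#'
#' @param distribution_pct percentage of stained cells, in \[0, 100\].
#' @param intensity intensity grade in {0, 1, 2, 3}.
#' @return integer IR score(s) in 0-12.
#' @export
ir_score <- function(distribution_pct, intensity) {
  if (any(distribution_pct < 0 | distribution_pct > 100, na.rm = TRUE))
    stop("distribution_pct must be in [0, 100]")
  if (!all(intensity %in% 0:3 | is.na(intensity)))
    stop("intensity must be an integer in 0..3")
  bin <- findInterval(distribution_pct, c(0, 25, 50, 75), left.open = TRUE)
  as.integer(bin * intensity)
}

#' Combinatory PSA/Ki67 prognostic grouping
#'
#' Dichotomizes tissue PSA immunoreactivity at the cohort median (strictly
#' above = high; the median itself falls in the low group) and the Ki67
#' fraction at the cohort upper quartile (at or above = high), then crosses
#' the two into four groups. Cutoffs are computed within the supplied cohort
#' unless overridden, since they are cohort-specific by construction.
#'
#' @param psa_ir per-sample PSA IR scores (0-12).
#' @param ki67_pct per-sample Ki67 percentages.
#' @param cutoffs optional list with elements `psa` and `ki67` overriding the
#'   cohort-derived cutoffs.
#' @param quartile_type quantile estimator type for the Ki67 upper quartile
#'   (default 7, linear interpolation); group membership at the boundary can
#'   shift with this choice, so it is exposed.
#' @return a data frame with `psa_high`, `ki67_high` and `group` (factor with
#'   levels `highPSA_lowKi67`, `lowPSA_lowKi67`, `lowPSA_highKi67`,
#'   `highPSA_highKi67`); attributes `cutoffs` (the values used) and
#'   `frequencies` (group fractions). Degenerate all-identical inputs are
#'   flagged with a warning.
#' @export
combinatory_score <- function(psa_ir, ki67_pct, cutoffs = NULL,
                              quartile_type = 7) {
  if (length(psa_ir) != length(ki67_pct))
    stop("psa_ir and ki67_pct must have equal length")
  if (is.null(cutoffs)) {
    if (length(psa_ir) < 4)
      stop("need >= 4 samples to derive cohort cutoffs; supply `cutoffs`")
    cutoffs <- list(psa = stats::median(psa_ir, na.rm = TRUE),
                    ki67 = stats::quantile(ki67_pct, 0.75,
                                           type = quartile_type,
                                           na.rm = TRUE, names = FALSE))
  }
  if (length(unique(stats::na.omit(psa_ir))) == 1 ||
      length(unique(stats::na.omit(ki67_pct))) == 1)
    warning("degenerate cutoff: all values identical for at least one marker")
  psa_high <- psa_ir > cutoffs$psa     # strictly above median
  ki67_high <- ki67_pct >= cutoffs$ki67 # upper quartile inclusive
  group <- factor(
    ifelse(psa_high & !ki67_high, "highPSA_lowKi67",
    ifelse(!psa_high & !ki67_high, "lowPSA_lowKi67",
    ifelse(!psa_high & ki67_high, "lowPSA_highKi67", "highPSA_highKi67"))),
    levels = c("highPSA_lowKi67", "lowPSA_lowKi67", "lowPSA_highKi67",
               "highPSA_highKi67"))
  out <- data.frame(psa_high = psa_high, ki67_high = ki67_high, group = group)
  attr(out, "cutoffs") <- cutoffs
  attr(out, "frequencies") <- prop.table(table(group))
  out
}
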