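#' Configuration for the synthetic bone-metastasis cohort generator
#'
#' The generator emulates the statistical structure the workflow assumes in
#' real cohorts: two bead-array batches of log2-scale expression carrying three
#' planted molecular subtypes (a luminal/AR-driven majority subtype A, a
#' high-proliferation subtype B, a stroma/EMT subtype C), each with its own
#' up-regulated marker block; additive per-probe batch offsets that per-cohort
#' probe centering removes exactly; subtype-dependent exponential survival;
#' and tissue PSA/Ki67 immunoreactivity that is negatively rank-correlated at
#' cohort level (low PSA and high Ki67 in subtype B).
#'
#' @param n_samples number of samples in the cohort.
#' @param subtype_proportions length-3 vector of subtype fractions (A, B, C);
#'   must sum to 1. Defaults to the 71/17/12 percent composition typical of
#'   bone-metastasis series. Subtype counts are fixed by largest-remainder
#'   rounding so the planted composition is exact, not multinomial.
#' @param n_genes number of genes simulated.
#' @param n_markers_per_subtype size of each subtype's up-regulated marker
#'   block; `3 * n_markers_per_subtype` must not exceed `n_genes`.
#' @param marker_effect log2 shift added to a subtype's marker block in that
#'   subtype's samples. The default (4x the noise SD) gives well-separated
#'   subtypes that unsupervised discovery recovers essentially perfectly.
#' @param noise_sd residual log2-scale standard deviation per measurement.
#' @param n_batches number of batches (cohorts) the samples are split into,
#'   round-robin within subtype so batches are balanced.
#' @param batch_shift_sd SD of the additive per-probe, per-batch offset.
#' @param survival_medians length-3 vector of median cancer-specific survival
#'   (months from first androgen-deprivation therapy) per subtype. Defaults
#'   (49, 25, 43) reflect the poor prognosis of subtype B.
#' @param censor_rate fraction of subjects censored (uniformly before their
#'   event time); 0 means every event is observed.
#' @param ihc_params list of immunohistochemistry parameters, see
#'   [default_ihc_params()].
#' @param seed integer seed; all generator output is reproducible given the
#'   config.
#'
#' @return an object of class `SynthConfig` (a validated list).
#' @export
synth_config <- function(n_samples = 72,
                         subtype_proportions = c(0.71, 0.17, 0.12),
                         n_genes = 1000,
                         n_markers_per_subtype = 40,
                         marker_effect = 4,
                         noise_sd = 1,
                         n_batches = 2,
                         batch_shift_sd = 1,
                         survival_medians = c(49, 25, 43),
                         censor_rate = 0.25,
                         ihc_params = default_ihc_params(),
                         seed = 1L) {
  stopifnot(length(subtype_proportions) == 3, length(survival_medians) == 3)
  if (abs(sum(subtype_proportions) - 1) > 1e-9)
    stop("subtype_proportions must sum to 1")
  if (any(subtype_proportions < 0)) stop("subtype_proportions must be >= 0")
  counts <- c(n_samples = n_samples, n_genes = n_genes,
              n_markers_per_subtype = n_markers_per_subtype,
              n_batches = n_batches)
  if (any(counts <= 0) || any(counts != round(counts)))
    stop("counts must be positive integers")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  if (batch_shift_sd < 0) stop("batch_shift_sd must be >= 0")
  if (marker_effect < 0) stop("marker_effect must be >= 0")
  if (3 * n_markers_per_subtype > n_genes)
    stop("3 * n_markers_per_subtype exceeds n_genes: invalid config")
  if (any(survival_medians <= 0)) stop("survival_medians must be > 0")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  structure(
    list(n_samples = as.integer(n_samples),
         subtype_proportions = subtype_proportions,
         n_genes = as.integer(n_genes),
         n_markers_per_subtype = as.integer(n_markers_per_subtype),
         marker_effect = marker_effect, noise_sd = noise_sd,
         n_batches = as.integer(n_batches), batch_shift_sd = batch_shift_sd,
         survival_medians = survival_medians, censor_rate = censor_rate,
         ihc_params = ihc_params, seed = as.integer(seed)),
    class = "SynthConfig"
  )
}

#' Default immunohistochemistry simulation parameters
#'
#' PSA immunoreactivity and the Ki67 proliferation fraction are driven by a
#' pair of latent normals coupled through a Gaussian copula, plus
#' subtype-specific location shifts (PSA lower and Ki67 higher in subtype B).
#' The staining intensity grade (0-3) is obtained by thresholding the PSA
#' latent, matching the ordinal 4-level scale pathologists use. `latent_rho`
#' is the residual (within-subtype) latent correlation; its default was
#' calibrated by simulation so that, together with the between-subtype shifts,
#' the cohort-level Spearman correlation between the PSA IR score and Ki67
#' is close to the configured `target_spearman` of -0.32.
#'
#' @param psa_mu per-subtype mean of the PSA latent normal.
#' @param psa_sd SD of the PSA latent normal.
#' @param intensity_breaks 3 increasing thresholds on the intensity latent
#'   cutting it into grades 0,1,2,3.
#' @param ki67_median per-subtype median Ki67 percentage.
#' @param ki67_log_sd SD of log(Ki67).
#' @param latent_rho residual latent correlation between the PSA and Ki67
#'   latents within subtype.
#' @param target_spearman cohort-level Spearman(PSA IR, Ki67) the defaults are
#'   calibrated to (kept for documentation/validation; not used directly).
#' @param chromogranin_mean per-subtype mean chromogranin-A percentage of an
#'   exponential; most samples are near zero.
#' @return a named list of parameters.
#' @export
default_ihc_params <- function(psa_mu = c(0.9, -1.5, -0.2),
                               psa_sd = 1,
                               intensity_breaks = c(-1.7, -0.7, 0.4),
                               ki67_median = c(14, 33, 12),
                               ki67_log_sd = 0.55,
                               latent_rho = -0.12,
                               target_spearman = -0.32,
                               chromogranin_mean = c(0.15, 0.8, 0.1)) {
  list(psa_mu = psa_mu, psa_sd = psa_sd, intensity_breaks = intensity_breaks,
       ki67_median = ki67_median, ki67_log_sd = ki67_log_sd,
       latent_rho = latent_rho, target_spearman = target_spearman,
       chromogranin_mean = chromogranin_mean)
}

# Largest-remainder rounding of n * proportions to integer counts summing to n.
allocate_counts <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Generate a synthetic expression matrix with planted subtypes
#'
#' Produces a log2-scale genes x samples matrix: per-gene baselines drawn from
#' N(8, 1.5) (typical bead-array log2 intensities), three disjoint marker
#' blocks each shifted up by `marker_effect` in its own subtype's samples,
#' additive per-probe batch offsets drawn from N(0, `batch_shift_sd`), and
#' i.i.d. N(0, `noise_sd`) measurement noise.
#'
#' @param config a [synth_config()].
#' @return a list with elements `expression` (an [expression_matrix()] whose
#'   cohort label is the batch), `truth` (factor of planted subtypes A/B/C per
#'   sample), and `marker_blocks` (named list of the three planted marker gene
#'   sets, usable as a gene-set collection for enrichment tests).
#' @export
generate_expression <- function(config) {
  stopifnot(inherits(config, "SynthConfig"))
  set.seed(config$seed)
  n <- config$n_samples
  p <- config$n_genes
  m <- config$n_markers_per_subtype

  counts <- allocate_counts(n, config$subtype_proportions)
  truth <- factor(rep(c("A", "B", "C"), counts), levels = c("A", "B", "C"))
  # balanced batches: round-robin within subtype, then shuffle sample order
  batch <- unlist(lapply(counts, function(k) {
    rep_len(seq_len(config$n_batches), k)
  }))
  ord <- sample.int(n)
  truth <- truth[ord]
  batch <- batch[ord]

  genes <- sprintf("GENE%04d", seq_len(p))
  probes <- sprintf("ILMN_%06d", seq_len(p))
  samples <- sprintf("S%03d", seq_len(n))

  baseline <- stats::rnorm(p, mean = 8, sd = 1.5)
  values <- matrix(baseline, nrow = p, ncol = n) +
    matrix(stats::rnorm(p * n, sd = config$noise_sd), nrow = p)

  blocks <- list(A = genes[seq_len(m)],
                 B = genes[m + seq_len(m)],
                 C = genes[2 * m + seq_len(m)])
  for (s in c("A", "B", "C")) {
    rows <- match(blocks[[s]], genes)
    cols <- which(truth == s)
    values[rows, cols] <- values[rows, cols] + config$marker_effect
  }

  if (config$batch_shift_sd > 0) {
    offsets <- matrix(stats::rnorm(p * config$n_batches,
                                   sd = config$batch_shift_sd), nrow = p)
    values <- values + offsets[, batch]
  }

  expr <- expression_matrix(values, probe_ids = probes, gene_symbols = genes,
                            sample_ids = samples,
                            cohort = paste0("batch", batch), log_scale = TRUE)
  list(expression = expr, truth = stats::setNames(truth, samples),
       marker_blocks = blocks)
}

#' Generate synthetic clinical and immunohistochemistry records
#'
#' Survival times are exponential with subtype-specific medians; censoring
#' times are independent exponentials with the rate set so each subject is
#' censored with probability `censor_rate` (censored records are split evenly
#' between death-by-other-cause and alive-at-follow-up for bookkeeping). PSA/Ki67 immunoreactivity is
#' simulated through the Gaussian copula described in [default_ihc_params()],
#' giving a negative cohort-level rank correlation with low tissue PSA and
#' high Ki67 in subtype B. Serum PSA is log-normal with subtype-specific
#' medians (lower in B); Gleason score is drawn from {7, 8, 9}.
#'
#' @param config a [synth_config()].
#' @param truth_labels factor of planted subtypes, as returned by
#'   [generate_expression()].
#' @return a `data.frame` with one row per sample: `sample_id`, `subtype`,
#'   `time_from_first_adt` (months), `event` (1 = prostate-cancer death, 0 =
#'   censored), `event_type`, `serum_psa` (ng/mL), `gleason_score`, `age`,
#'   `psa_distribution_pct`, `psa_intensity` (0-3), `psa_ir` (0-12),
#'   `ki67_pct`, `chromogranin_pct`.
#' @export
generate_clinical <- function(config, truth_labels) {
  stopifnot(inherits(config, "SynthConfig"))
  truth_labels <- factor(truth_labels, levels = c("A", "B", "C"))
  n <- length(truth_labels)
  set.seed(config$seed + 1L)
  idx <- as.integer(truth_labels)

  rate <- log(2) / config$survival_medians[idx]
  t_event <- stats::rexp(n, rate = rate)
  # independent exponential censoring with P(censored) = censor_rate:
  # for T ~ Exp(l) and C ~ Exp(m) independent, P(C < T) = m / (l + m)
  if (config$censor_rate > 0) {
    rate_c <- rate * config$censor_rate / (1 - config$censor_rate)
    t_cens <- stats::rexp(n, rate = rate_c)
  } else {
    t_cens <- rep(Inf, n)
  }
  censored <- t_cens < t_event
  time <- pmin(t_event, t_cens)
  event <- as.integer(!censored)
  event_type <- ifelse(!censored, "pc_death",
                       ifelse(stats::runif(n) < 0.5, "other_death_censored",
                              "alive_censored"))

  ip <- config$ihc_params
  e1 <- stats::rnorm(n)
  e2 <- ip$latent_rho * e1 + sqrt(1 - ip$latent_rho^2) * stats::rnorm(n)
  z_psa <- ip$psa_mu[idx] + ip$psa_sd * e1
  ki67 <- pmin(100, exp(log(ip$ki67_median[idx]) + ip$ki67_log_sd * e2))
  dist_pct <- 100 * stats::plogis(z_psa)
  z_int <- z_psa + 0.3 * stats::rnorm(n)
  intensity <- findInterval(z_int, ip$intensity_breaks)
  chroma <- stats::rexp(n, rate = 1 / ip$chromogranin_mean[idx])

  serum_median <- c(160, 45, 81)[idx]
  serum_psa <- exp(log(serum_median) + stats::rnorm(n, sd = 1))
  gleason <- sample(c(7L, 8L, 9L), n, replace = TRUE)
  age <- round(stats::rnorm(n, mean = 72, sd = 6))

  data.frame(
    sample_id = names(truth_labels) %||% sprintf("S%03d", seq_len(n)),
    subtype = truth_labels,
    time_from_first_adt = time,
    event = event,
    event_type = event_type,
    serum_psa = serum_psa,
    gleason_score = gleason,
    age = age,
    psa_distribution_pct = dist_pct,
    psa_intensity = intensity,
    psa_ir = ir_score(dist_pct, intensity),
    ki67_pct = ki67,
    chromogranin_pct = chroma,
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a complete synthetic cohort
#'
#' Convenience wrapper running [generate_expression()] and
#' [generate_clinical()] from one config.
#'
#' @param config a [synth_config()].
#' @return a list of class `SynthCohort` with elements `expression`, `truth`,
#'   `marker_blocks`, `clinical`, `config`.
#' @export
generate_cohort <- function(config = synth_config()) {
  ex <- generate_expression(config)
  clin <- generate_clinical(config, ex$truth)
  structure(list(expression = ex$expression, truth = ex$truth,
                 marker_blocks = ex$marker_blocks, clinical = clin,
                 config = config),
            class = "SynthCohort")
}

#' Write a synthetic cohort to TSV files
#'
#' Writes `expression.tsv` (first column gene ID), `clinical.tsv`, and
#' `truth_labels.tsv` (sample_id, subtype) into a directory.
#'
#' @param cohort a `SynthCohort` from [generate_cohort()].
#' @param dir output directory, created if needed.
#' @return the directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "SynthCohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression_tsv(cohort$expression, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(cohort$truth), subtype = cohort$truth),
    file.path(dir, "truth_labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
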