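#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the statistical structure of the clinical validation
#' cohort the package's analyses are designed for: sPTB prevalence 7.3%, a
#' biomarker score with Pearson correlation -0.5 with GA at birth, dating
#' methods at the observed shares (49.5% LMP, 37.3% 1st-trimester
#' ultrasound, 11.0% early 2nd-trimester, 2.1% late 2nd-trimester, plus
#' 0.1% with no recorded method), blood draws across 18^0/7-20^6/7 weeks
#' (days 126-146), and a Gaussian score marginal placed so that roughly
#' 15% of subjects fall at or above the validated threshold of -1.37.
#'
#' @param n_subjects Number of subjects.
#' @param case_prevalence Target sPTB case fraction, default 0.073.
#' @param target_score_gab_correlation Target Pearson correlation between
#'   score and true GA at birth, in `(-1, 0]`; default -0.5.
#' @param threshold Validated decision threshold carried for reference.
#' @param method_prevalences Named proportions over dating methods.
#' @param draw_window_days Inclusive blood-draw window `c(min, max)` in
#'   days.
#' @param score_mean,score_sd Marginal mean and SD of the score.
#' @param seed Integer seed.
#' @return A `cohort_gen_config` list.
#' @export
cohort_gen_config <- function(n_subjects,
                              case_prevalence = 0.073,
                              target_score_gab_correlation = -0.5,
                              threshold = -1.37,
                              method_prevalences = c(
                                LMP_ONLY = 0.495, US_T1 = 0.373,
                                US_T2_EARLY = 0.110, US_T2_LATE = 0.021,
                                UNKNOWN = 0.001),
                              draw_window_days = c(126L, 146L),
                              score_mean = -2.0, score_sd = 0.6,
                              seed = 1L) {
  if (abs(sum(method_prevalences) - 1) > 1e-9) {
    stop("'method_prevalences' must sum to 1", call. = FALSE)
  }
  if (is.null(names(method_prevalences)) ||
      !all(names(method_prevalences) %in% dating_methods())) {
    stop("'method_prevalences' must be named with valid dating methods",
         call. = FALSE)
  }
  if (case_prevalence <= 0 || case_prevalence >= 1) {
    stop("'case_prevalence' must be in (0, 1)", call. = FALSE)
  }
  if (target_score_gab_correlation > 0 ||
      target_score_gab_correlation <= -1) {
    stop("'target_score_gab_correlation' must be in (-1, 0]", call. = FALSE)
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 case_prevalence = case_prevalence,
                 target_score_gab_correlation = target_score_gab_correlation,
                 threshold = threshold,
                 method_prevalences = method_prevalences,
                 draw_window_days = as.integer(draw_window_days),
                 score_mean = score_mean, score_sd = score_sd,
                 seed = as.integer(seed)),
            class = "cohort_gen_config")
}

# Pearson correlation between a standard normal Z and the PMF quantile
# transform Q(Phi(Z)), by quadrature on a fine z grid. The copula is
# linear in the latent correlation, so the latent value that achieves a
# target output correlation is target / this constant.
copula_attenuation <- function(pmf) {
  z <- seq(-8, 8, length.out = 32001L)
  w <- stats::dnorm(z)
  w <- w / sum(w)
  g <- pmf_quantile(pmf, stats::pnorm(z))
  mu <- sum(w * g)
  sg <- sqrt(sum(w * (g - mu)^2))
  sum(w * z * (g - mu)) / sg
}

# Quantile function of a daily PMF (left-continuous inverse CDF).
pmf_quantile <- function(pmf, u) {
  cdf <- cumsum(pmf$probability)
  idx <- findInterval(u, cdf, left.open = TRUE) + 1L
  pmf$ga_days[pmin(idx, length(pmf$ga_days))]
}

#' Generate a synthetic case-control cohort with known ground truth
#'
#' Subjects are generated from a Gaussian copula: a latent standard
#' bivariate normal whose first coordinate is mapped through the
#' GA-at-birth PMF's quantile function to give the true GA at birth, and
#' whose second is scaled to the score marginal. The latent correlation is
#' calibrated (by a precomputed attenuation constant) so the OUTPUT
#' Pearson correlation between score and true GA hits the configured
#' target. The cohort is rejection-sampled to the configured case
#' prevalence: preterm (true GA < 259 d) draws fill the case quota,
#' term draws the control quota. Case labels derive from the TRUE GA; the
#' observed GA at birth adds each subject's dating-method error (method
#' drawn from the configured shares), so all-subject versus excluding-LMP
#' analyses see realistic label misclassification. Blood-draw GA is
#' uniform on the configured window; BMI is Gaussian (mean 28, SD 5.5,
#' clipped to 15-55).
#'
#' @param config A [cohort_gen_config()].
#' @param pmf A [daily_gab_pmf()]; defaults to the bundled synthetic
#'   distribution.
#' @param model A [dating_error_model()] for the observation noise.
#' @param unknown_sd Observation-noise SD for method `UNKNOWN`.
#' @return A cohort data frame with columns `subject_id`, `score`,
#'   `true_gab_days`, `gab_days` (observed), `gabd_days`, `method`,
#'   `is_case`, `bmi`.
#' @export
generate_cohort <- function(config, pmf = synthetic_ga_distribution(),
                            model = dating_error_model(),
                            unknown_sd = dating_sd(model, "US_T2_EARLY")) {
  stopifnot(inherits(config, "cohort_gen_config"),
            inherits(pmf, "daily_gab_pmf"))
  cutoff <- attr(pmf, "preterm_cutoff_days")
  pf <- preterm_fraction(pmf)
  if (pf <= 0 || pf >= 1) {
    stop("PMF is degenerate: cannot reach the target case prevalence",
         call. = FALSE)
  }
  n <- config$n_subjects
  n_cases <- round(n * config$case_prevalence)
  n_controls <- n - n_cases
  if (n_cases < 1L || n_controls < 1L) {
    stop("cohort too small for the target prevalence", call. = FALSE)
  }
  rho <- config$target_score_gab_correlation / copula_attenuation(pmf)
  if (!is.finite(rho) || abs(rho) > 1) {
    stop("target correlation unreachable for this GA distribution",
         call. = FALSE)
  }

  set.seed(config$seed)
  gab <- integer(0)
  score <- numeric(0)
  need <- function() {
    (n_cases - sum(gab < cutoff)) > 0L || (n_controls - sum(gab >= cutoff)) > 0L
  }
  while (need()) {
    m <- max(2L * n, 1000L)
    z1 <- stats::rnorm(m)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(m)
    g <- pmf_quantile(pmf, stats::pnorm(z1))
    s <- config$score_mean + config$score_sd * z2
    pre <- g < cutoff
    take_case <- which(pre)[seq_len(min(sum(pre),
                                        n_cases - sum(gab < cutoff)))]
    take_ctrl <- which(!pre)[seq_len(min(sum(!pre),
                                         n_controls - sum(gab >= cutoff)))]
    keep <- sort(c(take_case, take_ctrl))
    gab <- c(gab, g[keep])
    score <- c(score, s[keep])
  }
  ord <- sample.int(length(gab))  # shuffle cases and controls together
  gab <- gab[ord]; score <- score[ord]

  method <- sample(names(config$method_prevalences), n, replace = TRUE,
                   prob = config$method_prevalences)
  sds <- vapply(method, function(m) {
    if (m == "UNKNOWN") unknown_sd else dating_sd(model, m)
  }, numeric(1), USE.NAMES = FALSE)
  obs <- as.integer(round(gab + stats::rnorm(n, 0, sds)))
  gabd <- sample(seq.int(config$draw_window_days[1],
                         config$draw_window_days[2]), n, replace = TRUE)
  # a birth cannot be observed before the blood draw that enrolled it
  obs <- pmax(obs, gabd + 1L)
  bmi <- round(pmin(pmax(stats::rnorm(n, 28, 5.5), 15), 55), 1)
  out <- data.frame(subject_id = sprintf("S%05d", seq_len(n)),
                    score = score,
                    true_gab_days = as.integer(gab),
                    gab_days = obs,
                    gabd_days = as.integer(gabd),
                    method = method,
                    is_case = gab < cutoff,
                    bmi = bmi,
                    stringsAsFactors = FALSE)
  class(out) <- c("ptb_cohort", "data.frame")
  out
}

# Required schema for any cohort table.
cohort_required_columns <- function() {
  c("subject_id", "score", "gab_days", "gabd_days", "method", "is_case",
    "bmi")
}

#' Validate a cohort data frame
#'
#' Checks the cohort schema (`subject_id`, `score`, `gab_days`,
#' `gabd_days`, `method`, `is_case`, `bmi`), method names, and the
#' draw-before-birth ordering `gabd_days < gab_days`.
#'
#' @param cohort A data frame.
#' @return The validated cohort (invisibly classed `ptb_cohort`).
#' @export
validate_cohort <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  missing_cols <- setdiff(cohort_required_columns(), names(cohort))
  if (length(missing_cols)) {
    stop(sprintf("cohort is missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  bad <- which(!cohort$method %in% dating_methods())
  if (length(bad)) {
    stop(sprintf("invalid dating method '%s' in column 'method', row %d",
                 cohort$method[bad[1]], bad[1]), call. = FALSE)
  }
  bad <- which(cohort$gabd_days >= cohort$gab_days)
  if (length(bad)) {
    stop(sprintf("gabd_days >= gab_days in row %d", bad[1]), call. = FALSE)
  }
  if (!inherits(cohort, "ptb_cohort")) {
    class(cohort) <- c("ptb_cohort", class(cohort))
  }
  cohort
}

#' Write / read a cohort as CSV
#'
#' Round-trips all cohort fields through a plain CSV (schema:
#' `subject_id,score,gab_days,gabd_days,method,is_case,bmi`, plus
#' `true_gab_days` when the cohort carries ground truth).
#'
#' @param cohort A validated cohort.
#' @param file Path or connection.
#' @return `write_cohort` returns `file` invisibly; `read_cohort` returns
#'   the validated cohort.
#' @export
write_cohort <- function(cohort, file) {
  cohort <- validate_cohort(cohort)
  cols <- intersect(c(cohort_required_columns(), "true_gab_days"),
                    names(cohort))
  utils::write.csv(as.data.frame(cohort)[cols], file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  tab$is_case <- as.logical(tab$is_case)
  validate_cohort(tab)
}
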