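#' Threshold classification of predictor scores
#'
#' A subject is called higher-risk when the biomarker score is at or above
#' the threshold. The default threshold, -1.37 on the ln(IBP4/SHBG
#' response-ratio) scale, is the validated cut-point corresponding to 15%
#' sPTB risk. Scores exactly at the threshold are higher-risk.
#'
#' @param score Finite numeric scores.
#' @param threshold Decision threshold, default `-1.37`.
#' @return Logical vector of higher-risk calls.
#' @export
classify_at_threshold <- function(score, threshold = -1.37) {
  if (any(!is.finite(score))) {
    stop("'score' must be finite", call. = FALSE)
  }
  score >= threshold
}

# Wilson 95% score interval for x successes in n trials.
wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Sensitivity and specificity with Wilson confidence intervals
#'
#' @param calls Logical higher-risk calls.
#' @param labels Logical case labels; both classes must be present.
#' @param conf Confidence level, default 0.95.
#' @return List with `sensitivity`, `specificity`, their Wilson score CIs,
#'   and the 2x2 counts (`tp`, `fn`, `tn`, `fp`).
#' @export
sensitivity_specificity <- function(calls, labels, conf = 0.95) {
  calls <- as.logical(calls)
  labels <- as.logical(labels)
  stopifnot(length(calls) == length(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("both classes must be present to compute sensitivity/specificity",
         call. = FALSE)
  }
  tp <- sum(calls & labels)
  tn <- sum(!calls & !labels)
  list(sensitivity = tp / n1,
       specificity = tn / n0,
       se_ci = wilson_ci(tp, n1, conf),
       sp_ci = wilson_ci(tn, n0, conf),
       tp = tp, fn = n1 - tp, tn = tn, fp = n0 - tn)
}

#' Prevalence-anchored predictive values
#'
#' PPV and NPV computed from sensitivity, specificity and an externally
#' fixed disease prevalence — the appropriate form for a case-control
#' design, where the sample case mix does not estimate prevalence:
#' \deqn{PPV = \frac{se\,p}{se\,p + (1-sp)(1-p)}, \quad
#'       NPV = \frac{sp\,(1-p)}{sp\,(1-p) + (1-se)\,p}.}
#' Degenerate denominators (e.g. `se = 0` with `sp = 1`) are returned as
#' the 0/0 limit `NaN`.
#'
#' @param se,sp Sensitivity and specificity in `(0, 1)` (boundaries
#'   allowed).
#' @param prevalence Disease prevalence, default 0.073 (sPTB).
#' @return List with `ppv` and `npv`.
#' @examples
#' ppv_npv(0.75, 0.74, 0.073)  # ppv 0.18, npv 0.97
#' @export
ppv_npv <- function(se, sp, prevalence = 0.073) {
  stopifnot(se >= 0, se <= 1, sp >= 0, sp <= 1,
            prevalence > 0, prevalence < 1)
  p <- prevalence
  list(ppv = se * p / (se * p + (1 - sp) * (1 - p)),
       npv = sp * (1 - p) / (sp * (1 - p) + (1 - se) * p))
}

#' Case-control confidence intervals for PPV and NPV
#'
#' Propagates the binomial sampling variance of sensitivity (over
#' `n_cases`) and specificity (over `n_controls`) into the predictive
#' values by the delta method on the logit scale, holding prevalence fixed
#' — prevalence is a design constant in a case-control study, not an
#' estimate. Since `logit(PPV) = log(se p) - log((1-sp)(1-p))`,
#' `Var(logit PPV) = Var(se)/se^2 + Var(sp)/(1-sp)^2`, and symmetrically
#' for NPV. Zero cells are continuity-corrected by adding 0.5 (a note is
#' messaged).
#'
#' @param se,sp Sensitivity and specificity point estimates.
#' @param n_cases,n_controls Class sizes from which `se` and `sp` were
#'   estimated.
#' @param prevalence Fixed prevalence, default 0.073.
#' @param conf Confidence level, default 0.95.
#' @return List with `ppv_ci` and `npv_ci` (lower/upper vectors).
#' @export
ppv_npv_ci <- function(se, sp, n_cases, n_controls, prevalence = 0.073,
                       conf = 0.95) {
  stopifnot(n_cases > 0, n_controls > 0)
  tp <- se * n_cases; fn <- n_cases - tp
  tn <- sp * n_controls; fp <- n_controls - tn
  if (min(tp, fn, tn, fp) < 0.5) {
    message("zero or near-zero cell: applying 0.5 continuity correction ",
            "to PPV/NPV intervals")
    tp <- tp + 0.5; fn <- fn + 0.5; tn <- tn + 0.5; fp <- fp + 0.5
    se <- tp / (tp + fn); sp <- tn / (tn + fp)
  }
  n1 <- tp + fn; n0 <- tn + fp
  var_se <- se * (1 - se) / n1
  var_sp <- sp * (1 - sp) / n0
  z <- stats::qnorm(1 - (1 - conf) / 2)
  pv <- ppv_npv(se, sp, prevalence)
  lgt <- function(q) log(q / (1 - q))
  inv <- function(x) 1 / (1 + exp(-x))
  sd_lp <- sqrt(var_se / se^2 + var_sp / (1 - sp)^2)
  sd_ln <- sqrt(var_sp / sp^2 + var_se / (1 - se)^2)
  list(ppv_ci = c(lower = inv(lgt(pv$ppv) - z * sd_lp),
                  upper = inv(lgt(pv$ppv) + z * sd_lp)),
       npv_ci = c(lower = inv(lgt(pv$npv) - z * sd_ln),
                  upper = inv(lgt(pv$npv) + z * sd_ln)))
}

#' Pearson correlation between predictor score and GA at birth
#'
#' @param scores Numeric scores, non-constant, length >= 3.
#' @param gab_days GA at birth in days.
#' @return Product-moment correlation in `[-1, 1]`.
#' @export
pearson_r <- function(scores, gab_days) {
  if (length(scores) < 3L || length(scores) != length(gab_days)) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (stats::sd(scores) == 0 || stats::sd(gab_days) == 0) {
    stop("correlation undefined for a constant vector", call. = FALSE)
  }
  stats::cor(scores, gab_days)
}

#' Likelihood-ratio regression test of case classification
#'
#' Tests whether higher-risk calls are associated with case status by a
#' single-predictor logistic regression, comparing the fitted model to the
#' intercept-only model with a likelihood-ratio chi-square test on 1
#' degree of freedom. For a binary predictor this deviance difference
#' equals the G-statistic of the 2x2 table, which is used directly as a
#' closed form if the glm fit fails to converge (e.g. complete
#' separation).
#'
#' @param calls Logical higher-risk calls.
#' @param labels Logical case labels; both classes must be present.
#' @return Two-sided p-value.
#' @export
classification_regression_test <- function(calls, labels) {
  calls <- as.logical(calls)
  labels <- as.logical(labels)
  stopifnot(length(calls) == length(labels))
  if (all(labels) || !any(labels)) {
    stop("both classes must be present", call. = FALSE)
  }
  g <- if (all(calls) || !any(calls)) {
    0  # constant predictor carries no information
  } else {
    fit <- suppressWarnings(
      tryCatch(stats::glm(labels ~ calls, family = stats::binomial()),
               error = function(e) NULL))
    if (!is.null(fit) && fit$converged) {
      fit$null.deviance - fit$deviance
    } else {
      g_statistic_2x2(calls, labels)
    }
  }
  stats::pchisq(g, df = 1L, lower.tail = FALSE)
}

# G = 2*(l1 - l0) of the saturated 2x2 binomial fit vs intercept only.
g_statistic_2x2 <- function(calls, labels) {
  ll <- function(k, n) {
    p <- k / n
    sum(ifelse(c(k, n - k) > 0, c(k, n - k) * log(c(p, 1 - p)), 0))
  }
  n_pos <- sum(calls); n_neg <- sum(!calls)
  k_pos <- sum(labels & calls); k_neg <- sum(labels & !calls)
  l1 <- ll(k_pos, n_pos) + ll(k_neg, n_neg)
  l0 <- ll(k_pos + k_neg, n_pos + n_neg)
  2 * (l1 - l0)
}

#' Full performance report for a cohort at a threshold
#'
#' Evaluates the biomarker risk predictor on a case-control cohort at a
#' fixed threshold: sensitivity and specificity with Wilson 95% CIs, the
#' Mann-Whitney AUC of the continuous score with a DeLong CI, PPV and NPV
#' anchored to a fixed prevalence with case-control delta-method CIs, the
#' Pearson correlation between score and GA at birth, and the
#' likelihood-ratio test of the threshold classification.
#'
#' Optional filters mirror the study's subgroup analyses: a blood-draw
#' window in days, exclusion of directly LMP-dated subjects (the
#' excluding-LMP population keeps ultrasound-dated, confirmed-LMP and
#' method-unknown subjects), and restriction to the BMI stratum
#' (>22 to <=37 kg/m^2).
#'
#' @param cohort A cohort data frame (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param threshold Decision threshold, default -1.37.
#' @param prevalence Fixed sPTB prevalence, default 0.073.
#' @param window Optional blood-draw window `c(min_days, max_days)`,
#'   inclusive, applied to `gabd_days`.
#' @param exclude_lmp If `TRUE`, drop subjects with method `LMP_ONLY`.
#' @param bmi_stratified If `TRUE`, keep only subjects with BMI > 22 and
#'   <= 37.
#' @return A `performance_report` object.
#' @export
performance_report <- function(cohort, threshold = -1.37,
                               prevalence = 0.073, window = NULL,
                               exclude_lmp = FALSE, bmi_stratified = FALSE) {
  cohort <- validate_cohort(cohort)
  if (!is.null(window)) {
    cohort <- cohort[cohort$gabd_days >= window[1] &
                       cohort$gabd_days <= window[2], , drop = FALSE]
  }
  if (exclude_lmp) {
    cohort <- cohort[cohort$method != "LMP_ONLY", , drop = FALSE]
  }
  if (bmi_stratified) {
    cohort <- cohort[cohort$bmi > 22 & cohort$bmi <= 37, , drop = FALSE]
  }
  labels <- as.logical(cohort$is_case)
  if (nrow(cohort) < 3L || all(labels) || !any(labels)) {
    stop("filtered cohort must retain both cases and controls",
         call. = FALSE)
  }
  calls <- classify_at_threshold(cohort$score, threshold)
  ss <- sensitivity_specificity(calls, labels)
  pv <- ppv_npv(ss$sensitivity, ss$specificity, prevalence)
  pvci <- ppv_npv_ci(ss$sensitivity, ss$specificity,
                     n_cases = sum(labels), n_controls = sum(!labels),
                     prevalence = prevalence)
  auc <- auc_mann_whitney(cohort$score, labels)
  roc <- pROC::roc(response = labels, predictor = cohort$score,
                   direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
  auc_ci <- as.numeric(pROC::ci.auc(roc, method = "delong"))[c(1, 3)]
  structure(list(
    n_cases = sum(labels), n_controls = sum(!labels),
    threshold = threshold, prevalence = prevalence,
    sensitivity = ss$sensitivity, se_ci = ss$se_ci,
    specificity = ss$specificity, sp_ci = ss$sp_ci,
    auc = auc, auc_ci = c(lower = auc_ci[1], upper = auc_ci[2]),
    ppv = pv$ppv, ppv_ci = pvci$ppv_ci,
    npv = pv$npv, npv_ci = pvci$npv_ci,
    pearson_r = pearson_r(cohort$score, cohort$gab_days),
    regression_p = classification_regression_test(calls, labels)),
    class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  ci <- function(v) sprintf("(%.2f-%.2f)", v[1], v[2])
  cat(sprintf("Risk predictor performance at threshold %.2f (prevalence %.1f%%)\n",
              x$threshold, 100 * x$prevalence))
  cat(sprintf("  cases/controls: %d/%d\n", x$n_cases, x$n_controls))
  cat(sprintf("  sensitivity: %.2f %s\n", x$sensitivity, ci(x$se_ci)))
  cat(sprintf("  specificity: %.2f %s\n", x$specificity, ci(x$sp_ci)))
  cat(sprintf("  AUC:         %.2f %s\n", x$auc, ci(x$auc_ci)))
  cat(sprintf("  PPV:         %.2f %s\n", x$ppv, ci(x$ppv_ci)))
  cat(sprintf("  NPV:         %.2f %s\n", x$npv, ci(x$npv_ci)))
  cat(sprintf("  Pearson r (score vs GA at birth): %.2f\n", x$pearson_r))
  cat(sprintf("  classification regression p: %.3g\n", x$regression_p))
  invisible(x)
}

#' Compare two performance reports by CI containment
#'
#' Flags a metric as significantly different when either report's point
#' estimate lies outside the other's 95% confidence interval — the
#' mean-outside-comparator-interval rule. The rule is symmetric in its
#' arguments.
#'
#' @param a,b `performance_report` objects.
#' @return Data frame with columns `metric`, `estimate_a`, `estimate_b`,
#'   `significant`.
#' @export
compare_performance <- function(a, b) {
  stopifnot(inherits(a, "performance_report"),
            inherits(b, "performance_report"))
  metrics <- c(sensitivity = "se_ci", specificity = "sp_ci",
               auc = "auc_ci", ppv = "ppv_ci", npv = "npv_ci")
  out <- lapply(names(metrics), function(m) {
    ci_a <- a[[metrics[[m]]]]
    ci_b <- b[[metrics[[m]]]]
    pa <- a[[m]]; pb <- b[[m]]
    sig <- (pa < ci_b[1] || pa > ci_b[2]) || (pb < ci_a[1] || pb > ci_a[2])
    data.frame(metric = m, estimate_a = pa, estimate_b = pb,
               significant = sig)
  })
  do.call(rbind, out)
}

#' Baseline-table comparison of two cohorts
#'
#' Compares variables between two cohorts the way clinical baseline tables
#' do: two-sided Wilcoxon rank-sum tests for continuous variables (medians
#' and IQRs echoed) and two-sided Fisher's exact tests on the 2xK
#' group-by-level table for categorical variables (counts echoed). Empty
#' levels are dropped with a message. For 2x2 tables the sample odds ratio
#' `(a d)/(b c)` and Fisher's conditional-MLE odds ratio are both
#' reported.
#'
#' @param group_a,group_b Data frames holding the variables.
#' @param variables Named character vector mapping variable names to
#'   `"continuous"` or `"categorical"`.
#' @return Data frame with one row per variable: `variable`, `type`,
#'   `p_value`, `summary_a`, `summary_b`, `odds_ratio_sample`,
#'   `odds_ratio_cmle` (NA unless 2x2).
#' @export
cohort_compare <- function(group_a, group_b, variables) {
  stopifnot(is.character(variables), !is.null(names(variables)),
            all(variables %in% c("continuous", "categorical")))
  rows <- lapply(names(variables), function(v) {
    type <- variables[[v]]
    xa <- group_a[[v]]; xb <- group_b[[v]]
    if (is.null(xa) || is.null(xb)) {
      stop(sprintf("variable '%s' missing from a cohort", v), call. = FALSE)
    }
    or_s <- NA_real_; or_c <- NA_real_
    if (type == "continuous") {
      p <- stats::wilcox.test(xa, xb, exact = FALSE)$p.value
      fmt <- function(x) sprintf("%.1f (%.1f-%.1f)", stats::median(x),
                                 stats::quantile(x, .25),
                                 stats::quantile(x, .75))
      sa <- fmt(xa); sb <- fmt(xb)
    } else {
      lev <- union(unique(xa), unique(xb))
      ca <- table(factor(xa, levels = lev))
      cb <- table(factor(xb, levels = lev))
      keep <- (ca + cb) > 0
      if (!all(keep)) {
        message(sprintf("variable '%s': dropping empty level(s) %s", v,
                        paste(lev[!keep], collapse = ", ")))
      }
      tab <- rbind(ca[keep], cb[keep])
      ft <- stats::fisher.test(tab)
      p <- ft$p.value
      if (all(dim(tab) == 2L)) {
        or_s <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
        or_c <- unname(ft$estimate)
      }
      fmt <- function(cc) paste(sprintf("%s:%d", colnames(tab), cc),
                                collapse = " ")
      sa <- fmt(tab[1, ]); sb <- fmt(tab[2, ])
    }
    data.frame(variable = v, type = type, p_value = p,
               summary_a = sa, summary_b = sb,
               odds_ratio_sample = or_s, odds_ratio_cmle = or_c)
  })
  do.call(rbind, rows)
}
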