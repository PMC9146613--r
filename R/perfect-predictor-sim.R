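#' Perfect preterm-predictor scores
#'
#' A hypothetical predictor with complete knowledge of the true GA at
#' birth: score 1 (high risk) for births strictly below the cutoff, 0
#' otherwise. Evaluating it against outcome labels recomputed from
#' noise-corrupted GAs isolates the performance loss attributable purely to
#' dating uncertainty.
#'
#' @param true_gab_days Integer GA at birth in days (non-empty).
#' @param cutoff Preterm boundary in days, default 259 (37 weeks).
#' @return Integer vector of 0/1 risk scores.
#' @export
perfect_scores <- function(true_gab_days, cutoff = 259L) {
  if (length(true_gab_days) == 0L) {
    stop("'true_gab_days' must be non-empty", call. = FALSE)
  }
  as.integer(true_gab_days < cutoff)
}

#' Mann-Whitney AUC
#'
#' Area under the ROC curve computed as the probability that a randomly
#' chosen positive outranks a randomly chosen negative, with ties counted
#' half — the rank-sum (Mann-Whitney) estimator, identical to the
#' trapezoidal area under the empirical ROC curve.
#'
#' @param scores Numeric predictor scores.
#' @param labels Logical (or 0/1) outcome labels; both classes must be
#'   present.
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels) || anyNA(scores) || anyNA(labels)) {
    stop("'scores' and 'labels' must be complete and of equal length",
         call. = FALSE)
  }
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: both label classes must be present", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Configuration for the dating-uncertainty simulation
#'
#' Defaults reproduce the study conditions: random sets of 0.1% of a
#' national birth cohort (3.7 million singleton births, so about 3,700
#' subjects per set) drawn 20 times; half the subjects dated by LMP
#' confirmed by ultrasound, half by pure ultrasound with the first- /
#' early-second- / late-second-trimester shares 37.3 : 11.0 : 2.1
#' renormalised to the ultrasound half.
#'
#' @param sample_fraction Fraction of `total_births` per replicate.
#' @param n_replicates Number of replicates.
#' @param total_births Cohort scale for `sample_fraction`.
#' @param method_mixture Named proportions over dating methods, summing
#'   to 1.
#' @param preterm_cutoff_days Preterm boundary in days.
#' @param seed Integer seed for the whole simulation.
#' @return A `sim_config` list.
#' @export
sim_config <- function(sample_fraction = 0.001,
                       n_replicates = 20L,
                       total_births = 3700000L,
                       method_mixture = c(
                         LMP_CONFIRMED = 0.5,
                         US_T1 = 0.5 * 37.3 / 50.4,
                         US_T2_EARLY = 0.5 * 11.0 / 50.4,
                         US_T2_LATE = 0.5 * 2.1 / 50.4),
                       preterm_cutoff_days = 259L,
                       seed = 1L) {
  if (abs(sum(method_mixture) - 1) > 1e-9) {
    stop("'method_mixture' must sum to 1", call. = FALSE)
  }
  if (is.null(names(method_mixture)) ||
      !all(names(method_mixture) %in% dating_methods())) {
    stop("'method_mixture' must be named with valid dating methods",
         call. = FALSE)
  }
  if (n_replicates < 1L) stop("'n_replicates' must be >= 1", call. = FALSE)
  if (sample_fraction <= 0 || sample_fraction > 1) {
    stop("'sample_fraction' must be in (0, 1]", call. = FALSE)
  }
  structure(list(sample_fraction = sample_fraction,
                 n_replicates = as.integer(n_replicates),
                 total_births = as.integer(total_births),
                 method_mixture = method_mixture,
                 preterm_cutoff_days = as.integer(preterm_cutoff_days),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Degradation of a perfect preterm predictor under dating uncertainty
#'
#' For each replicate: draw true GAs at birth from `pmf`, assign each birth
#' a dating method from the configured mixture, corrupt the GA with the
#' method's zero-mean Gaussian dating error (rounded to whole days), and
#' evaluate the perfect predictor (scored on the TRUE GA) against preterm
#' labels recomputed from the NOISY GA. AUCs are reported per dating group:
#' confirmed-LMP (`"lmp"`) versus pooled ultrasound (`"excluding_lmp"`).
#' Any degradation below AUC 1 is attributable solely to outcome-label
#' misclassification caused by dating error.
#'
#' A replicate whose noisy labels collapse to a single class within a group
#' is excluded from that group's mean (the count of such exclusions is kept
#' in the result and messaged).
#'
#' @param pmf A [daily_gab_pmf()] GA-at-birth sampling prior.
#' @param model A [dating_error_model()].
#' @param config A [sim_config()].
#' @return A `dating_sim` object: `auc` (replicate, group, auc),
#'   `summary` (group, mean_auc, n_used), `p_value` (paired two-sided
#'   Wilcoxon signed-rank test of the per-replicate group AUCs),
#'   `roc_band` (fpr grid, group, lo, hi), `n_excluded`, `config`.
#' @export
run_dating_simulation <- function(pmf, model = dating_error_model(),
                                  config = sim_config()) {
  stopifnot(inherits(pmf, "daily_gab_pmf"),
            inherits(model, "dating_error_model"),
            inherits(config, "sim_config"))
  n_sub <- max(1L, round(config$sample_fraction * config$total_births))
  methods <- names(config$method_mixture)
  sds <- vapply(methods, function(m) dating_sd(model, m), numeric(1))
  cutoff <- config$preterm_cutoff_days
  groups <- ifelse(methods %in% c("LMP_ONLY", "LMP_CONFIRMED"),
                   "lmp", "excluding_lmp")

  set.seed(config$seed)
  auc_rows <- list()
  rocs <- list(lmp = list(), excluding_lmp = list())
  n_excluded <- c(lmp = 0L, excluding_lmp = 0L)
  for (rep in seq_len(config$n_replicates)) {
    gab <- sample_gab(pmf, n_sub)
    midx <- sample.int(length(methods), n_sub, replace = TRUE,
                       prob = config$method_mixture)
    obs <- round(gab + stats::rnorm(n_sub, 0, sds[midx]))
    score <- perfect_scores(gab, cutoff)
    label <- obs < cutoff
    grp <- groups[midx]
    for (g in c("lmp", "excluding_lmp")) {
      in_g <- grp == g
      if (!any(in_g)) next
      lab_g <- label[in_g]
      if (all(lab_g) || !any(lab_g)) {
        n_excluded[g] <- n_excluded[g] + 1L
        next
      }
      auc <- auc_mann_whitney(score[in_g], lab_g)
      auc_rows[[length(auc_rows) + 1L]] <-
        data.frame(replicate = rep, group = g, auc = auc)
      rocs[[g]][[length(rocs[[g]]) + 1L]] <-
        roc_points(score[in_g], lab_g)
    }
  }
  auc_tab <- do.call(rbind, auc_rows)
  summ <- aggregate(auc ~ group, data = auc_tab, FUN = mean)
  names(summ)[names(summ) == "auc"] <- "mean_auc"
  summ$n_used <- aggregate(auc ~ group, data = auc_tab, FUN = length)$auc

  p_value <- NA_real_
  wide <- merge(auc_tab[auc_tab$group == "lmp", c("replicate", "auc")],
                auc_tab[auc_tab$group == "excluding_lmp",
                        c("replicate", "auc")],
                by = "replicate", suffixes = c("_lmp", "_us"))
  if (nrow(wide) >= 2L && any(wide$auc_lmp != wide$auc_us)) {
    p_value <- stats::wilcox.test(wide$auc_lmp, wide$auc_us,
                                  paired = TRUE, exact = FALSE)$p.value
  }

  band <- do.call(rbind, lapply(c("lmp", "excluding_lmp"), function(g) {
    if (length(rocs[[g]]) < 2L) return(NULL)
    b <- roc_band(rocs[[g]])
    cbind(data.frame(group = g), b)
  }))
  if (any(n_excluded > 0L)) {
    message(sprintf(
      "replicates excluded for single-class noisy labels: lmp %d, excluding_lmp %d",
      n_excluded["lmp"], n_excluded["excluding_lmp"]))
  }
  structure(list(auc = auc_tab, summary = summ, p_value = p_value,
                 roc_band = band, n_excluded = n_excluded, config = config),
            class = "dating_sim")
}

#' @export
print.dating_sim <- function(x, ...) {
  cat("Perfect-predictor dating-uncertainty simulation\n")
  cat(sprintf("  %d replicates of %d subjects\n",
              x$config$n_replicates,
              max(1L, round(x$config$sample_fraction * x$config$total_births))))
  for (i in seq_len(nrow(x$summary))) {
    cat(sprintf("  mean AUC [%s]: %.3f (%d replicates)\n",
                x$summary$group[i], x$summary$mean_auc[i], x$summary$n_used[i]))
  }
  cat(sprintf("  paired group difference p-value: %.3g\n", x$p_value))
  invisible(x)
}

# Empirical ROC points (fpr, tpr) for a score/label vector, threshold swept
# from high to low; includes the (0,0) and (1,1) endpoints.
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(scores[labels] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!labels] >= t), numeric(1))
  data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
}

#' Pointwise ROC confidence band across replicates
#'
#' Interpolates each replicate's ROC curve onto a fixed 1-specificity grid
#' and returns the empirical 2.5th and 97.5th percentiles of sensitivity at
#' each grid point — the shaded 95% band around a family of simulated ROC
#' curves.
#'
#' @param per_replicate_rocs List (length >= 2) of data frames with columns
#'   `fpr`, `tpr` as returned by the simulation.
#' @param grid Grid of 1-specificity values, default `seq(0, 1, 0.01)`.
#' @return Data frame with columns `fpr`, `lo`, `hi`.
#' @export
roc_band <- function(per_replicate_rocs, grid = seq(0, 1, by = 0.01)) {
  if (length(per_replicate_rocs) < 2L) {
    stop("at least 2 replicate ROC curves are required", call. = FALSE)
  }
  sens <- vapply(per_replicate_rocs, function(rc) {
    stats::approx(rc$fpr, rc$tpr, xout = grid, ties = max, rule = 2)$y
  }, numeric(length(grid)))
  data.frame(fpr = grid,
             lo = apply(sens, 1L, stats::quantile, probs = 0.025,
                        names = FALSE),
             hi = apply(sens, 1L, stats::quantile, probs = 0.975,
                        names = FALSE))
}
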