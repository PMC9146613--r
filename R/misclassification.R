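#' Posterior probability that an observed preterm/term label is truly term
#'
#' Given an observed GA at birth (dated with Gaussian error of known SD)
#' and a population GA-at-birth prior, computes the posterior probability
#' that the TRUE GA is at or beyond the term cutoff:
#' \deqn{P(T \ge c \mid obs) = \frac{\sum_{t \ge c} \pi(t)\,
#'   \phi(obs - t; 0, sd)}{\sum_t \pi(t)\, \phi(obs - t; 0, sd)}}
#' with the sum over the prior's integer-day support. An SD of half a day
#' or less is treated as error-free dating: the posterior is the indicator
#' `obs >= cutoff`.
#'
#' @param obs_gab_days Observed GA at birth in days (vectorised).
#' @param sd_days Dating error SD in days (non-negative scalar).
#' @param prior A [daily_gab_pmf()] population prior.
#' @param cutoff Term boundary in days, default 259.
#' @return Posterior probabilities in `[0, 1]`, one per observation.
#' @export
posterior_true_term <- function(obs_gab_days, sd_days, prior,
                                cutoff = 259L) {
  stopifnot(inherits(prior, "daily_gab_pmf"), sd_days >= 0)
  t_days <- prior$ga_days
  pi_t <- prior$probability
  term <- t_days >= cutoff
  vapply(obs_gab_days, function(obs) {
    if (sd_days <= 0.5) {
      return(as.numeric(obs >= cutoff))
    }
    w <- pi_t * stats::dnorm(obs - t_days, mean = 0, sd = sd_days)
    tot <- sum(w)
    if (tot <= 0 || !is.finite(tot)) {
      stop(sprintf(
        "prior has no mass where the likelihood of obs = %s is non-negligible",
        obs), call. = FALSE)
    }
    sum(w[term]) / tot
  }, numeric(1))
}

#' Expected outcome-label misclassifications in a cohort
#'
#' Sums subject-level posterior probabilities of label error: over
#' sPTB-labelled subjects, the posterior probability of being truly term
#' (`expected_false_preterm`); over term-labelled subjects, the posterior
#' probability of being truly preterm (`expected_false_term`). Each
#' subject's dating SD comes from their dating method's error model;
#' subjects with method `UNKNOWN` fall back to `unknown_sd` (default: the
#' early-2nd-trimester ultrasound SD, since unrecorded methods are grouped
#' with the excluding-LMP population) with a message.
#'
#' @param cohort A cohort data frame (see [generate_cohort()]).
#' @param model A [dating_error_model()].
#' @param prior A [daily_gab_pmf()] population prior for true GA at birth.
#' @param cutoff Term boundary in days, default 259.
#' @param unknown_sd Fallback SD for method `UNKNOWN`, in days.
#' @return A `misclass_estimate`: `expected_false_preterm`,
#'   `expected_false_term`, their nearest-integer roundings, and
#'   `per_subject` (subject_id, method, sd_days, posterior probability of
#'   being truly term).
#' @export
expected_misclassified <- function(cohort, model = dating_error_model(),
                                   prior, cutoff = 259L,
                                   unknown_sd = dating_sd(model, "US_T2_EARLY")) {
  cohort <- validate_cohort(cohort)
  stopifnot(inherits(model, "dating_error_model"))
  sds <- vapply(cohort$method, function(m) {
    if (m == "UNKNOWN") NA_real_ else dating_sd(model, m)
  }, numeric(1), USE.NAMES = FALSE)
  if (anyNA(sds)) {
    message(sprintf(
      "%d subject(s) with UNKNOWN dating method: using fallback sd %.1f d",
      sum(is.na(sds)), unknown_sd))
    sds[is.na(sds)] <- unknown_sd
  }
  post_term <- numeric(nrow(cohort))
  for (s in unique(sds)) {
    i <- sds == s
    post_term[i] <- posterior_true_term(cohort$gab_days[i], s, prior, cutoff)
  }
  is_case <- as.logical(cohort$is_case)
  efp <- sum(post_term[is_case])
  eft <- sum(1 - post_term[!is_case])
  structure(list(
    expected_false_preterm = efp,
    expected_false_term = eft,
    expected_false_preterm_rounded = round(efp),
    expected_false_term_rounded = round(eft),
    per_subject = data.frame(subject_id = cohort$subject_id,
                             method = cohort$method,
                             sd_days = sds,
                             posterior_term = post_term)),
    class = "misclass_estimate")
}

#' @export
print.misclass_estimate <- function(x, ...) {
  cat("Expected outcome-label misclassifications\n")
  cat(sprintf("  sPTB-labelled births likely term:    %.2f (~%d)\n",
              x$expected_false_preterm, x$expected_false_preterm_rounded))
  cat(sprintf("  term-labelled births likely preterm: %.2f (~%d)\n",
              x$expected_false_term, x$expected_false_term_rounded))
  invisible(x)
}
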