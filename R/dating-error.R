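#' Gestational age dating methods
#'
#' The closed set of GA dating methods handled by the package: dating by
#' last menstrual period alone (`LMP_ONLY`), LMP confirmed by an ultrasound
#' date within tolerance (`LMP_CONFIRMED`), ultrasound dating by trimester
#' window (`US_T1`, `US_T2_EARLY` for 14^0/7–20^0/7 weeks, `US_T2_LATE` for
#' 20^1/7–27^6/7 weeks, `US_T3`), and `UNKNOWN` for subjects with no recorded
#' method. Downstream analyses group `UNKNOWN` with the excluding-LMP
#' (not directly LMP-dated) population.
#'
#' @return Character vector of valid method names.
#' @export
dating_methods <- function() {
  c("LMP_ONLY", "LMP_CONFIRMED", "US_T1", "US_T2_EARLY", "US_T2_LATE",
    "US_T3", "UNKNOWN")
}

#' LMP-confirmation tolerances by ultrasound window
#'
#' Maximum absolute difference, in days, between an LMP-derived and an
#' ultrasound-derived due date for the LMP date to be retained
#' ("confirmed"). The comparison is strict: a difference exactly equal to
#' the tolerance falls to the ultrasound method.
#'
#' @return Named numeric vector of tolerances in days for `US_T1`,
#'   `US_T2_EARLY`, `US_T2_LATE` and `US_T3`.
#' @export
confirmation_tolerances <- function() {
  c(US_T1 = 7, US_T2_EARLY = 10, US_T2_LATE = 14, US_T3 = 21)
}

#' Convert a 95% confidence-interval half-width to a Gaussian SD
#'
#' GA dating guidelines state method accuracy as the half-width of a 95%
#' confidence interval. Treating that half-width as a two-standard-deviation
#' interval gives `sd = halfwidth / 2`.
#'
#' @param halfwidth_days Positive half-width in days.
#' @return Standard deviation in days.
#' @examples
#' sd_from_halfwidth(7)   # first-trimester ultrasound -> 3.5
#' sd_from_halfwidth(29)  # known LMP -> 14.5
#' @export
sd_from_halfwidth <- function(halfwidth_days) {
  if (!is.numeric(halfwidth_days) || any(!is.finite(halfwidth_days)) ||
      any(halfwidth_days <= 0)) {
    stop("'halfwidth_days' must be a positive finite number", call. = FALSE)
  }
  halfwidth_days / 2
}

#' Gaussian error model for GA dating methods
#'
#' Builds the per-method dating error model used throughout the package:
#' each method carries the half-width of a 95% confidence interval for its
#' due-date error and the implied Gaussian standard deviation
#' (`sd = halfwidth / 2`). Defaults follow obstetric guideline values:
#' 7 d for 1st-trimester ultrasound, 10 d for early 2nd-trimester, 14 d for
#' late 2nd-trimester, 21 d for 3rd-trimester, 29 d for a known LMP date and
#' 14 d for an LMP date confirmed by ultrasound. The 53 d interval reported
#' for uncertain LMP recall can be supplied via `halfwidths` but is not part
#' of the default model.
#'
#' @param halfwidths Named numeric vector mapping method names (see
#'   [dating_methods()]) to 95% CI half-widths in days. Entries replace the
#'   defaults; a method may be given half-width 0 to model error-free dating.
#' @return A `dating_error_model`: data frame with columns `method`,
#'   `ci95_halfwidth_days`, `sd_days`.
#' @examples
#' dating_error_model()
#' dating_error_model(c(LMP_ONLY = 53))  # uncertain LMP recall
#' @export
dating_error_model <- function(halfwidths = NULL) {
  hw <- c(US_T1 = 7, US_T2_EARLY = 10, US_T2_LATE = 14, US_T3 = 21,
          LMP_ONLY = 29, LMP_CONFIRMED = 14)
  if (!is.null(halfwidths)) {
    if (is.null(names(halfwidths)) ||
        !all(names(halfwidths) %in% dating_methods())) {
      stop("'halfwidths' must be named with valid dating methods",
           call. = FALSE)
    }
    if (any(!is.finite(halfwidths)) || any(halfwidths < 0)) {
      stop("'halfwidths' must be finite and non-negative", call. = FALSE)
    }
    hw[names(halfwidths)] <- halfwidths
  }
  out <- data.frame(method = names(hw),
                    ci95_halfwidth_days = unname(hw),
                    sd_days = unname(hw) / 2,
                    stringsAsFactors = FALSE)
  class(out) <- c("dating_error_model", "data.frame")
  out
}

#' Look up the dating error SD for a method
#'
#' @param model A [dating_error_model()].
#' @param method A single method name.
#' @return SD in days.
#' @export
dating_sd <- function(model, method) {
  stopifnot(inherits(model, "dating_error_model"), length(method) == 1L)
  i <- match(method, model$method)
  if (is.na(i)) {
    stop(sprintf("no dating error SD configured for method '%s'", method),
         call. = FALSE)
  }
  model$sd_days[i]
}

#' Select the dating method for a subject
#'
#' Applies the protocol rule for establishing the estimated due date (EDD):
#' ultrasound is preferred, and LMP is retained only when no ultrasound is
#' available (`LMP_ONLY`) or when the LMP-derived EDD lies strictly within
#' the confirmation tolerance of the ultrasound EDD (`LMP_CONFIRMED`):
#' under 7 d of a 1st-trimester date, 10 d of an early 2nd-trimester date,
#' 14 d of a late 2nd-trimester date, or 21 d of a 3rd-trimester date. A
#' difference exactly at the tolerance resolves to the ultrasound method.
#'
#' @param lmp_edd LMP-derived EDD (`Date` or numeric day), or `NULL`.
#' @param us_edd Ultrasound-derived EDD (`Date` or numeric day), or `NULL`.
#' @param us_window Ultrasound window, one of `"US_T1"`, `"US_T2_EARLY"`,
#'   `"US_T2_LATE"`, `"US_T3"`; required iff `us_edd` is given.
#' @param tolerances Named tolerances in days, default
#'   [confirmation_tolerances()].
#' @return A single method name.
#' @export
select_dating_method <- function(lmp_edd = NULL, us_edd = NULL,
                                 us_window = NULL,
                                 tolerances = confirmation_tolerances()) {
  if (is.null(lmp_edd) && is.null(us_edd)) {
    stop("at least one of 'lmp_edd' and 'us_edd' must be given",
         call. = FALSE)
  }
  if (is.null(us_edd)) {
    if (!is.null(us_window)) {
      stop("'us_window' given without 'us_edd'", call. = FALSE)
    }
    return("LMP_ONLY")
  }
  if (is.null(us_window) || !us_window %in% names(tolerances)) {
    stop("'us_window' must name an ultrasound window with a tolerance",
         call. = FALSE)
  }
  if (is.null(lmp_edd)) {
    return(us_window)
  }
  diff_days <- abs(as.numeric(lmp_edd) - as.numeric(us_edd))
  if (diff_days < tolerances[[us_window]]) "LMP_CONFIRMED" else us_window
}

#' Draw dating errors for a method
#'
#' Zero-mean Gaussian due-date errors with the method's configured SD.
#'
#' @param model A [dating_error_model()].
#' @param method A single method name present in the model.
#' @param n Number of draws.
#' @param seed Optional integer seed for reproducibility.
#' @return Numeric vector of `n` day offsets.
#' @export
sample_dating_error <- function(model, method, n, seed = NULL) {
  sd <- dating_sd(model, method)
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  stats::rnorm(n, mean = 0, sd = sd)
}

#' Acceptance probability and conditional SD of confirmed LMP dates
#'
#' Under independent zero-mean Gaussian errors for the LMP-derived date
#' (X, SD `lmp_sd`) and the ultrasound date (Y, SD `us_sd`), an LMP date is
#' confirmed when `|X - Y| < tolerance`. This computes the confirmation
#' probability `P(|X - Y| < tolerance)` and the standard deviation of the
#' LMP error among confirmed dates, `SD(X | |X - Y| < tolerance)` — the
#' effective dating error of the confirmed-LMP population. With the
#' guideline defaults (LMP SD 14.5 d, 2nd-trimester ultrasound SD 5 d,
#' tolerance 10 d) about half of LMP dates are confirmed and the confirmed
#' dates retain a two-SD interval of 14 days.
#'
#' Two modes are provided: `"monte-carlo"` draws `n_draws` error pairs;
#' `"quadrature"` evaluates the same quantities deterministically by
#' one-dimensional adaptive quadrature over the LMP error, using the
#' Gaussian CDF of the ultrasound error in closed form.
#'
#' @param lmp_sd,us_sd Positive SDs in days.
#' @param tolerance Positive confirmation tolerance in days.
#' @param mode `"monte-carlo"` (default) or `"quadrature"`.
#' @param n_draws Monte Carlo sample size; below 1e4 a warning about
#'   estimate instability is raised.
#' @param seed Optional seed for the Monte Carlo mode.
#' @return List with `accept_probability`, `conditional_sd`, `mode`, and
#'   (Monte Carlo) `n_draws`, `n_accepted`.
#' @examples
#' confirmed_lmp_stats(14.5, 5, 10, mode = "quadrature")
#' @export
confirmed_lmp_stats <- function(lmp_sd, us_sd, tolerance,
                                mode = c("monte-carlo", "quadrature"),
                                n_draws = 1e6, seed = NULL) {
  stopifnot(lmp_sd > 0, us_sd > 0, tolerance > 0)
  mode <- match.arg(mode)
  if (mode == "monte-carlo") {
    if (n_draws < 1e4) {
      warning("n_draws < 1e4: confirmed-LMP estimates may be unstable",
              call. = FALSE)
    }
    if (!is.null(seed)) set.seed(seed)
    x <- stats::rnorm(n_draws, 0, lmp_sd)
    y <- stats::rnorm(n_draws, 0, us_sd)
    keep <- abs(x - y) < tolerance
    list(accept_probability = mean(keep),
         conditional_sd = stats::sd(x[keep]),
         mode = mode, n_draws = n_draws, n_accepted = sum(keep))
  } else {
    # P(accept | X = x) in closed form; outer integral over x by quadrature
    w <- function(x) {
      stats::pnorm((x + tolerance) / us_sd) -
        stats::pnorm((x - tolerance) / us_sd)
    }
    accept <- stats::integrate(function(x) stats::dnorm(x, 0, lmp_sd) * w(x),
                               -Inf, Inf, rel.tol = 1e-10)$value
    # E[X | accept] = 0 by symmetry, so Var = E[X^2 | accept]
    ex2 <- stats::integrate(function(x) x^2 * stats::dnorm(x, 0, lmp_sd) * w(x),
                            -Inf, Inf, rel.tol = 1e-10)$value / accept
    list(accept_probability = accept,
         conditional_sd = sqrt(ex2),
         mode = mode)
  }
}
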