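#' Weekly gestational-age-at-birth counts
#'
#' Validated container for a week-resolution GA-at-birth count table, the
#' input to [interpolate_to_days()]. Weeks are completed weeks of gestation
#' (vital-statistics convention: week w covers days `7w` to `7w + 6`).
#'
#' @param week Integer vector of completed gestational weeks, strictly
#'   increasing.
#' @param count Non-negative birth counts (real; zero rows are retained).
#' @return A `weekly_gab_counts` data frame with columns `week`, `count`.
#' @seealso [read_weekly_counts()], [synthetic_ga_distribution()]
#' @export
weekly_gab_counts <- function(week, count) {
  if (length(week) != length(count)) {
    stop("'week' and 'count' must have equal length", call. = FALSE)
  }
  if (length(week) < 3L) {
    stop("at least 3 weekly entries are required", call. = FALSE)
  }
  if (any(!is.finite(week)) || any(week != as.integer(week))) {
    stop("'week' must be finite integers", call. = FALSE)
  }
  if (any(diff(week) <= 0)) {
    stop("'week' must be strictly increasing (no duplicates)", call. = FALSE)
  }
  if (any(!is.finite(count)) || any(count < 0)) {
    bad <- which(!is.finite(count) | count < 0)[1L]
    stop(sprintf("negative or non-finite count in row %d (week %s)",
                 bad, week[bad]), call. = FALSE)
  }
  if (sum(count) <= 0) {
    stop("total count must be positive", call. = FALSE)
  }
  out <- data.frame(week = as.integer(week), count = as.numeric(count))
  class(out) <- c("weekly_gab_counts", "data.frame")
  out
}

#' Read a weekly GA-at-birth count table from CSV
#'
#' Expects a two-column table with header `week,count`.
#'
#' @param file Path or connection.
#' @return A [weekly_gab_counts()] object.
#' @export
read_weekly_counts <- function(file) {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  if (!all(c("week", "count") %in% names(tab))) {
    stop("weekly count table must have columns 'week' and 'count'",
         call. = FALSE)
  }
  if (!is.numeric(tab$week) || !is.numeric(tab$count)) {
    bad <- which(is.na(suppressWarnings(as.numeric(tab$week))) |
                   is.na(suppressWarnings(as.numeric(tab$count))))[1L]
    stop(sprintf("malformed weekly count table at row %s",
                 if (length(bad)) bad else "?"), call. = FALSE)
  }
  if (anyDuplicated(tab$week)) {
    stop(sprintf("duplicate week in row %d", anyDuplicated(tab$week)),
         call. = FALSE)
  }
  tab <- tab[order(tab$week), , drop = FALSE]
  weekly_gab_counts(tab$week, tab$count)
}

#' The bundled synthetic GA-at-birth distribution
#'
#' A synthetic week-resolution approximation of the U.S. 2019 singleton
#' GA-at-birth distribution (preterm mass about 8.6%, modal week 39),
#' shipped as a plain-text fixture so that every simulation in the package
#' runs without any data download. It is synthetic: constructed to match
#' published marginal shares (preterm, late-preterm, early-term, modal
#' week), not an extract of the national natality file.
#'
#' @param as_pmf If `TRUE` (default) return the day-resolution PMF from
#'   [interpolate_to_days()]; otherwise the weekly count table.
#' @return A `daily_gab_pmf` or `weekly_gab_counts` object.
#' @export
synthetic_ga_distribution <- function(as_pmf = TRUE) {
  path <- system.file("extdata", "ga_weekly_synthetic.csv",
                      package = "gadating", mustWork = TRUE)
  weekly <- read_weekly_counts(path)
  if (as_pmf) interpolate_to_days(weekly) else weekly
}

#' Interpolate a weekly GA-at-birth table to a daily PMF
#'
#' Converts week-resolution counts to a day-resolution probability mass
#' function by spline interpolation. The cumulative distribution is
#' interpolated with a monotone shape-preserving cubic spline (Hyman
#' filtering) at the week boundaries and differenced to daily masses; this
#' guarantees non-negative masses and reproduces each input week's total
#' share exactly. Any residual negative daily mass (numerically possible
#' only through rounding) is clipped to zero and the PMF renormalised;
#' clipping of more than 1% of total mass signals pathological input and is
#' an error.
#'
#' @param weekly A [weekly_gab_counts()] object.
#' @param preterm_cutoff_days Preterm boundary in days, default `259`
#'   (37 completed weeks).
#' @return A `daily_gab_pmf` data frame with columns `ga_days`,
#'   `probability` over days `min_week*7` to `(max_week+1)*7 - 1`, and a
#'   `preterm_cutoff_days` attribute.
#' @export
interpolate_to_days <- function(weekly, preterm_cutoff_days = 259L) {
  stopifnot(inherits(weekly, "weekly_gab_counts"))
  prop <- weekly$count / sum(weekly$count)
  # CDF knots at week starts; weekly mass occupies [7w, 7(w+1))
  knots_x <- c(weekly$week * 7, (max(weekly$week) + 1L) * 7)
  knots_y <- c(0, cumsum(prop))
  cdf <- stats::splinefun(knots_x, knots_y, method = "hyman")
  days <- seq.int(min(knots_x), max(knots_x) - 1L)
  mass <- cdf(days + 1) - cdf(days)
  neg <- -sum(mass[mass < 0])
  if (neg > 0.01) {
    stop("interpolation produced more than 1% negative mass; ",
         "check the weekly table", call. = FALSE)
  }
  mass <- pmax(mass, 0)
  mass <- mass / sum(mass)
  daily_gab_pmf(days, mass, preterm_cutoff_days = preterm_cutoff_days)
}

#' Day-resolution GA-at-birth PMF
#'
#' @param ga_days Strictly increasing, contiguous integer GA in days.
#' @param probability Non-negative masses summing to 1 (within 1e-9).
#' @param preterm_cutoff_days Preterm boundary in days, default 259.
#' @return A `daily_gab_pmf` data frame.
#' @export
daily_gab_pmf <- function(ga_days, probability, preterm_cutoff_days = 259L) {
  if (length(ga_days) != length(probability)) {
    stop("'ga_days' and 'probability' must have equal length", call. = FALSE)
  }
  if (any(diff(ga_days) != 1L)) {
    stop("'ga_days' must be strictly increasing and contiguous",
         call. = FALSE)
  }
  if (any(probability < 0)) {
    stop("probabilities must be non-negative", call. = FALSE)
  }
  if (abs(sum(probability) - 1) > 1e-9) {
    stop("probabilities must sum to 1 (within 1e-9)", call. = FALSE)
  }
  out <- data.frame(ga_days = as.integer(ga_days),
                    probability = as.numeric(probability))
  attr(out, "preterm_cutoff_days") <- as.integer(preterm_cutoff_days)
  class(out) <- c("daily_gab_pmf", "data.frame")
  out
}

#' Write / read a daily GA-at-birth PMF as CSV
#'
#' Plain CSV with header `ga_days,probability`.
#'
#' @param pmf A [daily_gab_pmf()].
#' @param file Path or connection.
#' @param preterm_cutoff_days Cutoff used when reading, default 259.
#' @return `write_daily_pmf` returns `file` invisibly; `read_daily_pmf`
#'   returns a `daily_gab_pmf`.
#' @export
write_daily_pmf <- function(pmf, file) {
  stopifnot(inherits(pmf, "daily_gab_pmf"))
  utils::write.csv(as.data.frame(pmf)[c("ga_days", "probability")], file,
                   row.names = FALSE)
  invisible(file)
}

#' @rdname write_daily_pmf
#' @export
read_daily_pmf <- function(file, preterm_cutoff_days = 259L) {
  tab <- utils::read.csv(file)
  if (!all(c("ga_days", "probability") %in% names(tab))) {
    stop("daily PMF table must have columns 'ga_days' and 'probability'",
         call. = FALSE)
  }
  p <- tab$probability / sum(tab$probability)  # absorb CSV rounding
  daily_gab_pmf(tab$ga_days, p, preterm_cutoff_days = preterm_cutoff_days)
}

#' Sample GA at birth from a daily PMF
#'
#' @param pmf A [daily_gab_pmf()].
#' @param n Number of draws (positive integer).
#' @param seed Optional integer seed.
#' @return Integer vector of `n` GA-at-birth values in days.
#' @export
sample_gab <- function(pmf, n, seed = NULL) {
  stopifnot(inherits(pmf, "daily_gab_pmf"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("'n' must be a positive integer", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sample(pmf$ga_days, size = n, replace = TRUE, prob = pmf$probability)
}

#' Preterm fraction of a daily PMF
#'
#' Total probability mass strictly below the preterm cutoff (default 37
#' completed weeks = 259 days; births at or beyond the cutoff are term).
#'
#' @param pmf A [daily_gab_pmf()].
#' @param cutoff Cutoff in days; defaults to the PMF's own attribute.
#' @return Real in `[0, 1]`.
#' @export
preterm_fraction <- function(pmf, cutoff = NULL) {
  stopifnot(inherits(pmf, "daily_gab_pmf"))
  if (is.null(cutoff)) cutoff <- attr(pmf, "preterm_cutoff_days")
  sum(pmf$probability[pmf$ga_days < cutoff])
}
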