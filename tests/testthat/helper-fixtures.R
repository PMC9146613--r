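# Small in-code fixtures shared across test files.

# A weekly table with exactly 10% of mass below 37 completed weeks.
weekly_10pct_preterm <- function() {
  weekly_gab_counts(week = 33:42,
                    count = c(10, 20, 30, 40, 250, 350, 200, 70, 25, 5))
}

# Degenerate daily PMF: all mass on a single day.
point_mass_pmf <- function(day = 280L, halfspan = 2L) {
  days <- (day - halfspan):(day + halfspan)
  daily_gab_pmf(days, as.numeric(days == day))
}

# Tiny deterministic cohort around the preterm boundary.
boundary_cohort <- function(methods = c("LMP_ONLY", "US_T1"),
                            n_cases = 6L, n_controls = 12L,
                            seed = 404L) {
  set.seed(seed)
  n <- n_cases + n_controls
  gab <- c(sample(248:258, n_cases, replace = TRUE),
           sample(260:285, n_controls, replace = TRUE))
  data.frame(subject_id = sprintf("B%03d", seq_len(n)),
             score = rnorm(n, -2, 0.6),
             gab_days = gab,
             gabd_days = rep(135L, n),
             method = sample(methods, n, replace = TRUE),
             is_case = rep(c(TRUE, FALSE), c(n_cases, n_controls)),
             bmi = round(runif(n, 20, 38), 1),
             stringsAsFactors = FALSE)
}

bundled_pmf <- function() synthetic_ga_distribution()
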