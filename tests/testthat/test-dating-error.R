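test_that("half-width to SD conversion follows the two-SD convention", {
  expect_equal(sd_from_halfwidth(7), 3.5)
  expect_equal(sd_from_halfwidth(29), 14.5)
  expect_error(sd_from_halfwidth(0), "positive")
  m <- dating_error_model()
  expect_equal(m$sd_days, m$ci95_halfwidth_days / 2)
})

test_that("dating method selection follows the protocol rule", {
  d0 <- as.Date("2020-10-01")
  expect_equal(select_dating_method(d0 + 6, d0, "US_T1"), "LMP_CONFIRMED")
  # boundary is exclusive: exactly at tolerance falls to ultrasound
  expect_equal(select_dating_method(d0 + 10, d0, "US_T2_EARLY"), "US_T2_EARLY")
  expect_equal(select_dating_method(d0 + 9, d0, "US_T2_EARLY"), "LMP_CONFIRMED")
  expect_equal(select_dating_method(lmp_edd = d0), "LMP_ONLY")
  expect_equal(select_dating_method(us_edd = d0, us_window = "US_T3"), "US_T3")
  expect_error(select_dating_method(), "at least one")
  expect_error(select_dating_method(us_edd = d0), "us_window")
})

test_that("confirmed-LMP statistics match guideline values in both modes", {
  q <- confirmed_lmp_stats(14.5, 5, 10, mode = "quadrature")
  m <- confirmed_lmp_stats(14.5, 5, 10, mode = "monte-carlo",
                           n_draws = 1e6, seed = 3)
  # about half of LMP dates confirmed; two-SD interval of 14 whole days
  for (s in list(q, m)) {
    expect_equal(s$accept_probability, 0.5, tolerance = 0.1 / 0.5)
    expect_equal(round(2 * s$conditional_sd), 14)
  }
  # Monte Carlo and quadrature agree within 3 Monte Carlo SEs
  se_acc <- sqrt(q$accept_probability * (1 - q$accept_probability) / 1e6)
  se_sd <- q$conditional_sd / sqrt(2 * m$n_accepted)
  expect_lt(abs(q$accept_probability - m$accept_probability), 3 * se_acc)
  expect_lt(abs(q$conditional_sd - m$conditional_sd), 3 * se_sd)
})

test_that("quadrature mode matches an independent double-quadrature oracle", {
  # brute-force 2-D grid over +/- 6 SDs, implemented independently
  oracle <- function(sx, sy, tol, nx = 2001L, ny = 2001L) {
    x <- seq(-6 * sx, 6 * sx, length.out = nx)
    y <- seq(-6 * sy, 6 * sy, length.out = ny)
    wx <- dnorm(x, 0, sx) * (x[2] - x[1])
    wy <- dnorm(y, 0, sy) * (y[2] - y[1])
    acc_x <- vapply(x, function(xi) sum(wy[abs(xi - y) < tol]), numeric(1))
    accept <- sum(wx * acc_x)
    ex2 <- sum(wx * x^2 * acc_x) / accept
    c(accept = accept, sd = sqrt(ex2))
  }
  o <- oracle(14.5, 5, 10)
  q <- confirmed_lmp_stats(14.5, 5, 10, mode = "quadrature")
  expect_equal(q$accept_probability, unname(o["accept"]), tolerance = 1e-3)
  expect_equal(q$conditional_sd, unname(o["sd"]), tolerance = 1e-3)
})

test_that("confirmation statistics are monotone in tolerance and shrink", {
  tols <- c(3, 6, 10, 20, 40)
  stats <- lapply(tols, function(t)
    confirmed_lmp_stats(14.5, 5, t, mode = "quadrature"))
  acc <- vapply(stats, `[[`, numeric(1), "accept_probability")
  csd <- vapply(stats, `[[`, numeric(1), "conditional_sd")
  expect_true(all(diff(acc) > 0))
  expect_true(all(diff(csd) >= -1e-9))
  expect_true(all(csd <= 14.5 + 1e-9))
  # no truncation at huge tolerance
  free <- confirmed_lmp_stats(14.5, 5, 1e6, mode = "monte-carlo",
                              n_draws = 1e5, seed = 2)
  expect_equal(free$accept_probability, 1)
  expect_equal(free$conditional_sd, 14.5, tolerance = 0.02)
  expect_warning(confirmed_lmp_stats(14.5, 5, 10, n_draws = 100, seed = 1),
                 "unstable")
})

test_that("dating error draws have the configured spread and are seeded", {
  m <- dating_error_model()
  e <- sample_dating_error(m, "US_T1", 1e5, seed = 8)
  expect_equal(sd(e), 3.5, tolerance = 0.02)
  expect_equal(mean(e), 0, tolerance = 0.05)
  expect_identical(sample_dating_error(m, "LMP_ONLY", 10, seed = 4),
                   sample_dating_error(m, "LMP_ONLY", 10, seed = 4))
  m0 <- dating_error_model(c(US_T1 = 0))
  expect_identical(sample_dating_error(m0, "US_T1", 5, seed = 1), rep(0, 5))
  expect_error(sample_dating_error(m, "UNKNOWN", 5), "UNKNOWN")
})
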