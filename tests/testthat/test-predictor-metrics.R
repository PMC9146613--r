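test_that("threshold classification calls scores at the boundary higher-risk", {
  expect_true(classify_at_threshold(-1.37))
  expect_false(classify_at_threshold(-2.0))
  expect_equal(classify_at_threshold(c(-1.5, -1.37, -1.2)),
               c(FALSE, TRUE, TRUE))
  expect_error(classify_at_threshold(NA_real_), "finite")
})

test_that("sensitivity/specificity and Wilson intervals are correct", {
  p <- sensitivity_specificity(c(TRUE, TRUE, FALSE), c(TRUE, TRUE, FALSE))
  expect_equal(p$sensitivity, 1)
  expect_equal(p$specificity, 1)
  inv <- sensitivity_specificity(c(FALSE, FALSE, TRUE), c(TRUE, TRUE, FALSE))
  expect_equal(inv$sensitivity, 0)
  expect_equal(inv$specificity, 0)

  # (TP,FN,TN,FP) = (15,5,30,10)
  calls <- rep(c(TRUE, FALSE, FALSE, TRUE), c(15, 5, 30, 10))
  labels <- rep(c(TRUE, TRUE, FALSE, FALSE), c(15, 5, 30, 10))
  ss <- sensitivity_specificity(calls, labels)
  expect_equal(ss$sensitivity, 0.75)
  expect_equal(ss$specificity, 0.75)
  # Wilson score interval oracle: prop.test without continuity correction
  expect_equal(unname(ss$se_ci),
               as.numeric(prop.test(15, 20, correct = FALSE)$conf.int),
               tolerance = 1e-10)
  expect_equal(unname(ss$sp_ci),
               as.numeric(prop.test(30, 40, correct = FALSE)$conf.int),
               tolerance = 1e-10)
  expect_error(sensitivity_specificity(calls, rep(TRUE, 60)), "both classes")
})

test_that("Wilson intervals cover binomial proportions near the nominal rate", {
  # exact attained coverage by enumeration (the oracle); at n = 20,
  # p = 0.75 binomial discreteness puts it at 0.935, not exactly 0.95
  exact_coverage <- function(n, p) {
    k <- 0:n
    hit <- vapply(k, function(x) {
      ci <- gadating:::wilson_ci(x, n)
      ci[1] <= p && p <= ci[2]
    }, logical(1))
    sum(dbinom(k, n, p) * hit)
  }
  for (p in c(0.5, 0.75, 0.9)) {
    cov <- exact_coverage(20, p)
    expect_gt(cov, 0.92)
    expect_lt(cov, 0.98)
  }
  # Monte Carlo coverage agrees with the enumeration within 3 SEs
  set.seed(12)
  x <- rbinom(1e4, 20, 0.75)
  mc <- mean(vapply(x, function(k) {
    ci <- gadating:::wilson_ci(k, 20)
    ci[1] <= 0.75 && 0.75 <= ci[2]
  }, logical(1)))
  exp_cov <- exact_coverage(20, 0.75)
  expect_lt(abs(mc - exp_cov), 3 * sqrt(exp_cov * (1 - exp_cov) / 1e4))
})

test_that("prevalence-anchored predictive values match the closed form", {
  # exact closed-form values by direct arithmetic
  pv1 <- ppv_npv(0.75, 0.74, 0.073)
  expect_equal(pv1$ppv, 0.75 * 0.073 / (0.75 * 0.073 + 0.26 * 0.927))
  expect_equal(pv1$npv, 0.74 * 0.927 / (0.74 * 0.927 + 0.25 * 0.073))
  # agreement with the published whole-percent figures (18/97 and 22/99);
  # 18.5% PPV sits on the rounding boundary of the first
  expect_lt(abs(100 * pv1$ppv - 18), 1)
  expect_lt(abs(100 * pv1$npv - 97), 1)
  pv2 <- ppv_npv(0.88, 0.75, 0.073)
  expect_equal(round(pv2$ppv, 2), 0.22)
  expect_equal(round(pv2$npv, 2), 0.99)
  # symmetry: se = sp = s at prevalence 1/2 gives ppv = npv = s
  for (s in c(0.3, 0.6, 0.9)) {
    pv <- ppv_npv(s, s, 0.5)
    expect_equal(pv$ppv, s)
    expect_equal(pv$npv, s)
  }
  # prevalence limits
  expect_equal(ppv_npv(0.8, 0.7, 1e-9)$npv, 1, tolerance = 1e-6)
  expect_equal(ppv_npv(0.8, 0.7, 1 - 1e-9)$ppv, 1, tolerance = 1e-6)
  # monotone in se and sp as the formulas imply
  expect_gt(ppv_npv(0.9, 0.7)$ppv, ppv_npv(0.8, 0.7)$ppv)
  expect_gt(ppv_npv(0.8, 0.8)$ppv, ppv_npv(0.8, 0.7)$ppv)
  expect_gt(ppv_npv(0.9, 0.7)$npv, ppv_npv(0.8, 0.7)$npv)
})

test_that("case-control PPV/NPV intervals behave like the bootstrap", {
  # asymptotic agreement with a parametric bootstrap of se and sp
  boot_ci <- function(n1, n0, se, sp, p = 0.073, reps = 1e5) {
    seb <- rbinom(reps, n1, se) / n1
    spb <- rbinom(reps, n0, sp) / n0
    ppvb <- seb * p / (seb * p + (1 - spb) * (1 - p))
    npvb <- spb * (1 - p) / (spb * (1 - p) + (1 - seb) * p)
    list(ppv = quantile(ppvb, c(.025, .975), names = FALSE),
         npv = quantile(npvb, c(.025, .975), names = FALSE))
  }
  set.seed(11)
  big <- boot_ci(200, 400, 0.75, 0.75)
  ci_big <- ppv_npv_ci(0.75, 0.75, 200, 400)
  expect_equal(unname(ci_big$ppv_ci), big$ppv, tolerance = 0.01 / big$ppv[1])
  expect_equal(unname(ci_big$npv_ci), big$npv, tolerance = 0.01)
  # at the small counts (15,5,30,10) the delta linearization is coarser;
  # endpoints still agree to within 0.05
  small <- boot_ci(20, 40, 0.75, 0.75)
  ci_small <- ppv_npv_ci(0.75, 0.75, 20, 40)
  expect_lt(max(abs(unname(ci_small$ppv_ci) - small$ppv)), 0.05)
  expect_lt(max(abs(unname(ci_small$npv_ci) - small$npv)), 0.05)

  # vanishing variance at perfect performance (continuity-corrected)
  suppressMessages(ci_perf <- ppv_npv_ci(1, 1, 5000, 5000))
  expect_gt(ci_perf$ppv_ci["lower"], 0.95)
  expect_gt(ci_perf$npv_ci["lower"], 0.999)
  expect_message(ppv_npv_ci(1, 1, 50, 50), "continuity")
  # halving the counts widens both intervals
  wide <- ppv_npv_ci(0.75, 0.75, 10, 20)
  narrow <- ppv_npv_ci(0.75, 0.75, 20, 40)
  expect_gt(diff(unname(wide$ppv_ci)), diff(unname(narrow$ppv_ci)))
  expect_gt(diff(unname(wide$npv_ci)), diff(unname(narrow$npv_ci)))
})

test_that("score-GA correlation is the product-moment coefficient", {
  gab <- 250:279
  expect_equal(pearson_r(-gab, gab), -1)
  set.seed(23)
  expect_lt(abs(pearson_r(rnorm(1e4), sample(230:290, 1e4, TRUE))), 0.05)
  expect_error(pearson_r(rep(1, 10), 1:10), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("the classification regression test is a 2x2 logistic LRT", {
  # G-statistic equals the closed-form 2x2 log-likelihood difference
  set.seed(31)
  calls <- runif(120) < 0.4
  labels <- runif(120) < (0.2 + 0.3 * calls)
  fit <- glm(labels ~ calls, family = binomial())
  g_glm <- fit$null.deviance - fit$deviance
  expect_equal(gadating:::g_statistic_2x2(calls, labels), g_glm,
               tolerance = 1e-8)
  expect_equal(classification_regression_test(calls, labels),
               pchisq(g_glm, 1, lower.tail = FALSE))
  # perfectly associated table at n = 80
  expect_lt(classification_regression_test(rep(c(TRUE, FALSE), each = 40),
                                           rep(c(TRUE, FALSE), each = 40)),
            1e-6)
  expect_error(classification_regression_test(calls, rep(TRUE, 120)),
               "both classes")
})

test_that("the CI-containment comparison rule is symmetric", {
  cfg <- cohort_gen_config(800, seed = 61)
  coh <- generate_cohort(cfg)
  a <- performance_report(coh, threshold = quantile(coh$score, 0.8))
  expect_false(any(compare_performance(a, a)$significant))
  b <- performance_report(coh[1:400, ], threshold = quantile(coh$score, 0.6))
  ab <- compare_performance(a, b)
  ba <- compare_performance(b, a)
  expect_identical(ab$significant, ba$significant)
  # containment rule: point outside the comparator interval flags
  a2 <- a; a2$sensitivity <- 0.88
  a2$se_ci <- c(lower = 0.60, upper = 0.86)
  b2 <- a; b2$sensitivity <- 0.70; b2$se_ci <- c(lower = 0.60, upper = 0.86)
  cmp <- compare_performance(a2, b2)
  expect_true(cmp$significant[cmp$metric == "sensitivity"])
})

test_that("performance reports are internally consistent", {
  cfg <- cohort_gen_config(2000, seed = 77)
  coh <- generate_cohort(cfg)
  rep <- performance_report(coh)
  # point estimates inside their intervals
  expect_true(rep$se_ci[1] <= rep$sensitivity && rep$sensitivity <= rep$se_ci[2])
  expect_true(rep$sp_ci[1] <= rep$specificity && rep$specificity <= rep$sp_ci[2])
  expect_true(rep$auc_ci[1] <= rep$auc && rep$auc <= rep$auc_ci[2])
  expect_true(rep$ppv_ci[1] <= rep$ppv && rep$ppv <= rep$ppv_ci[2])
  expect_true(rep$npv_ci[1] <= rep$npv && rep$npv <= rep$npv_ci[2])
  # AUC point estimate agrees with the pROC cross-check
  roc <- pROC::roc(response = coh$is_case, predictor = coh$score,
                   direction = "<", levels = c(FALSE, TRUE), quiet = TRUE)
  expect_equal(rep$auc, as.numeric(pROC::auc(roc)), tolerance = 1e-12)
  # for binary calls, AUC of the calls equals (se + sp)/2 exactly
  calls <- classify_at_threshold(coh$score, rep$threshold)
  expect_equal(auc_mann_whitney(as.numeric(calls), coh$is_case),
               (rep$sensitivity + rep$specificity) / 2, tolerance = 1e-12)
})

test_that("baseline-table comparisons use Wilcoxon and Fisher correctly", {
  a <- data.frame(age = c(21, 25, 30, 24, 28), grav = c("P", "M", "M", "M", "P"))
  same <- cohort_compare(a, a, c(age = "continuous", grav = "categorical"))
  expect_equal(same$p_value[same$variable == "grav"], 1)
  expect_equal(same$p_value[same$variable == "age"], 1)

  # 2x2 table (18,10; 36,19): sample OR = (18*19)/(10*36) = 0.95
  ga <- data.frame(out = rep(c("case", "ctrl"), c(18, 10)))
  gb <- data.frame(out = rep(c("case", "ctrl"), c(36, 19)))
  r <- cohort_compare(ga, gb, c(out = "categorical"))
  expect_equal(r$odds_ratio_sample, (18 * 19) / (10 * 36))
  expect_equal(r$p_value, fisher.test(rbind(c(18, 10), c(36, 19)))$p.value)
  # conditional-MLE OR is reported separately and differs in general
  expect_false(is.na(r$odds_ratio_cmle))

  # disjoint continuous distributions
  d <- cohort_compare(data.frame(x = 1:20), data.frame(x = 101:120),
                      c(x = "continuous"))
  expect_lt(d$p_value, 0.001)
})
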