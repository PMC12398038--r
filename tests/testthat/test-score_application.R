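test_that("signature scoring delegates to the running-sum statistic", {
  m <- matrix(c(4, 3, 2, 1), 4, 1, dimnames = list(LETTERS[1:4], "s1"))
  expect_equal(unname(score_samples(m, "A", min_overlap = 1L)), 2)
  set.seed(7)
  m2 <- random_expression(20, 3)
  m2[, 3] <- m2[, 1]                       # identical samples
  sig <- rownames(m2)[1:6]
  sc <- score_samples(m2, sig)
  expect_equal(sc[[1]], sc[[3]])
  m3 <- m2
  m3[, 2] <- m3[, 2] + 57                  # constant shift, ranks unchanged
  expect_equal(score_samples(m3, sig), sc)
})

test_that("median dichotomization sends ties to the low group", {
  g1 <- dichotomize(setNames(c(1, 2, 3, 4), paste0("s", 1:4)))
  expect_identical(g1$group, c("low", "low", "high", "high"))
  expect_equal(attr(g1, "split_value"), 2.5)
  g2 <- dichotomize(setNames(c(1, 2, 2, 4), paste0("s", 1:4)))
  expect_identical(g2$group, c("low", "low", "low", "high"))
  expect_error(dichotomize(setNames(rep(3, 5), paste0("s", 1:5))),
               "degenerate")
  # continuous scores: group sizes differ by at most 1
  set.seed(8)
  for (n in c(10, 11, 101, 200)) {
    g <- dichotomize(setNames(rnorm(n), seq_len(n)))
    expect_lte(abs(sum(g$group == "high") - sum(g$group == "low")), 1)
  }
})

test_that("group comparison matches Welch/ANOVA references", {
  expect_equal(group_difference(c(1, 2, 3, 1, 2, 3),
                                rep(c("a", "b"), each = 3))[c("statistic", "p")],
               list(statistic = 0, p = 1))
  sep <- group_difference(c(1, 2, 3, 11, 12, 13), rep(c("a", "b"), each = 3))
  expect_lt(sep$p, 0.001)
  # independent reference: stats::t.test on the listed numbers
  ht <- t.test(c(1, 2, 3, 4), c(2, 3, 4, 5), var.equal = FALSE)
  got <- group_difference(c(1, 2, 3, 4, 2, 3, 4, 5), rep(c("a", "b"), each = 4))
  expect_equal(got$statistic, unname(ht$statistic), tolerance = 1e-12)
  expect_equal(got$p, ht$p.value, tolerance = 1e-12)
  # >= 3 groups: classical one-way ANOVA, referenced against oneway.test
  set.seed(9)
  v <- rnorm(30)
  g <- rep(c("a", "b", "c"), each = 10)
  ow <- oneway.test(v ~ factor(g), var.equal = TRUE)
  got3 <- group_difference(v, g)
  expect_equal(got3$statistic, unname(ow$statistic), tolerance = 1e-10)
  expect_equal(got3$p, ow$p.value, tolerance = 1e-10)
  expect_error(group_difference(1:3, c("a", "a", "b")), ">= 2 members")
})

test_that("diagnostic ROC is the empirical step curve with midrank AUC", {
  sc <- c(5, 4, 3, 2, 1)
  lab <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  roc <- diagnostic_roc(sc, lab)
  expect_equal(roc$auc, 1)
  expect_true(any(roc$curve$fpr == 0 & roc$curve$tpr == 1))
  expect_identical(nrow(roc$curve), length(unique(sc)) + 1L)
  expect_true(all(diff(roc$curve$fpr) >= 0) && all(diff(roc$curve$tpr) >= 0))
  set.seed(10)
  s <- rnorm(4000)
  l <- rbinom(4000, 1, 0.5)
  expect_lt(abs(diagnostic_roc(s, l)$auc - 0.5), 0.05)
  # cross-check AUC against pROC on random data
  skip_if_not_installed("pROC")
  set.seed(11)
  s2 <- round(rnorm(60), 1)
  l2 <- rbinom(60, 1, 0.4)
  expect_equal(diagnostic_roc(s2, l2)$auc,
               as.numeric(pROC::auc(pROC::roc(l2, s2, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("Kaplan-Meier estimates and log-rank match hand tabulation", {
  # no censoring: KM equals the empirical survival function
  st <- data.frame(sample_id = paste0("s", 1:6),
                   time = c(1, 2, 3, 4, 5, 6), event = rep(1, 6))
  res <- km_logrank(st, rep(c("A", "B"), each = 3))
  kmA <- res$km[res$km$group == "A", ]
  expect_equal(kmA$surv, c(2 / 3, 1 / 3, 0))
  # survivors/n at the last event time, exact
  expect_equal(res$km$surv[res$km$group == "B" & res$km$time == 6], 0)
  # hand tabulation of O, E, V for the worked 6-subject instance:
  # E_A = 3/6 + 2/5 + 1/4 = 1.15, V = 9/36 + 6/25 + 3/16 = 0.6775
  expect_equal(res$chisq, (3 - 1.15)^2 / 0.6775, tolerance = 1e-12)
  expect_equal(res$p, pchisq((3 - 1.15)^2 / 0.6775, 1, lower.tail = FALSE))
  # identical groups: statistic 0, p 1
  st2 <- data.frame(time = rep(c(1, 2, 3), 2), event = rep(1, 6))
  res2 <- km_logrank(st2, rep(c("A", "B"), each = 3))
  expect_equal(res2$chisq, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1, tolerance = 1e-12)
  # label swap leaves p unchanged
  swapped <- km_logrank(st, rep(c("B", "A"), each = 3))
  expect_equal(swapped$p, res$p, tolerance = 1e-12)
  expect_error(km_logrank(st, rep("A", 6)), "2 groups")
  expect_error(km_logrank(data.frame(time = 1:4, event = rep(0, 4)),
                          rep(c("A", "B"), 2)), "at least one event")
})

test_that("Cox fit is shift invariant, scale equivariant, and flags divergence", {
  set.seed(12)
  n <- 120
  x <- rnorm(n)
  t_ <- rexp(n, 0.2 * exp(0.5 * x))
  st <- data.frame(time = t_, event = rep(1L, n), x = x)
  f0 <- cox_ph(st, "x")
  expect_true(f0$converged)
  expect_equal(f0$table$hr, exp(f0$table$coef))
  expect_true(all(f0$table$ci_lower < f0$table$ci_upper))
  st$x_shift <- st$x + 1000
  expect_equal(cox_ph(st, "x_shift")$table$coef, f0$table$coef,
               tolerance = 1e-6)
  st$x_scaled <- st$x * 4
  expect_equal(cox_ph(st, "x_scaled")$table$coef, f0$table$coef / 4,
               tolerance = 1e-6)
  # Breslow ties flag accepted
  expect_true(cox_ph(st, "x", ties = "breslow")$converged)
  # monotone likelihood (perfect separation) is flagged, no estimates
  sep <- data.frame(time = 1:20, event = rep(1L, 20), x = -(1:20))
  fit_sep <- cox_ph(sep, "x")
  expect_false(fit_sep$converged)
  expect_null(fit_sep$table)
  expect_error(cox_ph(st, "missing_cov"), "not found")
})

test_that("Cox score test equals the log-rank statistic for a binary covariate", {
  set.seed(13)
  st <- data.frame(time = sample(seq_len(10000), 80), event = rbinom(80, 1, 0.7),
                   g = rep(0:1, 40))
  if (sum(st$event) == 0) st$event[1] <- 1L
  cf <- cox_ph(st, "g")
  lr <- km_logrank(st, ifelse(st$g == 1, "high", "low"))
  expect_equal(cf$score_test, lr$chisq, tolerance = 1e-8)
})
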