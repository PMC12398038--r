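test_that("crosstab counts match enumeration and reports exclusions", {
  marker <- c("high", "low", "high", NA, "low", "high")
  clin <- c("early", "early", "advanced", "early", "advanced", "advanced")
  tab <- crosstab(marker, clin)
  # enumeration over the 5 complete pairs
  expect_identical(tab["advanced", "high"], 2L)
  expect_identical(tab["advanced", "low"], 1L)
  expect_identical(tab["early", "high"], 1L)
  expect_identical(tab["early", "low"], 1L)
  expect_identical(attr(tab, "n_excluded"), 1L)
  expect_error(crosstab(character(), character()), "length|complete")
  expect_error(crosstab(c("a", "b", "c"), c("x", "y", "x")), "two levels")
})

test_that("crosstab reconstructs the reference cohort margins", {
  counts <- luad_marker_tables()
  stg <- counts[counts$table == "aldh1a1_ihc" & counts$parameter == "stage", ]
  marker <- rep(rep(c("low", "high"), 2), c(t(stg[, c("low", "high")])))
  clinical <- rep(stg$level, stg$low + stg$high)
  tab <- crosstab(marker, clinical)
  expect_equal(unname(colSums(tab)[c("low", "high")]), c(43, 52))
  expect_equal(sum(tab), 95)
  # every parameter of every bundled table preserves its cohort margins
  totals <- aggregate(cbind(low, high) ~ table + parameter, counts, sum)
  expect_true(all(totals$low[totals$table == "aldh1a1_ihc"] == 43))
  expect_true(all(totals$high[totals$table == "e2f1_ihc"] == 49))
  expect_true(all(totals$low[totals$table == "e2f1_elisa"] +
                    totals$high[totals$table == "e2f1_elisa"] == 100))
})

test_that("2x2 chi-square follows the closed formula and its exact invariants", {
  stage <- matrix(c(26, 17, 19, 33), 2)
  res <- chi_square_2x2(stage)
  expect_equal(floor(res$p * 1000 + 0.5) / 1000, 0.020)
  expect_equal(chi_square_2x2(matrix(c(10, 10, 10, 10), 2))$chisq, 0)
  expect_equal(chi_square_2x2(matrix(c(10, 10, 10, 10), 2))$p, 1)
  diag5 <- chi_square_2x2(matrix(c(5, 0, 0, 5), 2))
  expect_equal(diag5$chisq, 10)
  expect_error(chi_square_2x2(matrix(c(3, 0, 4, 0), 2)), "degenerate margin")
  # invariances: row swap, column swap, transpose; zero iff proportional rows
  set.seed(14)
  for (rep in 1:25) {
    m <- matrix(rpois(4, 20) + 1, 2)
    c0 <- chi_square_2x2(m)$chisq
    expect_equal(chi_square_2x2(m[2:1, ])$chisq, c0, tolerance = 1e-12)
    expect_equal(chi_square_2x2(m[, 2:1])$chisq, c0, tolerance = 1e-12)
    expect_equal(chi_square_2x2(t(m))$chisq, c0, tolerance = 1e-12)
    # independent oracle: stats::chisq.test without continuity correction
    ct <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(c0, unname(ct$statistic), tolerance = 1e-10)
    expect_equal(chi_square_2x2(m)$p, ct$p.value, tolerance = 1e-10)
  }
  prop <- matrix(c(6, 3, 10, 5), 2)  # rows exactly proportional
  expect_equal(chi_square_2x2(prop)$chisq, 0)
})

test_that("chi-square p agrees with the permutation null when expected counts are large", {
  m <- matrix(c(30, 18, 20, 32), 2)
  res <- chi_square_2x2(m)
  # conditional permutation null with fixed margins is hypergeometric in a
  n_perm <- 1e5
  set.seed(15)
  a_perm <- rhyper(n_perm, m = sum(m[1, ]), n = sum(m[2, ]), k = sum(m[, 1]))
  chi_of_a <- function(a) {
    b <- sum(m[1, ]) - a
    cc <- sum(m[, 1]) - a
    d <- sum(m[2, ]) - cc
    sum(m) * (a * d - b * cc)^2 /
      (sum(m[1, ]) * sum(m[2, ]) * sum(m[, 1]) * sum(m[, 2]))
  }
  chi_perm <- vapply(a_perm, chi_of_a, 0)
  # the permutation null is discrete; the continuous chi-square tail
  # approximates its mid-p (half the atom at the observed statistic)
  p_mid <- mean(chi_perm > res$chisq + 1e-12) +
    0.5 * mean(abs(chi_perm - res$chisq) <= 1e-12)
  mc_se <- sqrt(p_mid * (1 - p_mid) / n_perm)
  expect_lt(abs(p_mid - res$p), 3 * mc_se + 0.005)
})

test_that("association report rounds half-up to three decimals and flags 0.05", {
  counts <- luad_marker_tables()
  res <- association_from_counts(counts)
  t1 <- res[res$table == "aldh1a1_ihc", ]
  expect_equal(t1$p_display[match(c("stage", "invasion", "distant_metastasis",
                                    "gender", "age", "lymphatic"),
                                  t1$parameter)],
               c(0.020, 0.027, 0.006, 0.124, 0.097, 0.115))
  expect_identical(t1$significant, t1$p < 0.05)
  # per-sample route agrees with the pre-tabulated route
  stg <- counts[counts$table == "aldh1a1_ihc" & counts$parameter == "stage", ]
  clin <- structure(data.frame(
    sample_id = sprintf("p%02d", 1:95),
    stage = rep(stg$level, stg$low + stg$high), stringsAsFactors = FALSE),
    class = c("clinical_table", "data.frame"))
  marker <- setNames(rep(rep(c("low", "high"), 2), c(t(stg[, c("low", "high")]))),
                     clin$sample_id)
  via_samples <- association_report(clin, marker)
  expect_equal(via_samples$p, t1$p[t1$parameter == "stage"], tolerance = 1e-12)
})
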