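test_that("midrank AUC matches pair enumeration and its exact symmetries", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(1, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)),
               0.5)
  # pos {3,1,2} vs neg {2,0}: 6 pairs, 4 concordant + 1 tie = 4.5/6
  expect_equal(roc_auc(c(3, 1, 2, 2, 0), c(TRUE, TRUE, TRUE, FALSE, FALSE)),
               0.75)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  # label-flip complement, exact, over random data
  set.seed(5)
  for (rep in 1:25) {
    s <- sample(round(rnorm(20), 1))
    lab <- sample(c(TRUE, FALSE), 20, replace = TRUE)
    if (all(lab) || !any(lab)) next
    expect_identical(roc_auc(s, lab) + roc_auc(s, !lab), 1)
  }
})

test_that("discrimination filter keeps the inclusive AUC boundary and flips with labels", {
  # pos {1,2,3,4} vs neg {0,0,0,0,1.5}: 19 of 20 pairs concordant -> AUC 0.95
  scores <- matrix(c(1, 2, 3, 4, 0, 0, 0, 0, 1.5), 1, 9,
                   dimnames = list("S", sprintf("x%d", 1:9)))
  sm <- structure(list(scores = scores, alpha = 0.25, normalized = FALSE,
                       dropped = character()), class = "score_matrix")
  lab <- c(rep(TRUE, 4), rep(FALSE, 5))
  res <- filter_discriminative(sm, lab, auc_min = 0.95)
  expect_equal(res$report$auc, 0.95)
  expect_identical(res$retained, "S")      # boundary inclusive
  flipped <- filter_discriminative(sm, !lab, auc_min = 0.95)
  expect_equal(flipped$report$auc, 0.05)   # complement orientation
  expect_length(flipped$retained, 0L)
})

test_that("discrimination filter separates planted from null sets on the labeled panel", {
  d <- simulation_design(seed = 17)
  ss <- gen_stem_somatic(d)
  sm <- ssgsea_score(ss$matrix, ss$genesets$collection)
  res <- filter_discriminative(sm, ss$labels)
  truth <- ss$genesets$truth
  planted <- truth$set[truth$class != "null"]
  nulls <- truth$set[truth$class == "null"]
  expect_true(all(planted %in% res$retained))
  expect_lte(mean(nulls %in% res$retained), 0.05)
})

test_that("stability CV applies the hand formula on rescaled scores with inclusive boundary", {
  # anchor row pins the global min at 0 so the min-max rescale is a pure
  # scaling, which leaves each row's CV unchanged
  mk <- function(rows) structure(list(
    scores = do.call(rbind, rows), alpha = 0.25, normalized = FALSE,
    dropped = character()), class = "score_matrix")
  sm <- mk(list(anchor = c(0, 2, 2), const = c(0.7, 0.7, 0.7),
                edge = c(0.75, 1, 1.25), wide = c(0.5, 1.5, 1.0)))
  res <- stability_cv(sm, cv_max = 0.1)
  rep <- res$report
  expect_equal(rep$cv[rep$set == "const"], 0)                    # retained
  expect_true("const" %in% res$retained)
  expect_equal(rep$cv[rep$set == "edge"], 0.25)    # sd 0.25 / mean 1
  expect_equal(rep$cv[rep$set == "wide"], 0.5 / 1.0, tolerance = 1e-12)
  expect_false("wide" %in% res$retained)
  # inclusive boundary: edge sits exactly at cv_max (binary-exact values)
  expect_true("edge" %in% stability_cv(sm, cv_max = 0.25)$retained)
  # hand-formula cases: {0.9, 1.0, 1.1} -> sd 0.1 / mean 1
  sm_h <- mk(list(anchor = c(0, 1.1, 1.1), h = c(0.9, 1.0, 1.1)))
  expect_equal(stability_cv(sm_h, 0.1)$report$cv[2L], 0.1, tolerance = 1e-12)
  # {0.5, 1.5}: CV = (1/sqrt(2)) / 1
  sm2 <- mk(list(anchor = c(0, 1.5), pair = c(0.5, 1.5)))
  rep2 <- stability_cv(sm2, cv_max = 0.1)$report
  expect_equal(rep2$cv[rep2$set == "pair"], (1 / sqrt(2)) / 1,
               tolerance = 1e-12)
  expect_error(stability_cv(mk(list(a = 1)), 0.1), "at least 2")
})

test_that("consensus membership follows the count rule and deterministic order", {
  gsc <- gene_set_collection(list(S1 = c("A", "B"), S2 = c("A", "C"),
                                  S3 = c("A", "D"), S4 = "A", S5 = "B"))
  sig <- consensus_signature(gsc, min_membership = 4L)
  expect_identical(sig$genes, "A")
  expect_identical(unname(sig$membership_count), 4L)
  expect_warning(empty <- consensus_signature(gsc, min_membership = 6L),
                 "empty")
  expect_length(empty$genes, 0L)
  all_union <- consensus_signature(gsc, min_membership = 1L)
  expect_setequal(all_union$genes, c("A", "B", "C", "D"))
  # in exactly 4 of many sets -> included; in 3 -> excluded
  gsc2 <- gene_set_collection(c(
    setNames(lapply(1:4, function(i) c("IN4", "PAD", paste0("p", i))),
             paste0("x", 1:4)),
    list(x5 = c("IN3", "PAD"), x6 = c("IN3", "PAD"), x7 = c("IN3", "PAD"))))
  sig2 <- consensus_signature(gsc2, 4L)
  expect_true("IN4" %in% sig2$genes)
  expect_false("IN3" %in% sig2$genes)
  expect_true("PAD" %in% sig2$genes)   # 7 sets
  # ordering: descending count, then gene id
  expect_identical(sig2$genes, c("PAD", "IN4"))
})

test_that("distillation is monotone in its thresholds", {
  d <- simulation_design(seed = 23, n_stem = 12L, n_somatic = 12L,
                         n_lines = 60L)
  ss <- gen_stem_somatic(d)
  pan <- gen_cellline_panel(d)
  sm <- ssgsea_score(ss$matrix, ss$genesets$collection)
  pm <- ssgsea_score(pan$matrix, ss$genesets$collection)
  n_auc <- sapply(c(0.6, 0.8, 0.95, 0.99),
                  function(a) length(filter_discriminative(sm, ss$labels,
                                                           a)$retained))
  expect_true(all(diff(n_auc) <= 0))
  n_cv <- sapply(c(0.01, 0.05, 0.2, 1),
                 function(cv) length(stability_cv(pm, cv)$retained))
  expect_true(all(diff(n_cv) >= 0))
  n_sig <- sapply(1:6, function(mm) length(suppressWarnings(
    consensus_signature(ss$genesets$collection, mm))$genes))
  expect_true(all(diff(n_sig) <= 0))
})

test_that("correlation screen applies the t transform and strict thresholds", {
  set.seed(6)
  score <- c(1, 2, 3, 4, 5)
  m <- rbind(prop = 2 * score + 3,             # r = 1
             hand = c(1, 2, 3, 4, 6),
             flat = rep(2, 5),
             anti = -score,
             noise = c(0.3, -1, 2, 0.1, -0.4))
  colnames(m) <- sprintf("s%d", 1:5)
  expect_warning(res <- correlation_screen(m, score), "zero-variance")
  expect_false("flat" %in% res$gene)
  expect_equal(res$r[res$gene == "prop"], 1)
  expect_true(res$kept[res$gene == "prop"])
  expect_false(res$kept[res$gene == "anti"])   # r > 0.4 is one-sided
  # independent oracle: cor.test on the listed numbers
  ct <- cor.test(c(1, 2, 3, 4, 6), score)
  expect_equal(res$r[res$gene == "hand"], unname(ct$estimate),
               tolerance = 1e-12)
  expect_equal(res$p[res$gene == "hand"], ct$p.value, tolerance = 1e-12)
  expect_identical(res$kept[res$gene == "hand"],
                   unname(ct$estimate) > 0.4 && ct$p.value < 0.05)
  expect_equal(res$q, p.adjust(res$p, "BH"))
  expect_error(correlation_screen(m[, 1:2], score[1:2]), "3 samples")
})
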