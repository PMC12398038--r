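#' ROC AUC by the midrank (Mann-Whitney) formula
#'
#' AUC = P(score_pos > score_neg) + 0.5 P(tie), computed exactly from
#' midranks; equals the area under the empirical ROC curve with tied scores
#' traversed diagonally. Satisfies the exact complement identity
#' `auc(s, labels) + auc(s, flipped labels) = 1`.
#'
#' @param scores Numeric vector.
#' @param labels Logical/binary vector (TRUE / 1 = positive class, i.e.
#'   stem or tumor) or a [phenotype_labels()] object aligned with `scores`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- .as_positive(labels, scores)
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

.as_positive <- function(labels, scores) {
  if (inherits(labels, "phenotype_labels")) {
    if (!is.null(names(scores))) {
      labels <- labels[match(names(scores), labels$sample_id), ]
      if (anyNA(labels$sample_id)) stop("labels do not cover all samples")
    }
    labels <- labels$label == attr(labels, "positive")
  }
  if (is.numeric(labels)) labels <- labels != 0
  if (!is.logical(labels) || length(labels) != length(scores) ||
      anyNA(labels)) {
    stop("labels must be a complete binary vector aligned with scores")
  }
  labels
}

#' Discrimination filter: retain gene sets whose scores separate classes
#'
#' Stage one of the signature distillation: for each set, the AUC of its
#' per-sample scores for discriminating the positive class (stem) from the
#' negative class (somatic) is computed, and sets with AUC below `auc_min`
#' are excluded. The boundary is inclusive — exclusion applies to AUC strictly
#' below the threshold — and sets are evaluated on the stem-vs-somatic
#' orientation only (no flipping of anti-correlated sets).
#'
#' @param score_matrix A `score_matrix` from [ssgsea_score()].
#' @param labels [phenotype_labels()] covering every scored sample (or an
#'   aligned logical vector).
#' @param auc_min Retention threshold (default 0.95).
#' @return List with `retained` (set names) and `report` (data.frame:
#'   set, auc, passed_auc).
#' @export
filter_discriminative <- function(score_matrix, labels, auc_min = 0.95) {
  stopifnot(inherits(score_matrix, "score_matrix"))
  s <- score_matrix$scores
  auc <- vapply(seq_len(nrow(s)), function(i) {
    roc_auc(stats::setNames(s[i, ], colnames(s)), labels)
  }, 0)
  report <- data.frame(set = rownames(s), auc = auc,
                       passed_auc = auc >= auc_min,
                       stringsAsFactors = FALSE)
  list(retained = report$set[report$passed_auc], report = report)
}

#' Stability filter: coefficient of variation across a cell-line panel
#'
#' Stage two: sets whose scores fluctuate across a large tumor cell-line
#' panel are excluded as unstable. Enrichment scores are signed, so the CV is
#' computed after rescaling the whole score matrix to \[0, 1\] by its global
#' min-max (making means non-negative); this convention is recorded in the
#' report. CV = sample (n-1) standard deviation / mean; sets with mean 0
#' after rescaling have undefined CV and are excluded with a flag. The
#' boundary is inclusive: exclusion applies to CV strictly above `cv_max`.
#'
#' @param score_matrix `score_matrix` over the panel (>= 2 samples).
#' @param cv_max Retention threshold (default 0.1).
#' @return List with `retained` and `report` (set, cv, cv_defined,
#'   passed_cv).
#' @export
stability_cv <- function(score_matrix, cv_max = 0.1) {
  stopifnot(inherits(score_matrix, "score_matrix"))
  s <- score_matrix$scores
  if (ncol(s) < 2L) stop("panel must have at least 2 samples")
  rng <- max(s) - min(s)
  resc <- if (rng == 0) s * 0 + 1 else (s - min(s)) / rng
  m <- rowMeans(resc)
  sdv <- apply(resc, 1L, stats::sd)
  cv <- ifelse(m == 0, NA_real_, sdv / m)
  passed <- !is.na(cv) & cv <= cv_max
  report <- data.frame(set = rownames(s), cv = cv, cv_defined = !is.na(cv),
                       passed_cv = passed, stringsAsFactors = FALSE)
  list(retained = report$set[report$passed_cv], report = report)
}

#' Consensus signature: genes shared by enough retained sets
#'
#' Stage three: each gene's membership is counted across the retained sets
#' and genes present in at least `min_membership` of them form the signature,
#' ordered by (descending membership count, gene id). An empty result is a
#' warning, not an error.
#'
#' @param retained A [gene_set_collection()] of the retained sets.
#' @param min_membership Minimum number of sets a gene must appear in
#'   (default 4).
#' @return `consensus_signature` object: list with `genes`,
#'   `membership_count` (named, aligned with `genes`), `min_membership`,
#'   `source_set_names`.
#' @export
consensus_signature <- function(retained, min_membership = 4L) {
  stopifnot(inherits(retained, "gene_set_collection"))
  if (length(retained) == 0L) stop("`retained` collection is empty")
  counts <- table(unlist(retained, use.names = FALSE))
  keep <- counts[counts >= min_membership]
  if (length(keep) == 0L) {
    warning("no gene reaches min_membership = ", min_membership,
            "; signature is empty", call. = FALSE)
    genes <- character()
    cnt <- integer()
  } else {
    ord <- order(-as.integer(keep), names(keep), method = "radix")
    genes <- names(keep)[ord]
    cnt <- as.integer(keep)[ord]
  }
  structure(list(genes = genes,
                 membership_count = stats::setNames(cnt, genes),
                 min_membership = as.integer(min_membership),
                 source_set_names = names(retained)),
            class = "consensus_signature")
}

#' @export
print.consensus_signature <- function(x, ...) {
  cat("consensus_signature:", length(x$genes), "genes in >=",
      x$min_membership, "of", length(x$source_set_names), "sets\n")
  invisible(x)
}

#' Run the full three-stage distillation
#'
#' Convenience wrapper chaining [filter_discriminative()] (on the labeled
#' stem/somatic score matrix), [stability_cv()] (on the cell-line panel score
#' matrix, restricted to AUC survivors) and [consensus_signature()]. Returns
#' the signature plus a per-set report with the thresholds and the funnel
#' counts (entered / after AUC / after CV).
#'
#' @param collection Candidate [gene_set_collection()].
#' @param stem_scores `score_matrix` of `collection` on the labeled panel.
#' @param labels [phenotype_labels()] for `stem_scores`.
#' @param panel_scores `score_matrix` of `collection` on the cell-line panel.
#' @param auc_min,cv_max,min_membership Stage thresholds (defaults 0.95, 0.1,
#'   4).
#' @return List with `signature` ([consensus_signature()]), `report`
#'   (per-set data.frame), `counts` (named: entered, after_auc, after_cv),
#'   `thresholds`.
#' @export
distill_signature <- function(collection, stem_scores, labels, panel_scores,
                              auc_min = 0.95, cv_max = 0.1,
                              min_membership = 4L) {
  stopifnot(inherits(collection, "gene_set_collection"))
  st1 <- filter_discriminative(stem_scores, labels, auc_min)
  panel_sub <- panel_scores
  idx <- rownames(panel_scores$scores) %in% st1$retained
  if (!any(idx)) stop("no set passed the AUC filter")
  panel_sub$scores <- panel_scores$scores[idx, , drop = FALSE]
  st2 <- stability_cv(panel_sub, cv_max)
  report <- st1$report
  report$cv <- st2$report$cv[match(report$set, st2$report$set)]
  report$cv_defined <- st2$report$cv_defined[match(report$set, st2$report$set)]
  report$passed_cv <- report$set %in% st2$retained
  retained <- collection[names(collection) %in% st2$retained]
  class(retained) <- c("gene_set_collection", "list")
  attr(retained, "descriptions") <-
    attr(collection, "descriptions")[names(retained)]
  sig <- consensus_signature(retained, min_membership)
  counts <- c(entered = nrow(report), after_auc = length(st1$retained),
              after_cv = length(st2$retained))
  if (any(diff(counts) > 0)) stop("internal error: funnel counts increased")
  list(signature = sig, report = report, counts = counts,
       thresholds = c(auc_min = auc_min, cv_max = cv_max,
                      min_membership = min_membership))
}

#' Pearson screen for genes correlated with a per-sample score
#'
#' For each gene, the Pearson correlation of its expression with the score
#' is computed with the two-sided p-value from the exact t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom. Genes are
#' kept when `r > r_min` and `p < p_max` (both strict). No multiple-testing
#' correction is applied to the decision, but Benjamini-Hochberg q-values are
#' reported for transparency. Zero-variance genes have undefined r and are
#' excluded with a warning.
#'
#' @param matrix Expression matrix (genes x samples, >= 3 samples).
#' @param score Numeric per-sample score aligned with the columns.
#' @param r_min,p_max Strict thresholds (defaults 0.4 and 0.05).
#' @return data.frame (gene, r, p, q, kept) over genes with defined r,
#'   in matrix row order.
#' @export
correlation_screen <- function(matrix, score, r_min = 0.4, p_max = 0.05) {
  validate_expression(matrix)
  n <- ncol(matrix)
  if (n < 3L) stop("need at least 3 samples")
  if (length(score) != n) stop("score length must equal sample count")
  sds <- apply(matrix, 1L, stats::sd)
  degenerate <- sds == 0 | stats::sd(score) == 0
  if (stats::sd(score) == 0) stop("score is constant; correlation undefined")
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance gene(s) excluded", call. = FALSE)
  }
  m <- matrix[!degenerate, , drop = FALSE]
  r <- as.vector(stats::cor(t(m), score))
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  q <- stats::p.adjust(p, method = "BH")
  data.frame(gene = rownames(m), r = r, p = p, q = q,
             kept = r > r_min & p < p_max,
             stringsAsFactors = FALSE)
}
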