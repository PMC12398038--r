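#' Per-sample rank transform
#'
#' Ranks each sample's expression independently, 1 = lowest expression,
#' N = highest; ties receive midranks, so each column's ranks sum to
#' N(N+1)/2 exactly. All downstream scoring is a functional of these ranks,
#' which makes the scores invariant to any strictly increasing per-sample
#' transform of expression (log, quantile shift, scaling).
#'
#' @param matrix Validated expression matrix (genes x samples), >= 2 genes.
#' @return Numeric matrix of the same shape holding per-sample midranks.
#' @export
rank_transform <- function(matrix) {
  validate_expression(matrix)
  if (nrow(matrix) < 2L) stop("need at least 2 genes to rank")
  apply(matrix, 2L, rank, ties.method = "average")
}

# Deterministic walk order for one sample: decreasing rank, ties broken by
# gene id in C-locale (radix) lexicographic order. Returns the permutation.
.walk_order <- function(r, gene_ids) {
  order(-r, gene_ids, method = "radix")
}

#' Single-sample enrichment score (ssGSEA running sum)
#'
#' Walks the sample's genes from highest to lowest rank and accumulates the
#' difference between the weighted in-set cumulative distribution
#' (weights = rank^alpha, normalized over the set) and the uniform out-of-set
#' cumulative distribution. The statistic is the *sum* of the running
#' differences (the single-sample convention), not the maximum deviation.
#'
#' Tied ranks are handled block-wise: genes sharing a rank form one block and
#' contribute `block size x (P_hit - P_miss)` evaluated at the end of the
#' block, so the score does not depend on the arbitrary order within a tie
#' and a constant sample scores exactly 0 for every set. With distinct ranks
#' this reduces to the familiar position-by-position sum. The walk order among
#' ties is still fixed (lexicographic gene id) for reproducible reporting.
#'
#' @param ranks Named numeric vector of one sample's midranks (names = genes).
#' @param set Character vector of gene identifiers.
#' @param alpha Non-negative rank-weight exponent (default 0.25, the common
#'   single-sample default). `alpha = 0` weights all set genes equally.
#' @return The enrichment score (real scalar).
#' @export
#' @examples
#' r <- c(A = 4, B = 3, C = 2, D = 1)
#' enrichment_score(r, "A")            # 2
#' enrichment_score(r, "D")            # -2
#' enrichment_score(r, c("A", "C"), alpha = 0)  # 1
enrichment_score <- function(ranks, set, alpha = 0.25) {
  if (is.null(names(ranks))) stop("`ranks` must be a named vector")
  if (alpha < 0) stop("`alpha` must be non-negative")
  gene_ids <- names(ranks)
  n <- length(ranks)
  inset <- gene_ids %in% set
  k <- sum(inset)
  if (k == 0L) stop("set not represented in the expression matrix")
  if (k == n) stop("P_miss undefined: set covers every gene in the matrix")
  ord <- .walk_order(ranks, gene_ids)
  r_ord <- ranks[ord]
  in_ord <- inset[ord]
  w <- ifelse(in_ord, r_ord^alpha, 0)
  p_hit <- cumsum(w) / sum(w)
  p_miss <- cumsum(!in_ord) / (n - k)
  # block-wise ties: contribution of each tied-rank block is its size times
  # the running difference at the block end
  block_end <- c(r_ord[-n] != r_ord[-1L], TRUE)
  sizes <- diff(c(0L, which(block_end)))
  sum(sizes * (p_hit[block_end] - p_miss[block_end]))
}

#' Score a gene-set collection against every sample
#'
#' Computes the [enrichment_score()] of every retained set in every sample.
#' Sets whose overlap with the matrix genes is below `min_overlap` are dropped
#' and listed in the result; if requested, the whole score matrix is
#' normalized once by its global range (max - min), recorded in the output.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param collection A [gene_set_collection()].
#' @param alpha Rank-weight exponent, recorded in the result.
#' @param normalize Divide all scores by the global score range (skipped with
#'   a warning when the raw scores are constant).
#' @param min_overlap Minimum set/matrix gene overlap to score a set
#'   (default 2).
#' @return `score_matrix` object: list with `scores` (sets x samples matrix),
#'   `alpha`, `normalized`, `dropped` (names of under-overlap sets).
#' @export
ssgsea_score <- function(matrix, collection, alpha = 0.25, normalize = FALSE,
                         min_overlap = 2L) {
  validate_expression(matrix)
  stopifnot(inherits(collection, "gene_set_collection"))
  genes <- rownames(matrix)
  overlap <- vapply(collection, function(s) sum(genes %in% s), 0L)
  keep <- overlap >= min_overlap & overlap < length(genes)
  full <- overlap == length(genes)
  if (any(full)) {
    stop("P_miss undefined: set(s) cover every matrix gene: ",
         paste(names(collection)[full], collapse = ", "))
  }
  dropped <- names(collection)[!keep]
  if (length(dropped)) {
    warning(length(dropped), " set(s) below min_overlap dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "), call. = FALSE)
  }
  if (!any(keep)) stop("all gene sets dropped (overlap < ", min_overlap, ")")
  kept <- collection[keep]
  ranks <- rank_transform(matrix)
  n <- length(genes)
  scores <- matrix(NA_real_, nrow = length(kept), ncol = ncol(matrix),
                   dimnames = list(names(kept), colnames(matrix)))
  for (j in seq_len(ncol(ranks))) {
    r <- ranks[, j]
    ord <- .walk_order(r, genes)
    r_ord <- r[ord]
    g_ord <- genes[ord]
    block_end <- c(r_ord[-n] != r_ord[-1L], TRUE)
    sizes <- diff(c(0L, which(block_end)))
    miss_base <- cumsum(rep(1L, n))  # positions walked so far
    for (i in seq_along(kept)) {
      in_ord <- g_ord %in% kept[[i]]
      k <- sum(in_ord)
      w <- ifelse(in_ord, r_ord^alpha, 0)
      p_hit <- cumsum(w) / sum(w)
      p_miss <- (miss_base - cumsum(in_ord)) / (n - k)
      scores[i, j] <- sum(sizes * (p_hit[block_end] - p_miss[block_end]))
    }
  }
  normalized <- FALSE
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng == 0) {
      warning("score matrix is constant; normalization skipped", call. = FALSE)
    } else {
      scores <- scores / rng
      normalized <- TRUE
    }
  }
  structure(list(scores = scores, alpha = alpha, normalized = normalized,
                 dropped = dropped),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat("score_matrix:", nrow(x$scores), "sets x", ncol(x$scores), "samples",
      "(alpha =", x$alpha,
      if (x$normalized) ", range-normalized" else "", ")\n")
  if (length(x$dropped)) cat("  dropped:", paste(x$dropped, collapse = ", "),
                             "\n")
  invisible(x)
}

#' Write a score matrix as TSV with a JSON sidecar
#'
#' The sidecar (`<path>.json`) records alpha, the normalization flag and the
#' dropped sets so every score file is self-describing.
#'
#' @param x `score_matrix`.
#' @param path Output TSV path (sets x samples).
#' @return `path`, invisibly.
#' @export
write_score_matrix <- function(x, path) {
  stopifnot(inherits(x, "score_matrix"))
  df <- data.frame(set = rownames(x$scores), x$scores, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(alpha = x$alpha, normalized = x$normalized, dropped = x$dropped),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
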