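# Independent brute-force single-sample enrichment oracle. Materializes the
# P_hit / P_miss vectors with explicit loops and walks tied-rank blocks by
# scanning, sharing no code with the package implementation.
oracle_enrichment <- function(ranks, set, alpha) {
  ids <- names(ranks)
  n <- length(ids)
  inset <- ids %in% set
  k <- sum(inset)
  stopifnot(k >= 1L, k < n)
  ord <- order(-ranks, ids, method = "radix")
  p_hit <- numeric(n)
  p_miss <- numeric(n)
  total_w <- 0
  for (g in which(inset)) total_w <- total_w + ranks[g]^alpha
  acc_w <- 0
  acc_miss <- 0
  for (i in seq_len(n)) {
    g <- ord[i]
    if (inset[g]) acc_w <- acc_w + ranks[g]^alpha else acc_miss <- acc_miss + 1
    p_hit[i] <- acc_w / total_w
    p_miss[i] <- acc_miss / (n - k)
  }
  es <- 0
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && ranks[ord[j + 1L]] == ranks[ord[i]]) j <- j + 1L
    es <- es + (j - i + 1L) * (p_hit[j] - p_miss[j])
    i <- j + 1L
  }
  es
}

# random expression fixture: genes x samples, optionally with tied values
random_expression <- function(n_genes, n_samples, tie_prob = 0.3) {
  vals <- matrix(stats::rnorm(n_genes * n_samples), n_genes, n_samples)
  if (tie_prob > 0) {
    # round a random subset to one decimal to force ties
    sel <- matrix(stats::runif(n_genes * n_samples) < tie_prob,
                  n_genes, n_samples)
    vals[sel] <- round(vals[sel], 1L)
  }
  dimnames(vals) <- list(sprintf("g%02d", seq_len(n_genes)),
                         sprintf("s%02d", seq_len(n_samples)))
  vals
}

toy_ranks <- function() c(A = 4, B = 3, C = 2, D = 1)
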