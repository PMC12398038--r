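#' Score a cohort with a consensus signature
#'
#' The signature is scored as a single gene set with [ssgsea_score()]; the
#' result is the per-sample stemness score. Raw (unnormalized) scores are
#' returned so they remain comparable across calls on the same matrix.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param signature [consensus_signature()] or a character vector of genes.
#' @param alpha Rank-weight exponent passed to [ssgsea_score()].
#' @param min_overlap Minimum signature/matrix overlap (default 2).
#' @return Named numeric vector of per-sample scores.
#' @export
score_samples <- function(matrix, signature, alpha = 0.25, min_overlap = 2L) {
  genes <- if (inherits(signature, "consensus_signature")) signature$genes
           else as.character(signature)
  gsc <- gene_set_collection(list(signature = genes))
  sm <- ssgsea_score(matrix, gsc, alpha = alpha, normalize = FALSE,
                     min_overlap = min_overlap)
  stats::setNames(sm$scores["signature", ], colnames(sm$scores))
}

#' Dichotomize scores into high and low groups
#'
#' Median split with ties assigned to the low group: high = score > median,
#' low = score <= median. The split value and method are recorded so the rule
#' is auditable in every downstream output.
#'
#' @param scores Named numeric vector (>= 2 samples).
#' @param method Split rule; only `"median"` is implemented.
#' @return `cohort_scores` data.frame (sample_id, score, group) with
#'   attributes `split_value` and `split_method`.
#' @export
dichotomize <- function(scores, method = "median") {
  method <- match.arg(method, "median")
  if (length(scores) < 2L) stop("need at least 2 samples")
  if (max(scores) == min(scores)) stop("degenerate split: all scores identical")
  split_value <- stats::median(scores)
  group <- ifelse(scores > split_value, "high", "low")
  structure(data.frame(sample_id = if (is.null(names(scores)))
                         as.character(seq_along(scores)) else names(scores),
                       score = as.numeric(scores), group = group,
                       stringsAsFactors = FALSE),
            split_value = split_value, split_method = method,
            class = c("cohort_scores", "data.frame"))
}

#' Two-group (Welch) or multi-group (one-way ANOVA) comparison
#'
#' With two groups, the Welch unequal-variance two-sample t statistic and
#' two-sided p; with three or more, the classical one-way ANOVA F and p.
#' Every group needs at least 2 members.
#'
#' @param values Numeric vector.
#' @param groups Grouping factor/vector aligned with `values`.
#' @return List: `statistic`, `p`, `method`, `df`.
#' @export
group_difference <- function(values, groups) {
  groups <- as.factor(groups)
  if (length(values) != length(groups)) stop("length mismatch")
  sizes <- table(groups)
  if (any(sizes < 2L)) stop("every group needs >= 2 members")
  if (nlevels(groups) < 2L) stop("need >= 2 groups")
  if (nlevels(groups) == 2L) {
    x <- values[groups == levels(groups)[1L]]
    y <- values[groups == levels(groups)[2L]]
    vx <- stats::var(x) / length(x)
    vy <- stats::var(y) / length(y)
    se2 <- vx + vy
    if (se2 == 0) {
      # both groups constant: defined by the limit of the Welch formula
      tstat <- if (mean(x) == mean(y)) 0 else sign(mean(x) - mean(y)) * Inf
      return(list(statistic = tstat, p = if (tstat == 0) 1 else 0,
                  method = "welch_t", df = NA_real_))
    }
    tstat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
    list(statistic = tstat, p = 2 * stats::pt(abs(tstat), df,
                                              lower.tail = FALSE),
         method = "welch_t", df = df)
  } else {
    fit <- stats::aov(values ~ groups)
    tab <- summary(fit)[[1L]]
    list(statistic = tab[["F value"]][1L], p = tab[["Pr(>F)"]][1L],
         method = "oneway_anova",
         df = c(tab[["Df"]][1L], tab[["Df"]][2L]))
  }
}

#' Diagnostic ROC curve and AUC
#'
#' Builds the empirical (FPR, TPR) step polyline over the distinct score
#' thresholds (classifier: score >= threshold is called positive) plus the
#' midrank AUC from [roc_auc()]. The curve has one vertex per distinct score
#' plus the (0,0) and (1,1) endpoints.
#'
#' @inheritParams roc_auc
#' @return List: `curve` (data.frame threshold, fpr, tpr) and `auc`.
#' @export
diagnostic_roc <- function(scores, labels) {
  lab <- .as_positive(labels, scores)
  auc <- roc_auc(scores, lab)
  thr <- sort(unique(scores), decreasing = TRUE)
  n_pos <- sum(lab)
  n_neg <- sum(!lab)
  tpr <- vapply(thr, function(t) sum(scores >= t & lab) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(scores >= t & !lab) / n_neg, 0)
  curve <- data.frame(threshold = c(Inf, thr), fpr = c(0, fpr),
                      tpr = c(0, tpr))
  list(curve = curve, auc = auc)
}

#' Kaplan-Meier curves and the log-rank test for two groups
#'
#' Product-limit survival estimates per group (right-continuous step
#' functions; censoring at an event time processed after the event) and the
#' log-rank chi-square with hypergeometric variance on 1 df. Delegates the
#' estimation to the `survival` package.
#'
#' @param survival_table data.frame with `time`, `event` (and optionally
#'   `sample_id`), e.g. from [read_survival_table()].
#' @param groups Two-level grouping vector aligned with the rows.
#' @return List: `km` (data.frame group, time, n_risk, n_event, surv),
#'   `chisq`, `df`, `p`, `fit` (the underlying `survfit`).
#' @export
km_logrank <- function(survival_table, groups) {
  groups <- as.factor(as.character(groups))
  if (nlevels(groups) != 2L) stop("exactly 2 groups required")
  if (any(table(groups) == 0L)) stop("a group has zero subjects")
  if (length(groups) != nrow(survival_table)) stop("length mismatch")
  if (sum(survival_table$event) < 1L) stop("need at least one event")
  df <- data.frame(time = survival_table$time, event = survival_table$event,
                   group = groups)
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = df)
  sf <- summary(fit, censored = TRUE)
  km <- data.frame(group = sub("^group=", "", as.character(sf$strata)),
                   time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
                   surv = sf$surv, stringsAsFactors = FALSE)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = df)
  p <- stats::pchisq(sd_$chisq, df = 1L, lower.tail = FALSE)
  list(km = km, chisq = unname(sd_$chisq), df = 1L, p = p, fit = fit)
}

#' Cox proportional-hazards regression
#'
#' Maximum partial likelihood via the `survival` package with Efron tie
#' handling by default (Breslow by flag); reports per-covariate coefficient,
#' hazard ratio, Wald 95% CI, z and p, the log partial likelihood, the score
#' (log-rank-equivalent) test, and a convergence flag. A fit flagged as
#' non-converged (or with infinite coefficients from monotone likelihood)
#' reports no estimates.
#'
#' @param survival_table data.frame with `time`, `event` and the covariate
#'   columns.
#' @param covariates Character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return `cox_fit` object: list with `table` (data.frame term, coef, hr,
#'   ci_lower, ci_upper, se, z, p), `loglik`, `score_test`, `converged`,
#'   `iterations`, `n`, `n_event`, `fit`.
#' @export
cox_ph <- function(survival_table, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  if (sum(survival_table$event) < 1L) stop("need at least one event")
  missing_cov <- setdiff(covariates, names(survival_table))
  if (length(missing_cov)) stop("covariate(s) not found: ",
                                paste(missing_cov, collapse = ", "))
  fml <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                 paste(covariates, collapse = " + ")))
  diverged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = survival_table, ties = ties,
                    control = survival::coxph.control(iter.max = 50L,
                                                      eps = 1e-9)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite|Loglik",
                conditionMessage(w))) {
        diverged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  converged <- !diverged && all(is.finite(stats::coef(fit)))
  if (!converged) {
    return(structure(list(table = NULL, loglik = NA_real_,
                          score_test = NA_real_, converged = FALSE,
                          iterations = fit$iter, n = fit$n,
                          n_event = fit$nevent, fit = fit),
                     class = "cox_fit"))
  }
  sm <- summary(fit)
  co <- sm$coefficients
  tab <- data.frame(term = rownames(co), coef = co[, "coef"],
                    hr = exp(co[, "coef"]), se = co[, "se(coef)"],
                    ci_lower = exp(co[, "coef"] - 1.959963984540054 *
                                     co[, "se(coef)"]),
                    ci_upper = exp(co[, "coef"] + 1.959963984540054 *
                                     co[, "se(coef)"]),
                    z = co[, "z"], p = co[, "Pr(>|z|)"],
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(table = tab, loglik = fit$loglik[2L],
                 score_test = unname(sm$sctest["test"]),
                 converged = TRUE, iterations = fit$iter, n = fit$n,
                 n_event = fit$nevent, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  if (!x$converged) {
    cat("cox_fit: did not converge (", x$iterations, "iterations )\n")
    return(invisible(x))
  }
  cat("cox_fit:", x$n, "subjects,", x$n_event, "events\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
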