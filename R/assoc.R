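#' Build a 2x2 contingency table from paired binary levels
#'
#' Rows are the clinical levels, columns the marker levels (low, high).
#' Samples missing either level are excluded and counted in the
#' `n_excluded` attribute.
#'
#' @param marker_level Per-sample binary marker level (e.g. "low"/"high").
#' @param clinical_level Per-sample binary clinical level, aligned.
#' @return 2x2 integer matrix (`contingency_2x2`) with dimnames and
#'   attribute `n_excluded`.
#' @export
crosstab <- function(marker_level, clinical_level) {
  if (length(marker_level) != length(clinical_level)) stop("length mismatch")
  ok <- !is.na(marker_level) & !is.na(clinical_level)
  if (!any(ok)) stop("no complete observations")
  n_excluded <- sum(!ok)
  marker <- factor(as.character(marker_level[ok]))
  clinical <- factor(as.character(clinical_level[ok]))
  if (nlevels(marker) != 2L) stop("marker level must have exactly two levels")
  if (nlevels(clinical) != 2L) {
    stop("clinical level must have exactly two levels, found ",
         nlevels(clinical))
  }
  tab <- table(clinical, marker)
  m <- matrix(as.integer(tab), 2L, 2L, dimnames = dimnames(tab))
  structure(m, n_excluded = n_excluded,
            class = c("contingency_2x2", class(m)))
}

#' Uncorrected Pearson chi-square test on a 2x2 table
#'
#' The closed form `chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` with the
#' upper chi-square tail on 1 df; no continuity correction and no exact test,
#' at any expected count. That convention was fixed by verifying that it
#' reproduces the published marker-by-clinicopathology P-values bundled in
#' [luad_marker_tables()] at their printed 3-decimal rounding (a corrected or
#' exact test does not).
#'
#' @param table 2x2 numeric matrix of counts (or `contingency_2x2`).
#' @return List: `chisq`, `df` (= 1), `p`.
#' @export
chi_square_2x2 <- function(table) {
  if (!is.matrix(table) || any(dim(table) != 2L)) stop("need a 2x2 matrix")
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  a <- table[1L, 1L]; b <- table[1L, 2L]
  c_ <- table[2L, 1L]; d <- table[2L, 2L]
  n <- a + b + c_ + d
  if (n == 0) stop("empty table")
  margins <- c(a + b, c_ + d, a + c_, b + d)
  if (any(margins == 0)) stop("degenerate margin: a row or column sums to 0")
  chisq <- n * (a * d - b * c_)^2 / prod(margins)
  list(chisq = chisq, df = 1L,
       p = stats::pchisq(chisq, df = 1L, lower.tail = FALSE))
}

# display rounding used by the published tables: 3 decimals, half-up
.round_half_up <- function(x, digits = 3L) floor(x * 10^digits + 0.5) / 10^digits

#' Marker-by-clinical association report
#'
#' One row per clinical parameter: the 2x2 counts against the dichotomized
#' marker, the uncorrected Pearson chi-square, the full-precision P-value, a
#' 3-decimal half-up display rounding, and a significance flag at 0.05.
#'
#' @param clinical A `clinical_table` (data.frame with `sample_id` plus
#'   two-level categorical columns).
#' @param marker_level Named (by sample id) or aligned binary marker level
#'   per sample.
#' @param parameters Clinical columns to test; default all except
#'   `sample_id`.
#' @return data.frame: parameter, a, b, c, d (counts, rows = clinical levels,
#'   columns = marker levels in factor order), chisq, p, p_display,
#'   significant.
#' @export
association_report <- function(clinical, marker_level,
                               parameters = setdiff(names(clinical),
                                                    "sample_id")) {
  if (!is.null(names(marker_level)) && "sample_id" %in% names(clinical)) {
    marker_level <- marker_level[match(clinical$sample_id,
                                       names(marker_level))]
  }
  rows <- lapply(parameters, function(pm) {
    tab <- crosstab(marker_level, clinical[[pm]])
    ts <- chi_square_2x2(tab)
    data.frame(parameter = pm, a = tab[1L, 1L], b = tab[1L, 2L],
               c = tab[2L, 1L], d = tab[2L, 2L], chisq = ts$chisq,
               p = ts$p, p_display = .round_half_up(ts$p),
               significant = ts$p < 0.05, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Published LUAD marker-by-clinicopathology 2x2 counts
#'
#' The printed 2x2 counts from a published LUAD cohort study relating
#' dichotomized marker levels to clinicopathological parameters: ALDH1A1
#' protein by IHC (n = 95, 43 low / 52 high), E2F1 protein by IHC (n = 95,
#' 46 low / 49 high) and E2F1 by serum ELISA (n = 100, 56 low / 44 high).
#' Rows are the clinical levels; `low`/`high` are the marker columns. These
#' counts are the reference inputs for validating [chi_square_2x2()] against
#' the study's printed P-values.
#'
#' @return data.frame: table (aldh1a1_ihc, e2f1_ihc, e2f1_elisa), parameter,
#'   level, low, high.
#' @export
luad_marker_tables <- function() {
  rows <- function(table, parameter, l1, a, b, l2, c, d) {
    data.frame(table = table, parameter = parameter,
               level = c(l1, l2), low = c(a, c), high = c(b, d),
               stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    rows("aldh1a1_ihc", "gender", "female", 18, 30, "male", 25, 22),
    rows("aldh1a1_ihc", "age", "<50", 7, 3, ">=50", 36, 49),
    rows("aldh1a1_ihc", "stage", "I+II", 26, 19, "III+IV", 17, 33),
    rows("aldh1a1_ihc", "invasion", "T1+T2", 28, 22, "T3+T4", 15, 30),
    rows("aldh1a1_ihc", "lymphatic", "negative", 26, 23, "positive", 17, 29),
    rows("aldh1a1_ihc", "distant_metastasis", "M0", 27, 18, "M1", 16, 34),
    rows("e2f1_ihc", "gender", "female", 26, 22, "male", 20, 27),
    rows("e2f1_ihc", "age", "<50", 6, 4, ">=50", 40, 45),
    rows("e2f1_ihc", "stage", "I+II", 27, 18, "III+IV", 19, 31),
    rows("e2f1_ihc", "invasion", "T1+T2", 29, 21, "T3+T4", 17, 28),
    rows("e2f1_ihc", "lymphatic", "negative", 28, 21, "positive", 18, 28),
    rows("e2f1_ihc", "distant_metastasis", "M0", 27, 18, "M1", 19, 31),
    rows("e2f1_elisa", "gender", "female", 27, 22, "male", 29, 22),
    rows("e2f1_elisa", "age", "<50", 3, 4, ">=50", 53, 40),
    rows("e2f1_elisa", "stage", "I+II", 30, 14, "III+IV", 26, 30),
    rows("e2f1_elisa", "invasion", "T1+T2", 32, 21, "T3+T4", 24, 23),
    rows("e2f1_elisa", "lymphatic", "negative", 28, 16, "positive", 28, 28),
    rows("e2f1_elisa", "distant_metastasis", "M0", 36, 18, "M1", 20, 26)))
}

#' Chi-square association on pre-tabulated 2x2 counts
#'
#' Runs [chi_square_2x2()] on every (table, parameter) block of a counts
#' data.frame laid out like [luad_marker_tables()].
#'
#' @param counts data.frame with columns table, parameter, level, low, high
#'   (two rows per parameter).
#' @return data.frame: table, parameter, chisq, p, p_display, significant.
#' @export
association_from_counts <- function(counts) {
  need <- c("table", "parameter", "level", "low", "high")
  if (!all(need %in% names(counts))) {
    stop("counts must have columns: ", paste(need, collapse = ", "))
  }
  key <- unique(counts[, c("table", "parameter")])
  rows <- lapply(seq_len(nrow(key)), function(i) {
    blk <- counts[counts$table == key$table[i] &
                    counts$parameter == key$parameter[i], ]
    if (nrow(blk) != 2L) stop("parameter '", key$parameter[i],
                              "' does not have exactly two levels")
    tab <- matrix(c(blk$low, blk$high), 2L, 2L,
                  dimnames = list(blk$level, c("low", "high")))
    ts <- chi_square_2x2(tab)
    data.frame(table = key$table[i], parameter = key$parameter[i],
               chisq = ts$chisq, p = ts$p, p_display = .round_half_up(ts$p),
               significant = ts$p < 0.05, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
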