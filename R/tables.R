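#' Read a survival table
#'
#' Expects a TSV with header and at least the columns `sample_id`, `time`
#' (strictly positive duration, arbitrary units) and `event` (1 = death
#' observed, 0 = censored). Any further numeric columns are kept as
#' covariates. Rows violating the invariants (missing mandatory fields,
#' `time <= 0`, `event` outside {0,1}) are rejected and their count reported
#' via the `n_rejected` attribute and a warning — never silently dropped.
#'
#' @param path TSV path.
#' @return A data.frame (`survival_table`) with attributes `n_rejected` and
#'   `covariates` (names of covariate columns).
#' @export
read_survival_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "time", "event")
  if (!all(need %in% names(df))) {
    stop("survival table needs columns: ", paste(need, collapse = ", "))
  }
  df$time <- suppressWarnings(as.numeric(df$time))
  df$event <- suppressWarnings(as.numeric(df$event))
  bad <- is.na(df$sample_id) | !nzchar(as.character(df$sample_id)) |
    is.na(df$time) | df$time <= 0 |
    is.na(df$event) | !(df$event %in% c(0, 1))
  if (any(bad)) {
    warning(sum(bad), " invalid survival row(s) rejected", call. = FALSE)
  }
  df <- df[!bad, , drop = FALSE]
  if (anyDuplicated(df$sample_id)) stop("duplicate sample identifiers")
  covs <- setdiff(names(df), need)
  for (cv in covs) {
    if (is.numeric(df[[cv]]) && any(!is.finite(df[[cv]]))) {
      stop("non-finite values in covariate '", cv, "'")
    }
  }
  rownames(df) <- NULL
  structure(df, n_rejected = sum(bad), covariates = covs,
            class = c("survival_table", "data.frame"))
}

#' Read a clinical (categorical) table
#'
#' TSV with header, `sample_id` plus categorical columns (e.g. stage,
#' metastasis, gender, age group). Columns fed to the 2x2 association must
#' have exactly two levels; that is enforced at association time, not on read,
#' so extra columns can ride along.
#'
#' @param path TSV path.
#' @return A data.frame (`clinical_table`); rows with an empty `sample_id` are
#'   rejected with a reported count.
#' @export
read_clinical_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df)) stop("clinical table needs a sample_id column")
  bad <- is.na(df$sample_id) | !nzchar(as.character(df$sample_id))
  if (any(bad)) warning(sum(bad), " invalid clinical row(s) rejected",
                        call. = FALSE)
  df <- df[!bad, , drop = FALSE]
  if (anyDuplicated(df$sample_id)) stop("duplicate sample identifiers")
  rownames(df) <- NULL
  structure(df, n_rejected = sum(bad),
            class = c("clinical_table", "data.frame"))
}

#' Write a data.frame as TSV (full numeric precision)
#'
#' @param x data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
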