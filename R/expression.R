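#' Validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix, genes in rows and samples in
#' columns, with unique non-empty dimnames and all values finite. Any monotone
#' expression scale (linear or log) is acceptable: downstream scoring uses
#' within-sample ranks only, so the scale is never interpreted and no transform
#' is applied on read. Missing values are rejected (no imputation rule is
#' defined).
#'
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x)) stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("expression matrix needs gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(x))) {
    stop("duplicate gene identifiers: ",
         paste(utils::head(unique(rownames(x)[duplicated(rownames(x))]), 3L),
               collapse = ", "))
  }
  if (anyDuplicated(colnames(x))) stop("duplicate sample identifiers")
  if (any(!nzchar(rownames(x))) || any(!nzchar(colnames(x)))) {
    stop("empty gene or sample identifier")
  }
  if (!all(is.finite(x))) {
    idx <- which(!is.finite(x), arr.ind = TRUE)[1L, ]
    stop("non-finite expression value at gene '", rownames(x)[idx[1L]],
         "', sample '", colnames(x)[idx[2L]], "'")
  }
  invisible(x)
}

#' Read an expression matrix (TSV or GCT 1.2)
#'
#' The TSV dialect is a header row of sample identifiers followed by one row
#' per gene (first column = gene id). The GCT 1.2 dialect adds the two-line
#' preamble (`#1.2`, then `<n_genes><TAB><n_samples>`) and a per-gene
#' Description column; declared and parsed dimensions must agree.
#'
#' @param path Input path.
#' @param dialect `"tsv"` or `"gct"`.
#' @return A validated numeric matrix (genes x samples).
#' @export
read_expression <- function(path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "gct") {
    head2 <- readLines(path, n = 2L, warn = FALSE)
    if (length(head2) < 2L || !startsWith(head2[1L], "#1.2")) {
      stop("not a GCT 1.2 file (missing '#1.2' preamble): ", path)
    }
    dims <- suppressWarnings(as.integer(strsplit(head2[2L], "\t")[[1L]][1:2]))
    if (any(is.na(dims))) stop("GCT: unparsable dimension line")
    df <- utils::read.delim(path, skip = 2L, header = TRUE,
                            check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) < 3L) stop("GCT: expected Name, Description and data columns")
    genes <- trimws(as.character(df[[1L]]))
    body <- df[, -(1:2), drop = FALSE]
    if (nrow(df) != dims[1L] || ncol(body) != dims[2L]) {
      stop("GCT dimension mismatch: declared ", dims[1L], "x", dims[2L],
           ", parsed ", nrow(df), "x", ncol(body))
    }
  } else {
    df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2L) stop("TSV: expected a gene-id column plus sample columns")
    genes <- trimws(as.character(df[[1L]]))
    body <- df[, -1L, drop = FALSE]
  }
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      if (anyNA(num) && !anyNA(col)) {
        i <- which(is.na(num))[1L]
        stop("non-numeric expression value at row ", i, " (gene '", genes[i],
             "'), column '", colnames(body)[j], "'")
      }
      body[[j]] <- num
    }
  }
  m <- as.matrix(body)
  rownames(m) <- genes
  validate_expression(m)
  m
}

#' Write an expression matrix (TSV or GCT 1.2)
#'
#' Values are written at full precision (`%.17g`) so a write/read round-trip is
#' bitwise exact.
#'
#' @inheritParams read_expression
#' @param x Validated expression matrix.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path, dialect = c("tsv", "gct")) {
  dialect <- match.arg(dialect)
  validate_expression(x)
  fmt <- function(v) formatC(v, format = "g", digits = 17)
  rows <- apply(x, 1L, function(v) paste(fmt(v), collapse = "\t"))
  con <- file(path, "w")
  on.exit(close(con))
  if (dialect == "gct") {
    writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t")), con)
    writeLines(paste(c("Name", "Description", colnames(x)), collapse = "\t"),
               con)
    writeLines(paste(rownames(x), "na", rows, sep = "\t"), con)
  } else {
    writeLines(paste(c("gene_id", colnames(x)), collapse = "\t"), con)
    writeLines(paste(rownames(x), rows, sep = "\t"), con)
  }
  invisible(path)
}

#' Construct binary phenotype labels
#'
#' @param sample_ids Character vector of sample identifiers (unique).
#' @param label Per-sample class label; coerced to character.
#' @param positive The positive class (stem / tumor); must be one of the
#'   observed levels.
#' @return A data.frame with columns `sample_id`, `label`, and attribute
#'   `positive`; class `phenotype_labels`.
#' @export
phenotype_labels <- function(sample_ids, label, positive) {
  sample_ids <- as.character(sample_ids)
  label <- as.character(label)
  if (length(sample_ids) != length(label)) stop("length mismatch")
  if (anyDuplicated(sample_ids)) stop("duplicate sample identifiers")
  if (anyNA(label)) stop("missing labels are not allowed")
  lev <- unique(label)
  if (length(lev) > 2L) stop("labels must be binary, found: ",
                             paste(lev, collapse = ", "))
  if (!positive %in% lev) stop("positive class '", positive, "' not observed")
  structure(data.frame(sample_id = sample_ids, label = label,
                       stringsAsFactors = FALSE),
            positive = positive, class = c("phenotype_labels", "data.frame"))
}
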