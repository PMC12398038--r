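#' Construct a gene-set collection
#'
#' A gene-set collection is the container consumed by [ssgsea_score()] and the
#' distillation functions: a named list of character vectors of gene
#' identifiers, with an optional description per set. Identifiers are matched
#' case-sensitively after whitespace stripping; no alias mapping is performed.
#'
#' @param sets Named list of character vectors (gene identifiers). Names must
#'   be unique and non-empty; each member vector must be non-empty.
#' @param descriptions Optional character vector of per-set descriptions,
#'   recycled to `length(sets)`.
#' @return An object of class `gene_set_collection`: a named list of unique,
#'   whitespace-stripped gene identifier vectors with a `descriptions`
#'   attribute.
#' @export
#' @examples
#' gsc <- gene_set_collection(list(SETA = c("G1", "G2"), SETB = "G3"))
#' lengths(gsc)
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets) || length(sets) == 0L) {
    stop("`sets` must be a non-empty named list of character vectors")
  }
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) stop("every gene set must be named")
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  sets <- lapply(seq_along(sets), function(i) {
    members <- trimws(as.character(sets[[i]]))
    members <- members[nzchar(members)]
    if (length(members) == 0L) stop("gene set '", nm[i], "' is empty")
    if (anyDuplicated(members)) {
      warning("gene set '", nm[i], "': duplicate members removed",
              call. = FALSE)
      members <- unique(members)
    }
    members
  })
  names(sets) <- nm
  structure(sets, descriptions = stats::setNames(descriptions, nm),
            class = c("gene_set_collection", "list"))
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection:", length(x), "sets,",
      length(unique(unlist(x, use.names = FALSE))), "distinct genes\n")
  show <- utils::head(seq_along(x), 6L)
  for (i in show) cat("  ", names(x)[i], " (", length(x[[i]]), " genes)\n",
                      sep = "")
  if (length(x) > 6L) cat("  ...\n")
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' GMT is the tab-separated gene-set exchange format: one set per line as
#' `name<TAB>description<TAB>member1<TAB>member2...`. Duplicate members within
#' a line are removed with a warning; a line with fewer than three fields or a
#' duplicated set name is an error (parsers are total: malformed input is
#' diagnosed, never silently truncated).
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(structure(stats::setNames(list(), character()),
                     descriptions = stats::setNames(character(), character()),
                     class = c("gene_set_collection", "list")))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1L], ": expected >= 3 tab-separated ",
         "fields, found ", length(fields[[bad[1L]]]))
  }
  nm <- trimws(vapply(fields, `[[`, "", 1L))
  desc <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  names(members) <- nm
  gene_set_collection(members, descriptions = desc)
}

#' Write a gene-set collection (or a consensus signature) as GMT
#'
#' @param x A [gene_set_collection()] or [consensus_signature()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  if (inherits(x, "consensus_signature")) {
    x <- gene_set_collection(
      stats::setNames(list(x$genes), "consensus_signature"),
      descriptions = sprintf("genes in >= %d of %d retained sets",
                             x$min_membership, length(x$source_set_names)))
  }
  stopifnot(inherits(x, "gene_set_collection"))
  desc <- attr(x, "descriptions")
  lines <- vapply(seq_along(x), function(i) {
    paste(c(names(x)[i], desc[[i]], x[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
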