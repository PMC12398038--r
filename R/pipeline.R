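#' Default pipeline configuration
#'
#' All tunable parameters of the analysis in one list: the scoring exponent,
#' the distillation thresholds (AUC >= 0.95, CV <= 0.1, membership >= 4), the
#' correlation screen thresholds (r > 0.4, p < 0.05), the split rule, and the
#' synthetic design arguments. Values can be overridden by a YAML file or a
#' named list; unknown keys are an error so typos fail before any
#' computation.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(alpha = 0.25, normalize = FALSE, min_overlap = 2L,
       auc_min = 0.95, cv_max = 0.1, min_membership = 4L,
       r_min = 0.4, p_max = 0.05, split = "median", ties = "efron",
       seed = 1L, out_dir = NULL, design = list())
}

#' Load and validate a pipeline configuration
#'
#' @param config `NULL` (defaults), a named list of overrides, or the path to
#'   a YAML file of overrides.
#' @return Validated config list.
#' @export
read_pipeline_config <- function(config = NULL) {
  base <- default_config()
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config)) config <- list()
  if (!is.list(config)) stop("config must be NULL, a list or a YAML path")
  unknown <- setdiff(names(config), names(base))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(base, config)
  if (cfg$auc_min < 0.5 || cfg$auc_min > 1) stop("auc_min must be in [0.5, 1]")
  if (cfg$cv_max < 0) stop("cv_max must be non-negative")
  if (cfg$min_membership < 1) stop("min_membership must be >= 1")
  if (cfg$alpha < 0) stop("alpha must be non-negative")
  if (cfg$r_min < -1 || cfg$r_min > 1) stop("r_min must be in [-1, 1]")
  if (cfg$p_max <= 0 || cfg$p_max > 1) stop("p_max must be in (0, 1]")
  cfg
}

.pipeline_design <- function(cfg) {
  do.call(simulation_design, c(cfg$design[setdiff(names(cfg$design), "seed")],
                               list(seed = cfg$seed)))
}

.write_manifest <- function(cfg, dir, extra = list()) {
  manifest <- c(list(package = "stemscore",
                     version = as.character(utils::packageVersion("stemscore")),
                     config = cfg), extra)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Generate and write the full synthetic dataset bundle
#'
#' Writes the stem/somatic panel (GCT), its labels (TSV), the candidate
#' collection (GMT), the cell-line panel (GCT), the cohort matrix (GCT) with
#' tumor/normal labels, survival and clinical tables (TSV), plus a manifest
#' JSON recording the full design, so a run is reproducible from its files
#' alone.
#'
#' @param config See [read_pipeline_config()]; `out_dir` is required.
#' @return The output directory, invisibly.
#' @export
pipeline_simulate <- function(config = NULL) {
  cfg <- read_pipeline_config(config)
  if (is.null(cfg$out_dir)) stop("config$out_dir is required")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  design <- .pipeline_design(cfg)
  ss <- gen_stem_somatic(design)
  panel <- gen_cellline_panel(design)
  cohort <- gen_tumor_cohort(design)
  d <- cfg$out_dir
  write_expression(ss$matrix, file.path(d, "stem_somatic.gct"), "gct")
  write_tsv(as.data.frame(ss$labels), file.path(d, "stem_somatic_labels.tsv"))
  write_gmt(ss$genesets$collection, file.path(d, "candidates.gmt"))
  write_tsv(ss$genesets$truth, file.path(d, "candidates_truth.tsv"))
  write_expression(panel$matrix, file.path(d, "cellline_panel.gct"), "gct")
  write_expression(cohort$matrix, file.path(d, "cohort.gct"), "gct")
  write_tsv(as.data.frame(cohort$labels), file.path(d, "cohort_labels.tsv"))
  write_tsv(as.data.frame(cohort$survival), file.path(d, "survival.tsv"))
  write_tsv(as.data.frame(cohort$clinical), file.path(d, "clinical.tsv"))
  files <- list.files(d, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  .write_manifest(cfg, d, list(design = unclass(design),
                               checksums = as.list(tools::md5sum(files))))
  invisible(d)
}

#' Run the full stemness-score analysis end to end
#'
#' One call covering the whole flow on the synthetic study: generate the
#' inputs from the design, score the candidate collection on the labeled
#' stem/somatic panel and the cell-line panel, distill the consensus
#' signature (AUC filter, CV filter, consensus membership), apply the
#' signature to the tumor/normal cohort (scores, median dichotomization,
#' diagnostic ROC, Kaplan-Meier + log-rank, Cox on the standardized score),
#' screen score-correlated genes, and cross the high/low score groups against
#' the clinical parameters. If `out_dir` is set, every tabular result is
#' written as TSV/JSON together with a manifest.
#'
#' @param config See [read_pipeline_config()].
#' @return List: `design`, `stem_scores`, `panel_scores`, `distilled`,
#'   `cohort_scores` (grouped), `diagnostic`, `km`, `cox`, `correlation`,
#'   `association`.
#' @export
run_pipeline <- function(config = NULL) {
  cfg <- read_pipeline_config(config)
  design <- .pipeline_design(cfg)
  ss <- gen_stem_somatic(design)
  panel <- gen_cellline_panel(design)
  cohort <- gen_tumor_cohort(design)

  stem_scores <- ssgsea_score(ss$matrix, ss$genesets$collection,
                              alpha = cfg$alpha, normalize = cfg$normalize,
                              min_overlap = cfg$min_overlap)
  st1 <- filter_discriminative(stem_scores, ss$labels, cfg$auc_min)
  surviving <- ss$genesets$collection[st1$retained]
  class(surviving) <- c("gene_set_collection", "list")
  attr(surviving, "descriptions") <-
    attr(ss$genesets$collection, "descriptions")[st1$retained]
  panel_scores <- ssgsea_score(panel$matrix, surviving, alpha = cfg$alpha,
                               normalize = cfg$normalize,
                               min_overlap = cfg$min_overlap)
  distilled <- distill_signature(ss$genesets$collection, stem_scores,
                                 ss$labels, panel_scores,
                                 auc_min = cfg$auc_min, cv_max = cfg$cv_max,
                                 min_membership = cfg$min_membership)

  scores <- score_samples(cohort$matrix, distilled$signature,
                          alpha = cfg$alpha, min_overlap = cfg$min_overlap)
  tumor_ids <- cohort$labels$sample_id[cohort$labels$label == "tumor"]
  groups <- dichotomize(scores[tumor_ids], method = cfg$split)
  diagnostic <- diagnostic_roc(scores, cohort$labels)
  km <- km_logrank(cohort$survival,
                   groups$group[match(cohort$survival$sample_id,
                                      groups$sample_id)])
  surv <- cohort$survival
  surv$stemness_score <- as.vector(scale(scores[surv$sample_id]))
  cox <- cox_ph(surv, "stemness_score", ties = cfg$ties)
  # Pearson is scale-sensitive (unlike the rank-based scores), so the screen
  # runs on log expression to tame the log-normal skew
  correlation <- correlation_screen(log(cohort$matrix[, tumor_ids]),
                                    scores[tumor_ids],
                                    r_min = cfg$r_min, p_max = cfg$p_max)
  marker <- stats::setNames(groups$group, groups$sample_id)
  association <- association_report(cohort$clinical, marker,
                                    parameters = c("stage", "metastasis",
                                                   "gender", "age_group"))

  res <- list(design = design, stem_scores = stem_scores,
              panel_scores = panel_scores, distilled = distilled,
              cohort_scores = groups, diagnostic = diagnostic, km = km,
              cox = cox, correlation = correlation,
              association = association)
  if (!is.null(cfg$out_dir)) {
    d <- cfg$out_dir
    dir.create(d, recursive = TRUE, showWarnings = FALSE)
    write_score_matrix(stem_scores, file.path(d, "stem_somatic_scores.tsv"))
    write_score_matrix(panel_scores, file.path(d, "panel_scores.tsv"))
    write_tsv(distilled$report, file.path(d, "distillation_report.tsv"))
    jsonlite::write_json(
      list(counts = as.list(distilled$counts),
           thresholds = as.list(distilled$thresholds),
           signature_size = length(distilled$signature$genes)),
      file.path(d, "distillation_report.json"), auto_unbox = TRUE,
      digits = NA)
    write_gmt(distilled$signature, file.path(d, "signature.gmt"))
    write_tsv(as.data.frame(groups), file.path(d, "cohort_scores.tsv"))
    write_tsv(diagnostic$curve, file.path(d, "diagnostic_roc.tsv"))
    write_tsv(km$km, file.path(d, "km_curves.tsv"))
    jsonlite::write_json(
      list(chisq = km$chisq, df = km$df, p = km$p),
      file.path(d, "logrank.json"), auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(
      list(converged = cox$converged, iterations = cox$iterations,
           n = cox$n, n_event = cox$n_event, loglik = cox$loglik,
           score_test = cox$score_test, table = cox$table),
      file.path(d, "cox_fit.json"), auto_unbox = TRUE, digits = NA)
    write_tsv(correlation, file.path(d, "correlation_screen.tsv"))
    write_tsv(association, file.path(d, "association_report.tsv"))
    .write_manifest(cfg, d, list(design = unclass(design)))
  }
  res
}

#' Association report for externally supplied counts or tables
#'
#' The association stage on its own: either a counts file with columns
#' (table, parameter, level, low, high) — two rows per parameter — or a
#' clinical table TSV plus a marker-level TSV (sample_id, marker).
#'
#' @param counts_path Path to a TSV of pre-tabulated 2x2 counts.
#' @param out_path Optional output TSV.
#' @return The association data.frame (invisibly when written).
#' @export
pipeline_assoc <- function(counts_path, out_path = NULL) {
  counts <- utils::read.delim(counts_path, header = TRUE,
                              stringsAsFactors = FALSE)
  res <- association_from_counts(counts)
  if (!is.null(out_path)) {
    write_tsv(res, out_path)
    return(invisible(res))
  }
  res
}
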