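#' Simulation design for the synthetic stemness study
#'
#' Fixes every condition of the synthetic study in one object: the gene
#' universe, the candidate gene-set collection (planted discriminative+stable
#' sets, discriminative-but-unstable decoys, null decoys), the labeled
#' stem/somatic panel, the cell-line stability panel, and the tumor/normal
#' survival cohort. Identical design + seed gives bitwise-identical outputs;
#' the seed expands into fixed per-component substreams so generating one
#' component never perturbs another.
#'
#' Defaults mirror the funnel the method was built for: 28 candidate sets
#' (11 planted + 2 unstable + 15 null) of 30 genes each, a 2-SD planted
#' expression shift on a 20 + 20 stem/somatic panel, a 200-line stability
#' panel, and a 500-tumor cohort whose hazard is exponential in the
#' standardized planted stemness with log-hazard 0.7 per SD and ~30%
#' uniform censoring.
#'
#' @param n_genes Size of the gene universe.
#' @param n_stem,n_somatic Labeled panel sizes.
#' @param n_lines Cell-line panel size.
#' @param n_tumor,n_normal Cohort sizes.
#' @param n_sets_planted,n_sets_unstable,n_sets_null Candidate set counts by
#'   truth class.
#' @param set_size Genes per candidate set.
#' @param core_size Size of the shared core pool planted sets draw from.
#' @param core_draw Core genes sampled into each planted set (the rest of the
#'   set is private), so core-gene membership across planted sets is
#'   Binomial(n_sets_planted, core_draw / core_size).
#' @param delta Planted mean shift, in units of `sigma`, on the log scale.
#' @param sigma Log-normal noise SD of baseline expression.
#' @param panel_shift Fixed log-scale shift (x `sigma`) of stable-set genes on
#'   every cell line.
#' @param panel_instability SD (x `sigma`) of the per-line random shift of
#'   unstable-set genes.
#' @param beta Log-hazard per SD of the planted stemness score.
#' @param baseline_hazard Exponential baseline hazard (1 / time unit).
#' @param censoring_rate Target fraction censored under uniform censoring,
#'   in \[0, 1).
#' @param stage_or Odds multiplier of advanced stage (and M1) per stemness
#'   quartile.
#' @param seed Integer master seed.
#' @return `simulation_design` list.
#' @export
simulation_design <- function(n_genes = 1000L, n_stem = 20L, n_somatic = 20L,
                              n_lines = 200L, n_tumor = 500L, n_normal = 100L,
                              n_sets_planted = 11L, n_sets_unstable = 2L,
                              n_sets_null = 15L, set_size = 30L,
                              core_size = 40L, core_draw = 20L,
                              delta = 2, sigma = 1, panel_shift = 2,
                              panel_instability = 3, beta = 0.7,
                              baseline_hazard = 0.1, censoring_rate = 0.3,
                              stage_or = 2, seed = 1L) {
  d <- list(n_genes = as.integer(n_genes), n_stem = as.integer(n_stem),
            n_somatic = as.integer(n_somatic), n_lines = as.integer(n_lines),
            n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
            n_sets_planted = as.integer(n_sets_planted),
            n_sets_unstable = as.integer(n_sets_unstable),
            n_sets_null = as.integer(n_sets_null),
            set_size = as.integer(set_size), core_size = as.integer(core_size),
            core_draw = as.integer(core_draw), delta = delta, sigma = sigma,
            panel_shift = panel_shift, panel_instability = panel_instability,
            beta = beta, baseline_hazard = baseline_hazard,
            censoring_rate = censoring_rate, stage_or = stage_or,
            seed = as.integer(seed))
  counts <- unlist(d[c("n_genes", "n_stem", "n_somatic", "n_lines", "n_tumor",
                       "n_normal", "n_sets_planted", "n_sets_null",
                       "set_size", "core_size", "core_draw")])
  if (any(counts <= 0)) stop("all counts must be positive")
  if (d$n_sets_unstable < 0) stop("n_sets_unstable must be non-negative")
  if (d$delta < 0 || d$sigma <= 0 || d$baseline_hazard <= 0) {
    stop("delta must be >= 0, sigma and baseline_hazard > 0")
  }
  if (d$censoring_rate < 0 || d$censoring_rate >= 1) {
    stop("censoring_rate must be in [0, 1)")
  }
  if (d$core_draw > d$core_size) stop("core_draw cannot exceed core_size")
  needed <- d$core_size + d$n_sets_planted * (d$set_size - d$core_draw) +
    (d$n_sets_unstable + d$n_sets_null) * d$set_size
  if (needed > d$n_genes) {
    stop("planted sets exceed the gene universe: need ", needed, " genes")
  }
  structure(d, class = "simulation_design")
}

# fixed substreams of the master seed; adding a component never perturbs
# earlier draws because each component re-seeds its own stream
.substream <- function(design, k) {
  s <- (as.numeric(design$seed) * 1009 + k * 7919) %% 2147483647
  set.seed(as.integer(s), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
}

.gene_ids <- function(n) sprintf("G%04d", seq_len(n))

#' Candidate gene sets with planted truth
#'
#' Builds the design's candidate collection deterministically (substream 1 of
#' the seed): planted sets draw `core_draw` genes from a shared core pool
#' plus a private slice; unstable and null decoys take disjoint slices of the
#' remaining universe. The planted signature truth is the set of genes
#' present in at least `min_membership` planted sets.
#'
#' @param design A [simulation_design()].
#' @return List: `collection` ([gene_set_collection()]), `truth`
#'   (data.frame set, class in planted/unstable/null), `core_genes`,
#'   `signature_truth` function of `min_membership`.
#' @export
design_genesets <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  .substream(design, 1L)
  genes <- .gene_ids(design$n_genes)
  core <- genes[seq_len(design$core_size)]
  cursor <- design$core_size
  take <- function(n) {
    out <- genes[cursor + seq_len(n)]
    cursor <<- cursor + n
    out
  }
  sets <- list()
  truth <- character()
  for (i in seq_len(design$n_sets_planted)) {
    members <- c(sample(core, design$core_draw),
                 take(design$set_size - design$core_draw))
    sets[[sprintf("PLANTED_%02d", i)]] <- members
    truth[sprintf("PLANTED_%02d", i)] <- "planted"
  }
  for (i in seq_len(design$n_sets_unstable)) {
    sets[[sprintf("UNSTABLE_%02d", i)]] <- take(design$set_size)
    truth[sprintf("UNSTABLE_%02d", i)] <- "unstable"
  }
  for (i in seq_len(design$n_sets_null)) {
    sets[[sprintf("NULL_%02d", i)]] <- take(design$set_size)
    truth[sprintf("NULL_%02d", i)] <- "null"
  }
  collection <- gene_set_collection(sets)
  planted <- collection[truth[names(collection)] == "planted"]
  signature_truth <- function(min_membership = 4L) {
    counts <- table(unlist(planted, use.names = FALSE))
    sort(names(counts)[counts >= min_membership])
  }
  list(collection = collection,
       truth = data.frame(set = names(collection),
                          class = unname(truth[names(collection)]),
                          stringsAsFactors = FALSE),
       core_genes = core, signature_truth = signature_truth)
}

.baseline_log <- function(design, n_samples, ids) {
  m <- matrix(stats::rnorm(design$n_genes * n_samples, 0, design$sigma),
              nrow = design$n_genes,
              dimnames = list(.gene_ids(design$n_genes), ids))
  m
}

#' Labeled stem/somatic expression panel with planted signal
#'
#' Baseline expression is log-normal(0, sigma); in stem samples the members
#' of every discriminative set (planted and unstable decoys alike) are
#' up-shifted by `delta x sigma` on the log scale, so both classes of
#' discriminative set pass an AUC screen while null decoys stay at chance.
#'
#' @param design A [simulation_design()].
#' @return List: `matrix` (expression, genes x samples), `labels`
#'   ([phenotype_labels()], positive = "stem"), `genesets` (the
#'   [design_genesets()] bundle).
#' @export
gen_stem_somatic <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  gs <- design_genesets(design)
  .substream(design, 2L)
  ids <- c(sprintf("stem_%02d", seq_len(design$n_stem)),
           sprintf("somatic_%02d", seq_len(design$n_somatic)))
  logm <- .baseline_log(design, design$n_stem + design$n_somatic, ids)
  disc <- gs$truth$set[gs$truth$class %in% c("planted", "unstable")]
  shifted <- unique(unlist(gs$collection[disc], use.names = FALSE))
  logm[shifted, seq_len(design$n_stem)] <-
    logm[shifted, seq_len(design$n_stem)] + design$delta * design$sigma
  labels <- phenotype_labels(ids, rep(c("stem", "somatic"),
                                      c(design$n_stem, design$n_somatic)),
                             positive = "stem")
  list(matrix = validate_expression(exp(logm)), labels = labels,
       genesets = gs)
}

#' Cell-line panel with stable and unstable planted signal
#'
#' Every line expresses the planted (stable) sets with the same fixed
#' `panel_shift x sigma` up-shift, so their enrichment is constant up to
#' noise; unstable decoy sets get an independent per-line shift drawn from
#' Normal(panel_shift x sigma, (panel_instability x sigma)^2), producing
#' large score swings across the panel and a high coefficient of variation.
#'
#' @param design A [simulation_design()].
#' @return List: `matrix`, `genesets`.
#' @export
gen_cellline_panel <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  gs <- design_genesets(design)
  .substream(design, 3L)
  ids <- sprintf("line_%03d", seq_len(design$n_lines))
  logm <- .baseline_log(design, design$n_lines, ids)
  stable <- gs$truth$set[gs$truth$class == "planted"]
  stable_genes <- unique(unlist(gs$collection[stable], use.names = FALSE))
  logm[stable_genes, ] <- logm[stable_genes, ] +
    design$panel_shift * design$sigma
  for (s in gs$truth$set[gs$truth$class == "unstable"]) {
    shifts <- stats::rnorm(design$n_lines, design$panel_shift * design$sigma,
                           design$panel_instability * design$sigma)
    logm[gs$collection[[s]], ] <- logm[gs$collection[[s]], ] +
      rep(shifts, each = length(gs$collection[[s]]))
  }
  list(matrix = validate_expression(exp(logm)), genesets = gs)
}

# uniform censoring bound giving the target marginal censoring fraction for
# an Exponential(lambda) event time: solves (1 - exp(-l a)) / (l a) = rate
.censor_bound <- function(lambda, rate) {
  if (rate <= 0) return(Inf)
  f <- function(a) (1 - exp(-lambda * a)) / (lambda * a) - rate
  stats::uniroot(f, lower = 1e-9 / lambda, upper = 1e9 / lambda,
                 tol = 1e-12)$root
}

#' Tumor/normal cohort with survival and clinical links to stemness
#'
#' Tumor samples carry the planted-set expression shift scaled by a latent
#' per-sample stemness multiplier in \[0.5, 2\] (uniform); normals carry no
#' shift. Overall survival of the tumors is Exponential with hazard
#' `baseline_hazard x exp(beta x z)` where z is the standardized latent
#' stemness, with independent uniform censoring calibrated to
#' `censoring_rate`. Advanced stage and distant metastasis are logistic in
#' the stemness quartile with odds multiplier `stage_or` per quartile. A
#' standard-normal `noise` covariate independent of the hazard is included
#' for null calibration.
#'
#' @param design A [simulation_design()].
#' @return List: `matrix` (tumors then normals), `labels` (tumor/normal,
#'   positive = "tumor"), `survival` (`survival_table` for the tumors, with
#'   covariates `stemness_latent` and `noise`), `clinical`
#'   (`clinical_table` for the tumors), `genesets`, `latent` (per-tumor
#'   multiplier).
#' @export
gen_tumor_cohort <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  gs <- design_genesets(design)
  .substream(design, 4L)
  tumor_ids <- sprintf("tumor_%03d", seq_len(design$n_tumor))
  normal_ids <- sprintf("normal_%03d", seq_len(design$n_normal))
  ids <- c(tumor_ids, normal_ids)
  logm <- .baseline_log(design, length(ids), ids)
  planted <- gs$truth$set[gs$truth$class == "planted"]
  sig_genes <- unique(unlist(gs$collection[planted], use.names = FALSE))
  mult <- 0.5 + 1.5 * stats::runif(design$n_tumor)
  logm[sig_genes, seq_len(design$n_tumor)] <-
    logm[sig_genes, seq_len(design$n_tumor)] +
    rep(mult * design$delta * design$sigma, each = length(sig_genes))
  labels <- phenotype_labels(ids, rep(c("tumor", "normal"),
                                      c(design$n_tumor, design$n_normal)),
                             positive = "tumor")
  z <- as.vector(scale(mult))
  hazard <- design$baseline_hazard * exp(design$beta * z)
  t_event <- stats::rexp(design$n_tumor, rate = hazard)
  if (design$censoring_rate > 0) {
    cmax <- .censor_bound(design$baseline_hazard, design$censoring_rate)
    t_cens <- stats::runif(design$n_tumor, 0, cmax)
  } else {
    t_cens <- rep(Inf, design$n_tumor)
  }
  surv <- data.frame(sample_id = tumor_ids,
                     time = pmin(t_event, t_cens),
                     event = as.integer(t_event <= t_cens),
                     stemness_latent = z,
                     noise = stats::rnorm(design$n_tumor),
                     stringsAsFactors = FALSE)
  surv <- structure(surv, n_rejected = 0L,
                    covariates = c("stemness_latent", "noise"),
                    class = c("survival_table", "data.frame"))
  quart <- findInterval(mult, stats::quantile(mult, c(0.25, 0.5, 0.75))) + 1L
  p_adv <- stats::plogis(log(design$stage_or) * (quart - 2.5))
  p_met <- stats::plogis(log(design$stage_or) * (quart - 2.5))
  clin <- data.frame(
    sample_id = tumor_ids,
    stage = ifelse(stats::runif(design$n_tumor) < p_adv, "advanced", "early"),
    metastasis = ifelse(stats::runif(design$n_tumor) < p_met, "M1", "M0"),
    gender = sample(c("female", "male"), design$n_tumor, replace = TRUE),
    age_group = sample(c("<50", ">=50"), design$n_tumor, replace = TRUE,
                       prob = c(0.1, 0.9)),
    stringsAsFactors = FALSE)
  clin <- structure(clin, n_rejected = 0L,
                    class = c("clinical_table", "data.frame"))
  list(matrix = validate_expression(exp(logm)), labels = labels,
       survival = surv, clinical = clin, genesets = gs, latent = mult)
}

#' Paired binary samples with a planted odds ratio
#'
#' Marker level is Bernoulli(`p_marker`); the clinical level is Bernoulli
#' with log-odds `qlogis(p_clinical) + log(odds_ratio) x (marker - p_marker)`,
#' so the marginal clinical rate stays near `p_clinical` while the planted
#' marker/clinical odds ratio is `odds_ratio`.
#'
#' @param n Sample count.
#' @param odds_ratio Planted odds ratio (1 = null).
#' @param p_marker,p_clinical Marginal rates.
#' @param seed Integer seed.
#' @return data.frame: sample_id, marker ("low"/"high"), clinical
#'   ("level0"/"level1").
#' @export
gen_contingency <- function(n, odds_ratio, p_marker = 0.5, p_clinical = 0.5,
                            seed = 1L) {
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  marker <- stats::runif(n) < p_marker
  eta <- stats::qlogis(p_clinical) + log(odds_ratio) * (marker - p_marker)
  clinical <- stats::runif(n) < stats::plogis(eta)
  data.frame(sample_id = sprintf("s%04d", seq_len(n)),
             marker = ifelse(marker, "high", "low"),
             clinical = ifelse(clinical, "level1", "level0"),
             stringsAsFactors = FALSE)
}
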