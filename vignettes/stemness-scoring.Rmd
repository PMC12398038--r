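---
title: "Stemness scoring: model, distillation and validation analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stemness scoring: model, distillation and validation analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemscore)
```

## The problem

Cancer stem-like cells drive relapse and drug resistance in solid tumors,
and several transcriptomic programs ("stemness gene sets") mark them. Given
a collection of candidate sets of uneven quality, the task is to distill a
single consensus signature that (a) discriminates stem from somatic
profiles, (b) behaves stably across a heterogeneous tumor cell-line panel,
and then to use that signature's per-sample enrichment — the *stemness
score* — as a diagnostic and prognostic covariate in tumor cohorts.
`stemscore` implements the scoring statistic, the three-stage distillation,
the cohort analytics, and a synthetic-data module that makes the whole
chain testable against planted ground truth.

## The enrichment statistic

For a sample with $N$ genes, expression is replaced by midranks
$r_g \in \{1,\dots,N\}$ (ties averaged, so ranks always sum to
$N(N+1)/2$). Genes are walked from highest to lowest rank and a set $G$
accumulates

$$\mathrm{ES}(G) \;=\; \sum_{i=1}^{N}\big[P_{\mathrm{hit}}(i) - P_{\mathrm{miss}}(i)\big],
\qquad
P_{\mathrm{hit}}(i)=\frac{\sum_{g\in G,\; \mathrm{pos}(g)\le i} r_g^{\alpha}}
                         {\sum_{g\in G} r_g^{\alpha}},
\quad
P_{\mathrm{miss}}(i)=\frac{\#\{g\notin G:\mathrm{pos}(g)\le i\}}{N-|G|}.$$

Two conventions matter and are fixed deliberately:

* **Sum, not extremum.** The single-sample statistic is the sum of the
  running differences, which rewards coordinate up-shift of the whole set;
  the classical two-group GSEA maximum deviation is *not* used here.
* **Rank-power weights.** Weights are $r_g^\alpha$, never raw expression,
  so scores are invariant to any strictly increasing per-sample transform
  (tested exactly). This buys platform robustness at the cost of ignoring
  expression magnitudes.

### Tie handling

Midranks create tied blocks, and a naive position-by-position walk makes
the score depend on the arbitrary order chosen inside a block — a constant
sample would even get a nonzero score for any proper subset. We therefore
evaluate contributions *block-wise*: a tied-rank block of size $b$
contributes $b \cdot [P_{\mathrm{hit}} - P_{\mathrm{miss}}]$ at the block
end. With distinct ranks this is literally the sum above; with ties it is
order-independent, a constant sample scores exactly 0 for every set, and
the $\alpha = 0$ complement antisymmetry
$\mathrm{ES}(G) = -\mathrm{ES}(G^c)$ stays exact. The walk order among tied
genes (lexicographic gene id, C locale) is still fixed so reports are
bit-reproducible. The test suite checks the implementation against an
independent brute-force evaluation that materializes the
$P_{\mathrm{hit}}/P_{\mathrm{miss}}$ vectors explicitly, to $10^{-12}$
over random instances.

## Parameters that matter

| parameter | default | meaning, units, why |
|---|---|---|
| `alpha` | 0.25 | rank-weight exponent; the widespread single-sample default. 0 = unweighted. Recorded in every score matrix because published analyses rarely state it. |
| `min_overlap` | 2 | minimum set/matrix gene overlap to score a set; below it a set is dropped and reported. |
| `normalize` | off | one global division of the score matrix by its range (max − min); recorded in the output. Raw scores are kept by default so scores stay comparable across calls. |
| `auc_min` | 0.95 | discrimination threshold; retention is AUC ≥ 0.95 (the exclusion rule is "below 95%", so the boundary is inclusive). Sets are evaluated on the stem-positive orientation only — an anti-correlated set is a failure, not a candidate for flipping. |
| `cv_max` | 0.1 | stability threshold; retention is CV ≤ 0.1 (exclusion is "above 0.1", boundary inclusive). |
| `min_membership` | 4 | consensus rule: a gene enters the signature when it appears in at least this many retained sets. |
| `r_min`, `p_max` | 0.4, 0.05 | Pearson screen thresholds, both strict (r > 0.4 *and* p < 0.05). |
| `split` | median | high/low dichotomization; ties go to the low group and the split value is recorded. |

Raising `auc_min`, lowering `cv_max` or raising `min_membership` can only
shrink what survives; this monotonicity is asserted as a property test.

## Numerical and statistical choices

* **CV on signed scores.** Enrichment scores can be negative, so sd/mean is
  ill-defined as written. The package computes CV after min–max rescaling
  the whole panel score matrix to $[0,1]$, which makes means non-negative
  and leaves CV invariant to the overall score scale; sets with rescaled
  mean 0 are flagged and excluded as undefined. The convention is recorded
  in the report so it is auditable.
* **Sample standard deviation** ($n-1$) for the CV: the cell-line panel is
  a sample of lines, not a population.
* **AUC** is the exact midrank (Mann–Whitney) statistic, ties counted half;
  the label-flip complement `auc + auc_flipped = 1` holds exactly.
* **Chi-square on 2×2 tables** is the uncorrected Pearson closed form with
  no continuity correction and no exact test at any expected count. That
  choice was fixed by verification: it reproduces all 18 published
  P-values bundled in `luad_marker_tables()` at their printed 3-decimal
  rounding, including a cell with expected count below 5, whereas a
  corrected or exact test does not. Display rounding is half-up to 3
  decimals; full precision is kept in the JSON outputs.
* **Welch t** (unequal variances) for two-group contrasts — the safer
  default when only "t-test" is specified — and the classical one-way
  ANOVA for three or more groups. Both-groups-constant input is resolved
  by the limit of the Welch formula (t = 0, p = 1 when means agree).
* **Cox regression** uses Efron tie handling (Breslow by flag), up to 50
  Newton iterations; non-convergence and monotone-likelihood (perfect
  separation) fits are flagged and report no estimates. Estimation is
  delegated to the `survival` package; the score test it reports equals the
  log-rank statistic for a binary covariate without ties (asserted to
  1e-8).
* **Kaplan–Meier** curves are right-continuous step functions; censoring at
  an event time is processed after the event. With no censoring the
  estimate equals the empirical survival function exactly.
* **Pearson screen p-values** come from the exact t transform
  $t = r\sqrt{(n-2)/(1-r^2)}$. No multiple-testing correction is applied to
  the keep decision (matching the stated thresholds), but BH q-values are
  reported alongside. Inside `run_pipeline()` the screen runs on log
  expression: unlike the rank-based scores, Pearson correlation is
  scale-sensitive, and log stabilizes the log-normal noise.

## The synthetic study

The generator plants exactly the structure the method assumes, at sizes a
single CPU handles in seconds (stated here as the package's chosen study
conditions):

* **Candidate collection** (seed substream 1): 11 *planted* sets drawing 20
  of their 30 genes from a 40-gene shared core (so core-gene membership is
  Binomial(11, 1/2) and most core genes sit in ≥ 4 sets — the planted
  signature truth), 2 *unstable* decoys and 15 *null* decoys with disjoint
  private genes: 28 sets entering the funnel, 13 discriminative, 11 stable,
  mirroring the funnel shape the method was designed around.
* **Stem/somatic panel** (substream 2): 20 + 20 samples; baseline
  log-expression N(0, σ²) with σ = 1; stem samples add δ·σ (δ = 2) to every
  gene of every discriminative set. Values are exponentiated — the skewed
  log-normal margin is realistic, and ranks make it irrelevant downstream.
* **Cell-line panel** (substream 3): 200 lines; planted sets get the same
  fixed 2σ shift on every line (stable enrichment, rescaled CV ≈ 0.03);
  unstable sets get an independent per-line shift ~ N(2σ, (3σ)²), giving
  rescaled CV ≈ 0.4, well past the 0.1 filter.
* **Tumor cohort** (substream 4): 500 tumors + 100 normals. Each tumor
  carries the planted-set shift scaled by a latent stemness multiplier
  uniform on [0.5, 2]; normals carry none. Survival is exponential with
  hazard $\lambda \exp(\beta z)$, λ = 0.1, β = 0.7 per SD of the
  standardized latent stemness, under independent uniform censoring whose
  bound is solved numerically to hit a 30% marginal censoring rate
  (closed-form for the baseline-hazard case). Advanced stage and distant
  metastasis are logistic in the stemness quartile with odds multiplier 2
  per quartile. A pure-noise covariate is included for null calibration.
* **Contingency generator** (own seed): paired binary samples with a
  planted odds ratio and preserved margins, used to calibrate the
  chi-square null (p-values uniform across seeds at OR = 1).

Because the per-component substreams are fixed functions of the master
seed, resizing one component never changes another's draws, and identical
design + seed is bitwise reproducible (Mersenne-Twister with inversion
normals, pinned explicitly).

**What the generator does not emulate** — and hence what green tests do
*not* establish about real data: microarray/RNA-seq normalization and batch
effects, probe-to-gene collapsing, gene–gene correlation beyond the planted
sets, realistic marginal distributions or cohort sizes of public stem-cell,
cell-line or tumor compendia, non-proportional hazards, and informative
censoring. Recovery results here certify the machinery (filters,
estimators, plumbing), not field performance of any particular signature.

## Design decisions where the design was open

* The split between "high" and "low" score groups is the median with ties
  to low — the simplest auditable rule; the split value and method are
  recorded in every output. Optimal-cutpoint methods would inflate the
  apparent prognostic contrast.
* The discrimination filter takes one labeled panel at a time; if several
  labeled chips exist they can be filtered separately and intersected by
  the caller.
* Expression scale is never interpreted on read (no log transform, no
  imputation — missing values are rejected), because every score is a rank
  functional; the only scale-sensitive step, the Pearson screen, makes its
  transform explicit.
* Gene identifiers match case-sensitively after whitespace stripping; alias
  and ortholog mapping are dataset policy, not method, and are out of
  scope.
* `cox_ph` reports the Wald CI and p per covariate plus the score test;
  multivariate models are supported by passing several covariate names,
  with covariate choice left to the analyst.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the default design above
(28 sets, 40 labeled samples, 200 lines, 600-sample cohort), 1,000 random
oracle instances up to 12 genes × 4 samples, and a 100,000-draw
permutation cross-check of the chi-square — a few seconds end to end on
one CPU. These sizes were chosen as the package's own study conditions.

## Known limitations

* The running-sum score has no attached significance machinery (no
  permutation p-values or empirical-null normalization); it is a
  descriptive index, which is how it is used downstream.
* The CV rescaling convention is one defensible reading of "CV of signed
  enrichment scores"; alternatives (absolute mean, shift-to-positive)
  would move the boundary for sets near the threshold. The report carries
  the rescaled values so the decision can be audited.
* The chi-square is asymptotic; with very small expected counts its
  p-values are approximations (kept deliberately, see above, to match the
  published convention).
* `group_difference` covers two-group and one-way layouts only; factorial
  designs are out of scope.
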