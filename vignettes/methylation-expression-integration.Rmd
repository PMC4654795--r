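---
title: "Integrating array methylation and expression in two-group designs"
author: "methexpress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating array methylation and expression in two-group designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope

methexpress implements a complete two-group methylome–transcriptome
integration analysis for array data: quality filtering, M-value
transformation, moderated differential testing with FDR control, gene-region
aggregation, categorical methylation classification, contingency and
prediction-probability statistics linking methylation change to expression
change, and control-set-calibrated over-representation analysis. A
ground-truth synthetic generator makes the whole chain testable end to end.
The motivating design is a small developmental comparison — triplicate fetal
versus adult tissue — but nothing in the code assumes more than two groups
labelled `fetal` and `adult` with at least two samples each.

Out of scope by design: raw IDAT/CEL processing, RMA, functional or
probe-type (BMIQ) normalization, and surrogate-variable estimation. The
package starts from normalized beta values and log2 expression; numeric
covariates in the sample design substitute for latent-variable adjustment.

## The statistical model

**Transformation.** Beta values $\beta \in [0,1]$ are heteroscedastic and
bounded, so testing is performed on M-values,

$$M = \log_2\frac{\beta + o}{1 - \beta + o},$$

with offset $o = 10^{-6}$ by default (units of a proportion). The offset
exists only to keep the transform finite at $\beta \in \{0, 1\}$; any value
well below array noise (~$10^{-2}$) leaves results unchanged. Effects are
reported back on the beta scale as $d\beta = \bar\beta_{adult} -
\bar\beta_{fetal}$, so a fetal-to-adult methylation *decrease* is $d\beta <
0$. This convention is fixed throughout and stated in output headers.

**Per-feature model.** Each feature is fit by ordinary least squares on an
intercept plus the group indicator (plus any numeric covariates), giving an
effect (the adult-minus-fetal coefficient), a residual variance $s^2$ with
$d$ degrees of freedom, and the leverage $c$ (the group coefficient's
unscaled variance, $1/n_1 + 1/n_2$ in the plain two-group case). For
group-only designs missing betas are excluded pairwise per feature; with
covariates complete data are required.

**Variance moderation.** With three samples per group, per-feature variances
are noisy ($d = 4$). They are modelled as draws from a scaled F-distribution
around a prior $(d_0, s_0^2)$, estimated by method of moments on
$z = \log s^2$: with $e = z - \psi(d/2) + \log(d/2)$,
$\mathrm{Var}(e) - \psi'(d/2)$ estimates $\psi'(d_0/2)$, inverted by Newton
iteration on the trigamma function (relative tolerance $10^{-10}$), and
$s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\}$. The posterior variance

$$\tilde s^2 = \frac{d_0 s_0^2 + d\, s^2}{d_0 + d}$$

is always a convex combination of $s_0^2$ and $s^2$. The moderated statistic
$t = \mathrm{effect} / \sqrt{\tilde s^2 c}$ is referred to a t-distribution
with $d + d_0$ degrees of freedom, two-sided. Degenerate regimes are handled
explicitly: when the observed spread of $\log s^2$ does not exceed what
sampling noise predicts, $d_0 = \infty$ and every posterior equals the common
(geometric-mean) variance, with a normal reference distribution; with $d_0 =
0$ the statistic reduces exactly to the classical pooled-variance t-test
(`moderate = FALSE`); zero-variance features are excluded from prior
estimation (the method of moments cannot take $\log 0$) and assigned the
prior variance. The test suite cross-checks the whole path against limma to
$10^{-10}$ and against the ordinary t in the $d_0 = 0$ limit.

**Multiplicity.** Benjamini–Hochberg step-up q-values, computed separately
for methylation and expression. The implementation delegates to
`stats::p.adjust` after range validation; the tests hold it to exact
agreement with a brute-force evaluation of the definition
$q_{(i)} = \min_{j \ge i} m\, p_{(j)}/j$ on a thousand random vectors.

**Expression conventions.** The expression effect is the fetal-minus-adult
log2 ratio; the signed fold change is $+r$ when the fetal mean is higher and
$-r$ otherwise, magnitude always $\ge 1$, equal means giving $+1$.

## Thresholds and defaults

| parameter | default | units | role |
|---|---|---|---|
| detection p | 0.05, all samples | p-value | probe quality filter |
| q cutoff | 0.05 | FDR | significance, both data types |
| logit offset | 1e-6 | proportion | finiteness of M |
| d-beta cuts | 0.2, 0.5 | beta | effect-size filters (strict >) |
| overexpression fold | 5 | ratio | fetal/adult overexpressed classes |
| similarity bound | 1.1 | ratio | "similarly expressed" control pool |
| prediction folds | 2, 5 | ratio | expression-change criteria |
| methylation bins | 0.3, 0.7 | beta | hypo / intermediate / hyper |
| histogram width | 0.05 | beta | density summaries |
| control sets | 5 | count | enrichment calibration |

Requiring detection p below threshold in *every* sample is the strictest
reading of array quality filtering; the threshold is a parameter, and the
alternative (per-sample missingness) can be emulated by setting failed cells
to NA upstream. Missing betas are encoded as `NA` and excluded pairwise from
means and variances — array practice varies here and the choice is surfaced
rather than hidden.

## Region aggregation

Manifest RefGene groups map onto two aggregates: TSS200, TSS1500 and 1stExon
form TSS/Ex1; 5'UTR, Body and 3'UTR form UTR/GB. Three genuinely open design
points are resolved as follows.

* **Multi-region probes.** A probe annotated to several fine regions of the
  same gene takes TSS/Ex1 with priority: promoter-proximal membership is the
  scientifically loaded property, and "restricted to TSS/Ex1 CpGs" reads
  naturally as membership. The collapse is in `cpgRegionClass()`; the
  link-level table keeps every fine region for stratified densities.
* **Multi-gene probes.** A CpG linked to several genes contributes
  independently to each gene (contingency tables count (CpG, gene) links by
  default, with a `dedupCpGs` flag), and in the prediction probabilities a
  CpG qualifies if *any* linked gene meets the expression criterion — "a CpG
  associated with overexpression" is an existential statement.
* **Gene means.** Per-gene methylation is the unweighted mean of the
  qualifying CpGs' group means; no inverse-variance weighting, matching the
  plain "mean beta value for the sites on that gene" summary this analysis
  style reports.

## Categorical and prediction statistics

Methylation levels are a total partition with half-open bins — hypo $[0,
0.3)$, intermediate $[0.3, 0.7)$, hyper $[0.7, 1]$ — because the verbal
description "0 to 0.3, 0.3 to 0.7, 0.7 to 1.0" overlaps at the boundaries
and a partition is required; the convention is recorded in output metadata.
Displayed percentages round half away from zero to integers; raw counts are
always retained. Empty strata are flagged with NA percentages, never divided.

Chi-square tests are Pearson statistics without continuity correction,
df $=(r-1)(c-1)$, with an error on zero marginals (expected counts
undefined) and a flag when any expected count falls below 5. The pipeline
compares each overexpressed context against the similarly-expressed control
within tissue and region class.

Prediction probabilities condition on methylation q $\le 0.05$, the stated
direction beyond the cut (strict inequality, matching "decrease > 0.2"), and
the region class; the success criterion is an opposite-direction expression
change of at least the fold cut. By default the expression change must also
be q-significant (`requireExprQ = TRUE`) — the analysis is about significant
coupling, and the rest of the pipeline conditions on q throughout — but the
fold-only variant is one flag away since the tabular description mentions
only the fold. The $\ge 5$-fold probability can never exceed the
$\ge 2$-fold probability (nested events); zero-CpG strata report NA with
`n_cpgs = 0` rather than a fabricated 0.

## Calibrated enrichment

The scorer is the upper-tail hypergeometric test (over-representation
analysis). Significance is calibrated, not fixed: `kControls` gene lists of
the query's size are sampled without replacement from the similarly-expressed
pool (controls need not be mutually disjoint — nothing requires it and small
pools would make disjointness impossible), every control is scored against
every set, and the query is flagged only when its p-value is *strictly below*
the minimum control p-value. The minimum is taken globally across all sets
and controls — the strictest of the possible readings (per-set calibration
would be more permissive). The seed is mandatory; the control draw is the
only stochastic step in the whole pipeline.

## The synthetic generator

`simulateDataset()` emulates the statistical structure the analysis assumes,
with every default chosen once as the study condition:

* **Marginal betas** are a hypo/intermediate/hyper mixture (weights
  0.35/0.25/0.40): extreme modes are drawn from Beta(1.2, 12) (reflected for
  hyper), intermediate from U(0.35, 0.65), giving the characteristic bimodal
  histogram of 450K data.
* **Noise** is Beta$(\mu\kappa, (1-\mu)\kappa)$ per CpG, so the per-CpG
  variance is $\mu(1-\mu)/(\kappa+1)$; $\kappa = 120$ was derived from
  $E[\mu(1-\mu)] \approx 0.118$ under the default mixture to put the mean
  within-group variance at the observed $\sim 10^{-3}$ scale of consistent
  triplicate tissue arrays.
* **Differential CpGs** (default fraction 0.4, reflecting that near half of
  liver CpGs shift between fetus and adult) receive signed mean-scale
  effects: exponential magnitudes (mean 0.12, truncated at 0.6) so the
  delta-beta spectrum peaks near small values, with the adult mean higher
  with probability 0.72 (the observed adult hypermethylation excess); a
  fixed-magnitude mode exists for power studies. Means are clipped to
  [0.01, 0.99] to avoid degenerate Beta parameters, and the truth table
  records post-clipping means, so true delta beta is always exactly adult
  minus fetal.
* **Coupling.** A configurable fraction (default 5%) of genes with TSS/Ex1
  probes become adult-overexpressed with inverse promoter methylation: their
  TSS/Ex1 CpG fetal means are drawn from U(0.75, 0.98) and adult means from
  U(0.30, 0.50). The draw ranges are deliberately separated so every coupled
  gene is guaranteed a TSS/Ex1 CpG with $|d\beta| > 0.2$ (a wider
  hyper-to-intermediate box would allow coupled genes with sub-threshold
  effects and make truth bookkeeping ambiguous). Fetal-overexpressed genes
  (default 5%) get an expression effect only — mirroring the empirical
  asymmetry where fetal overexpression shows no distinctive methylation
  signature. The expression effect is 3 log2 units with N(0, 0.25²)
  per-sample noise on an N(7, 1.5²) baseline. With `fracDiffCpgs = 0` the
  methylome is fully null and no coupled genes are created.
* **Plumbing.** Region labels follow 450K-like proportions (Body-dominant);
  25% of probes are unannotated, 21% carry a regulatory-feature group, 2.5%
  sit on X/Y; detection failures are injected uniformly at random at 0.1%
  per cell (no failure structure is assumed). A single RNG stream under a
  mandatory seed makes output byte-reproducible.

**What it does not emulate** — and hence what passing tests do *not*
demonstrate about real arrays: Infinium I/II probe-chemistry differences,
batch effects, spatially correlated CpGs, cell-type mixture (fetal liver is
a hematopoietic organ; deconvolution is out of scope), multi-gene probes
(the generator assigns one gene per CpG; the multi-gene parsing paths are
exercised by hand-written annotation fixtures instead), and any dependence
structure between methylation noise across samples. Tests passing here show
the *procedures* are correct and calibrated under the declared model, not
that the model captures everything in deposited data.

## Validation problem sizes

The test suite and the acceptance script size their simulations to be
decisive but quick: 50,000 CpGs (3 vs 3) for the global-null type-I check
(fraction of raw p < 0.05 expected within 0.05 ± 0.015) and for the
sensitivity/FDR check under planted $|d\beta| = 0.3$ effects; 20,000 CpGs /
2,000 genes for end-to-end coupling recovery, where the estimated TSS/Ex1
decrease-to-adult-overexpression probability must fall inside the 95%
binomial interval of the generator's truth rate and strictly exceed the
UTR/GB analogue; 10,000 features for the moderation parameter-recovery and
ordinary-t-limit checks; 1,000 random vectors for BH exactness and 500
random tables for the chi-square closed form; 2,000 CpGs for the
byte-determinism rerun.

## Known limitations

Only two groups, fixed labels, and homoscedastic OLS within feature;
no surrogate-variable estimation (covariates must be supplied); annotation
coordinates are taken as given (no liftover), and region assignment trusts
the manifest labels rather than recomputing distances; the enrichment scorer
is a plain hypergeometric — pathway-topology or weighted statistics are not
provided; percentages in display tables are integer-rounded, so rows may sum
to 100 ± 1.
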