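# methexpress

Joint analysis of array DNA methylation and gene expression in two-group
designs — the canonical use case being small fetal-versus-adult tissue
comparisons profiled on an Illumina 450K-style methylation array (CpG beta
values) and a log2 expression microarray.

The package is aimed at analysts who have per-CpG beta values, detection
p-values, a manifest-style probe annotation and a matched expression matrix,
and who want to answer the question: *which methylation changes between the
two groups actually track with expression changes, and where on the gene do
they sit?*

## What it computes

**Differential testing.** Betas are logit-transformed to M-values,
`M = log2((β + o) / (1 − β + o))` with a small offset `o`, after a detection
p-value filter (p < 0.05 in **all** samples) and removal of X/Y probes. Each
feature is fit by per-row OLS on the group indicator (plus optional numeric
covariates), and variances are shrunk by empirical Bayes: the per-feature
sample variances s² with d residual df are modelled as draws from a scaled
F-distribution around a prior (d₀, s₀²), estimated by method of moments on
log s² (digamma/trigamma matching), giving posterior variances

    s̃² = (d₀·s₀² + d·s²) / (d₀ + d)

and a moderated statistic t = effect / √(s̃²·leverage) referred to a
t-distribution with d + d₀ df, followed by Benjamini–Hochberg FDR. Tests run
on the M scale; effect sizes are reported on the beta scale as
delta beta = adult mean − fetal mean. Expression uses the same machinery with
signed fold changes (+r fetal-higher, −r adult-higher, |r| ≥ 1).

**Region integration.** Manifest RefGene groups are collapsed into two
aggregate classes — TSS/Ex1 (TSS200, TSS1500, first exon) and UTR/GB (5'UTR,
gene body, 3'UTR) — and every (CpG, gene) pair joined with the gene's
expression class (fetal-overexpressed, adult-overexpressed, similarly
expressed, other). On top of that the package computes: the gene-level
methylation-versus-expression tables under the nested filter hierarchy
(significance / |dβ| > 0.2 / TSS-Ex1 restriction), contingency tables of
hypo/intermediate/hyper methylation (bins 0–0.3, 0.3–0.7, 0.7–1.0) by
expression context with Pearson chi-square tests, and prediction
probabilities: among q-significant CpGs with a fetal-to-adult methylation
decrease beyond 0.2 (or 0.5), the fraction lying on genes with ≥2-fold
(or ≥5-fold) adult overexpression — and the mirror-image statistics for
methylation increases.

**Calibrated enrichment.** A hypergeometric over-representation scorer whose
significance threshold is set empirically: k (default 5) size-matched control
gene lists are drawn from the similarly-expressed pool, and a query
enrichment counts as significant only when its p-value is strictly below the
minimum p observed across all control scores.

**Synthetic data with ground truth.** `simulateDataset()` generates the
whole input bundle — bimodal betas with per-CpG Beta(μκ, (1−μ)κ) noise
(within-group variance ≈ 10⁻³ at the default κ = 120), a configurable
differential fraction with a small-effect-dominated delta-beta spectrum,
manifest-style annotation, detection failures, and a subset of
adult-overexpressed genes whose TSS/Ex1 CpGs transition from fetal
hypermethylation to intermediate adult methylation — plus the complete truth
tables, so sensitivity, FDR and coupling recovery can be measured exactly.

## Worked example

```r
library(methexpress)

cfg  <- simulationConfig(nCpgs = 5000, nGenes = 800, seed = 42)
d    <- simulateDataset(cfg)
meth <- filterSexChromosomes(filterDetection(d$meth))
meth
#> MethylExperiment: 4843 CpGs x 6 samples (fetal=3, adult=3)
#> assays: beta, detectionP
#> annotation: CHR, MAPINFO, UCSC_RefGene_Name, UCSC_RefGene_Group, Regulatory_Feature_Group

dm    <- diffMethylation(meth)          # moderated t on M-values, BH q
de    <- diffExpression(d$expr)
links <- buildLinks(cpgAnnotation(meth))
rec   <- integrationRecords(dm, links, classifyExpression(de))

predictionProbability(rec, direction = "decrease", dbetaCut = 0.2, region = "TSS_EX1")
#>   direction dbeta_cut region_class n_cpgs  prob_ge2  prob_ge5
#> 1  decrease       0.2      TSS_EX1    132 0.6439394 0.6439394
predictionProbability(rec, direction = "decrease", dbetaCut = 0.2, region = "UTR_GB")
#>   direction dbeta_cut region_class n_cpgs  prob_ge2  prob_ge5
#> 1  decrease       0.2       UTR_GB     84 0.1190476 0.1190476
```

Reading: of the 132 TSS/Ex1 CpGs with a q-significant fetal-to-adult
methylation decrease larger than 0.2, 64% lie on genes with a q-significant
≥2-fold adult overexpression — the promoter-proximal inverse coupling the
generator planted — while gene-body/UTR CpGs carry much weaker signal (12%).
`varianceSummary(meth)` confirms the emulated array precision (mean
within-group per-CpG variance ≈ 0.001, >99% of CpGs below 0.01).

The end-to-end driver `runPipeline(pipelineConfig(inputDir, outputDir, seed))`
executes filter → transform → difftest → regions → integrate → enrich,
writing one TSV per output plus a JSON run manifest (versions, seed,
thresholds, input checksums, per-stage record counts); identical config and
seed reproduce every file byte for byte. A thin command-line wrapper lives at
`inst/scripts/methexpress.R` (`simulate` and `run` subcommands).

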