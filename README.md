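# bivalScore

Bivalent chromatin domains — promoter regions carrying both the activating
H3K4me3 and the repressive H3K27me3 histone marks — poise developmental
regulator genes for rapid activation or silencing when a pluripotent cell
commits to a lineage. `bivalScore` is an R/Bioconductor-style package for
calling enriched domains of each mark from ChIP-seq tags and scoring each
gene's bivalency, and for integrating those scores with a microarray
differential-expression stage and qPCR quantitation. It is aimed at
epigenomics analysts who want a transparent, fully testable implementation
of this workflow, exercisable end to end on synthetic data with planted
ground truth.

## The method

**Island calling.** Each chromosome is tiled with fixed windows of
*w* = 200 bp. With *N* tags on a genome of effective length *L·f*, the
background rate is λ = *N·w*/(*L·f*) tags per window, and a window with
*k* tags is *eligible* when the Poisson upper tail P(X ≥ k | λ) < p₀
(default p₀ = 0.2). Runs of eligible windows are linked into candidate
islands, bridging internal ineligible runs of at most *g*/*w* windows for a
gap size *g* ∈ {200, 400, 600, 800, 1000} bp. An island is scored

> S = Σ over eligible windows −ln P(X = kᵢ | λ),

and retained when S reaches a threshold calibrated by Monte-Carlo
simulation of pure-background genomes so that the expected number of
background islands is at most *E* = 0.1 (the E-value).

**Bivalency score.** For each gene the promoter interval TSS ± 2 kb is
intersected with the H3K4me3 and the H3K27me3 domain sets called at each
gap size; a gene is bivalent at a gap size when the interval overlaps at
least one domain of *each* mark. The bivalency score (0–5) counts the gap
sizes at which the gene is bivalent: 0 means never bivalent, 5 means
bivalent regardless of the gap size chosen.

**Expression and qPCR stages.** Probe-level intensities with per-value
standard errors are quantile normalised and background subtracted, then
tested per contrast with an error-weighted one-way ANOVA (weights 1/SE²;
with equal SEs it reduces exactly to ordinary ANOVA) and a
Benjamini–Hochberg FDR threshold of 0.05; fold changes are signed linear
ratios (−1.64 means 1.64-fold down). Relative transcript quantities follow
the comparative ΔΔCt method (RQ = 2^−ΔΔCt), and ChIP-qPCR enrichment is
reported as 2^(Ct_IgG − Ct_IP) fold over the IgG control, with a
percent-input alternative.

## Worked example

```r
library(bivalScore)
library(GenomicRanges)

layout <- makeGenome(2, 500000)                       # 1 Mb, two chromosomes
truth  <- plantTruth(layout, 5, 5, 5, 5, seed = 1)    # 20 genes, 4 classes
k4  <- simulateTags(truth, layout, "H3K4me3",  seed = 2)
k27 <- simulateTags(truth, layout, "H3K27me3", seed = 3)

callDomains(k4, layout, CallerParams(gapSize = 600))
#> DomainSet: H3K4me3 at gap 600 bp; 10 domain(s); lambda = 0.2996 ; kMin = 2 ; score threshold = 17.02

biv <- scoreBivalency(plantedGenes(truth), k4, k27, layout)
head(biv[order(-biv$score), ], 4)
#>     gene_id flag_g200 flag_g400 flag_g600 flag_g800 flag_g1000 score
#> 4  geneS004      TRUE      TRUE      TRUE      TRUE       TRUE     5
#> 10 geneS010      TRUE      TRUE      TRUE      TRUE       TRUE     5
#> 12 geneS012      TRUE      TRUE      TRUE      TRUE       TRUE     5
#> 1  geneS001     FALSE      TRUE      TRUE      TRUE       TRUE     4

table(planted = truthClasses(truth)[biv$gene_id], score = biv$score)
#>           score
#> planted    0 4 5
#>   bivalent 0 2 3
#>   k27_only 5 0 0
#>   k4_only  5 0 0
#>   unmarked 5 0 0
```

All ten planted H3K4me3 regions are recovered by called domains (none on
the background-only chromosome), every single-mark or unmarked gene scores
0, and the planted bivalent genes score 5 — or 4 when a marginal island
slips under the calibrated threshold at one extreme gap size.

The full pipeline (differential expression → day-2-specific set →
probe-to-gene collapse → bivalency → annotated report) runs from a YAML
configuration:

```r
cfg <- writeDemoInputs(tempfile("demo"), seed = 1)  # synthetic inputs + config
res <- runPipeline(cfg)
head(res$report, 3)
#>   gene_symbol      entrez_name fold_change        fdr_q bivalency_score is_tf
#> 1    geneS001 synthetic gene 1    2.771436 2.648585e-05               4  TRUE
#> 2    geneS002 synthetic gene 2   -2.606276 1.091913e-04               0 FALSE
#> 3    geneS003 synthetic gene 3    2.871067 2.437631e-05               4  TRUE
```

Each report row is a differentially expressed gene with its signed linear
fold change, FDR q-value, 0–5 bivalency score (NA when the gene was not
scored) and transcription-factor flag from the user-supplied annotation.

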