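---
title: "Bivalent domain calling and scoring: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bivalent domain calling and scoring: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bivalScore` implements a four-stage workflow: (i) island-style calling of
H3K4me3 and H3K27me3 enriched domains from ChIP-seq tags under a Poisson
background, at five gap sizes; (ii) a 0–5 per-gene bivalency score from
TSS ± 2 kb overlap with both marks' domains; (iii) an error-weighted
ANOVA / BH-FDR differential-expression stage for microarray intensities
with per-value standard errors; and (iv) comparative-Ct qPCR quantitation.
This vignette explains the models, the tunable parameters, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## The island model

Tags are counted into non-overlapping windows of `windowSize` = 200 bp.
The background assumes tags fall uniformly over the mappable genome, so
with `N` total tags on chromosomes of summed length `L` and effective
(mappable) fraction `f`, window counts are Poisson with rate
`lambda = N * w / (L * f)` tags per window. A window with `k` tags is
*eligible* when `P(X >= k | lambda) < p0`; eligible windows are linked
into candidate islands, bridging internal ineligible runs of at most
`g / w` windows; an island's score is the sum of `-log P(X = k_i | lambda)`
over its eligible windows (bridged windows contribute nothing, so the
score is additive and non-negative); and islands are kept when the score
reaches a threshold calibrated so that a pure-background genome yields at
most `E` islands in expectation.

Model assumptions worth stating plainly: a single genome-wide Poisson
rate (no input/control track, no local rate model, no copy-number or
mappability variation), independent windows, and tags already positioned
at the location to be counted (a strand-directed `shift` is available for
raw read BED files, default 0).

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `windowSize` | 200 | bp | tiling resolution of the Poisson model |
| `gapSize` | one of 200–1000 | bp | ineligible run length bridged inside an island |
| `eValue` | 0.1 | islands | expected background islands tolerated genome-wide |
| `p0` | 0.2 | probability | window eligibility tail threshold |
| `shift` | 0 | bp | strand-directed tag shift for raw reads |
| `effectiveFraction` | 1 (synthetic) | — | mappable genome fraction; ~0.74 is conventional for human |
| `mcReps` | 100 | — | Monte-Carlo calibration replicates |
| `flank` | 2000 | bp | promoter half-width around the TSS |

The window size, E-value and the five gap sizes are the published
parameterisation of this analysis; `p0 = 0.2` is the conventional
window-eligibility tail for this family of callers. The five gap sizes
are deliberately redundant: the bivalency score uses their disagreement
as a robustness measure.

### E-value calibration

The cited tool family computes its E-value threshold from an asymptotic
analytic approximation. We instead calibrate by direct Monte Carlo:
simulate `mcReps` Poisson background genomes of the observed size and
rate, form candidate islands exactly as the caller does, and take the
smallest *observed* score `s` such that the mean number of background
islands with score ≥ `s` is at most `E`. This choice trades a little
calibration variance for complete transparency — the null model used for
the threshold is, verbatim, the caller applied to background — and is
deterministic given the seed carried in `CallerParams`. Two edge cases
are well-defined rather than errors: if the entire candidate population
is already rare enough the threshold is 0 (no filtering), and if no
observed score qualifies the threshold sits just above the background
maximum. Because island scores are sums over integer counts they are
heavily tied; the threshold search respects ties, which makes the
realised background rate at the threshold at most `E`, often a little
below. The threshold is recalibrated for every gap size, since linking
changes the candidate-island population: thresholds rise with `g`, so a
marginal enrichment can pass at one gap size and fail at another —
exactly the instability the 0–5 score is designed to expose.

## The bivalency score

The promoter interval is read as the closed symmetric window
`[TSS - 2000, TSS + 2000]` — 4001 bases when not clipped at a chromosome
end; inclusivity is a convention we fix and record, since "± 2 kb" does
not state it. One TSS is used per gene (plus strand: leftmost base; minus
strand: rightmost); when a GTF supplies several records per gene they are
collapsed to the spanning range, which uses the 5'-most annotated start
on the coding strand, with a warning. A gene is bivalent at a gap size
when its window shares at least one base with a domain of *each* mark —
the two overlaps may be different domains at different ends of the
window, since the defining condition is that the promoter "contains
enriched domains for both marks", not that the domains be co-located.
No minimum-overlap fraction is applied. The score is the count of gap
sizes (0–5) at which the gene is bivalent; removing a gap size can only
lower or preserve it.

Coordinates are handled as 1-based closed `GRanges` throughout the
package, with BED's 0-based half-open convention converted at the
file boundary by `rtracklayer`; abutting intervals do not overlap under
either convention.

## The expression stage

Intensities are linear-scale with strictly positive values; per-value
standard errors accompany them. Background subtraction (per-sample mean
of negative-control probes, floored at 1 to keep ratios defined) precedes
quantile normalisation, mirroring the vendor order; both steps are
exposed separately so the order can be changed. Quantile normalisation
delegates to `limma::normalizeQuantiles` (ties averaged); standard errors
are rescaled by each value's normalisation ratio so relative precision is
preserved.

The test is a one-way ANOVA with observation weights `1 / SE^2`:
between- and within-group weighted sums of squares on `k - 1` and `N - k`
degrees of freedom, p-values from the F upper tail. Its compatibility
anchor is exact reduction to ordinary one-way ANOVA when all SEs are
equal, which the tests verify against `stats::oneway.test`. The
underlying assumption — observations Gaussian around their group mean
with the stated SE — matches the synthetic generator by construction,
which is what makes the null calibration checkable. Degenerate probes
with zero within-group variability are flagged and reported at p = 0
(p = 1 when the group means also coincide) rather than crashing.

Fold changes are signed linear ratios (`B/A` up, `-(A/B)` down, so
magnitude ≥ 1, matching mixed-sign microarray reporting conventions);
they are computed from the inverse-variance weighted group means, the
same means the test compares. BH adjustment (`stats::p.adjust`) is
applied within each contrast separately, because per-comparison
significant counts are the quantity of interest. The "timepoint-specific"
set defaults to probes significant in the focal contrast and in no other
supplied contrast; this is one reading of a "unique probe sets" summary,
so the rule is configurable (`intersection`, `union`) and the mode used
is recorded on the result. PCA (`stats::prcomp` on centred log2
intensities, samples as observations) is reporting-only.

## The qPCR stage

The comparative method fixes amplification efficiency at 2 per cycle;
replicates are averaged on the Ct scale before exponentiation, and
`RQ = 2^-ddCt` against an endogenous control and a calibrator sample
(whose RQ is 1 by construction, and which is invariant to any constant
shift of all Cts). ChIP enrichment is `2^(Ct_IgG - Ct_IP)` fold over the
IgG negative control; percent-input adjusts the input Ct by
`log2(1 / inputFraction)` first. No efficiency correction, melt-curve QC
or replicate outlier rejection is attempted.

## What the synthetic generator emulates — and what it does not

The generator plants, on a grid-aligned toy genome, enriched regions of
each mark around gene TSSs in four truth classes (bivalent, K4-only,
K27-only, unmarked), with window counts Poisson at the background rate
outside regions and `enrichmentFold` times that inside. Defaults — 1 Mb
genome over two chromosomes, 0.25 background tags per 200 bp window,
8-fold enrichment, 2 kb regions, 20 genes — describe a strongly marked,
cleanly separable regime: region centres sit on the window grid, slots
are spaced so promoter windows can never touch a neighbour's region, and
genes fill chromosomes in order so trailing chromosomes stay
background-only for false-positive checks. Expression matrices plant
log2 shifts of known sign in one group with SEs that are *exactly* the
noise scale used (scaled-chi heteroscedasticity across values), and Ct
tables encode a known relative quantity.

Passing tests on these data therefore demonstrate internal correctness —
the caller finds what its own model says is findable, the score
reproduces planted classes, the test statistics are calibrated when
their assumptions hold. They do not demonstrate robustness to what real
data add: fragment-shifted reads, duplicate tags, mappability and
copy-number structure, input-dependent local backgrounds, probe
cross-hybridisation, batch effects, or annotation ambiguity. Those are
deliberately out of scope; the `shift` parameter and the configurable
`effectiveFraction` are the only concessions to raw-data geometry.

Because planted regions are strong but finite (Poisson mean 20 tags per
region), a small fraction of planted bivalent genes score 4 rather than
5 — a marginal island falls below the rising threshold at `g = 1000` or
fragments at `g = 200`. This is the intended behaviour of the score, not
a defect: it is precisely the gap-size sensitivity the 0–5 scale
measures.

## Problem sizes and numerical conventions

The test and acceptance simulations use the default synthetic scale —
5,000 windows, 20 genes, 100 calibration replicates, 2,000 probes, and
10–20 seeded repetitions per property — sizes at which every stage's
expected behaviour is resolvable in seconds while keeping Monte-Carlo
error well inside the asserted bands. Determinism is enforced
throughout: every stochastic function takes a seed and restores the
caller's RNG state (`withr::with_seed`), and the pipeline writes
byte-identical reports when re-run with the same configuration.

Other conventions: window counting conserves tags exactly (shifted
positions are clamped to the chromosome); TSS windows are clipped, never
dropped, at chromosome ends; probe-to-gene collapse takes the smallest-q
probe with ties broken by larger absolute fold change then lexicographic
probe id; a gene absent from the bivalency table reports `NA`, which is
deliberately distinct from score 0 (never bivalent); and the pipeline
validates every configured path before any stage runs, then aborts with
the stage name on any downstream failure.

## Known limitations

The caller is a faithful parameterisation of the published analysis, not
a bit-exact clone of the cited tool — window p-value threshold, shift,
redundancy filtering and the analytic E-value machinery of that tool are
not reproduced, so domain-level agreement with its output on real data
is approximate. Gene-level scoring uses one TSS per gene; transcript
isoform resolution, CpG-island context and chromatin-state segmentation
are out of scope. The expression stage models neither probe annotation
nor gene-level summarisation beyond the best-probe collapse, and the
transcription-factor annotation joined into the final report is entirely
user-supplied.
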