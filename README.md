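# chromprime

Summit-anchored differential chromatin accessibility and lineage-priming
analysis for paired-condition ATAC-seq experiments, with ChIP-seq, motif and
expression integration and a fully synthetic validation harness.

## The problem

In conditional-induction experiments (e.g. a doxycycline-inducible mutant
transcription factor switched on at the endothelial–haematopoietic
transition), the question is how induction reshapes the open-chromatin
landscape and whether the newly accessible regions carry the chromatin
signature of specific mature blood lineages — *chromatin priming* — before
any expression program activates. This package implements the complete
downstream analysis for that design: it starts from peak calls and bedGraph
signal tracks and ends at a per-cell-type enrichment/depletion Z-score for
the condition-specific peak sets. It is aimed at computational biologists
who have run a standard upstream pipeline (alignment, peak calling) and
need the bespoke comparative statistics.

## The statistics at its core

**Differential accessibility.** Peaks from the −dox and +dox samples are
merged into a union whenever their summits lie within 400 bp (transitively;
the merged summit is the mean of member summits). Mean tag density in a
400-bp summit-centred window is normalised per sample as counts-per-million
(promoter-proximal and distal elements separately), and a peak is *gained*
when

    fold = (CPM₊ + 1) / (CPM₋ + 1) ≥ 2,

*lost* when fold ≤ 1/2, *shared* otherwise.

**Motif enrichment.** For motif *i* in peak set *j* with `n_ij` motif-bearing
sites out of `m_j`,

    S_ij = (n_ij / m_j) / (Σ_j n_ij / Σ_j m_j),

the per-set frequency over the pooled frequency; `S = 1` means no
enrichment, and each motif's `m_j`-weighted row mean is exactly 1.

**Lineage priming.** A cell type's signature is the set of peaks
reproducible in all of its replicates and absent from every other cell
type. With `x` the number of condition-specific distal peaks overlapping a
signature, the null is built by drawing matched-size peak sets uniformly
without replacement from the full distal universe (gained + lost + shared),
1,000 times by default:

    z = (x − μ) / σ,

with μ, σ the mean and SD of the resampled overlap counts;
`p_enrich` is the fraction of resamples whose count exceeds `x` (and
`p_deplete` the fraction below). Sampling without replacement makes the
null count exactly hypergeometric, which the test suite exploits as an
independent oracle.

## Worked example

Twenty distal peaks, five of them carrying a signature; a test set of
eight condition-specific peaks of which four overlap the signature:

```r
library(chromprime)
universe  <- peak_set("chrS", (0:19) * 1000, (0:19) * 1000 + 400)
signature <- peak_set("chrS", (0:4) * 1000 + 100, (0:4) * 1000 + 200)
test <- universe[c(1:4, 10:13), ]; class(test) <- class(universe)
priming_test(test, universe, signature, n_resamples = 10000, seed = 42)
#>  x     mu     sigma        z p_enrich p_deplete n_resamples seed degenerate
#>  4 2.0094 0.9763768 2.038762   0.0033      0.94       10000   42      FALSE
```

The exact hypergeometric null for this instance has μ = 2, σ = 0.9733 and
z = 2.055 — the resampled values agree to Monte-Carlo precision, and
`p_enrich` matches the exact strict tail P(count > 4) = 0.0036: the
signature is over-represented in the test set.

The motif score and the twofold call on small hand examples:

```r
enrichment_scores(motif_counts(matrix(c(5, 0), 1,
                  dimnames = list("RUNX", c("gained", "lost"))), m = c(10, 10)))
#>      gained lost
#> RUNX      2    0
call_differential(cpm_minus = c(10, 30, 50), cpm_plus = c(40, 20, 20))
#>  cpm_minus cpm_plus log2_minus log2_plus      fold  class
#>         10       40   3.459432  5.357552 3.7272727 gained
#>         30       20   4.954196  4.392317 0.6774194 shared
#>         50       20   5.672425  4.392317 0.4117647   lost
```

## The analysis workflow

The `analysis/` directory is a numbered end-to-end run on synthetic data
(written under `results/analysis/`): `01_simulate.R` generates a replicated
five-cell-type atlas, a paired −dox/+dox experiment with a fourfold planted
accessibility change and 40% of gained peaks placed on the megakaryocyte
signature, and DE tables; `02`–`06` then run union/differential calling,
motif scoring, ChIP integration, expression integration and the priming
panel, each reading only the files the previous stages wrote. A single
configurable orchestrator, `run_pipeline()`, runs the same stages from one
seed and writes a manifest of MD5-hashed outputs plus a structured run log.

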