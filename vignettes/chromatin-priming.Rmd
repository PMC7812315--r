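---
title: "Methods: summit-anchored differential accessibility and the lineage-priming test"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summit-anchored differential accessibility and the lineage-priming test}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromprime)
```

# Scope and model

`chromprime` implements the downstream comparative analysis of a
paired-condition (−dox/+dox) chromatin-accessibility experiment. Everything
is anchored on peak *summits*: the single-base position of maximal signal
within a called peak. The pipeline assumes that upstream processing
(alignment, deduplication, peak calling, blacklist files) has already
produced BED-family peak calls and bedGraph signal tracks; those formats are
the package's input contract, and `filter_blacklist()` is provided for the
artefact-removal step.

Coordinates are 0-based and half-open throughout (BED convention), and
*overlap* always means at least one shared base — the `bedtools intersect`
default — in every operation that counts or filters by overlap.

## Differential accessibility

1. **Union construction** (`build_peak_union`). Peaks whose summits lie
   within `summit_distance` (default 400 bp) on one chromosome merge
   *transitively*, i.e. with `bedtools merge` chain semantics. The merged
   summit is the floor of the mean of all member summits; for two peaks this
   is the midpoint between the original summits, and the chain rule is the
   natural n-peak extension of that two-peak definition. The merged interval
   spans min start to max end.
2. **Quantification** (`window_tag_density`). Mean bedGraph density over the
   half-open window `[summit − w/2, summit + w/2)`, `w` = 400 bp by default.
   Windows truncated at position 0 keep divisor `w` — off-chromosome bases
   count as zero coverage — which is the simplest contract consistent with
   "uncovered means zero".
3. **Normalisation** (`cpm_log_normalize`). Each sample column is scaled to
   sum to 10^6 (CPM), then log-transformed as log2(CPM + 1). Promoter-proximal
   peaks (summit within 1.5 kb of a TSS, boundary inclusive) and distal peaks
   are normalised and analysed *separately*, since the two element classes
   behave differently and are kept apart in all downstream steps.
4. **Calling** (`call_differential`). `fold = (CPM₊ + 1)/(CPM₋ + 1)`;
   gained iff fold ≥ 2, lost iff fold ≤ 1/2. The pseudocount of 1 CPM makes
   zero-coverage peaks well defined; the boundary counts as differential
   ("at least twofold"). Because the rule is a deterministic function of the
   two CPM columns, swapping the conditions swaps gained and lost labels
   exactly — a property the test suite asserts.

Absolute CPM values depend on how the upstream tool scaled its bedGraphs;
the module accepts any non-negative track and only the *ratios* are
interpreted.

ChIP integration reuses this machinery verbatim (`differential_chip` is the
same code path), with the window width taken from a per-mark configuration:
400 bp for point-source factors, 800 bp for broad marks such as H3K27ac so
that signal flanking the open-chromatin site is counted. Windows are always
centred on the ATAC union summit. "Within open chromatin" is interpreted as
any-base overlap with an ATAC peak, not summit containment.

## Motif enrichment score

For motif $i$ in peak set $j$, $S_{ij} = (n_{ij}/m_j) / (\sum_j n_{ij} /
\sum_j m_j)$: the per-set motif frequency over the pooled frequency.
Algebraically this forces $\sum_j m_j S_{ij} / \sum_j m_j = 1$ for every
motif (asserted to 10⁻⁹ on random inputs) and makes $S$ invariant to
multiplying all counts and set sizes by a constant. Motifs observed in no
set are dropped with a warning rather than producing 0/0. Motif discovery
and scanning are out of scope; `aggregate_motif_hits()` accepts any
scanner's per-peak binary calls. For display, `score_zscale()` offers
per-row z-scaling; the raw $S$ matrix is always the quantitative output.
Hierarchical clusterings here and elsewhere use complete linkage on
Euclidean distances (`stats::hclust`), with ties resolved by the
deterministic agglomeration sequence, so equal inputs give equal leaf
orders.

## The lineage-priming test

Cell-type signatures are derived in two steps: a peak is *reproducible* for
a cell type when the first replicate's peak overlaps every other replicate,
and *specific* when it has zero overlap with the union of all other cell
types' reproducible peaks. Specific sets are therefore exclusive by
construction.

`priming_test()` takes a condition-specific distal peak set (size $n$), the
full distal universe (size $N$; gained, lost and shared peaks alike) and a
signature. The observed statistic $x$ counts *test peaks* that overlap the
signature (each once, ≥1 bp rule). The null resamples $n$ distinct peaks
uniformly from the universe — **without replacement**, since the resample
emulates drawing an alternative peak *set* of the same size; this choice
also makes the null count exactly hypergeometric
($\mu = nK/N$, $\sigma^2 = nK/N(1-K/N)(N-n)/(N-1)$ with $K$ the number of
signature-overlapping universe peaks), which the tests use as an
independent oracle. Then

$$z = \frac{x - \mu}{\sigma},\qquad
p_\text{enrich} = \frac{\#\{c > x\}}{R},\qquad
p_\text{deplete} = \frac{\#\{c < x\}}{R}$$

over the $R$ resampled counts $c$ (default $R = 1000$), with $\sigma$ the
*population* SD (divisor $R$). The strict inequalities follow the
definition of the procedure; they make the empirical p conservative at 0
for ties, and an add-one smoothed variant
$(\#\{c \ge x\}+1)/(R+1)$ is available behind `smoothed = TRUE` for users
who need $p > 0$. When every resample yields the same count ($\sigma = 0$,
e.g. signature equal to or disjoint from the universe) the result is
flagged `degenerate` and $z$ is `NA` rather than ±∞.

`priming_panel()` runs the test for the gained and lost distal sets against
every signature. Each test's RNG stream is seeded by an FNV-1a hash of the
master seed and the (condition, class, cell type) labels, so adding a cell
type never perturbs the other tests' draws, and empty classes are emitted
as rows flagged `absent` instead of silently disappearing.

## Expression integration

Genes are kept when any sample has ≥ 50 reads. Trajectory classification
across the two conditions uses linear folds with threshold 2: up iff fold ≥
2, down iff fold ≤ 1/2, giving seven categories (up/down in both, up/down
in one condition only, unchanged). The classification is exhaustive and
exclusive, which forces a decision for *discordant* genes (up in one
condition, down in the other): `classify_trajectory()` assigns them to the
condition with the larger |log2 fold|, and on a tie to the up-regulated
side — the only tie rule that keeps the classification exactly symmetric
under swapping the conditions, a property the tests assert. Figure-style
counting, where a discordant gene contributes to both per-condition
tallies, is provided separately as `trajectory_tallies()`; the two
conventions are deliberately kept in separate functions rather than
overloading one.

Deregulation for overlap and correlation analyses uses |fold| ≥ 2 together
with adjusted p < 0.05 when an `adj_p` column is present, and the fold rule
alone when it is not. Fold-change correlation across contrasts is computed
over the union of deregulated genes, imputing log2fc = 0 for genes missing
from a contrast (keeping a common feature space); `drop_missing = TRUE`
restricts to shared genes instead.

# The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline is validated.

* `simulate_atlas()` — 5 cell types × 2,000 peaks each by default, 30%
  exclusive per type, two replicates with 5% independent dropout, placed
  without overlap on a single 100-Mb synthetic chromosome `chrS`. A single
  chromosome keeps fixtures simple while exercising all interval code; a
  second chromosome is covered by dedicated tests.
* `simulate_experiment()` — a 10,000-peak universe with 10% gained and 10%
  lost peaks at a planted fourfold density change. Noise is multiplicative
  log-normal with CV 0.2 per sample (log-normal keeps densities strictly
  positive and the CV parameterisation is the natural scale-free knob).
  Signature structure: `signature_enrichment` places an exact fraction of
  gained peaks on a named cell type's exclusive atlas peaks (the planted
  truth for the priming test), while every class also carries each
  signature at a background rate of `sig_background_rate / n_celltypes`
  per type (default 10%/5 = 2%), so roughly 10% of the universe is
  signature-bearing overall. The background is stratified by class on
  purpose: it keeps non-planted signatures at the universe-level rate
  inside the gained and lost sets, so they are true nulls for the priming
  test. Synthetic TSSs are placed more than 2 kb from every peak, making
  the default universe all-distal (promoter classification is exercised by
  dedicated fixtures instead).
* `simulate_motifs()` — per-set binomial hit counts with uniform positions
  inside carrier peaks; `simulate_de_tables()` — noiseless planted
  trajectories with exact category mixes.

What the generator does **not** emulate: read-level data (fragment-length
and Tn5 insertion models, GC bias), realistic peak-width and signal-shape
variation, correlated replicate noise, multi-chromosome genomes, or any
covariate structure (GC, distance-to-gene) in the signature overlap.
Passing the planted-recovery tests therefore demonstrates that the
*computations* are correct under the stated statistical structure, not that
the thresholds are optimal for any particular real dataset.

# Numerical and design choices

* Merged summits, midpoint fallbacks and mean summits are floored to whole
  bases.
* Nearest-gene ties (equidistant TSSs, or several genes at one TSS) go to
  the lexicographically smallest `gene_id`; strand is carried but ignored
  for distance. Peaks on gene-less chromosomes map to `"unassigned"`.
* CPM column sums are exact to 10⁻⁶ relative tolerance; zero-sum columns
  are an error naming the sample, as is a zero-variance sample in
  correlation clustering.
* UpSet-style shared-site counts are *exclusive* combinations of a
  designated base set, so they partition it exactly.
* All generators and tests are seed-deterministic; generator functions
  save and restore the caller's RNG state.

# Problem sizes

The validation suite runs the worked resampling instance at 10⁵ resamples
against the exact hypergeometric oracle; planted priming recovery at the
full default scale (10,000-peak universe, 1,000 resamples, ten seeds); null
calibration over 200 uniform tests on a 2,000-peak universe; the
union-versus-brute-force comparison on 100 random sets with summit gaps
concentrated around the 400-bp threshold; and end-to-end determinism on a
reduced configuration (400-peak universe, 100 resamples). These sizes were
chosen so the whole suite completes in well under two minutes while keeping
every statistical check at meaningful power.

# Known limitations

* The differential call is a plain fold rule, faithful to the analysis it
  implements; it has no replicate-aware variance model (use DESeq2/limma
  for that) and therefore no per-peak significance.
* The priming null is uniform over the distal universe — no GC, width or
  distance matching of the resampled sets.
* ChIP replicate structure is not modelled (single track per condition);
  input/IgG normalisation is out of scope.
* bedGraph absolute scale is taken as given; only ratios are meaningful.
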