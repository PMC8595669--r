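---
title: "Quantifying 3D-genome reprogramming: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D-genome reprogramming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicreprog)
```

## The problem

When a somatic nucleus is reprogrammed to pluripotency — by nuclear
transfer into an enucleated oocyte (yielding ntESCs) or by transcription
factors (yielding iPSCs) — its three-dimensional genome must be rebuilt
into an embryonic-stem-cell-like state at three nested scales: megabase
A/B compartments, topologically associating domains (TADs), and focal
chromatin loops. Reprogramming is incomplete: some regions resist the
switch, some stall at intermediate states, and some overshoot. This
package provides the quantitative machinery to measure that process from
binned Hi-C contact maps and ATAC-seq peak intensities, to classify each
changed region into a four-class taxonomy (reprogrammed / partial / hyper
/ resistant), to relate resistant structures to the heterochromatin mark
H3K9me3, and to contrast the nuclear-transfer and iPSC routes.

Because the full analysis normally requires deep sequencing data, the
package ships a synthetic-data generator that plants known structure at
every level. Every claim the test suite makes is checked against planted
truth or an independent oracle.

## Contact-map preprocessing

A `ContactMatrix` is a symmetric per-chromosome map at a fixed bin width
(200 kb for compartments, 40 kb for insulation/TADs, 20 kb or 5 kb for
loops). Preprocessing follows the standard sequence:

1. **Masking.** Bins with zero marginal count, or a marginal below the 1st
   percentile of the nonzero marginals, are excluded (`mask_low_coverage`).
   The percentile is configurable; the source analyses do not state their
   filter, so a conservative default was chosen once.
2. **Balancing.** Iterative correction (`balance_matrix`): alternate
   row/column scaling on the unmasked submatrix until the variance of the
   normalised row sums drops below `tol = 1e-5` (at most 200 sweeps). The
   multiplicative bias vector is kept, so the raw matrix is recoverable to
   machine precision. Non-convergence yields a warning and a best-effort
   result, never a silent failure.
3. **Distance normalisation.** `expected_profile` averages contacts per
   separation over unmasked pairs; `observed_over_expected` divides each
   pixel by the expected value at its separation. Where the expected value
   is zero or undefined the O/E entry is 0 rather than NaN.

A caveat worth knowing: iterative correction recovers planted biases
exactly only when the bias-free matrix has equal row sums. A linear
chromosome with a power-law decay does not (edge bins see fewer
neighbours), so the classic "balance, then O/E equals one" identity holds
exactly only on circulant (wrap-around) test matrices; the test suite
constructs exactly that case for its closed-form check.

The contact-decay curve (`contact_decay_curve`) aggregates the expected
profile into log-spaced separation bins and normalises the curve to unit
sum, which makes libraries of different depth comparable at fixed
separations (e.g. 80 kb vs 400 kb, where donor cells and ESCs differ in
opposite directions).

## Compartments

Compartment calling is the textbook eigenvector procedure: Pearson
correlation matrix of the O/E map over unmasked bins
(`pearson_oe_matrix`), then the unit-norm leading principal component of
the column-centred correlation matrix (`compute_pc1`). The eigenvector
sign is arbitrary, so `orient_and_call` flips it, when needed, to
correlate positively with an activity reference (gene density or ATAC
coverage binned at 200 kb); A is assigned to positive PC1, B to negative,
and exact zeros are left unassigned. If PC1 barely correlates with
activity (|r| < 0.2) while PC2 correlates better — the classic
arm-tracking failure — `call_compartments` substitutes PC2 and says so.

Compartmentalisation strength uses the saddle construction
(`compartment_strength`): bins are ranked by PC1 into quantiles and the
mean O/E among (top, top) and (bottom, bottom) pairs is divided by the
(top, bottom) mean. On the generator's plaid model with within-type
enrichment $w$ and between-type enrichment $1/w$ the analytic value is
$w^2$ (4 at the default $w = 2$) — a useful calibration because the ratio
is invariant to the per-diagonal contamination that affects each term
individually.

### Switches and the four-class taxonomy

`call_switches` takes the donor track and two lines each of ntESC and
fESC. The ESC state is defined only where both fESC lines agree in PC1
sign; condition PC1 values are the mean of the two lines (lines are never
pooled at the matrix level). Each bin is labelled stable, A-to-B or
B-to-A, runs of identical labels merge into regions, and percentages are
reported over defined bins.

For a switched region, the progress of the ntESC along the donor-to-fESC
trajectory is
$$r = \frac{\mathrm{PC1}_{nt} - \mathrm{PC1}_{cc}}{\mathrm{PC1}_{f} - \mathrm{PC1}_{cc}},$$
and `classify_dynamics` assigns, with boundary half-width `delta = 0.15`:
**Resis** when $r \le \delta$ *or* the ntESC still carries the donor sign;
**Hyper** when $r > 1 + \delta$; **Repro** when
$1 - \delta < r \le 1 + \delta$; **Partial** otherwise. The sign clause
makes the rule faithful to the state-based definition of resistance (the
ntESC shows the donor state), and it has a consequence for simulation
design discussed below. `delta` has no published value; 0.15 is the
package default and is exposed everywhere.

### Comparing the NT and iPSC routes

`compare_processes` works on five tracks: donor (CC), MEF, ntESC, iPSC
and a consensus ESC reference (bins where fESC and a standard ESC line
agree, `consensus_track`). A process "switches" a bin when its donor state
differs from the ESC state and its product cell reaches the ESC state.
Bins switching in both processes are `common`; the rest are NT- or
iPSC-specific and subdivided into `donor-specific` (CC and MEF states
already differ) versus `method-specific` (same starting state, different
outcome between ntESC and iPSC).

## TADs

Insulation scores (`insulation_track`) use the sliding-diamond
construction at 40 kb with a 480 kb window (12 bins): the mean contact
between the `w` bins on either side of a bin, log2-normalised by the
chromosome-wide mean diamond, hence scale-invariant and centred near 0.
Boundaries (`call_boundaries`) are local minima whose contrast — the mean
of the two nearest flanking local maxima minus the minimum — reaches
`min_delta = 0.1`; minima within 2 bins merge, keeping the deeper.
Consecutive boundaries delimit TADs; domains under 3 bins are dropped.
For cross-condition comparisons, `consensus_boundaries` pools boundary
sets (support in at least 2 conditions within one bin) so that intensity
triples are computed over identical intervals.

Relative TAD intensity (`relative_tad_intensity`) is the mean O/E inside
the TAD square over the mean O/E of the TAD-versus-flank rectangles,
with flank length equal to the TAD length (truncated at chromosome ends).
It is 1 on structureless maps and monotone in the planted intra/inter
ratio. Note that on a simulated chromosome where planted domains cover a
large fraction of the short-range diagonals, the estimated expected
profile absorbs part of the domain signal and RTI reads below the planted
ratio; the calibration tests therefore construct the O/E map directly
(intra pixels at the planted ratio), which isolates the RTI formula from
expected-profile estimation — a distinction that matters when comparing
absolute RTI values across datasets.

TAD dynamics reuse the $r$ statistic on RTI triples, with a preceding
Static gate: $|\log_2(\mathrm{RTI}_{cc}/\mathrm{RTI}_{f})| < \log_2(1.5)$.
There is no Partial group for TADs; mid-trajectory values resolve to the
nearer of Resis/Repro at $r = 0.5$. Condition-specific TADs use a simple
fold rule (`specific_tads`, default 1.5x).

## Loops

`call_loops` is a desk-scale reimplementation of the donut-background
approach: for each pixel in the 100 kb–2 Mb band, four local
neighbourhoods (donut with radii 3–7 bins, lower-left quadrant,
horizontal and vertical stripes, all excluding the centre 3×3) each give
an expected count — the distance-decay expectation at the pixel scaled by
the neighbourhood's observed/expected ratio — and the pixel's Poisson
upper-tail p-value is taken against the largest of the four. Three
choices deserve explanation:

* **FDR within λ-chunks.** The expected count spans more than a decade
  across the band. A single band-wide Benjamini–Hochberg pass lets the
  shallow far-distance chunks ride on the many discoveries made in the
  deep short-distance chunks, producing isolated far-distance false
  positives at exactly the rate FDR arithmetic predicts. Adjusting within
  log2-width-1/3 chunks of the expected count — as the cited method's
  published implementation does — restores per-regime error control.
* **Singleton rule.** Clusters (8-connectivity over significant pixels)
  of size one are kept only below `fdr/5`. Bin-spanning focal peaks
  produce multi-pixel clusters; isolated single pixels are
  disproportionately counting noise.
* **Poisson on raw counts.** The test runs on counts, not balanced
  values, because the Poisson model is only calibrated for counts; the
  balanced O/E map is used downstream for APA.

Aggregate peak analysis (`apa_score`) averages (2k+1)×(2k+1) O/E windows
(k = 5) over loop pixels and scores the centre against the mean of the
3×3 lower-left corner. Per-loop cross-condition comparisons use the focal
enrichment (pixel over local background, `loop_enrichment`) evaluated on
a union loop list, not per-loop APA; APA is reserved for set-level
summaries. Loop dynamics reuse the TAD rule, plus the set-level
categories "CC-specific disappeared" and "ESC-like gained".

## ATAC peaks

`normalize_peak_matrix` scales samples to counts-per-million within
peaks, log2(x+1)-transforms, and keeps a per-peak z-score view for
clustering. The z-scores are *moderated*: the row standard deviation is
floored at the median row standard deviation. Without the floor, peaks
that are open in every cell type (a flat intensity row) have their noise
amplified to unit scale and scatter across clusters — with it, the flat
archetype stays compact and K-means recovers it cleanly.

`kmeans_clusters` (k = 3, 10 restarts, fixed seed) is followed by
*semantic* relabelling from cluster centre means — C1 = open in all
(highest minimum per-sample mean), C2 = donor-specific (largest
donor-vs-ESC contrast), C3 = ESC-specific (remainder) — so labels never
depend on K-means' arbitrary cluster indices. `differential_esc_peaks`
then splits C3: Welch t-tests on log2 intensities between the two fESC
and two ntESC samples, with |fold| ≥ 2 and p < 0.05, yield C4
(fESC-higher) and C5 (ntESC-higher). With two samples per group the
Welch test is underpowered by design; the planted 2-log2-unit contrast
at σ = 0.1 is detected with sensitivity above 0.9, which is the regime
the thresholds were chosen for. Peak genomic context
(`annotate_peaks`) classifies the peak centre (or summit) with precedence
promoter > exon > intron > intergenic, where promoters are TSS ± 1 kb
(strand-aware, 0-based half-open).

## H3K9me3 marking and expression

`bin_signal` converts a ChIP/Input bedGraph to length-weighted per-bin
means. A region is H3K9me3-marked (`mark_regions`) when at least half of
its defined bins have ratio ≥ 2; both thresholds are configurable
substitutes for criteria published elsewhere, and marking is monotone in
both. Group comparisons (`group_intensity_compare`) are two-sided
Wilcoxon rank-sum tests with the three-band star convention
(\*\*\* ≤ 0.0005 < \*\* ≤ 0.005 < \* ≤ 0.05). Genes map to regions by TSS
only (`expression_by_structure`, `degs_in_abnormal`); half-open interval
convention means a TSS at a region's end coordinate is outside it. DEG
calling itself is out of scope — the package consumes an externally
computed list.

## The synthetic world

`sim_config` fixes the generator's stated world; `simulate_*` functions
derive data from truth, never the reverse. Key defaults:

* One synthetic chromosome: 600 bins × 200 kb for compartments, 1500
  bins × 40 kb for TADs. Depth is set so the median expected pixel count
  in the analysis band is ~5; decay exponent α = 1.
* Plaid: alternating compartment blocks (mean 10 bins), within-type
  enrichment 2, between-type 1/2. Per-bin compartment values are signed
  and continuous, so condition trajectories (Partial at the midpoint,
  Hyper at 1.4× the fESC value, Resis at the donor value) translate into
  the plaid factor $w^{v_i v_j}$.
* Line pairs (NT5/NT6, F35/F40) are independent Poisson draws from the
  same condition mean.
* Loops: 20 anchors with log-normal separations (median ~300 kb,
  truncated to the 100 kb–2 Mb band, matching published loop-size
  distributions) at 2.5× focal enrichment over the 3×3 pixel vicinity —
  at bin-sized anchors a punctate peak bleeds into adjacent pixels,
  which is precisely why donut callers exclude the centre 3×3.
* ATAC archetypes (log2 units over CC, NT5, NT6, F35, F40): C1
  (6,6,6,6,6), C2 (7,1,1,1,1), C3 (1,6,6,6,6), C4 (1,3,3,5,5), C5
  (1,5,5,3,3); noise σ = 0.1; sample depths deliberately unequal to
  exercise CPM normalisation.
* ChIP/Input ratios are log-normal, mean 3 in marked regions and 1
  elsewhere (σ = 0.2); expression plants the resistant-A-to-B contrast
  (ESC conditions at a quarter of donor level).

One generator choice needs justification. In
`simulate_dynamics_records`, donor and fESC PC1 magnitudes are
asymmetric (0.4 vs 0.8). A Partial compartment is *defined* as
intermediate with the ESC sign; with symmetric magnitudes a planted
mid-trajectory Partial sits exactly at PC1 = 0 and keeps the donor sign
half the time — i.e. it is genuinely resistant in the emitted world, and
no classifier could (or should) recover the intended label. Truth-first
generation requires every planted label to be realizable, so the zero
crossing is placed below the mid-trajectory point. PC1 magnitude carries
no absolute physical scale (eigenvectors are norm-conventions), so this
is a labelling-consistency constraint, not a biological claim.

### What a green test does not establish

The generator emulates statistical structure, not biology: a single
artificial chromosome, exact power-law decay, block-constant
compartments, non-overlapping rectangular TADs, independent Poisson
noise, and (optionally) smooth log-normal bin biases. Real data add
translocations, copy-number variation, mappability artefacts,
condition-dependent decay shapes, nested and overlapping domains, and
correlated noise. Recovery rates measured here are therefore upper bounds
on real-data performance, and parameter defaults (insulation window,
`delta`, fold thresholds, marking thresholds) remain substitutes for
unpublished originals — they reproduce the *logic* of the source
analyses, not their exact numbers.

## Numerical notes

* Ties and zeros: PC1 exactly 0 → state NA; `classify_dynamics` skips
  records with identical donor and fESC values (undefined trajectory)
  with a warning; Wilcoxon p-values fall back to the normal approximation
  when ties prevent exact computation (via `stats::wilcox.test`).
* Degenerate inputs error early and descriptively: all-masked matrices,
  uniform correlation matrices ("no principal axis"), zero-variance
  activity tracks, empty loop lists, all-zero sample columns.
* Determinism: every stochastic routine takes a seed (`sim_config`,
  `kmeans_clusters`), and fixed seeds give byte-identical outputs.
* All disk formats are plain text, 0-based half-open (BED convention);
  bin indices in triplet files are 0-based, R-internal indices 1-based.
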