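---
title: "Calling and classifying temporally dynamic A/B compartments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling and classifying temporally dynamic A/B compartments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compdyn)
```

## The problem

Chromosomes partition into two alternating classes of spatial compartments:
A (active, open chromatin) and B (inactive). The classes are read off the
sign of the leading eigenvector of the bin-bin correlation matrix of a
balanced, observed/expected-normalised contact map. `compdyn` implements
this call at a fixed bin size (default 100 Kb) and, on top of it, a
classification of how compartments change across a five-timepoint hormone
stimulation course (T0, T1, T4, T16, T24 hours of estradiol treatment of an
ER-positive breast cancer cell line) and in a tamoxifen-resistant derivative
(TamR). Everything downstream of binned contact matrices is covered; read
mapping, fragment-level filtering, peak calling, ChromHMM training and loop
calling are consumed as inputs, not recomputed.

All coordinates in the package are 0-based half-open (BED-native), a
convention chosen once and applied everywhere because mixing conventions is
the classic source of off-by-one-bin errors in this kind of analysis.
Chromosome names are never normalised; they must match the declared genome
layout exactly.

## Compartment calling

The matrix pipeline is `filter_bins()` (mask bins with less than half of
their length sequenced, then the lowest 1% of remaining bins by marginal
count), `truncate_trans_outliers()` (clamp the top 0.05% of
interchromosomal counts, which are likely PCR blowouts, to the quantile
value), `ice_balance()` (iterative correction until every unmasked row sum
is within `1e-5` relative of their common mean; the tolerance is our
numerical choice, small enough that further iterations change labels
nowhere), and `compartment_eigenvector()`.

The eigenvector step removes the diagonal, converts to observed/expected
using the product of trans marginals as the expectation, and computes the
leading eigenvector of the bin-bin correlation matrix. Two modes are
exposed:

* `trans_only` (default): cis cells are excluded pairwise from the
  correlation. A correlation entry between bins on two different
  chromosomes is only defined when a third chromosome supplies shared rows;
  for two-chromosome layouts the undefined entries are filled from the
  cis-faked correlation and the result should be treated with caution.
* `faked_cis`: cis cells are replaced by their trans-derived expectation
  (observed/expected = 1) before the correlation. This reading of an
  ambiguous "fake the cis contacts" step is fixed by contract: both modes
  must agree on planted data, and the test suite checks that they do.

The sign of an eigenvector is arbitrary. Because a silent global flip
relabels every compartment, `compartment_eigenvector()` refuses to guess:
it either receives an `orientation_track` (any per-bin activity proxy —
gene density, coverage, a known label indicator) and orients the positive
class to the higher track mean, or it marks the output unoriented. Bins
with positive values are A, negative B; maximal same-label runs become
compartments (`segment_compartments()`), and single-bin compartments are
kept because the downstream shift granularity is one bin.

Two degenerate inputs are rejected rather than silently handled: constant
matrices (no variance, no compartments) and chromosomes with fewer than
`min_bins_per_chrom` (default 10) unmasked bins, where a leading
eigenvector is numerically meaningless.

## The 24-pattern / six-type classification

`match_compartments()` compares a reference segmentation with another
timepoint: a compartment is **Common** when the best same-type overlap has
the identical span, otherwise **Transit** with a shift of
`max(|delta start|, |delta end|)`; a compartment whose footprint majority
changes sign is **flipped**. A **converted bin** is a footprint bin whose
A/B label differs between the two tracks — the minimal operational
definition consistent with both boundary shifts and flips producing
converted bins. Ties in the overlap matching go to the leftmost candidate,
for determinism.

`classify_timeline()` builds, per T0 compartment, the status vector of the
four comparisons (T0 vs T1, T4, T16, T24). The 2^4 = 16 status sets yield
15 patterns directly; the all-Transit set is subdivided into 9 further
patterns by the converted-bin count, giving 24 patterns in six types of
four: HCC (highly common), ETC (early transit), LTC (late transit), LDC
(lowly dynamic), MDC (moderately dynamic), HDC (highly dynamic). The
mapping of the 15 sets to pattern numbers and the converted-bin class edges
(`1, 3, 5, 7, 9, 12, 15, 19`) are exposed as an overridable constant
(`pattern_table()`): they reproduce the published structure — 16 sets,
15 + 9 = 24 patterns, six types, and 4^4 = 256 combinations when each
timepoint additionally carries its A/B identity — but the exact ordering
within types is our canonical choice, flagged for revision should a
definitive table become available. An all-Transit compartment with zero
converted bins (a pure boundary shift outside the footprint) falls into the
lowest class (pattern 16).

`call_trac()` then compares each compartment footprint against the
resistant-condition segmentation: a compartment is a TRAC
(tamoxifen-resistant altered compartment) iff its timeline includes a
Transit status and at least one footprint bin is converted in TamR;
otherwise a TRUC. The T0 footprint is the reference because the resistant
cells are asynchronous and untreated. Change classes are Shrunk/Expanded
(matched TamR segment at least two bins shorter/longer), Flipped (majority
sign change), else Other.

## Differential statistics

`eigen_variance()` computes, per compartment, the variance of its five
per-timepoint mean eigenvector values. The population variance (divide by
5) is the default because the quantity is descriptive over exactly the
observed timepoints; `population = FALSE` gives the sample variance.

`ranksum_test()` is the two-sided Wilcoxon rank-sum comparison of two
variance groups. For combined sizes up to 12 it enumerates all labelings of
the pooled midranks (exact under ties); beyond that it delegates to the
tie-corrected normal approximation in `stats::wilcox.test()`.

`permutation_fdr()` implements the permutation null for the difference of
two compartment groups: the observed statistic is the absolute difference
in means; each of 1000 rounds (default) pools the values and re-splits them
at the original sizes; the estimate is the fraction of permuted statistics
at least as large as the observed one. The absolute-value convention makes
the statistic symmetric in the two groups, ties count as exceedances
(conservative), and an `exhaustive = TRUE` mode enumerates all splits for
small inputs, which the tests use as the ground truth for the random
estimator. By default the values entering the test are per-compartment
means; a per-bin analysis can be run by passing bin-level values directly.

## Annotation and the loop cascade

`classify_states()` reads a chromatin-state emission matrix (states x the
five histone marks) and classes each state as active (any of H3K4me3,
H3K27ac, H3K4me1 at or above the cutoff), repressive (H3K27me3 or
H3K9me3), bivalent (both) or low_signal (neither). The cutoff, 0.3, is a
threshold on the emission probabilities themselves — emissions are
probabilities, not p-values, so the occasionally seen "p value cutoff"
phrasing is read as a probability threshold. State composition over
compartment groups is base-pair arithmetic; uncovered bases count as
low_signal so fractions sum to one.

Peak statistics use summits (the interval midpoint when no summit is
given): counts inside footprints, the percentage of compartments with at
least one summit, and the mean summits per compartment boundary within
±1 bin of the junction (the window is a flag; the summary window is not
fixed by any published convention). The joint summary flags patterns with
more than 80% ER-alpha-positive compartments and fewer than 0.4 CTCF peaks
per boundary, both strict inequalities.

The loop cascade filters putative loops (logP at most −6, anchor-center
distance at least 20 Kb, trans pairs dropped; differential loops
additionally FDR at most 0.1 and distance in the closed 40 Kb–5 Mb range)
and then annotates promoter (any anchor overlapping a −5 Kb/+1 Kb
strand-reflected TSS window by at least 1 bp), enhancer (an H3K27ac or
H3K4me1 peak at the distal anchor; when both anchors carry promoters either
may serve as distal) and ER-alpha-PE (an ER-alpha summit in either anchor)
flags, which are monotone by construction. `cascade_summary()` reports
stage counts and, restricted to loops whose anchor centers fall inside
altered compartments of the chosen types (both centers by default; the
single-anchor reading is available as `anchor_mode = "either"`), the
distinct differentially expressed genes linked through the final loops.

## The synthetic generator

Real data for this design are genome-scale sequencing experiments; the
package instead ships a generator whose defaults define the desk-scale
study conditions used throughout the tests:

* Genome: 3 chromosomes x 20 Mb at 100 Kb bins (600 bins). Three
  chromosomes, not two, because the trans-only correlation between bins on
  different chromosomes is only defined through shared rows on a third.
* Contact model: expected count `base_mean` (20) between different-label
  bins and `base_mean * enrichment` (enrichment 3) between same-label bins,
  negative-binomial noise (dispersion 0.05), symmetric, no distance decay —
  compartment eigenvectors on trans-style block signal do not need decay,
  and adding it would only dilute the planted truth.
* Dynamics: each planted compartment carries a pattern (1–24). Transit
  timepoints are realised by flipping an interior block of footprint bins,
  sized to land inside the intended converted-bin class; the first and last
  footprint bins are never flipped so neighbouring compartments keep their
  own footprints and every planted pattern is recoverable by construction
  (a boundary-shift planting would cascade Transit status into neighbours).
* TamR: a configurable fraction of Transit compartments gets one interior
  bin converted in the resistant track.
* Peaks: per-bin sampling weights `compartment_bias^(planted A) *
  boundary_bias^(near a planted boundary)`; infinite bias restricts the
  support.
* Loops: anchors are laid out on mutually disjoint genomic slots, and each
  loop's TSS, enhancer mark and ER-alpha summit are placed inside its own
  anchors, so the realized cascade truth equals the planted configuration;
  the generator still records realized flags by brute-force scans that are
  independent of the GenomicRanges-based annotation code. Significance
  values span both sides of the filters through the logP and FDR columns.
* Expression: log2-scale baselines N(5, 2), planted dynamic genes follow a
  scaled temporal profile of amplitude `effect_log2fc` (2), Gaussian noise
  sd 0.3.

What passing tests on this generator show: the matrix pipeline, the
classifier, the TRAC caller, the statistics and the cascade recover planted
structure exactly or nearly exactly under block-model contact noise. What
they do not show: robustness to distance decay, translocations, copy-number
variation, partial coverage, sub-bin boundary placement, or biological
deviations from the block model — genome-scale counts from real data (total
compartment numbers, stage counts of the published cascade) are not
reproducible at this scale and are not asserted anywhere.

Because the generated matrices have complete, uniform coverage, the
recovery analyses run the pipeline with `low_coverage_quantile = 0`: the 1%
low-marginal mask exists to remove sequencing artifacts and would otherwise
discard valid bins and split footprints. The filter logic itself is tested
with planted low-coverage bins.

All generators are pure functions of their parameters and a seed, restore
the caller's RNG state, and the planted truth serialises losslessly to a
YAML sidecar (`write_truth()` / `read_truth()`).

## Problem sizes

The test suite and the acceptance script use the 600-bin genome, six
contact matrices per run, 1000-loop fixtures, 200-round calibration
replicates and 1000 permutation rounds; a full run takes well under a
minute on one core, which makes the suite cheap enough to run on every
change.

## Known limitations

* The pattern-number ordering within types is a documented canonical
  choice, not a reproduction of an external table.
* Two-chromosome genomes get imputed cross-chromosome correlation entries
  in `trans_only` mode; three or more chromosomes are recommended.
* `boundary_peak_density()` assumes alternating segmentations; boundaries
  against masked gaps are not counted as junctions.
* The shift length of a compartment with no same-type overlap at the other
  timepoint is reported as 0 (its boundaries there are undefined) with
  `flipped = TRUE`, rather than a fabricated distance.
* Whether a shift is measured per boundary or summed over both is not
  fixed by any published convention; the maximum over the two boundaries is
  used.
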