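# compdyn

Temporal dynamics of A/B chromatin compartments from binned contact
matrices.

## What it does, and for whom

Hi-C-type experiments (here: tethered chromatin capture across a
five-timepoint estradiol stimulation of an ER-positive breast cancer line,
plus a tamoxifen-resistant derivative) produce binned genome-wide contact
matrices. `compdyn` is for analysts who start from those matrices and want
to know **which compartments change, when, and how much**:

1. **Compartment calling.** Mask under-sequenced bins, clamp trans-count
   outliers, balance the matrix by iterative correction (ICE), and call
   A/B compartments from the sign of the leading eigenvector of the
   observed/expected bin–bin correlation matrix — positive = A (active),
   negative = B (inactive) — at a configurable bin size (default 100 Kb).
2. **Dynamics classification.** Compare the reference (T0) segmentation
   with T1, T4, T16, T24. Each compartment is Common (identical span) or
   Transit (shifted or flipped) per comparison; the 16 possible status sets
   give 15 patterns plus 9 converted-bin subclasses of the all-Transit set:
   24 patterns in six types — HCC, ETC, LTC, LDC, MDC, HDC (from highly
   common to highly dynamic). A **converted bin** is a footprint bin whose
   A/B label differs between two tracks.
3. **Resistant-cell comparison.** A Transit compartment with at least one
   converted bin versus the resistant-cell track is a TRAC
   (tamoxifen-resistant altered compartment), otherwise a TRUC; change
   classes Shrunk / Expanded / Flipped / Other.
4. **Statistics.** Across-timepoint eigenvector variance per compartment
   (sigma^2), exact/approximate Wilcoxon rank-sum comparison between
   compartment types, and a permutation FDR (pool the two groups' values,
   re-split 1000 times, count permuted absolute mean differences at least
   as large as the observed one).
5. **Annotation.** Chromatin-state composition (active / repressive /
   bivalent / low-signal at emission cutoff 0.3), ER-alpha peak content and
   CTCF boundary density per pattern, and the promoter (−5 Kb/+1 Kb of a
   TSS) → enhancer (H3K27ac/H3K4me1 at the distal anchor) → ER-alpha-PE
   loop cascade with differential-gene linkage.
6. **Synthetic data.** A generator that plants compartments, patterns,
   TRACs, peaks, loops and dynamic genes with a serialisable ground truth,
   so the whole pipeline is testable without any sequencing data.

All coordinates are 0-based half-open (BED-native). Formats: dense or
triplet matrix text, BED3/BED6/state-BED, BEDPE with `logP`/`fdr` columns,
bedGraph, tab-separated TSS/expression tables, YAML truth sidecars.

## Worked example

```r
library(compdyn)

truth <- synthetic_truth(seed = 42)                      # plant ground truth
mats  <- generate_contact_series(truth, intra_block_enrichment = 3, seed = 43)
orient <- as.numeric(truth$labels[, "T0"] == "A")        # orientation proxy

tracks <- lapply(names(mats), function(tk)
  call_compartments(mats[[tk]], low_coverage_quantile = 0,
                    orientation_track = orient, timepoint = tk))
names(tracks) <- names(mats)
segs <- lapply(tracks, segment_compartments)

asg   <- classify_timeline(segs$T0, segs$T1, segs$T4, segs$T16, segs$T24)
calls <- call_trac(asg, segs$TamR)
table(calls$tdrc_type)
#> ETC HCC HDC LDC LTC MDC
#>  12  14  12  12  12  12
table(calls$call)
#> TRAC TRUC
#>   29   45

v  <- eigen_variance(tracks[c("T0", "T1", "T4", "T16", "T24")], asg)
hi <- v$sigma2[v$tdrc_type %in% c("MDC", "HDC")]
lo <- v$sigma2[!v$tdrc_type %in% c("MDC", "HDC")]
ranksum_test(hi, lo)                  # 4.44e-12
permutation_fdr(hi, lo, seed = 7)$fdr # 0
```

The 74 planted compartments are recovered with their planted types; the
moderately/highly dynamic types (MDC/HDC) have much larger eigenvector
variance than the stable types, so the rank-sum p-value is tiny and no
permutation reaches the observed group difference (FDR 0 at 1000 rounds).

A thin CLI wraps the same functions
(`inst/cli/compdyn.R`: `simulate`, `call-compartments`,
`classify-dynamics`, `compare-types`, `annotate`, `loop-cascade`,
`enumerate`).

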