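# Temporal compartment dynamics: Common/Transit comparison of two
# segmentations, the five-timepoint 24-pattern / six-type classification,
# and resistant-cell altered-compartment (TRAC) calling.

# Canonical ordering of the 15 non-all-Transit status sets. Status order is
# (T0 vs T1, T0 vs T4, T0 vs T16, T0 vs T24); "C" = Common, "T" = Transit.
# The all-Transit set is subdivided into patterns 16-24 by converted-bin
# count. The supplement's exact table is not in the main text of the source
# study, so this mapping is a documented, overridable constant that
# reproduces the published structure exactly: 16 sets, 15 + 9 = 24 patterns,
# six types of four patterns each, with early-transit (ETC) and late-transit
# (LTC) semantics.
.pattern_sets <- matrix(c(
  "C","C","C","C",  # 1  HCC
  "C","T","C","C",  # 2
  "C","C","T","C",  # 3
  "C","C","C","T",  # 4
  "T","C","C","C",  # 5  ETC
  "T","T","C","C",  # 6
  "T","C","T","C",  # 7
  "T","C","C","T",  # 8
  "C","T","T","C",  # 9  LTC
  "C","T","C","T",  # 10
  "C","C","T","T",  # 11
  "C","T","T","T",  # 12
  "T","T","T","C",  # 13 LDC
  "T","T","C","T",  # 14
  "T","C","T","T"   # 15
), ncol = 4, byrow = TRUE)

# upper edges (inclusive) of the converted-bin classes for the all-Transit
# set; counts above the last edge fall in pattern 24
.default_x_edges <- c(1, 3, 5, 7, 9, 12, 15, 19)

#' The canonical 24-pattern table
#'
#' @param x_class_edges inclusive upper edges of the eight lowest
#'   converted-bin classes subdividing the all-Transit set into patterns
#'   16-24 (default `c(1, 3, 5, 7, 9, 12, 15, 19)`).
#' @return data.frame with columns `pattern` (1-24), `s1`, `s4`, `s16`,
#'   `s24` (status set; NA for the converted-bin-subdivided all-Transit
#'   patterns beyond the set itself), `converted_min`, `converted_max`, and
#'   `tdrc_type` (HCC/ETC/LTC/LDC/MDC/HDC).
#' @export
pattern_table <- function(x_class_edges = .default_x_edges) {
  stopifnot(length(x_class_edges) == 8, !is.unsorted(x_class_edges))
  lo <- c(0, x_class_edges + 1)
  hi <- c(x_class_edges, Inf)
  df <- data.frame(
    pattern = 1:24,
    s1 = c(.pattern_sets[, 1], rep("T", 9)),
    s4 = c(.pattern_sets[, 2], rep("T", 9)),
    s16 = c(.pattern_sets[, 3], rep("T", 9)),
    s24 = c(.pattern_sets[, 4], rep("T", 9)),
    converted_min = c(rep(NA, 15), lo),
    converted_max = c(rep(NA, 15), hi),
    tdrc_type = tdrc_type_of(1:24),
    stringsAsFactors = FALSE)
  df
}

#' Type of a pattern id
#'
#' Patterns 1-4 are HCC (highly common), 5-8 ETC (early transit), 9-12 LTC
#' (late transit), 13-16 LDC (lowly dynamic), 17-20 MDC (moderately
#' dynamic), 21-24 HDC (highly dynamic).
#'
#' @param pattern integer vector of pattern ids in 1..24.
#' @return character vector of type codes.
#' @export
tdrc_type_of <- function(pattern) {
  stopifnot(all(pattern %in% 1:24))
  c("HCC", "ETC", "LTC", "LDC", "MDC", "HDC")[ceiling(pattern / 4)]
}

.opposite <- function(type) ifelse(type == "A", "B", "A")

# bin index range (global, 1-based) of a segment
.seg_bins <- function(layout, chrom, start, end) {
  i1 <- .pos_to_bin(layout, chrom, start)
  i2 <- .pos_to_bin(layout, chrom, end - 1)
  i1:i2
}

#' Compare two compartment segmentations (Common / Transit)
#'
#' Each reference segment is matched to the same-type segment at the other
#' timepoint with maximal bin overlap (ties to the leftmost). A comparison
#' is Common iff the matched segment has the identical bin span and type;
#' otherwise it is Transit with shift = max(|delta start|, |delta end|). A
#' segment is flipped when more than 50 percent of its footprint bins carry
#' the opposite label at the other timepoint; segments with no same-type
#' overlap are Transit and flipped with shift 0 (their boundaries at the
#' other timepoint are undefined). Converted bins are the footprint bins
#' whose label differs between the two tracks (unlabelled bins excluded).
#'
#' @param ref `compartment_segments` at the reference timepoint.
#' @param other `compartment_segments` at the compared timepoint.
#' @return data.frame with the reference segment columns plus `status`
#'   ("Common"/"Transit"), `shift` (bp), `flipped`, `converted_bins`,
#'   `matched_start`, `matched_end`.
#' @export
match_compartments <- function(ref, other) {
  layout <- attr(ref, "layout")
  lo <- attr(other, "layout")
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.null(lo) && !.layouts_equal(layout, lo))
    stop("segmentations are on different layouts")
  other_lab <- segments_to_labels(other, layout)
  n <- nrow(ref)
  status <- character(n); shift <- numeric(n); flipped <- logical(n)
  conv <- integer(n)
  mstart <- rep(NA_real_, n); mend <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    bins <- .seg_bins(layout, ref$chrom[k], ref$start[k], ref$end[k])
    t <- ref$type[k]
    olab <- other_lab[bins]
    conv[k] <- sum(!is.na(olab) & olab != t)
    flipped[k] <- sum(!is.na(olab) & olab == .opposite(t)) >
      length(bins) / 2
    cand <- other[other$chrom == ref$chrom[k] & other$type == t &
                    other$start < ref$end[k] & other$end > ref$start[k], ,
                  drop = FALSE]
    if (!nrow(cand)) {
      status[k] <- "Transit"; flipped[k] <- TRUE; shift[k] <- 0
      next
    }
    ov <- pmin(cand$end, ref$end[k]) - pmax(cand$start, ref$start[k])
    best <- cand[which.max(ov), ]  # which.max resolves ties leftmost
    mstart[k] <- best$start; mend[k] <- best$end
    if (best$start == ref$start[k] && best$end == ref$end[k]) {
      status[k] <- "Common"; shift[k] <- 0; flipped[k] <- FALSE
      conv[k] <- 0L
    } else {
      status[k] <- "Transit"
      shift[k] <- max(abs(best$start - ref$start[k]),
                      abs(best$end - ref$end[k]))
    }
  }
  out <- data.frame(chrom = ref$chrom, start = ref$start, end = ref$end,
                    type = ref$type, status = status, shift = shift,
                    flipped = flipped, converted_bins = conv,
                    matched_start = mstart, matched_end = mend,
                    stringsAsFactors = FALSE)
  attr(out, "layout") <- layout
  out
}

#' Classify the five-timepoint compartment timeline into the 24 patterns
#'
#' For each reference (T0) compartment, a status vector is built by
#' comparing it against the T1, T4, T16 and T24 segmentations with
#' [match_compartments()]. The 15 non-all-Transit status sets map to
#' patterns 1-15 via [pattern_table()]; the all-Transit set is subdivided
#' into patterns 16-24 by the number of converted bins (footprint bins whose
#' label differs from the reference type at any of the four timepoints).
#' Types are assigned by the documented ranges.
#'
#' @param t0,t1,t4,t16,t24 `compartment_segments`, all on one layout.
#' @param x_class_edges see [pattern_table()].
#' @return data.frame of class `pattern_assignments` with footprint columns,
#'   `s1`, `s4`, `s16`, `s24`, `converted_bins`, `pattern`, `tdrc_type`.
#' @export
classify_timeline <- function(t0, t1, t4, t16, t24,
                              x_class_edges = .default_x_edges) {
  layout <- attr(t0, "layout")
  cmp <- lapply(list(t1, t4, t16, t24),
                function(s) match_compartments(t0, s))
  labs <- lapply(list(t1, t4, t16, t24),
                 function(s) segments_to_labels(s, layout))
  n <- nrow(t0)
  st <- sapply(cmp, function(x) ifelse(x$status == "Common", "C", "T"))
  if (n == 1) st <- matrix(st, nrow = 1)
  conv <- integer(n)
  for (k in seq_len(n)) {
    bins <- .seg_bins(layout, t0$chrom[k], t0$start[k], t0$end[k])
    diff_any <- rep(FALSE, length(bins))
    for (l in labs) {
      lb <- l[bins]
      diff_any <- diff_any | (!is.na(lb) & lb != t0$type[k])
    }
    conv[k] <- sum(diff_any)
  }
  pt <- pattern_table(x_class_edges)
  key <- apply(st, 1, paste, collapse = "")
  set_key <- apply(.pattern_sets, 1, paste, collapse = "")
  pattern <- integer(n)
  for (k in seq_len(n)) {
    if (key[k] == "TTTT") {
      xr <- pt[pt$pattern >= 16, ]
      pattern[k] <- xr$pattern[conv[k] >= xr$converted_min &
                                 conv[k] <= xr$converted_max][1]
    } else {
      pattern[k] <- match(key[k], set_key)
    }
  }
  out <- data.frame(chrom = t0$chrom, start = t0$start, end = t0$end,
                    type = t0$type,
                    s1 = st[, 1], s4 = st[, 2], s16 = st[, 3], s24 = st[, 4],
                    converted_bins = conv, pattern = pattern,
                    tdrc_type = tdrc_type_of(pattern),
                    stringsAsFactors = FALSE)
  attr(out, "layout") <- layout
  class(out) <- c("pattern_assignments", "data.frame")
  out
}

#' Enumerate the pattern space of the classification scheme
#'
#' Pure enumeration: the number of status sets over four Common/Transit
#' comparisons, the non-all-Transit (combinatorial) pattern count, the
#' converted-bin subdivision count of the all-Transit set, the resulting
#' total pattern and type counts, and the size of the reference-contrast
#' state space where each of the four timepoints takes one of four states
#' (Common-A, Common-B, Transit-A, Transit-B).
#'
#' @param x_class_edges see [pattern_table()].
#' @return named list: `sets`, `combinatorial_patterns`,
#'   `x_subdivision_patterns`, `total_patterns`, `types`,
#'   `t0_contrast_combinations`.
#' @export
enumerate_pattern_space <- function(x_class_edges = .default_x_edges) {
  status <- c("C", "T")
  sets <- expand.grid(status, status, status, status)
  all_t <- apply(sets, 1, function(r) all(r == "T"))
  n_x <- length(x_class_edges) + 1
  pt <- pattern_table(x_class_edges)
  states <- c("Common-A", "Common-B", "Transit-A", "Transit-B")
  combos <- expand.grid(states, states, states, states)
  list(sets = nrow(sets),
       combinatorial_patterns = sum(!all_t),
       x_subdivision_patterns = n_x,
       total_patterns = sum(!all_t) + n_x,
       types = length(unique(pt$tdrc_type)),
       t0_contrast_combinations = nrow(combos))
}

#' Call tamoxifen-resistant altered compartments (TRAC/TRUC)
#'
#' Converted bins are counted between the reference footprint labels (all
#' equal to the compartment type, since a compartment is a uniform-label
#' run) and the resistant-cell (TamR) labels. A compartment is a TRAC iff
#' its timeline status includes Transit and at least one footprint bin is
#' converted in TamR; otherwise it is a TRUC. The change class is Shrunk
#' when the matched TamR segment is at least two bins shorter, Expanded when
#' at least two bins longer, Flipped when the majority of footprint bins
#' changed sign, else Other.
#'
#' @param assignments `pattern_assignments` from [classify_timeline()].
#' @param tamr `compartment_segments` of the resistant condition, same
#'   layout.
#' @return data.frame of class `trac_calls`: assignment columns plus
#'   `tamr_converted`, `call` ("TRAC"/"TRUC"), `trac_type` ("TA-" + type,
#'   NA for TRUCs) and `change_class`.
#' @export
call_trac <- function(assignments, tamr) {
  layout <- attr(assignments, "layout")
  lo <- attr(tamr, "layout")
  if (!is.null(lo) && !.layouts_equal(layout, lo))
    stop("TamR segmentation is on a different layout")
  tamr_lab <- segments_to_labels(tamr, layout)
  bs <- layout$bin_size
  n <- nrow(assignments)
  convr <- integer(n); call <- character(n)
  change <- character(n)
  for (k in seq_len(n)) {
    bins <- .seg_bins(layout, assignments$chrom[k], assignments$start[k],
                      assignments$end[k])
    t <- assignments$type[k]
    lb <- tamr_lab[bins]
    convr[k] <- sum(!is.na(lb) & lb != t)
    transit <- any(c(assignments$s1[k], assignments$s4[k],
                     assignments$s16[k], assignments$s24[k]) == "T")
    call[k] <- if (transit && convr[k] >= 1) "TRAC" else "TRUC"
    flipped <- sum(!is.na(lb) & lb == .opposite(t)) > length(bins) / 2
    cand <- tamr[tamr$chrom == assignments$chrom[k] & tamr$type == t &
                   tamr$start < assignments$end[k] &
                   tamr$end > assignments$start[k], , drop = FALSE]
    if (!nrow(cand)) {
      change[k] <- if (flipped) "Flipped" else "Other"
      next
    }
    ov <- pmin(cand$end, assignments$end[k]) -
      pmax(cand$start, assignments$start[k])
    best <- cand[which.max(ov), ]
    ref_bins <- length(bins)
    match_bins <- (best$end - best$start) / bs
    change[k] <- if (match_bins <= ref_bins - 2) "Shrunk"
      else if (match_bins >= ref_bins + 2) "Expanded"
      else if (flipped) "Flipped"
      else "Other"
  }
  out <- assignments
  out$tamr_converted <- convr
  out$call <- call
  out$trac_type <- ifelse(call == "TRAC",
                          paste0("TA-", assignments$tdrc_type), NA_character_)
  out$change_class <- change
  attr(out, "layout") <- layout
  class(out) <- c("trac_calls", "data.frame")
  out
}

#' Compartment size summaries by type or call
#'
#' @param x `pattern_assignments` or `trac_calls`.
#' @param by grouping column (default `"tdrc_type"`; use `"trac_type"` or
#'   `"call"` for TRAC summaries).
#' @return data.frame with per-group `n`, `mean_bp`, `median_bp`; empty
#'   groups are absent from the output rather than reported as zero.
#' @export
size_statistics <- function(x, by = "tdrc_type") {
  stopifnot(nrow(x) > 0, by %in% names(x))
  sizes <- x$end - x$start
  grp <- x[[by]]
  keep <- !is.na(grp)
  agg <- lapply(split(sizes[keep], grp[keep]), function(s)
    data.frame(n = length(s), mean_bp = mean(s), median_bp = stats::median(s)))
  out <- do.call(rbind, agg)
  out <- data.frame(group = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out)[1] <- by
  out
}
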