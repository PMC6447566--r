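# Epigenetic-state and peak composition over compartment groups.

.active_marks <- c("H3K4me3", "H3K27ac", "H3K4me1")
.repressive_marks <- c("H3K27me3", "H3K9me3")

#' Classify chromatin-state emissions into active/repressive/bivalent
#'
#' Each state row of the emission matrix is classified by which mark sets
#' exceed the emission cutoff: active if only active marks (H3K4me3,
#' H3K27ac, H3K4me1) pass, repressive if only repressive marks (H3K27me3,
#' H3K9me3) pass, bivalent if both, low_signal if neither. The cutoff is a
#' threshold on the emission probabilities themselves (default 0.3).
#'
#' @param emissions numeric matrix, states (rows, rownames = labels) x marks
#'   (columns); entries in \[0, 1\]. Columns must be exactly the five named
#'   marks (any order).
#' @param cutoff emission-probability threshold.
#' @return data.frame with columns `state`, `class`.
#' @export
classify_states <- function(emissions, cutoff = 0.3) {
  emissions <- as.matrix(emissions)
  unknown <- setdiff(colnames(emissions),
                     c(.active_marks, .repressive_marks))
  if (length(unknown))
    stop("unknown mark column(s): ", paste(unknown, collapse = ", "))
  miss <- setdiff(c(.active_marks, .repressive_marks), colnames(emissions))
  if (length(miss))
    stop("missing mark column(s): ", paste(miss, collapse = ", "))
  if (any(emissions < 0 | emissions > 1))
    stop("emission probabilities must be in [0, 1]")
  act <- apply(emissions[, .active_marks, drop = FALSE] >= cutoff, 1, any)
  rep_ <- apply(emissions[, .repressive_marks, drop = FALSE] >= cutoff, 1, any)
  cls <- ifelse(act & rep_, "bivalent",
                ifelse(act, "active",
                       ifelse(rep_, "repressive", "low_signal")))
  data.frame(state = rownames(emissions), class = unname(cls),
             stringsAsFactors = FALSE)
}

# intersect bp of intervals `x` (data.frame chrom/start/end) with one
# footprint row
.overlap_bp <- function(x, chrom, start, end) {
  sub <- x[x$chrom == chrom & x$start < end & x$end > start, , drop = FALSE]
  if (!nrow(sub)) return(0)
  sum(pmin(sub$end, end) - pmax(sub$start, start))
}

#' State-class composition of compartment groups
#'
#' Per group, the base-pair fraction of the footprints covered by each state
#' class. Footprint bases not covered by any state record count as
#' low_signal, so fractions sum to one per group.
#'
#' @param states `interval_set` of a chromatin-state segmentation
#'   (state label in the `name` column).
#' @param classes state classification from [classify_states()].
#' @param footprints data.frame with chrom, start, end and a grouping
#'   column.
#' @param group name of the grouping column (default `"tdrc_type"`).
#' @return data.frame: one row per group, columns `active`, `repressive`,
#'   `bivalent`, `low_signal`, `total_bp`.
#' @export
state_composition <- function(states, classes, footprints,
                              group = "tdrc_type") {
  stopifnot(group %in% names(footprints))
  cls_of <- stats::setNames(classes$class, classes$state)
  unk <- setdiff(unique(states$name), classes$state)
  if (length(unk))
    stop("state(s) missing from classification: ",
         paste(unk, collapse = ", "))
  states$class <- cls_of[states$name]
  levels <- c("active", "repressive", "bivalent", "low_signal")
  by_class <- split(states, states$class)
  groups <- split(footprints, footprints[[group]])
  rows <- lapply(names(groups), function(g) {
    fp <- groups[[g]]
    total <- sum(fp$end - fp$start)
    bp <- stats::setNames(numeric(length(levels)), levels)
    for (cl in names(by_class)) {
      bp[cl] <- sum(vapply(seq_len(nrow(fp)), function(k)
        .overlap_bp(by_class[[cl]], fp$chrom[k], fp$start[k], fp$end[k]),
        numeric(1)))
    }
    bp["low_signal"] <- bp["low_signal"] + (total - sum(bp))
    data.frame(group = g, t(bp / total), total_bp = total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out)[1] <- group
  out
}

#' Peak summit counts inside compartment groups
#'
#' Peak summits (midpoint of each peak interval) are counted inside each
#' footprint; per group, the total count and the percentage of compartments
#' containing at least one summit are reported.
#'
#' @param peaks `interval_set` of peaks.
#' @param footprints data.frame with chrom, start, end and a grouping
#'   column.
#' @param group grouping column name (default `"pattern"`).
#' @return list with `by_compartment` (footprints + `n_peaks`) and
#'   `by_group` (group, `n_compartments`, `n_peaks`,
#'   `pct_with_peak`, `peaks_per_compartment`).
#' @export
peaks_in_compartments <- function(peaks, footprints, group = "pattern") {
  stopifnot(group %in% names(footprints))
  s <- .summits(peaks)
  sc <- peaks$chrom
  counts <- vapply(seq_len(nrow(footprints)), function(k)
    sum(sc == footprints$chrom[k] & s >= footprints$start[k] &
          s < footprints$end[k]), numeric(1))
  bc <- footprints
  bc$n_peaks <- counts
  groups <- split(seq_len(nrow(bc)), bc[[group]])
  bg <- do.call(rbind, lapply(names(groups), function(g) {
    i <- groups[[g]]
    data.frame(group = g, n_compartments = length(i),
               n_peaks = sum(counts[i]),
               pct_with_peak = 100 * mean(counts[i] >= 1),
               peaks_per_compartment = mean(counts[i]),
               stringsAsFactors = FALSE)
  }))
  names(bg)[1] <- group
  list(by_compartment = bc, by_group = bg)
}

# boundary positions (bp) of a compartment within an alternating
# segmentation: each end of the footprint where an adjacent opposite-type
# segment abuts
.boundaries_of <- function(segments) {
  segments <- segments[order(segments$chrom, segments$start), ]
  n <- nrow(segments)
  res <- vector("list", n)
  for (k in seq_len(n)) {
    b <- numeric(0)
    if (k > 1 && segments$chrom[k - 1] == segments$chrom[k] &&
        segments$end[k - 1] == segments$start[k] &&
        segments$type[k - 1] != segments$type[k])
      b <- c(b, segments$start[k])
    if (k < n && segments$chrom[k + 1] == segments$chrom[k] &&
        segments$start[k + 1] == segments$end[k] &&
        segments$type[k + 1] != segments$type[k])
      b <- c(b, segments$end[k])
    res[[k]] <- b
  }
  res
}

#' Mean peak summits per compartment boundary
#'
#' A boundary is the junction between two adjacent opposite-type
#' compartments; summits within `window_bins` bins of the junction (the
#' half-open window `[p - w, p + w)` with `w = window_bins * bin_size`) are
#' counted and averaged per group over boundaries.
#'
#' @param peaks `interval_set` of peaks.
#' @param segments segmentation data.frame (chrom, start, end, type) with a
#'   grouping column; must carry a `layout` attribute (or pass `bin_size`).
#' @param group grouping column name (default `"pattern"`).
#' @param window_bins window half-width in bins (default 1).
#' @param bin_size bin size override when no layout attribute is present.
#' @return data.frame: group, `n_boundaries`, `n_peaks`,
#'   `peaks_per_boundary`.
#' @export
boundary_peak_density <- function(peaks, segments, group = "pattern",
                                  window_bins = 1, bin_size = NULL) {
  stopifnot(group %in% names(segments))
  layout <- attr(segments, "layout")
  bs <- if (!is.null(bin_size)) bin_size else layout$bin_size
  if (is.null(bs)) stop("no layout attribute: pass bin_size")
  w <- window_bins * bs
  s <- .summits(peaks)
  bnds <- .boundaries_of(segments)
  ord <- order(segments$chrom, segments$start)
  grp <- segments[[group]][ord]
  chroms <- segments$chrom[ord]
  rows <- lapply(split(seq_along(bnds), grp), function(i) {
    npk <- 0; nb <- 0
    for (k in i) {
      for (p in bnds[[k]]) {
        nb <- nb + 1
        npk <- npk + sum(peaks$chrom == chroms[k] & s >= p - w & s < p + w)
      }
    }
    data.frame(n_boundaries = nb, n_peaks = npk,
               peaks_per_boundary = if (nb > 0) npk / nb else NA_real_)
  })
  out <- do.call(rbind, rows)
  out <- data.frame(group = rownames(out), out, row.names = NULL,
                    stringsAsFactors = FALSE)
  names(out)[1] <- group
  out
}

#' Joint ERalpha / CTCF summary per pattern
#'
#' Joins the per-pattern percentage of compartments with an ERalpha peak and
#' the per-pattern CTCF boundary density, and flags patterns with more than
#' `era_min` percent ERalpha-positive compartments and fewer than `ctcf_max`
#' CTCF peaks per boundary (both strict inequalities).
#'
#' @param era data.frame with columns `pattern` and `pct_with_peak` (see
#'   [peaks_in_compartments()] `by_group`).
#' @param ctcf data.frame with columns `pattern` and `peaks_per_boundary`
#'   (see [boundary_peak_density()]).
#' @param era_min,ctcf_max thresholds (defaults 80 percent and 0.4 peaks).
#' @return data.frame over patterns 1-24: `pattern`, `era_pct`,
#'   `ctcf_per_boundary`, `flagged` (NA where a pattern is absent from
#'   either input).
#' @export
era_ctcf_summary <- function(era, ctcf, era_min = 80, ctcf_max = 0.4) {
  out <- data.frame(pattern = 1:24)
  out$era_pct <- era$pct_with_peak[match(out$pattern,
                                         as.integer(era$pattern))]
  out$ctcf_per_boundary <-
    ctcf$peaks_per_boundary[match(out$pattern, as.integer(ctcf$pattern))]
  out$flagged <- out$era_pct > era_min & out$ctcf_per_boundary < ctcf_max
  out
}
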