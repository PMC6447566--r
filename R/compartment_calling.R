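# A/B compartment calling: bin filtering, trans-outlier truncation,
# iterative correction (ICE) and leading-eigenvector decomposition of the
# observed/expected correlation matrix.

.eigen_track <- function(values, layout, timepoint = NA_character_,
                         oriented = FALSE) {
  bt <- bin_table(layout)
  bt$value <- as.numeric(values)
  bt$label <- ifelse(is.na(bt$value), NA_character_,
                     ifelse(bt$value > 0, "A",
                            ifelse(bt$value < 0, "B", NA_character_)))
  attr(bt, "layout") <- layout
  attr(bt, "timepoint") <- timepoint
  attr(bt, "oriented") <- oriented
  class(bt) <- c("eigen_track", "data.frame")
  bt
}

#' Mask low-coverage bins
#'
#' Masks (i) bins with less than `min_coverage_fraction` of the bin
#' sequenced and then (ii) the lowest `low_coverage_quantile` of the
#' remaining bins by marginal contact count. Masked rows/columns are zeroed.
#'
#' @param m a [contact_matrix()].
#' @param min_coverage_fraction coverage threshold (default 0.5: at least
#'   half of the bin sequenced).
#' @param low_coverage_quantile fraction of remaining bins to drop by lowest
#'   marginal (default 0.01).
#' @return filtered `contact_matrix`.
#' @export
filter_bins <- function(m, min_coverage_fraction = 0.5,
                        low_coverage_quantile = 0.01) {
  stopifnot(inherits(m, "contact_matrix"))
  m$mask <- m$mask & (m$coverage >= min_coverage_fraction)
  m <- .apply_mask(m)
  k <- floor(low_coverage_quantile * sum(m$mask))
  if (k > 0) {
    marg <- rowSums(m$counts)
    cand <- which(m$mask)
    drop <- cand[order(marg[cand])][seq_len(k)]
    m$mask[drop] <- FALSE
  }
  if (!any(m$mask)) stop("degenerate input: all bins masked after filtering")
  .apply_mask(m)
}

#' Truncate extreme interchromosomal counts
#'
#' Clamps the top `top_quantile` of interchromosomal (trans) cell values —
#' possible PCR blowouts — to the (1 - top_quantile) quantile of trans
#' values. Intrachromosomal cells are untouched.
#'
#' @param m a [contact_matrix()].
#' @param top_quantile fraction of trans cells to clamp (default 5e-4, i.e.
#'   the top 0.05 percent).
#' @return `contact_matrix` with clamped trans cells.
#' @export
truncate_trans_outliers <- function(m, top_quantile = 0.0005) {
  stopifnot(inherits(m, "contact_matrix"))
  if (length(m$layout$chroms) < 2) {
    warning("single-chromosome layout: no trans cells, returning unchanged")
    return(m)
  }
  if (top_quantile <= 0) return(m)
  cis <- .cis_cells(m$layout)
  keep <- outer(m$mask, m$mask, "&") & !cis & upper.tri(m$counts)
  vals <- m$counts[keep]
  if (!length(vals)) return(m)
  thr <- stats::quantile(vals, 1 - top_quantile, names = FALSE)
  hi <- !cis & m$counts > thr
  m$counts[hi] <- thr
  m
}

#' Iterative correction (ICE) of a contact matrix
#'
#' Iteratively equalises the marginals of the unmasked submatrix so that
#' every unmasked row sum equals their common mean within `tolerance`
#' (relative). The corrected cell is the raw cell divided by the product of
#' the two bin biases.
#'
#' @param m filtered [contact_matrix()]; every unmasked bin must have a
#'   positive marginal.
#' @param tolerance relative row-sum imbalance at convergence (default 1e-5).
#' @param max_iterations iteration cap (default 200).
#' @return `contact_matrix` with balanced counts, per-bin `bias` vector (NA
#'   for masked bins) and attribute `iterations`.
#' @export
ice_balance <- function(m, tolerance = 1e-5, max_iterations = 200) {
  stopifnot(inherits(m, "contact_matrix"))
  m <- .apply_mask(m)
  u <- which(m$mask)
  W <- m$counts[u, u, drop = FALSE]
  marg <- rowSums(W)
  if (any(marg == 0))
    stop("ice_balance did not converge: unmasked bin(s) with zero marginal ",
         "(mask them first); bins: ",
         paste(utils::head(u[marg == 0], 5), collapse = ", "))
  bias <- rep(1, length(u))
  it <- 0
  repeat {
    s <- rowSums(W)
    mu <- mean(s)
    imbalance <- max(abs(s - mu)) / mu
    if (imbalance < tolerance) break
    it <- it + 1
    if (it > max_iterations)
      stop(sprintf(
        "ice_balance did not converge in %d iterations (imbalance %.3g)",
        max_iterations, imbalance))
    b <- s / mu
    W <- W / outer(sqrt(b), sqrt(b))
    bias <- bias * sqrt(b)
  }
  out <- matrix(0, nrow(m$counts), ncol(m$counts))
  out[u, u] <- W
  full_bias <- rep(NA_real_, nrow(m$counts))
  full_bias[u] <- bias
  res <- contact_matrix(out, m$layout, mask = m$mask, coverage = m$coverage,
                        bias = full_bias)
  attr(res, "iterations") <- it
  res
}

#' Leading-eigenvector A/B compartment call
#'
#' Removes the diagonal, converts the balanced matrix to observed/expected
#' (expected = product of trans marginals), builds the bin-bin correlation
#' matrix of the trans-only or cis-faked signal and takes its leading
#' eigenvector. Bins with positive values are labelled A, negative B.
#'
#' In `trans_only` mode cis cells are excluded pairwise from the
#' correlation; correlation entries with no complete trans observations
#' (cross-chromosome bin pairs in a two-chromosome layout) are filled from
#' the cis-faked correlation, which treats cis cells as exactly their
#' expectation. In `faked_cis` mode cis cells are replaced by the
#' trans-derived expectation (observed/expected = 1) before correlation.
#'
#' The global sign of the eigenvector is arbitrary; when
#' `orientation_track` (any per-bin activity signal: gene density, coverage,
#' a known label indicator) is supplied, the sign is chosen so that the
#' positive class has the higher mean of the track and the result is marked
#' oriented. Otherwise the track is flagged unoriented.
#'
#' @param m balanced [contact_matrix()] (see [ice_balance()]).
#' @param mode `"trans_only"` (default) or `"faked_cis"`.
#' @param orientation_track optional numeric vector, one value per bin.
#' @param timepoint tag stored on the returned track.
#' @param min_bins_per_chrom minimum unmasked bins required per chromosome
#'   (default 10).
#' @return an `eigen_track` data.frame (columns chrom, start, end, value,
#'   label; attributes layout, timepoint, oriented).
#' @export
compartment_eigenvector <- function(m, mode = c("trans_only", "faked_cis"),
                                    orientation_track = NULL,
                                    timepoint = NA_character_,
                                    min_bins_per_chrom = 10) {
  mode <- match.arg(mode)
  stopifnot(inherits(m, "contact_matrix"))
  layout <- m$layout
  if (length(layout$chroms) < 2)
    stop("trans-signal compartment calling requires >= 2 chromosomes")
  ch <- .bin_chroms(layout)
  per <- tapply(m$mask, ch, sum)
  if (any(per < min_bins_per_chrom))
    stop("fewer than ", min_bins_per_chrom, " unmasked bins on chromosome(s): ",
         paste(names(per)[per < min_bins_per_chrom], collapse = ", "))
  u <- which(m$mask)
  W <- m$counts
  diag(W) <- 0
  cis <- .cis_cells(layout)
  Wu <- W[u, u, drop = FALSE]
  cis_u <- cis[u, u, drop = FALSE]
  # expected from trans marginals
  Wt <- Wu
  Wt[cis_u] <- 0
  mt <- rowSums(Wt)
  tot <- sum(Wt)
  if (tot == 0) stop("degenerate input: no trans signal among unmasked bins")
  E <- outer(mt, mt) / tot
  OE <- Wu / E
  OE[E == 0] <- NA
  trans_vals <- OE[!cis_u & is.finite(OE)]
  if (length(trans_vals) == 0 || stats::sd(trans_vals) == 0)
    stop("degenerate input: constant observed/expected signal")
  OE_faked <- OE
  OE_faked[cis_u] <- 1
  corr <- suppressWarnings(stats::cor(OE_faked))
  if (mode == "trans_only") {
    OE_trans <- OE
    OE_trans[cis_u] <- NA
    corr_t <- suppressWarnings(
      stats::cor(OE_trans, use = "pairwise.complete.obs"))
    corr[!is.na(corr_t)] <- corr_t[!is.na(corr_t)]
  }
  corr[is.na(corr)] <- 0
  diag(corr) <- 1
  corr <- (corr + t(corr)) / 2
  ev <- eigen(corr, symmetric = TRUE)
  v <- ev$vectors[, 1]
  values <- rep(NA_real_, n_bins(layout))
  values[u] <- v
  oriented <- FALSE
  if (!is.null(orientation_track)) {
    stopifnot(length(orientation_track) == n_bins(layout))
    pos <- mean(orientation_track[!is.na(values) & values > 0], na.rm = TRUE)
    neg <- mean(orientation_track[!is.na(values) & values < 0], na.rm = TRUE)
    if (is.finite(pos) && is.finite(neg) && pos < neg) values <- -values
    oriented <- TRUE
  }
  .eigen_track(values, layout, timepoint, oriented)
}

#' Segment an eigenvector track into A/B compartments
#'
#' Maximal runs of same-label bins become compartments; masked bins
#' terminate runs. Single-bin compartments are kept (the 100 Kb shift
#' granularity requires them). A size histogram over the classes
#' <1 Mb, 1-2 Mb, 2-5 Mb, >5 Mb is attached as attribute `size_histogram`.
#'
#' @param track an `eigen_track` (or any data.frame with chrom/start/end/
#'   value/label and a layout attribute).
#' @return data.frame of class `compartment_segments` (columns chrom, start,
#'   end, type, mean_value, n_bins), ordered by chromosome and start.
#' @export
segment_compartments <- function(track) {
  layout <- attr(track, "layout")
  stopifnot(inherits(layout, "genome_layout"))
  segs <- list()
  for (ch in layout$chroms) {
    sub <- track[track$chrom == ch, , drop = FALSE]
    lab <- sub$label
    if (!nrow(sub)) next
    r <- rle(ifelse(is.na(lab), "NA", lab))
    endi <- cumsum(r$lengths)
    starti <- endi - r$lengths + 1
    keep <- r$values != "NA"
    if (!any(keep)) next
    segs[[ch]] <- data.frame(
      chrom = ch,
      start = sub$start[starti[keep]],
      end = sub$end[endi[keep]],
      type = r$values[keep],
      mean_value = vapply(which(keep), function(k)
        mean(sub$value[starti[k]:endi[k]]), numeric(1)),
      n_bins = r$lengths[keep],
      stringsAsFactors = FALSE)
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               type = character(), mean_value = numeric(),
               n_bins = integer(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  sizes <- out$end - out$start
  hist <- c("<1Mb" = sum(sizes < 1e6),
            "1-2Mb" = sum(sizes >= 1e6 & sizes < 2e6),
            "2-5Mb" = sum(sizes >= 2e6 & sizes <= 5e6),
            ">5Mb" = sum(sizes > 5e6))
  attr(out, "layout") <- layout
  attr(out, "size_histogram") <- hist
  attr(out, "timepoint") <- attr(track, "timepoint")
  class(out) <- c("compartment_segments", "data.frame")
  out
}

#' Per-bin labels from a compartment segmentation
#'
#' Inverse of [segment_compartments()]: expands segments back to a per-bin
#' label vector on the layout (NA for uncovered bins).
#'
#' @param segs `compartment_segments` (or a data.frame with chrom/start/end/
#'   type).
#' @param layout a `genome_layout`.
#' @return character vector of "A"/"B"/NA, one entry per bin.
#' @export
segments_to_labels <- function(segs, layout) {
  lab <- rep(NA_character_, n_bins(layout))
  if (!nrow(segs)) return(lab)
  off <- .chrom_offsets(layout)
  for (k in seq_len(nrow(segs))) {
    i1 <- .pos_to_bin(layout, segs$chrom[k], segs$start[k])
    i2 <- .pos_to_bin(layout, segs$chrom[k], segs$end[k] - 1)
    lab[i1:i2] <- segs$type[k]
  }
  lab
}

#' Per-bin labels of an eigenvector track
#' @param track an `eigen_track`.
#' @return character vector of "A"/"B"/NA per bin.
#' @export
track_labels <- function(track) track$label
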