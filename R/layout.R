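#' Genome layout: chromosomes, lengths and a fixed bin size
#'
#' A `genome_layout` fixes the coordinate frame used by every other object in
#' the package. Coordinates are 0-based half-open throughout (BED-native);
#' bins are `bin_size` wide, the last bin of each chromosome is clipped to
#' the chromosome length. Bins are indexed 1..n_bins(layout) in
#' chromosome-major order inside R; text matrix files use 0-based indices.
#'
#' @param chroms character vector of chromosome names (must be unique).
#' @param lengths numeric vector of chromosome lengths in base pairs.
#' @param bin_size bin width in base pairs (default 1e5, i.e. 100 Kb).
#' @return An object of class `genome_layout`.
#' @examples
#' gl <- genome_layout(c("chr1", "chr2"), c(3e7, 3e7))
#' n_bins(gl)
#' @export
genome_layout <- function(chroms, lengths, bin_size = 1e5) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths))
    stop("chroms and lengths must have equal length")
  if (anyDuplicated(chroms)) stop("duplicated chromosome names")
  if (bin_size <= 0) stop("bin_size must be > 0")
  if (any(lengths <= 0)) stop("all chromosome lengths must be > 0")
  nb <- as.integer(ceiling(lengths / bin_size))
  structure(
    list(chroms = chroms, lengths = stats::setNames(lengths, chroms),
         bin_size = bin_size, n_per_chrom = stats::setNames(nb, chroms)),
    class = "genome_layout")
}

#' Total number of bins in a layout
#' @param layout a `genome_layout`.
#' @return integer bin count.
#' @export
n_bins <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  sum(layout$n_per_chrom)
}

#' Per-bin coordinate table for a layout
#'
#' @param layout a `genome_layout`.
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), one row per bin in chromosome-major order.
#' @export
bin_table <- function(layout) {
  stopifnot(inherits(layout, "genome_layout"))
  out <- lapply(layout$chroms, function(ch) {
    nb <- layout$n_per_chrom[[ch]]
    start <- (seq_len(nb) - 1) * layout$bin_size
    data.frame(chrom = ch, start = start,
               end = pmin(start + layout$bin_size, layout$lengths[[ch]]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# global (1-based) index of the first bin of each chromosome
.chrom_offsets <- function(layout) {
  off <- cumsum(c(0, utils::head(layout$n_per_chrom, -1)))
  stats::setNames(off, layout$chroms)
}

# per-bin chromosome vector, chromosome-major order
.bin_chroms <- function(layout) {
  rep(layout$chroms, times = layout$n_per_chrom)
}

# map (chrom, position in bp) -> global 1-based bin index
.pos_to_bin <- function(layout, chrom, pos) {
  off <- .chrom_offsets(layout)
  if (!all(chrom %in% layout$chroms))
    stop("unknown chromosome(s): ",
         paste(unique(chrom[!chrom %in% layout$chroms]), collapse = ", "))
  as.integer(off[chrom] + floor(pos / layout$bin_size) + 1)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosome(s), bin size %g bp, %d bins\n",
              length(x$chroms), x$bin_size, n_bins(x)))
  invisible(x)
}

#' @export
format.genome_layout <- function(x, ...) {
  sprintf("<genome_layout %d chroms, %d bins @ %g bp>",
          length(x$chroms), n_bins(x), x$bin_size)
}

.layouts_equal <- function(a, b) {
  identical(a$chroms, b$chroms) &&
    isTRUE(all.equal(unname(a$lengths), unname(b$lengths))) &&
    a$bin_size == b$bin_size
}
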