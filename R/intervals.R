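#' Interval set: the package's carrier for peaks, states and promoters
#'
#' A thin validated data.frame (columns `chrom`, `start`, `end`, `name`,
#' `score`, `strand`) in 0-based half-open coordinates. When a layout is
#' supplied, chromosome names are checked against it (exactly, no "chr"
#' normalisation).
#'
#' @param chrom,start,end,name,score,strand record fields; `name`, `score`
#'   and `strand` are optional (defaults ".", 0, ".").
#' @param layout optional `genome_layout` to validate chromosomes against.
#' @return data.frame of class `interval_set`.
#' @export
interval_set <- function(chrom, start, end, name = NULL, score = NULL,
                         strand = NULL, layout = NULL) {
  n <- length(chrom)
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    end = as.numeric(end),
    name = if (is.null(name)) rep(".", n) else as.character(name),
    score = if (is.null(score)) rep(0, n) else as.numeric(score),
    strand = if (is.null(strand)) rep(".", n) else as.character(strand),
    stringsAsFactors = FALSE)
  bad <- which(df$start >= df$end | df$start < 0)
  if (length(bad))
    stop("invalid interval(s) (start >= end or start < 0) at record(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (!is.null(layout)) {
    unk <- unique(df$chrom[!df$chrom %in% layout$chroms])
    if (length(unk))
      stop("chromosome(s) not in layout: ", paste(unk, collapse = ", "))
  }
  class(df) <- c("interval_set", "data.frame")
  df
}

# interval_set -> GRanges (internal; package coordinates are 0-based
# half-open, GRanges is 1-based closed)
.as_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end),
    strand = ifelse(x$strand %in% c("+", "-"), x$strand, "*"))
}

# peak summit positions (bp): midpoint of the interval when no explicit
# summit is carried (score column is not a summit in this package)
.summits <- function(peaks) {
  floor((peaks$start + peaks$end) / 2)
}
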