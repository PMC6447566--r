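#' Binned contact matrix with bin metadata
#'
#' Container for a symmetric nonnegative count matrix on a [genome_layout()]
#' frame, with a per-bin validity mask and a per-bin coverage fraction (the
#' proportion of the bin with sequence information; defaults to 1).
#'
#' @param counts symmetric numeric matrix, one row/column per layout bin.
#' @param layout a `genome_layout`.
#' @param mask logical per-bin validity (TRUE = usable); default all TRUE.
#' @param coverage numeric per-bin coverage fraction in \[0, 1\].
#' @param bias optional per-bin balancing bias (set by [ice_balance()]).
#' @return object of class `contact_matrix`.
#' @export
contact_matrix <- function(counts, layout, mask = NULL, coverage = NULL,
                           bias = NULL) {
  stopifnot(inherits(layout, "genome_layout"))
  nb <- n_bins(layout)
  counts <- as.matrix(counts)
  if (nrow(counts) != nb || ncol(counts) != nb)
    stop(sprintf("counts is %d x %d but layout has %d bins",
                 nrow(counts), ncol(counts), nb))
  if (any(counts < 0)) stop("counts must be nonnegative")
  if (!isTRUE(all.equal(counts, t(counts), tolerance = 1e-10)))
    stop("counts matrix must be symmetric")
  if (is.null(mask)) mask <- rep(TRUE, nb)
  if (is.null(coverage)) coverage <- rep(1, nb)
  stopifnot(length(mask) == nb, length(coverage) == nb)
  structure(list(counts = counts, layout = layout, mask = as.logical(mask),
                 coverage = as.numeric(coverage), bias = bias),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d bins (%d masked), total count %g\n",
              n_bins(x$layout), sum(!x$mask), sum(x$counts)))
  invisible(x)
}

# logical matrix, TRUE where the cell is intrachromosomal
.cis_cells <- function(layout) {
  ch <- .bin_chroms(layout)
  outer(ch, ch, "==")
}

# zero out rows/columns of masked bins
.apply_mask <- function(m) {
  bad <- !m$mask
  if (any(bad)) {
    m$counts[bad, ] <- 0
    m$counts[, bad] <- 0
  }
  m
}
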