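#' Read a binned contact matrix from text
#'
#' Accepts either a dense whitespace-separated square matrix (one row per
#' bin) or a 3-column triplet list `bin_i bin_j count` with 0-based global
#' bin indices. Triplets are mirrored to enforce symmetry; missing triplet
#' cells are 0. Dense input must already be symmetric.
#'
#' @param path file path.
#' @param layout `genome_layout` defining the bin frame.
#' @return a [contact_matrix()].
#' @export
read_matrix <- function(path, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  nb <- n_bins(layout)
  first <- scan(path, what = character(), nlines = 1, quiet = TRUE)
  if (length(first) == 3 && nb != 3) {
    dat <- utils::read.table(path, header = FALSE,
                             col.names = c("i", "j", "count"))
    .triplets_to_matrix(dat, nb, path, layout)
  } else if (length(first) == nb) {
    m <- as.matrix(utils::read.table(path, header = FALSE))
    dimnames(m) <- NULL
    .validate_dense(m, nb, path)
    contact_matrix(m, layout)
  } else if (length(first) == 3) {
    # ambiguous only when the layout has exactly 3 bins; decide by line count
    nl <- length(readLines(path))
    if (nl == 3) {
      m <- as.matrix(utils::read.table(path, header = FALSE))
      dimnames(m) <- NULL
      .validate_dense(m, nb, path)
      contact_matrix(m, layout)
    } else {
      dat <- utils::read.table(path, header = FALSE,
                               col.names = c("i", "j", "count"))
      .triplets_to_matrix(dat, nb, path, layout)
    }
  } else {
    stop(sprintf(
      "%s: line 1 has %d fields; expected 3 (triplet) or %d (dense row)",
      path, length(first), nb))
  }
}

.validate_dense <- function(m, nb, path) {
  if (nrow(m) != ncol(m))
    stop(sprintf("%s: dense matrix is not square (%d x %d)",
                 path, nrow(m), ncol(m)))
  if (nrow(m) != nb)
    stop(sprintf("%s: dense matrix has %d bins, layout has %d",
                 path, nrow(m), nb))
  if (any(m < 0)) {
    idx <- which(m < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("%s: negative count at line %d", path, idx[1]))
  }
  if (!isTRUE(all.equal(m, t(m))))
    stop(sprintf("%s: dense matrix is not symmetric", path))
}

.triplets_to_matrix <- function(dat, nb, path, layout) {
  bad <- which(dat$count < 0)
  if (length(bad))
    stop(sprintf("%s: negative count at line %d", path, bad[1]))
  oob <- which(dat$i < 0 | dat$i >= nb | dat$j < 0 | dat$j >= nb)
  if (length(oob))
    stop(sprintf("%s: bin index out of range [0, %d) at line %d",
                 path, nb, oob[1]))
  m <- matrix(0, nb, nb)
  i <- dat$i + 1; j <- dat$j + 1
  m[cbind(i, j)] <- dat$count
  m[cbind(j, i)] <- dat$count
  contact_matrix(m, layout)
}

#' Write a contact matrix to text
#'
#' Writes the sparse upper-triangle (including diagonal) triplet dialect by
#' default (`bin_i bin_j count`, 0-based indices, tab-separated); `dense =
#' TRUE` writes the full square matrix instead.
#'
#' @param m a [contact_matrix()].
#' @param path output file path.
#' @param dense write dense instead of triplets.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, dense = FALSE) {
  stopifnot(inherits(m, "contact_matrix"))
  if (dense) {
    utils::write.table(m$counts, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  } else {
    idx <- which(upper.tri(m$counts, diag = TRUE) & m$counts != 0,
                 arr.ind = TRUE)
    df <- data.frame(i = idx[, 1] - 1, j = idx[, 2] - 1,
                     count = m$counts[idx])
    df <- df[order(df$i, df$j), ]
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}
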