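#' Read a BED-dialect interval file
#'
#' Supported dialects: `bed3` (chrom, start, end), `bed6` (plus name, score,
#' strand) and `state_bed` (BED4+, chromatin-state label in the name
#' column). Records are preserved in file order; strand defaults to "." when
#' absent. Coordinates are 0-based half-open as in BED.
#'
#' @param path file path.
#' @param kind one of `"bed3"`, `"bed6"`, `"state_bed"`.
#' @param layout optional `genome_layout`; when given, unknown chromosomes
#'   are an error listing the offenders.
#' @return an [interval_set()].
#' @export
read_intervals <- function(path, kind = c("bed3", "bed6", "state_bed"),
                           layout = NULL) {
  kind <- match.arg(kind)
  dat <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  need <- switch(kind, bed3 = 3, state_bed = 4, bed6 = 3)
  if (ncol(dat) < need)
    stop(sprintf("%s: expected >= %d tab-separated columns for %s, got %d",
                 path, need, kind, ncol(dat)))
  bad <- which(dat[[2]] >= dat[[3]])
  if (length(bad))
    stop(sprintf("%s: start >= end at line %d", path, bad[1]))
  interval_set(
    chrom = dat[[1]], start = dat[[2]], end = dat[[3]],
    name = if (ncol(dat) >= 4) dat[[4]] else NULL,
    score = if (ncol(dat) >= 5) dat[[5]] else NULL,
    strand = if (ncol(dat) >= 6) dat[[6]] else NULL,
    layout = layout)
}

#' Write an interval set as BED
#'
#' `bed3` writes three columns, `bed6` six, `state_bed` four (name column =
#' state label). Round trips through [read_intervals()] are lossless for the
#' written columns.
#'
#' @param x an [interval_set()] (or compatible data.frame).
#' @param path output path.
#' @param kind BED dialect to emit.
#' @return `path`, invisibly.
#' @export
write_intervals <- function(x, path, kind = c("bed6", "bed3", "state_bed")) {
  kind <- match.arg(kind)
  cols <- switch(kind,
                 bed3 = c("chrom", "start", "end"),
                 state_bed = c("chrom", "start", "end", "name"),
                 bed6 = c("chrom", "start", "end", "name", "score", "strand"))
  df <- as.data.frame(x)[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an eigenvector track as bedGraph
#'
#' @param track an `eigen_track` (see [compartment_eigenvector()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- track[!is.na(track$value), c("chrom", "start", "end", "value")]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file as an eigenvector track on a layout
#'
#' Values are assigned to the bin containing each record's start; bins with
#' no record are masked (NA value, no label). Labels follow the sign rule
#' (positive = A, negative = B).
#'
#' @param path bedGraph path.
#' @param layout `genome_layout`.
#' @param timepoint tag stored on the track (e.g. "T0").
#' @return an `eigen_track` data.frame.
#' @export
read_bedgraph <- function(path, layout, timepoint = NA_character_) {
  dat <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(dat) < 4)
    stop(sprintf("%s: bedGraph needs 4 columns, got %d", path, ncol(dat)))
  idx <- .pos_to_bin(layout, dat[[1]], dat[[2]])
  val <- rep(NA_real_, n_bins(layout))
  val[idx] <- dat[[4]]
  .eigen_track(val, layout, timepoint, oriented = TRUE)
}

#' Read a gene/TSS table
#'
#' Tab-separated with header columns `gene_id`, `chrom`, `tss`, `strand`.
#'
#' @param path file path.
#' @param layout optional layout for chromosome validation.
#' @return data.frame of gene records.
#' @export
read_tss <- function(path, layout = NULL) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "tss", "strand")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  if (!all(dat$strand %in% c("+", "-")))
    stop(sprintf("%s: strand must be '+' or '-'", path))
  if (any(dat$tss < 0)) stop(sprintf("%s: negative TSS position", path))
  if (!is.null(layout)) {
    unk <- unique(dat$chrom[!dat$chrom %in% layout$chroms])
    if (length(unk))
      stop("chromosome(s) not in layout: ", paste(unk, collapse = ", "))
  }
  dat[, need]
}

#' Read an expression matrix (genes x timepoints)
#'
#' Tab-separated, header row of timepoint names, first column `gene_id`.
#'
#' @param path file path.
#' @return numeric matrix with gene ids as rownames.
#' @export
read_expression <- function(path) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(dat[, -1, drop = FALSE])
  rownames(m) <- dat[[1]]
  m
}

#' Write an expression matrix
#' @param m numeric matrix, gene ids as rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
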