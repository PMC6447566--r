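#' Read loop anchor pairs (BEDPE + significance columns)
#'
#' Expects a header line with at least: `chrom1 start1 end1 chrom2 start2
#' end2 logP fdr`. Anchors are canonicalised so anchor1 <= anchor2 by
#' (chrom, start); the center-to-center distance is computed for cis pairs
#' and is NA for trans pairs.
#'
#' @param path BEDPE-like file path.
#' @param layout optional layout for chromosome validation.
#' @return data.frame of class `loop_records` with annotation flag columns
#'   initialised to FALSE.
#' @export
read_loops <- function(path, layout = NULL) {
  dat <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "logP", "fdr")
  miss <- setdiff(need, names(dat))
  if (length(miss))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(miss, collapse = ", ")))
  loop_records(dat[, need], layout = layout)
}

#' Construct canonical loop records
#'
#' @param df data.frame with the eight BEDPE+significance columns.
#' @param layout optional layout for chromosome validation.
#' @return `loop_records` data.frame: canonical anchor order, `distance`
#'   (center-to-center, NA for trans), flags `putative`, `promoter`,
#'   `enhancer`, `era_pe`, `promoter_anchor` (0 none / 1 / 2 / 3 both) and a
#'   comma-separated `genes` column.
#' @export
loop_records <- function(df, layout = NULL) {
  if (!is.null(layout)) {
    unk <- unique(c(df$chrom1[!df$chrom1 %in% layout$chroms],
                    df$chrom2[!df$chrom2 %in% layout$chroms]))
    if (length(unk))
      stop("chromosome(s) not in layout: ", paste(unk, collapse = ", "))
  }
  swap <- df$chrom2 < df$chrom1 |
    (df$chrom1 == df$chrom2 & df$start2 < df$start1)
  if (any(swap)) {
    tmp <- df[swap, c("chrom1", "start1", "end1")]
    df[swap, c("chrom1", "start1", "end1")] <-
      df[swap, c("chrom2", "start2", "end2")]
    df[swap, c("chrom2", "start2", "end2")] <- tmp
  }
  c1 <- (df$start1 + df$end1) / 2
  c2 <- (df$start2 + df$end2) / 2
  df$distance <- ifelse(df$chrom1 == df$chrom2, abs(c2 - c1), NA_real_)
  for (fl in c("putative", "promoter", "enhancer", "era_pe"))
    if (is.null(df[[fl]])) df[[fl]] <- FALSE
  if (is.null(df$promoter_anchor)) df$promoter_anchor <- 0L
  if (is.null(df$genes)) df$genes <- ""
  rownames(df) <- NULL
  class(df) <- c("loop_records", "data.frame")
  df
}

#' Write loop records as BEDPE + significance columns
#' @param loops `loop_records`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_loops <- function(loops, path) {
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "logP", "fdr")
  utils::write.table(as.data.frame(loops)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
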