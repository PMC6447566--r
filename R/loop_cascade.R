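# Promoter -> enhancer -> ERalpha -> gene annotation cascade over
# significant interaction loops.

.anchor_granges <- function(loops, which = c("1", "2")) {
  which <- match.arg(which)
  GenomicRanges::GRanges(
    seqnames = loops[[paste0("chrom", which)]],
    ranges = IRanges::IRanges(start = loops[[paste0("start", which)]] + 1,
                              end = loops[[paste0("end", which)]]))
}

.overlaps_any <- function(query, subject_gr) {
  if (length(subject_gr) == 0) return(rep(FALSE, length(query)))
  IRanges::overlapsAny(query, subject_gr, ignore.strand = TRUE)
}

#' Filter putative loops
#'
#' Retains cis loops with `logP <= logp_cutoff` and center-to-center
#' distance at least `min_center_distance`; trans loops are dropped. Kept
#' loops get the `putative` flag.
#'
#' @param loops `loop_records`.
#' @param logp_cutoff log p-value cutoff (default -6; more negative = more
#'   significant).
#' @param min_center_distance minimum anchor-center distance in bp
#'   (default 20000).
#' @return filtered `loop_records` with `putative = TRUE`.
#' @export
filter_putative <- function(loops, logp_cutoff = -6,
                            min_center_distance = 20000) {
  keep <- !is.na(loops$distance) & loops$logP <= logp_cutoff &
    loops$distance >= min_center_distance
  out <- loops[keep, , drop = FALSE]
  out$putative <- rep(TRUE, nrow(out))
  rownames(out) <- NULL
  out
}

#' Filter differential loops
#'
#' Retains loops with `fdr <= fdr_cutoff` and center distance inside the
#' closed `distance_range`.
#'
#' @param loops `loop_records`.
#' @param fdr_cutoff FDR cutoff (default 0.1).
#' @param distance_range closed distance range in bp (default 40 Kb - 5 Mb).
#' @return filtered `loop_records`.
#' @export
filter_differential <- function(loops, fdr_cutoff = 0.1,
                                distance_range = c(40000, 5e6)) {
  keep <- !is.na(loops$distance) & loops$fdr <= fdr_cutoff &
    loops$distance >= distance_range[1] & loops$distance <= distance_range[2]
  out <- loops[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Promoter windows of a gene table
#'
#' The promoter window is `[tss - upstream, tss + downstream)` on the +
#' strand and `[tss - downstream + 1, tss + upstream + 1)` on the - strand
#' (strand-reflected around the TSS).
#'
#' @param genes gene table (gene_id, chrom, tss, strand).
#' @param upstream,downstream window extents in bp (defaults 5000 / 1000).
#' @return `interval_set` with the gene id in the name column.
#' @export
promoter_windows <- function(genes, upstream = 5000, downstream = 1000) {
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tss - upstream, genes$tss - downstream + 1)
  end <- ifelse(plus, genes$tss + downstream, genes$tss + upstream + 1)
  start <- pmax(start, 0)
  interval_set(genes$chrom, start, end, name = genes$gene_id,
               strand = genes$strand)
}

#' Flag promoter loops
#'
#' A loop is a promoter loop iff at least one anchor overlaps at least one
#' promoter window (>= 1 bp intersection); overlapping gene ids are recorded
#' in the `genes` column and `promoter_anchor` records which anchor carries
#' the promoter (1, 2 or 3 = both).
#'
#' @param loops `loop_records` (typically [filter_putative()] output).
#' @param genes gene table (gene_id, chrom, tss, strand).
#' @param upstream,downstream promoter window extents (defaults 5000/1000).
#' @return `loop_records` with `promoter`, `promoter_anchor` and `genes`
#'   filled.
#' @export
annotate_promoter <- function(loops, genes, upstream = 5000,
                              downstream = 1000) {
  pw <- promoter_windows(genes, upstream, downstream)
  gr <- .as_granges(pw)
  a1 <- .anchor_granges(loops, "1")
  a2 <- .anchor_granges(loops, "2")
  h1 <- GenomicRanges::findOverlaps(a1, gr, ignore.strand = TRUE)
  h2 <- GenomicRanges::findOverlaps(a2, gr, ignore.strand = TRUE)
  p1 <- tabulate(S4Vectors::queryHits(h1), nrow(loops)) > 0
  p2 <- tabulate(S4Vectors::queryHits(h2), nrow(loops)) > 0
  loops$promoter <- p1 | p2
  loops$promoter_anchor <- as.integer(p1) + 2L * as.integer(p2)
  gene_ids <- rep("", nrow(loops))
  hits <- rbind(
    data.frame(q = S4Vectors::queryHits(h1), g = pw$name[S4Vectors::subjectHits(h1)]),
    data.frame(q = S4Vectors::queryHits(h2), g = pw$name[S4Vectors::subjectHits(h2)]))
  if (nrow(hits)) {
    agg <- tapply(hits$g, hits$q, function(g) paste(sort(unique(g)),
                                                    collapse = ","))
    gene_ids[as.integer(names(agg))] <- unname(agg)
  }
  loops$genes <- gene_ids
  loops
}

#' Flag promoter-enhancer loops
#'
#' A promoter loop is an enhancer loop iff its distal (non-promoter) anchor
#' overlaps at least one peak of either enhancer mark (H3K27ac or H3K4me1).
#' When both anchors carry promoters, either anchor may serve as the distal
#' one.
#'
#' @param loops promoter-annotated `loop_records`.
#' @param marks list of `interval_set`s (e.g.
#'   `list(H3K27ac = ..., H3K4me1 = ...)`).
#' @return `loop_records` with the `enhancer` flag filled.
#' @export
annotate_enhancer <- function(loops, marks) {
  mk <- do.call(rbind, lapply(marks, function(x)
    as.data.frame(x)[, c("chrom", "start", "end")]))
  gr <- if (!is.null(mk) && nrow(mk))
    .as_granges(interval_set(mk$chrom, mk$start, mk$end)) else
      GenomicRanges::GRanges()
  a1 <- .overlaps_any(.anchor_granges(loops, "1"), gr)
  a2 <- .overlaps_any(.anchor_granges(loops, "2"), gr)
  pa <- loops$promoter_anchor
  loops$enhancer <- loops$promoter &
    ((pa == 1L & a2) | (pa == 2L & a1) | (pa == 3L & (a1 | a2)))
  loops
}

#' Flag ERalpha-regulated promoter-enhancer loops
#'
#' An enhancer loop is an ERalpha-PE loop iff either anchor contains at
#' least one ERalpha summit (summit = peak midpoint, a 1 bp point).
#'
#' @param loops enhancer-annotated `loop_records`.
#' @param era `interval_set` of ERalpha peaks.
#' @return `loop_records` with the `era_pe` flag filled.
#' @export
annotate_era_pe <- function(loops, era) {
  if (nrow(era)) {
    s <- .summits(era)
    gr <- GenomicRanges::GRanges(era$chrom,
                                 IRanges::IRanges(start = s + 1, width = 1))
  } else gr <- GenomicRanges::GRanges()
  a1 <- .overlaps_any(.anchor_granges(loops, "1"), gr)
  a2 <- .overlaps_any(.anchor_granges(loops, "2"), gr)
  loops$era_pe <- loops$enhancer & (a1 | a2)
  loops
}

#' Cascade summary: stage counts and differentially expressed looping genes
#'
#' Reports the number of loops surviving each cascade stage (putative,
#' promoter, enhancer, era_pe) and, restricted to loops whose two anchor
#' centers fall inside altered compartments of the named types, the distinct
#' differentially expressed genes linked via era_pe loops. A gene linked by
#' several loops is counted once in `n_genes`; each loop counts in
#' `n_loops_linked`.
#'
#' @param loops fully annotated `loop_records` (already putative-filtered).
#' @param degs differential-expression table with a `gene_id` column.
#' @param trac_calls optional `trac_calls`; when NULL no compartment
#'   restriction is applied.
#' @param restrict_types altered-compartment types defining the restriction
#'   (default `c("TA-MDC", "TA-HDC")`).
#' @param anchor_mode `"both"` (default: both anchor centers inside the
#'   footprints) or `"either"`.
#' @return list: `stage_counts` (named numeric), `n_loops_linked`,
#'   `n_genes`, `genes` (character vector).
#' @export
cascade_summary <- function(loops, degs, trac_calls = NULL,
                            restrict_types = c("TA-MDC", "TA-HDC"),
                            anchor_mode = c("both", "either")) {
  anchor_mode <- match.arg(anchor_mode)
  stage_counts <- c(putative = sum(loops$putative),
                    promoter = sum(loops$promoter),
                    enhancer = sum(loops$enhancer),
                    era_pe = sum(loops$era_pe))
  sel <- loops$era_pe
  if (!is.null(trac_calls)) {
    fp <- trac_calls[!is.na(trac_calls$trac_type) &
                       trac_calls$trac_type %in% restrict_types, ,
                     drop = FALSE]
    inside <- function(chrom, center) {
      vapply(seq_along(chrom), function(k)
        any(fp$chrom == chrom[k] & fp$start <= center[k] &
              center[k] < fp$end), logical(1))
    }
    c1 <- inside(loops$chrom1, (loops$start1 + loops$end1) / 2)
    c2 <- inside(loops$chrom2, (loops$start2 + loops$end2) / 2)
    sel <- sel & if (anchor_mode == "both") c1 & c2 else c1 | c2
  }
  linked <- loops[sel & loops$genes != "", , drop = FALSE]
  gene_list <- unique(unlist(strsplit(linked$genes, ",", fixed = TRUE)))
  deg_genes <- sort(intersect(gene_list, degs$gene_id))
  n_loops_linked <- sum(vapply(strsplit(linked$genes, ",", fixed = TRUE),
                               function(g) any(g %in% degs$gene_id),
                               logical(1)))
  list(stage_counts = stage_counts,
       n_loops_linked = n_loops_linked,
       n_genes = length(deg_genes),
       genes = deg_genes)
}
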