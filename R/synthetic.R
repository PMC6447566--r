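# Synthetic multi-timepoint inputs with planted ground truth. The generator
# plants alternating A/B compartments on a desk-scale genome and realises
# each compartment's intended dynamics pattern by flipping an interior block
# of bins (never the first or last footprint bin) at the Transit timepoints,
# so that neighbouring compartments keep their own footprints intact and
# every planted pattern is recoverable by construction.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Default desk-scale layout for synthetic data
#'
#' Three chromosomes of 20 Mb at 100 Kb bins (600 bins): large enough for
#' 20+ compartments per chromosome, small enough for seconds-level tests.
#' Three chromosomes (not two) because a trans-only bin-bin correlation is
#' only fully defined when every cross-chromosome bin pair shares rows on at
#' least one further chromosome.
#'
#' @return a [genome_layout()].
#' @export
default_synthetic_layout <- function() {
  genome_layout(c("chrS1", "chrS2", "chrS3"), c(2e7, 2e7, 2e7), 1e5)
}

# representative planted converted-bin count per pattern (patterns 16-24
# are defined by converted-bin classes; a value inside each class is used)
.planted_converted <- function(pattern, x_class_edges = .default_x_edges) {
  lo <- c(0, x_class_edges + 1)
  reps <- pmax(1, lo)
  reps[9] <- x_class_edges[8] + 2
  ifelse(pattern <= 15, 1L, as.integer(reps[pmax(pattern - 15, 1)]))
}

#' Plant a synthetic compartment/dynamics truth
#'
#' Tiles each chromosome with alternating A/B compartments, assigns the
#' requested patterns cyclically, and derives per-bin A/B labels for the
#' five timepoints plus the resistant (TamR) condition. Transit timepoints
#' are realised by flipping an interior block of bins of the footprint;
#' all-Transit patterns (16-24) flip a block sized to land inside the
#' intended converted-bin class. A subset of Transit compartments is planted
#' as TamR-altered (one interior bin converted in the TamR track).
#'
#' @param layout a `genome_layout` (default [default_synthetic_layout()]).
#' @param patterns pattern ids to plant, recycled across compartments
#'   (default `1:24`).
#' @param trac_fraction fraction of Transit-pattern compartments planted as
#'   TamR-altered (default 0.5).
#' @param seed integer seed (RNG state restored on exit).
#' @return list of class `synthetic_truth`: `layout`, `labels` (bins x
#'   tracks character matrix, tracks T0/T1/T4/T16/T24/TamR), `compartments`
#'   (footprints with planted `pattern`, `tdrc_type`, status vector,
#'   `planted_converted`, `trac_altered`, `tamr_converted`), `seed`.
#' @export
synthetic_truth <- function(layout = default_synthetic_layout(),
                            patterns = 1:24, trac_fraction = 0.5,
                            seed = 1) {
  stopifnot(all(patterns %in% 1:24))
  pt <- pattern_table()
  .with_seed(seed, {
    comp <- list()
    pat_i <- 0
    for (ch in layout$chroms) {
      nb <- layout$n_per_chrom[[ch]]
      pos <- 0
      lab <- "A"
      while (TRUE) {
        pat_i <- pat_i + 1
        p <- patterns[((pat_i - 1) %% length(patterns)) + 1]
        creq <- .planted_converted(p)
        size <- if (p <= 15) sample(4:8, 1) else creq + 3
        if (pos + size > nb - 3) {
          # absorb the remainder: a final common compartment, or extend the
          # previous one when fewer than 3 bins remain (labels must cover
          # every bin)
          rem <- nb - pos
          if (rem >= 3) {
            comp[[length(comp) + 1]] <- list(chrom = ch, bin0 = pos,
                                             n = rem, type = lab,
                                             pattern = 1L)
          } else if (rem > 0 && length(comp) > 0) {
            comp[[length(comp)]]$n <- comp[[length(comp)]]$n + rem
          }
          break
        }
        comp[[length(comp) + 1]] <- list(chrom = ch, bin0 = pos, n = size,
                                         type = lab, pattern = p)
        pos <- pos + size
        lab <- .opposite(lab)
      }
    }
    cdf <- do.call(rbind, lapply(comp, as.data.frame))
    cdf$start <- cdf$bin0 * layout$bin_size
    cdf$end <- pmin((cdf$bin0 + cdf$n) * layout$bin_size,
                    layout$lengths[cdf$chrom])
    cdf$planted_converted <- .planted_converted(cdf$pattern)
    cdf$tdrc_type <- tdrc_type_of(cdf$pattern)
    st <- pt[match(cdf$pattern, pt$pattern), c("s1", "s4", "s16", "s24")]
    cdf <- cbind(cdf, st)
    transit <- cdf$s1 == "T" | cdf$s4 == "T" | cdf$s16 == "T" |
      cdf$s24 == "T"
    cdf$trac_altered <- transit & stats::runif(nrow(cdf)) < trac_fraction
    # build label matrix
    off <- .chrom_offsets(layout)
    nb_tot <- n_bins(layout)
    tracks <- c("T0", "T1", "T4", "T16", "T24", "TamR")
    labels <- matrix(NA_character_, nb_tot, length(tracks),
                     dimnames = list(NULL, tracks))
    for (k in seq_len(nrow(cdf))) {
      bins <- off[cdf$chrom[k]] + cdf$bin0[k] + seq_len(cdf$n[k])
      labels[bins, ] <- cdf$type[k]
      cvt <- cdf$planted_converted[k]
      flip_bins <- bins[1 + seq_len(min(cvt, length(bins) - 2))]
      stat <- c(cdf$s1[k], cdf$s4[k], cdf$s16[k], cdf$s24[k])
      for (j in which(stat == "T"))
        labels[flip_bins, c("T1", "T4", "T16", "T24")[j]] <-
          .opposite(cdf$type[k])
      if (cdf$trac_altered[k])
        labels[bins[2], "TamR"] <- .opposite(cdf$type[k])
    }
    cdf$tamr_converted <- as.integer(cdf$trac_altered)
    rownames(cdf) <- NULL
    structure(list(layout = layout,
                   labels = labels,
                   compartments = cdf[, c("chrom", "start", "end", "type",
                                          "pattern", "tdrc_type",
                                          "s1", "s4", "s16", "s24",
                                          "planted_converted",
                                          "trac_altered", "tamr_converted")],
                   seed = seed),
              class = "synthetic_truth")
  })
}

#' Planted segmentation of one truth track
#'
#' @param truth a `synthetic_truth`.
#' @param track track name ("T0", ..., "TamR").
#' @return `compartment_segments` derived from the planted labels.
#' @export
truth_segments <- function(truth, track = "T0") {
  lab <- truth$labels[, track]
  tr <- .eigen_track(ifelse(lab == "A", 1, -1), truth$layout, track, TRUE)
  segment_compartments(tr)
}

#' Write / read a synthetic truth sidecar (YAML)
#'
#' Lossless round trip: labels are stored as one collapsed string per track.
#'
#' @param truth a `synthetic_truth`.
#' @param path YAML file path.
#' @return `path` invisibly; `read_truth` returns the `synthetic_truth`.
#' @export
write_truth <- function(truth, path) {
  obj <- list(
    layout = list(chroms = truth$layout$chroms,
                  lengths = as.numeric(truth$layout$lengths),
                  bin_size = truth$layout$bin_size),
    labels = lapply(as.data.frame(truth$labels),
                    function(col) paste(col, collapse = "")),
    compartments = lapply(seq_len(nrow(truth$compartments)), function(k)
      as.list(truth$compartments[k, ])),
    seed = truth$seed)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  obj <- yaml::read_yaml(path)
  layout <- genome_layout(obj$layout$chroms, obj$layout$lengths,
                          obj$layout$bin_size)
  labels <- sapply(obj$labels, function(s) strsplit(s, "")[[1]])
  cdf <- do.call(rbind, lapply(obj$compartments, as.data.frame))
  rownames(cdf) <- NULL
  structure(list(layout = layout, labels = labels, compartments = cdf,
                 seed = obj$seed),
            class = "synthetic_truth")
}

#' Generate a contact-matrix series from a planted truth
#'
#' Per track, the expected count between two distinct unmasked bins is
#' `base_mean * intra_block_enrichment` when the planted labels agree and
#' `base_mean` otherwise (no distance decay: compartment eigenvectors on
#' trans-style block signal do not need it). Counts are drawn from an
#' over-dispersed Poisson-gamma (negative binomial) model, Poisson in the
#' `noise_dispersion = 0` limit, and mirrored to a symmetric matrix.
#'
#' @param truth a `synthetic_truth`.
#' @param intra_block_enrichment same-label/different-label mean ratio
#'   (must be > 1).
#' @param noise_dispersion negative-binomial dispersion (>= 0; 0 = Poisson).
#' @param base_mean expected count between different-label bins.
#' @param tracks which truth tracks to generate (default all six).
#' @param seed integer seed.
#' @return named list of [contact_matrix()] objects.
#' @export
generate_contact_series <- function(truth, intra_block_enrichment = 3,
                                    noise_dispersion = 0.05, base_mean = 20,
                                    tracks = colnames(truth$labels),
                                    seed = 1) {
  if (intra_block_enrichment <= 1)
    stop("intra_block_enrichment must be > 1 (truth unrecoverable otherwise)")
  stopifnot(noise_dispersion >= 0)
  per_chrom <- table(truth$compartments$chrom)
  if (any(per_chrom < 2))
    stop("every chromosome needs >= 2 planted compartments")
  layout <- truth$layout
  nb <- n_bins(layout)
  ut <- upper.tri(matrix(0, nb, nb))
  .with_seed(seed, {
    out <- lapply(tracks, function(tk) {
      lab <- truth$labels[, tk]
      same <- outer(lab, lab, "==")
      mu <- ifelse(same, base_mean * intra_block_enrichment, base_mean)
      muv <- mu[ut]
      draws <- if (noise_dispersion > 0)
        stats::rnbinom(length(muv), mu = muv, size = 1 / noise_dispersion)
      else stats::rpois(length(muv), muv)
      m <- matrix(0, nb, nb)
      m[ut] <- draws
      m <- m + t(m)
      contact_matrix(m, layout)
    })
    names(out) <- tracks
    out
  })
}

#' Generate factor peaks biased toward planted compartments/boundaries
#'
#' Peak centers are sampled per bin with weight
#' `compartment_bias^(planted A) * boundary_bias^(within one bin of a
#' planted boundary)`; an infinite bias restricts the support to the
#' corresponding bins. Peaks are `peak_width` wide, centered uniformly
#' inside the sampled bin.
#'
#' @param truth a `synthetic_truth`.
#' @param factor peak factor name stored in the name column (e.g. "ERa",
#'   "CTCF", "H3K27ac").
#' @param counts number of peaks (> 0).
#' @param compartment_bias weight multiplier for planted-A bins (>= 0;
#'   `Inf` = A-only).
#' @param boundary_bias weight multiplier for bins flanking a planted
#'   boundary (>= 0; `Inf` = boundary-only).
#' @param track truth track whose labels define A bins and boundaries.
#' @param peak_width peak interval width in bp.
#' @param seed integer seed.
#' @return an [interval_set()] of peaks.
#' @export
generate_peaks <- function(truth, factor, counts, compartment_bias = 1,
                           boundary_bias = 1, track = "T0",
                           peak_width = 200, seed = 1) {
  stopifnot(counts > 0, compartment_bias >= 0, boundary_bias >= 0)
  if (compartment_bias == 0 && boundary_bias == 0)
    stop("all biases zero: no bin can receive a peak")
  layout <- truth$layout
  lab <- truth$labels[, track]
  ch <- .bin_chroms(layout)
  nb <- n_bins(layout)
  is_a <- lab == "A"
  change <- which(lab[-nb] != lab[-1] & ch[-nb] == ch[-1])
  near <- rep(FALSE, nb)
  near[change] <- TRUE
  near[change + 1] <- TRUE
  wf <- function(bias, flag) {
    if (is.infinite(bias)) as.numeric(flag) else ifelse(flag, bias, 1)
  }
  w <- wf(compartment_bias, is_a) * wf(boundary_bias, near)
  if (all(w == 0)) stop("all bin weights zero under the given biases")
  bt <- bin_table(layout)
  .with_seed(seed, {
    bins <- sample.int(nb, counts, replace = TRUE, prob = w)
    width_in <- pmax(bt$end[bins] - bt$start[bins] - peak_width, 0)
    center <- bt$start[bins] + peak_width / 2 +
      stats::runif(counts) * width_in
    interval_set(bt$chrom[bins],
                 floor(center - peak_width / 2),
                 floor(center + peak_width / 2),
                 name = paste0(factor, "_", seq_len(counts)),
                 layout = layout)
  })
}

# brute-force promoter-window overlap used only to record realized truth at
# generation time (independent of the GenomicRanges annotation path)
.brute_overlap <- function(a_start, a_end, a_chrom, w_start, w_end,
                           w_chrom) {
  if (!length(w_start)) return(rep(FALSE, length(a_start)))
  hit <- outer(a_start, w_end, "<") & outer(a_end, w_start, ">") &
    outer(a_chrom, w_chrom, "==")
  rowSums(hit) > 0
}

#' Generate loops with planted promoter/enhancer/ERalpha configuration
#'
#' Generates `n_loops` cis anchor pairs with significance values spanning
#' both sides of the putative and differential filters, plants a TSS in
#' anchor 1 for a `fraction_promoter` share, an enhancer mark (H3K27ac or
#' H3K4me1) in anchor 2 for a `fraction_enhancer_given_promoter` share of
#' those, an ERalpha summit in one anchor for a `fraction_era` share of
#' those, and marks a `fraction_deg` share of the planted genes as
#' differentially expressed. Realized survivor flags per cascade stage are
#' recorded by brute-force coordinate scans at generation time.
#'
#' @param truth a `synthetic_truth` (provides the genome layout).
#' @param n_loops number of loops (> 0).
#' @param fraction_promoter,fraction_enhancer_given_promoter,fraction_era
#'   cascade proportions in \[0, 1\].
#' @param fraction_significant share of loops passing the putative and
#'   differential filters (default 0.8).
#' @param fraction_deg share of planted genes that are differentially
#'   expressed (default 0.5).
#' @param anchor_width anchor width in bp (default 20000).
#' @param seed integer seed.
#' @return list: `loops` (`loop_records`), `tss` (gene table), `marks`
#'   (named list of `interval_set`), `era` (`interval_set`), `degs`
#'   (DE table), `truth` (per-loop realized stage flags + planted gene).
#' @export
generate_loops <- function(truth, n_loops = 1000, fraction_promoter = 0.5,
                           fraction_enhancer_given_promoter = 0.5,
                           fraction_era = 0.5, fraction_significant = 0.8,
                           fraction_deg = 0.5, anchor_width = 20000,
                           seed = 1) {
  stopifnot(n_loops > 0,
            fraction_promoter >= 0, fraction_promoter <= 1,
            fraction_enhancer_given_promoter >= 0,
            fraction_enhancer_given_promoter <= 1,
            fraction_era >= 0, fraction_era <= 1)
  if (anchor_width < 12000)
    stop("anchor_width must be >= 12000 so promoter windows stay inside ",
         "their own anchor")
  layout <- truth$layout
  # anchors are laid out on mutually disjoint slots (slot m paired with slot
  # m + B within blocks of 2B slots) so that loops never touch another
  # loop's promoter/mark/peak and the realized cascade truth equals the
  # planted configuration
  slot <- min(1e5, floor(sum(layout$lengths) /
                           (2 * n_loops + 2 * length(layout$chroms))))
  if (slot < anchor_width + 5000)
    stop("too many loops for this layout (anchor slots would overlap)")
  jit_max <- slot - anchor_width - 1
  b_min <- max(2, ceiling((6e4 + slot) / slot))
  b_max <- max(b_min, floor(2e6 / slot))
  .with_seed(seed, {
    ns_chrom <- floor(layout$lengths / slot)
    alloc <- pmin(floor(n_loops * ns_chrom / sum(ns_chrom)),
                  floor(ns_chrom / 2))
    while (sum(alloc) < n_loops) {
      room <- which(alloc < floor(ns_chrom / 2))
      if (!length(room)) stop("too many loops for this layout")
      alloc[room[1]] <- alloc[room[1]] + 1
    }
    chrom <- character(0); slot1 <- numeric(0); slot2 <- numeric(0)
    for (ci in seq_along(layout$chroms)) {
      p <- 0; remaining <- alloc[ci]
      while (remaining > 0) {
        b <- min(sample(b_min:b_max, 1), remaining,
                 floor((ns_chrom[ci] - p) / 2))
        if (b < 1) stop("slot pairing exhausted; reduce n_loops")
        m <- seq_len(b) - 1
        chrom <- c(chrom, rep(layout$chroms[ci], b))
        slot1 <- c(slot1, (p + m) * slot)
        slot2 <- c(slot2, (p + m + b) * slot)
        p <- p + 2 * b
        remaining <- remaining - b
      }
    }
    ord <- sample.int(n_loops)  # decouple loop index from genomic order
    chrom <- chrom[ord]; slot1 <- slot1[ord]; slot2 <- slot2[ord]
    s1 <- slot1 + floor(stats::runif(n_loops, 0, jit_max))
    e1 <- s1 + anchor_width
    s2 <- slot2 + floor(stats::runif(n_loops, 0, jit_max))
    e2 <- s2 + anchor_width
    distance <- (s2 + e2) / 2 - (s1 + e1) / 2
    sig <- stats::runif(n_loops) < fraction_significant
    logP <- stats::runif(n_loops, -30, -7)
    fdr <- stats::runif(n_loops, 0, 0.1)
    fail_mode <- sample(1:2, n_loops, replace = TRUE)
    for (i in which(!sig)) {
      if (fail_mode[i] == 1) logP[i] <- stats::runif(1, -5, -1)
      else fdr[i] <- stats::runif(1, 0.15, 0.9)
    }
    has_prom <- stats::runif(n_loops) < fraction_promoter
    has_enh <- has_prom &
      stats::runif(n_loops) < fraction_enhancer_given_promoter
    has_era <- has_enh & stats::runif(n_loops) < fraction_era
    gene_id <- ifelse(has_prom, sprintf("LG%05d", seq_len(n_loops)),
                      NA_character_)
    tss <- floor((s1 + e1) / 2)
    strand <- sample(c("+", "-"), n_loops, replace = TRUE)
    genes <- data.frame(gene_id = gene_id[has_prom],
                        chrom = chrom[has_prom], tss = tss[has_prom],
                        strand = strand[has_prom],
                        stringsAsFactors = FALSE)
    mark_name <- sample(c("H3K27ac", "H3K4me1"), n_loops, replace = TRUE)
    mark_center <- floor((s2 + e2) / 2)
    marks <- lapply(c(H3K27ac = "H3K27ac", H3K4me1 = "H3K4me1"),
                    function(mn) {
      sel <- has_enh & mark_name == mn
      if (!any(sel))
        return(interval_set(character(0), numeric(0), numeric(0)))
      interval_set(chrom[sel], mark_center[sel] - 200,
                   mark_center[sel] + 200, name = mn)
    })
    era_anchor <- sample(1:2, n_loops, replace = TRUE)
    era_center <- ifelse(era_anchor == 1, floor((s1 + e1) / 2),
                         floor((s2 + e2) / 2))
    era <- if (any(has_era))
      interval_set(chrom[has_era], era_center[has_era] - 100,
                   era_center[has_era] + 100, name = "ERa")
    else interval_set(character(0), numeric(0), numeric(0))
    is_deg <- !is.na(gene_id) & stats::runif(n_loops) < fraction_deg
    degs <- data.frame(gene_id = gene_id[is_deg],
                       log2fc = stats::runif(sum(is_deg), 1, 3) *
                         sample(c(-1, 1), sum(is_deg), replace = TRUE),
                       stringsAsFactors = FALSE)
    # realized stage flags: brute-force scans over the generated coordinates
    pw_start <- ifelse(genes$strand == "+", genes$tss - 5000,
                       genes$tss - 1000 + 1)
    pw_end <- ifelse(genes$strand == "+", genes$tss + 1000,
                     genes$tss + 5000 + 1)
    p1 <- .brute_overlap(s1, e1, chrom, pw_start, pw_end, genes$chrom)
    p2 <- .brute_overlap(s2, e2, chrom, pw_start, pw_end, genes$chrom)
    mk <- do.call(rbind, lapply(names(marks), function(mn)
      as.data.frame(marks[[mn]])[, c("chrom", "start", "end")]))
    m1 <- .brute_overlap(s1, e1, chrom, mk$start, mk$end, mk$chrom)
    m2 <- .brute_overlap(s2, e2, chrom, mk$start, mk$end, mk$chrom)
    esum <- .summits(era)
    e1h <- .brute_overlap(s1, e1, chrom, esum, esum + 1, era$chrom)
    e2h <- .brute_overlap(s2, e2, chrom, esum, esum + 1, era$chrom)
    put <- logP <= -6 & distance >= 2e4
    prom <- put & (p1 | p2)
    enh <- prom & ((p1 & !p2 & m2) | (p2 & !p1 & m1) | (p1 & p2 & (m1 | m2)))
    erape <- enh & (e1h | e2h)
    loop_truth <- data.frame(
      loop = seq_len(n_loops), significant = sig,
      putative = put, promoter = prom, enhancer = enh, era_pe = erape,
      differential = fdr <= 0.1 & distance >= 4e4 & distance <= 5e6,
      gene_id = gene_id, deg = is_deg, stringsAsFactors = FALSE)
    loops <- loop_records(data.frame(
      chrom1 = chrom, start1 = s1, end1 = e1,
      chrom2 = chrom, start2 = s2, end2 = e2,
      logP = logP, fdr = fdr, stringsAsFactors = FALSE), layout = layout)
    list(loops = loops, tss = genes, marks = marks, era = era, degs = degs,
         truth = loop_truth)
  })
}

#' Generate a log-normal expression time course with planted dynamic genes
#'
#' Static genes hold a constant log2 baseline across the five timepoints;
#' dynamic genes additionally follow a scaled temporal profile of amplitude
#' `effect_log2fc`. Gaussian noise of sd `noise_sd` is added per cell.
#'
#' @param truth a `synthetic_truth` (for reproducibility bookkeeping only).
#' @param n_genes number of genes (> 0).
#' @param dynamic_fraction share of genes planted dynamic.
#' @param effect_log2fc log2 amplitude of the dynamic profile.
#' @param noise_sd per-observation Gaussian noise sd (log2 scale).
#' @param seed integer seed.
#' @return list: `expression` (log2 matrix genes x T0..T24), `de_table`
#'   (gene_id, dynamic, log2fc), `dynamic_genes` (character ids).
#' @export
generate_expression <- function(truth, n_genes = 2000,
                                dynamic_fraction = 0.2, effect_log2fc = 2,
                                noise_sd = 0.3, seed = 1) {
  stopifnot(n_genes > 0)
  tps <- c("T0", "T1", "T4", "T16", "T24")
  profiles <- rbind(c(0, 1, 0.6, 0.2, -0.2),
                    c(0, -1, -0.6, -0.2, 0.2),
                    c(0, 0.2, 0.6, 1, 0.8))
  .with_seed(seed, {
    ids <- sprintf("G%05d", seq_len(n_genes))
    base <- stats::rnorm(n_genes, 5, 2)
    dyn <- rep(FALSE, n_genes)
    dyn[sample.int(n_genes, round(n_genes * dynamic_fraction))] <- TRUE
    m <- matrix(rep(base, 5), ncol = 5, dimnames = list(ids, tps))
    if (any(dyn)) {
      shape <- profiles[sample.int(nrow(profiles), sum(dyn), replace = TRUE),
                        , drop = FALSE]
      m[dyn, ] <- m[dyn, ] + effect_log2fc * shape
    }
    if (noise_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), 0, noise_sd), nrow = n_genes)
    de <- data.frame(gene_id = ids, dynamic = dyn,
                     log2fc = apply(m, 1, function(r) max(r) - min(r)),
                     stringsAsFactors = FALSE)
    list(expression = m, de_table = de, dynamic_genes = ids[dyn])
  })
}
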