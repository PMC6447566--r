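# Shared fixtures and independent brute-force oracles.

tiny_layout <- function(nchrom = 3, nbins = 20, bin = 1e5) {
  genome_layout(paste0("c", seq_len(nchrom)), rep(nbins * bin, nchrom), bin)
}

# hand-built truth object for custom label plantings (same fields as
# synthetic_truth())
manual_truth <- function(layout, labels) {
  if (is.vector(labels))
    labels <- matrix(labels, ncol = 1, dimnames = list(NULL, "T0"))
  stopifnot(nrow(labels) == n_bins(layout))
  comp <- do.call(rbind, lapply(unique(.bin_chroms_test(layout)), function(ch)
    data.frame(chrom = c(ch, ch), stringsAsFactors = FALSE)))
  structure(list(layout = layout, labels = labels, compartments = comp,
                 seed = 0L), class = "synthetic_truth")
}

.bin_chroms_test <- function(layout)
  rep(layout$chroms, times = layout$n_per_chrom)

# expand a run-length spec like c(A = 3, B = 2, A = 1) to a label vector
labels_from_runs <- function(...) {
  runs <- c(...)
  rep(names(runs), times = unname(runs))
}

# eigen_track built directly from labels (values +/-1)
track_from_labels <- function(labels, layout, timepoint = NA_character_) {
  val <- ifelse(is.na(labels), NA_real_, ifelse(labels == "A", 1, -1))
  compdyn:::.eigen_track(val, layout, timepoint, oriented = TRUE)
}

# brute-force summit counts per footprint
brute_summit_counts <- function(peaks, footprints) {
  s <- floor((peaks$start + peaks$end) / 2)
  vapply(seq_len(nrow(footprints)), function(k) {
    hit <- 0
    for (i in seq_along(s)) {
      if (peaks$chrom[i] == footprints$chrom[k] &&
          s[i] >= footprints$start[k] && s[i] < footprints$end[k])
        hit <- hit + 1
    }
    hit
  }, numeric(1))
}

# brute-force bp overlap of an interval table with one window
brute_overlap_bp <- function(x, chrom, start, end) {
  total <- 0
  for (i in seq_len(nrow(x))) {
    if (x$chrom[i] != chrom) next
    lo <- max(x$start[i], start); hi <- min(x$end[i], end)
    if (hi > lo) total <- total + (hi - lo)
  }
  total
}

# brute-force anchor-vs-intervals overlap flag per loop
brute_anchor_hit <- function(loops, which, ivs) {
  s <- loops[[paste0("start", which)]]
  e <- loops[[paste0("end", which)]]
  ch <- loops[[paste0("chrom", which)]]
  vapply(seq_len(nrow(loops)), function(k)
    any(ivs$chrom == ch[k] & ivs$start < e[k] & ivs$end > s[k]),
    logical(1))
}

random_intervals <- function(n, layout, width = c(100, 5000), seed = 1) {
  set.seed(seed)
  ch <- sample(layout$chroms, n, replace = TRUE)
  len <- as.numeric(layout$lengths[ch])
  w <- floor(runif(n, width[1], width[2]))
  start <- floor(runif(n) * (len - w))
  interval_set(ch, start, start + w,
               name = paste0("iv", seq_len(n)),
               score = round(runif(n), 3),
               strand = sample(c("+", "-", "."), n, replace = TRUE))
}
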