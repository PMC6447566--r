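segs_from_runs <- function(gl, ...) {
  segment_compartments(track_from_labels(labels_from_runs(...), gl))
}

test_that("comparing a segmentation with itself yields all Common", {
  gl <- genome_layout("c1", 2e6, 1e5)
  segs <- segs_from_runs(gl, A = 5, B = 5, A = 6, B = 4)
  cmp <- match_compartments(segs, segs)
  expect_true(all(cmp$status == "Common"))
  expect_true(all(cmp$shift == 0))
  expect_true(all(cmp$converted_bins == 0))
  expect_false(any(cmp$flipped))
})

test_that("a one-bin boundary move is Transit with shift 100 Kb and 1 converted bin", {
  gl <- genome_layout("c1", 2e6, 1e5)
  ref <- segs_from_runs(gl, A = 10, B = 10)
  oth <- segs_from_runs(gl, A = 9, B = 11)
  cmp <- match_compartments(ref, oth)
  expect_equal(cmp$status, c("Transit", "Transit"))
  expect_equal(cmp$shift, c(1e5, 1e5))
  expect_equal(cmp$converted_bins, c(1, 0))
  expect_false(any(cmp$flipped))
})

test_that("a fully sign-changed footprint is flipped", {
  gl <- genome_layout("c1", 2e6, 1e5)
  ref <- segs_from_runs(gl, A = 5, B = 5, A = 10)
  oth <- segs_from_runs(gl, A = 5, A = 5, A = 10)  # middle B became A
  cmp <- match_compartments(ref, oth)
  expect_equal(cmp$status[2], "Transit")
  expect_true(cmp$flipped[2])
  expect_equal(cmp$shift[2], 0)  # no same-type match: boundaries undefined
  expect_equal(cmp$converted_bins[2], 5)
})

test_that("mismatched layouts are rejected", {
  g1 <- genome_layout("c1", 2e6, 1e5)
  g2 <- genome_layout("c1", 2e6, 2e5)
  s1 <- segs_from_runs(g1, A = 10, B = 10)
  s2 <- segs_from_runs(g2, A = 5, B = 5)
  expect_error(match_compartments(s1, s2), "different layouts")
})

test_that("pattern ranges partition 1-24 into the six types", {
  pt <- pattern_table()
  expect_equal(nrow(pt), 24)
  expect_equal(unname(table(pt$tdrc_type)[c("HCC", "ETC", "LTC", "LDC",
                                            "MDC", "HDC")]),
               rep(4L, 6), ignore_attr = TRUE)
  expect_equal(tdrc_type_of(c(1, 5, 9, 13, 17, 21)),
               c("HCC", "ETC", "LTC", "LDC", "MDC", "HDC"))
  # all-Transit iff pattern >= 16
  all_t <- pt$s1 == "T" & pt$s4 == "T" & pt$s16 == "T" & pt$s24 == "T"
  expect_equal(pt$pattern[all_t], 16:24)
  # the 16 status sets are distinct and complete
  keys <- unique(paste(pt$s1, pt$s4, pt$s16, pt$s24))
  expect_equal(length(keys), 16)
})

test_that("identical timepoints give all-Common HCC; early/late transits map to ETC/LTC", {
  gl <- genome_layout("c1", 3e6, 1e5)
  s <- segs_from_runs(gl, A = 8, B = 8, A = 8, B = 6)
  asg <- classify_timeline(s, s, s, s, s)
  expect_true(all(asg$pattern == 1))
  expect_true(all(asg$tdrc_type == "HCC"))
  expect_true(all(asg$converted_bins == 0))

  # Transit at T1 only (interior flip in first compartment)
  l0 <- labels_from_runs(A = 8, B = 8, A = 8, B = 6)
  l1 <- l0; l1[2] <- "B"
  s1 <- segment_compartments(track_from_labels(l1, gl))
  asg2 <- classify_timeline(s, s1, s, s, s)
  expect_equal(asg2$pattern[1], 5)
  expect_equal(asg2$tdrc_type[1], "ETC")

  # Transit at T16+T24 only -> LTC
  asg3 <- classify_timeline(s, s, s, s1, s1)
  expect_equal(asg3$pattern[1], 11)
  expect_equal(asg3$tdrc_type[1], "LTC")
})

test_that("all-Transit compartments are subdivided by converted bins", {
  gl <- genome_layout("c1", 4e6, 1e5)
  l0 <- labels_from_runs(A = 30, B = 10)
  s0 <- segment_compartments(track_from_labels(l0, gl))
  for (cv in c(1, 3, 8, 21)) {
    lx <- l0; lx[1 + seq_len(cv)] <- "B"
    sx <- segment_compartments(track_from_labels(lx, gl))
    asg <- classify_timeline(s0, sx, sx, sx, sx)
    expect_equal(asg$converted_bins[1], cv)
    expected_pattern <- c(`1` = 16, `3` = 17, `8` = 20, `21` = 24)
    expect_equal(asg$pattern[1], unname(expected_pattern[as.character(cv)]))
  }
})

test_that("pattern-space enumeration reproduces the published structure", {
  e <- enumerate_pattern_space()
  expect_equal(e$sets, 16)
  expect_equal(e$combinatorial_patterns, 15)
  expect_equal(e$x_subdivision_patterns, 9)
  expect_equal(e$total_patterns, 24)
  expect_equal(e$types, 6)
  expect_equal(e$t0_contrast_combinations, 256)
})

test_that("a dataset planting every status set realises exactly the 16 enumerated sets", {
  tr <- synthetic_truth(patterns = 1:24, seed = 8)
  segs <- lapply(colnames(tr$labels), function(tk) truth_segments(tr, tk))
  names(segs) <- colnames(tr$labels)
  asg <- classify_timeline(segs$T0, segs$T1, segs$T4, segs$T16, segs$T24)
  realised <- unique(paste(asg$s1, asg$s4, asg$s16, asg$s24))
  expect_equal(length(realised), 16)
  expect_setequal(asg$pattern, 1:24)
  # exhaustive & exclusive: one pattern and one type per compartment
  expect_false(any(is.na(asg$pattern)))
  expect_true(all(asg$tdrc_type == tdrc_type_of(asg$pattern)))
})

test_that("planted patterns are recovered from truth labels", {
  tr <- synthetic_truth(seed = 3)
  segs <- lapply(colnames(tr$labels), function(tk) truth_segments(tr, tk))
  names(segs) <- colnames(tr$labels)
  asg <- classify_timeline(segs$T0, segs$T1, segs$T4, segs$T16, segs$T24)
  key <- function(d) paste(d$chrom, d$start, d$end)
  m <- match(key(tr$compartments), key(asg))
  expect_false(any(is.na(m)))
  expect_equal(asg$pattern[m], tr$compartments$pattern)
})

test_that("TRAC calls require Transit status and a converted TamR bin", {
  gl <- genome_layout("c1", 3e6, 1e5)
  l0 <- labels_from_runs(A = 10, B = 10, A = 10)
  s0 <- segment_compartments(track_from_labels(l0, gl))
  l1 <- l0; l1[2] <- "B"   # compartment 1 Transit at all timepoints
  s1 <- segment_compartments(track_from_labels(l1, gl))
  asg <- classify_timeline(s0, s1, s1, s1, s1)

  # TamR identical to T0 -> every compartment TRUC
  tc <- call_trac(asg, s0)
  expect_true(all(tc$call == "TRUC"))
  expect_true(all(is.na(tc$trac_type)))

  # one converted TamR bin in the Transit compartment -> TRAC
  lt <- l0; lt[3] <- "B"
  st <- segment_compartments(track_from_labels(lt, gl))
  tc2 <- call_trac(asg, st)
  expect_equal(tc2$call[1], "TRAC")
  expect_equal(tc2$tamr_converted[1], 1)
  expect_equal(tc2$trac_type[1], paste0("TA-", asg$tdrc_type[1]))
  # all-Common compartments are never TRAC even with converted bins
  expect_true(all(tc2$call[asg$s1 == "C" & asg$s4 == "C" &
                             asg$s16 == "C" & asg$s24 == "C"] == "TRUC"))
})

test_that("TamR change classes detect shrunk, expanded and flipped footprints", {
  gl <- genome_layout("c1", 4e6, 1e5)
  l0 <- labels_from_runs(A = 10, B = 10, A = 10, B = 10)
  s0 <- segment_compartments(track_from_labels(l0, gl))
  l1 <- l0; l1[11] <- "A"  # make compartment 1 Transit
  s1 <- segment_compartments(track_from_labels(l1, gl))
  asg <- classify_timeline(s0, s1, s1, s1, s1)

  lt <- labels_from_runs(A = 7, B = 13, A = 12, B = 8)
  tc <- call_trac(asg, segment_compartments(track_from_labels(lt, gl)))
  expect_equal(tc$change_class[1], "Shrunk")     # A 10 -> 7
  expect_equal(tc$change_class[3], "Expanded")   # A 10 -> 22

  lf <- l0; lf[1:10] <- "B"
  tcf <- call_trac(asg, segment_compartments(track_from_labels(lf, gl)))
  expect_equal(tcf$change_class[1], "Flipped")
})

test_that("size statistics summarise by group and skip empty groups", {
  x <- data.frame(chrom = "c1", start = c(0, 3e5), end = c(3e5, 8e5),
                  tdrc_type = c("HDC", "HDC"))
  s <- size_statistics(x)
  expect_equal(s$mean_bp, 4e5)
  expect_equal(s$n, 2)

  x2 <- data.frame(chrom = "c1", start = 0, end = 1e5, tdrc_type = "HCC")
  s2 <- size_statistics(x2)
  expect_equal(s2$mean_bp, 1e5)     # single-bin compartment = bin size
  expect_false("HDC" %in% s2$tdrc_type)

  tr <- synthetic_truth(seed = 4)
  st <- size_statistics(tr$compartments)
  hdc <- st$mean_bp[st$tdrc_type == "HDC"]
  hcc <- st$mean_bp[st$tdrc_type == "HCC"]
  expect_gt(hdc, hcc)  # high-converted patterns are planted longer
})
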