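mk_loops <- function(df) {
  base <- data.frame(chrom1 = "c1", start1 = 0, end1 = 2e4,
                     chrom2 = "c1", start2 = 1e5, end2 = 1.2e5,
                     logP = -10, fdr = 0.01)
  out <- base[rep(1, nrow(df)), ]
  for (nm in names(df)) out[[nm]] <- df[[nm]]
  loop_records(out)
}

test_that("putative filter applies logP and center-distance cutoffs", {
  lp <- mk_loops(data.frame(logP = c(-5, -10, -7),
                            start2 = c(1e5, 5e3, 1e5),
                            end2 = c(1.2e5, 2.5e4, 1.2e5)))
  out <- filter_putative(lp)
  expect_equal(nrow(out), 1)          # -5 fails logP; 5 Kb fails distance
  expect_equal(out$logP, -7)
  expect_true(all(out$putative))

  trans <- mk_loops(data.frame(chrom2 = "c2"))
  expect_equal(nrow(filter_putative(trans)), 0)
})

test_that("differential filter applies FDR and the closed distance range", {
  lp <- mk_loops(data.frame(fdr = c(0.05, 0.2, 0.05, 0.05),
                            start2 = c(1e6, 1e6, 6e6, 2e4),
                            end2 = c(1e6 + 2e4, 1e6 + 2e4, 6e6 + 2e4, 4e4)))
  out <- filter_differential(lp)
  expect_equal(nrow(out), 1)
  expect_equal(out$distance, 1e6)
})

test_that("promoter windows reflect strand", {
  g <- data.frame(gene_id = c("g+", "g-"), chrom = "c1",
                  tss = c(1e5, 1e5), strand = c("+", "-"))
  w <- promoter_windows(g)
  expect_equal(w$start[1], 95000)
  expect_equal(w$end[1], 101000)
  expect_equal(w$start[2], 99001)
  expect_equal(w$end[2], 105001)
})

test_that("promoter annotation flags anchors overlapping promoter windows", {
  genes <- data.frame(gene_id = "g1", chrom = "c1", tss = 1e5,
                      strand = "+")
  # anchor [94000, 96000) overlaps the window [95000, 101000)
  lp <- mk_loops(data.frame(start1 = 94000, end1 = 96000,
                            start2 = 5e5, end2 = 5.2e5))
  out <- annotate_promoter(lp, genes)
  expect_true(out$promoter)
  expect_equal(out$promoter_anchor, 1L)
  expect_equal(out$genes, "g1")

  # anchor just left of the window is not flagged
  lp2 <- mk_loops(data.frame(start1 = 90000, end1 = 95000,
                             start2 = 5e5, end2 = 5.2e5))
  expect_false(annotate_promoter(lp2, genes)$promoter)
})

test_that("enhancer flag requires a mark at the distal anchor", {
  genes <- data.frame(gene_id = "g1", chrom = "c1", tss = 1e4,
                      strand = "+")
  lp <- mk_loops(data.frame(start1 = 5e3, end1 = 2.5e4,
                            start2 = 5e5, end2 = 5.2e5))
  lp <- annotate_promoter(lp, genes)
  expect_equal(lp$promoter_anchor, 1L)

  distal_mark <- list(H3K4me1 = interval_set("c1", 5.05e5, 5.1e5))
  expect_true(annotate_enhancer(lp, distal_mark)$enhancer)
  # a mark at the promoter anchor does not qualify
  prox_mark <- list(H3K27ac = interval_set("c1", 6e3, 7e3))
  expect_false(annotate_enhancer(lp, prox_mark)$enhancer)
  none <- list(H3K27ac = interval_set(character(0), numeric(0), numeric(0)))
  expect_false(annotate_enhancer(lp, none)$enhancer)
})

test_that("ERa flag accepts a summit in either anchor, only for enhancer loops", {
  genes <- data.frame(gene_id = "g1", chrom = "c1", tss = 1e4, strand = "+")
  lp <- mk_loops(data.frame(start1 = 5e3, end1 = 2.5e4,
                            start2 = 5e5, end2 = 5.2e5))
  lp <- annotate_promoter(lp, genes)
  lp <- annotate_enhancer(lp, list(H3K4me1 = interval_set("c1", 5.05e5,
                                                          5.1e5)))
  era2 <- interval_set("c1", 5.1e5, 5.1e5 + 200)   # summit in anchor 2
  expect_true(annotate_era_pe(lp, era2)$era_pe)
  era_out <- interval_set("c1", 8e5, 8e5 + 200)
  expect_false(annotate_era_pe(lp, era_out)$era_pe)

  lp_noenh <- lp; lp_noenh$enhancer <- FALSE
  expect_false(annotate_era_pe(lp_noenh, era2)$era_pe)
})

test_that("annotation flags match brute-force scans and are order-independent", {
  tr <- synthetic_truth(seed = 21)
  lp <- generate_loops(tr, n_loops = 400, fraction_promoter = 0.5,
                       fraction_enhancer_given_promoter = 0.6,
                       fraction_era = 0.5, fraction_significant = 1,
                       seed = 9)
  ann <- annotate_promoter(filter_putative(lp$loops), lp$tss)
  ann <- annotate_enhancer(ann, lp$marks)
  ann <- annotate_era_pe(ann, lp$era)

  pw <- promoter_windows(lp$tss)
  p1 <- brute_anchor_hit(ann, "1", pw)
  p2 <- brute_anchor_hit(ann, "2", pw)
  expect_equal(ann$promoter, p1 | p2)

  mk <- rbind(as.data.frame(lp$marks$H3K27ac)[, 1:3],
              as.data.frame(lp$marks$H3K4me1)[, 1:3])
  m1 <- brute_anchor_hit(ann, "1", mk)
  m2 <- brute_anchor_hit(ann, "2", mk)
  pa <- ann$promoter_anchor
  expect_equal(ann$enhancer,
               ann$promoter & ((pa == 1 & m2) | (pa == 2 & m1) |
                                 (pa == 3 & (m1 | m2))))

  es <- floor((lp$era$start + lp$era$end) / 2)
  ei <- data.frame(chrom = lp$era$chrom, start = es, end = es + 1)
  expect_equal(ann$era_pe,
               ann$enhancer & (brute_anchor_hit(ann, "1", ei) |
                                 brute_anchor_hit(ann, "2", ei)))

  # order-independence
  set.seed(1)
  perm <- sample(nrow(lp$loops))
  ann2 <- annotate_promoter(filter_putative(lp$loops[perm, ]), lp$tss)
  ann2 <- annotate_enhancer(ann2, lp$marks)
  ann2 <- annotate_era_pe(ann2, lp$era)
  o1 <- ann[order(ann$start1, ann$start2), ]
  o2 <- ann2[order(ann2$start1, ann2$start2), ]
  expect_equal(o1, o2, ignore_attr = TRUE)
})

test_that("cascade counts are monotone and survivor sets match planted truth", {
  tr <- synthetic_truth(seed = 21)
  set.seed(99)
  for (rep in 1:10) {
    lp <- generate_loops(tr, n_loops = 150,
                         fraction_promoter = runif(1, 0.2, 0.9),
                         fraction_enhancer_given_promoter = runif(1, 0.2, 0.9),
                         fraction_era = runif(1, 0.2, 0.9),
                         fraction_significant = runif(1, 0.5, 1),
                         seed = 1000 + rep)
    loops <- lp$loops
    loops$loop_id <- lp$truth$loop
    ann <- annotate_promoter(filter_putative(loops), lp$tss)
    ann <- annotate_enhancer(ann, lp$marks)
    ann <- annotate_era_pe(ann, lp$era)
    cs <- cascade_summary(ann, lp$degs)
    expect_true(all(diff(cs$stage_counts) <= 0))
    # survivor SETS (not merely counts) equal the planted truth
    tt <- lp$truth
    expect_setequal(ann$loop_id, tt$loop[tt$putative])
    expect_setequal(ann$loop_id[ann$promoter], tt$loop[tt$promoter])
    expect_setequal(ann$loop_id[ann$enhancer], tt$loop[tt$enhancer])
    expect_setequal(ann$loop_id[ann$era_pe], tt$loop[tt$era_pe])
  }
})

test_that("cascade gene counting is distinct per gene, per-loop for loops", {
  genes <- data.frame(gene_id = "g1", chrom = "c1", tss = c(1e4),
                      strand = "+")
  lp <- mk_loops(data.frame(start1 = c(5e3, 6e3), end1 = c(2.5e4, 2.6e4),
                            start2 = c(5e5, 7e5), end2 = c(5.2e5, 7.2e5)))
  lp <- filter_putative(lp)
  lp <- annotate_promoter(lp, genes)
  lp <- annotate_enhancer(lp, list(
    m = interval_set(c("c1", "c1"), c(5.05e5, 7.05e5), c(5.1e5, 7.1e5))))
  lp <- annotate_era_pe(lp, interval_set(c("c1", "c1"), c(5.05e5, 7.05e5),
                                         c(5.06e5, 7.06e5)))
  degs <- data.frame(gene_id = "g1", log2fc = 2)
  cs <- cascade_summary(lp, degs)
  expect_equal(cs$n_genes, 1)          # one distinct DEG
  expect_equal(cs$n_loops_linked, 2)   # linked by two loops
  expect_equal(cs$genes, "g1")

  empty <- lp[0, ]
  cs0 <- cascade_summary(empty, degs)
  expect_true(all(cs0$stage_counts == 0))
  expect_equal(cs0$n_genes, 0)
})

test_that("compartment restriction keeps loops inside the named TRAC types", {
  calls <- data.frame(chrom = "c1", start = 0, end = 1e6,
                      trac_type = "TA-HDC")
  genes <- data.frame(gene_id = "g1", chrom = "c1", tss = 1e4, strand = "+")
  inside <- mk_loops(data.frame(start1 = 5e3, end1 = 2.5e4,
                                start2 = 5e5, end2 = 5.2e5))
  outside <- mk_loops(data.frame(start1 = 5e3, end1 = 2.5e4,
                                 start2 = 2e6, end2 = 2.02e6))
  lp <- rbind(inside, outside)
  class(lp) <- class(inside)
  lp <- filter_putative(lp)
  lp <- annotate_promoter(lp, genes)
  lp$enhancer <- TRUE; lp$era_pe <- TRUE
  degs <- data.frame(gene_id = "g1")
  cs_both <- cascade_summary(lp, degs, trac_calls = calls)
  expect_equal(cs_both$n_loops_linked, 1)
  cs_any <- cascade_summary(lp, degs, trac_calls = calls,
                            anchor_mode = "either")
  expect_equal(cs_any$n_loops_linked, 2)
})
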