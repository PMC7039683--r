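test_that("flanked_regions applies the 1500 bp gap rule", {
  pk <- gintervals("c", c(100L, 1500L), c(200L, 1600L))
  fl <- flanked_regions(pk)
  expect_equal(nrow(fl), 1)
  expect_identical(c(fl$start, fl$end), c(200L, 1500L))

  far <- gintervals("c", c(100L, 1800L), c(200L, 1900L)) # gap 1600
  expect_equal(nrow(flanked_regions(far)), 0)
  expect_equal(nrow(flanked_regions(far, max_gap = 1600L)), 1)
  expect_equal(nrow(flanked_regions(pk[1, ])), 0)
  # configurable minimum gap
  expect_equal(nrow(flanked_regions(pk, min_gap = 1400L)), 0)
})

test_that("classify_k27: overlap, flanked gap, and distance cases", {
  pk <- gintervals("c", c(1000L, 3000L), c(2000L, 3100L)) # gap 1000
  nfrs <- gintervals("c", c(1200L, 2300L, 50000L), c(1600L, 2700L, 50400L))
  cl <- classify_k27(nfrs, pk)
  expect_identical(cl, c(1L, 1L, 2L))
  # union vs intersection across tracks
  pk2 <- gintervals("c", 49900L, 50500L)
  expect_identical(classify_k27(nfrs, list(pk, pk2)), c(1L, 1L, 1L))
  expect_identical(classify_k27(nfrs, list(pk, pk2), mode = "intersection"),
                   c(2L, 2L, 2L))
})

test_that("remove_tss_overlaps pads point TSSs", {
  tss <- gintervals("c", 5000L, 5001L)
  els <- gintervals("c", c(4900L, 5502L, 8000L), c(5300L, 5902L, 8400L))
  kept <- remove_tss_overlaps(els, tss)
  expect_identical(kept$start, c(5502L, 8000L)) # 501 bp away is retained
  expect_identical(remove_tss_overlaps(els, tss[0, ]), els)
  closecall <- gintervals("c", 5400L, 5800L) # touches the 500 bp pad
  expect_equal(nrow(remove_tss_overlaps(closecall, tss)), 0)
})

test_that("resize_to_width maximizes signal with leftmost ties", {
  cl <- c(c = 100000L)
  # uniform signal across an exactly 400 bp NFR (zero outside): unchanged
  nfr <- gintervals("c", 10000L, 10400L)
  cuts <- data.frame(chrom = "c", pos = seq(10000L, 10399L))
  r <- resize_to_width(nfr, cuts, cl)
  expect_identical(c(r$start, r$end), c(10000L, 10400L))
  # 800 bp NFR with all signal in the right half: flush right
  nfr2 <- gintervals("c", 20000L, 20800L)
  cuts2 <- data.frame(chrom = "c", pos = sample(20400:20799, 500, TRUE))
  r2 <- resize_to_width(nfr2, cuts2, cl)
  expect_identical(c(r2$start, r2$end), c(20400L, 20800L))
  # brute-force window-sum oracle
  sums <- vapply(20000:20799, function(cen)
    sum(cuts2$pos >= cen - 200 & cuts2$pos < cen + 200), numeric(1))
  best_center <- (20000:20799)[which.max(sums)]
  expect_identical(r2$start, best_center - 200L)
  # near chromosome start: clipped with warning
  nfr3 <- gintervals("c", 0L, 150L)
  expect_warning(r3 <- resize_to_width(nfr3, cuts, cl), "clipped")
  expect_identical(c(r3$start, r3$end), c(0L, 400L))
})

test_that("repeat_filter removes > 70% repeat elements, keeps exactly 70%", {
  g <- structure(c(c = paste0(strrep("a", 710), strrep("A", 290),
                              strrep("a", 700), strrep("A", 300),
                              strrep("A", 1000))), class = "genome")
  els <- gintervals("c", c(0L, 1000L, 2000L), c(1000L, 2000L, 3000L))
  kept <- repeat_filter(els, g)
  expect_identical(kept$start, c(1000L, 2000L)) # 71% dropped, 70% kept
  expect_error(repeat_filter(gintervals("c", 2500L, 3500L), g), "past")
})

test_that("assign_genes: distance cutoff, nearest-two, lexicographic ties", {
  el <- gintervals("c", 99800L, 100200L) # midpoint 100000
  tss <- gintervals("c", c(105000L, 250000L, 95000L, 150000L, 99000L),
                    c(105001L, 250001L, 95001L, 150001L, 99001L),
                    name = c("gA", "gB", "gC", "gD", "gE"))
  expect_identical(assign_genes(el, tss), c("gE", "gA"))
  expect_identical(assign_genes(el, tss, max_genes = 3), c("gE", "gA", "gC"))
  expect_identical(assign_genes(el, tss[tss$name == "gB", ]), character(0))
  # equidistant genes: lexicographic id order
  ties <- gintervals("c", c(99000L, 101000L), c(99001L, 101001L),
                     name = c("zz", "aa"))
  expect_identical(assign_genes(el, ties, max_genes = 1), "aa")
})

test_that("pipeline composition invariants hold on the synthetic run", {
  ds <- small_dataset()
  nfr <- select_nfr_fragments(ds$fragments)
  cl <- genome_lengths(ds$genome)
  cutsA <- fragment_cut_sites(nfr[startsWith(nfr$sample, "popA"), ])
  pkA <- call_peaks(cutsA, cl)
  pkB <- call_peaks(fragment_cut_sites(nfr[startsWith(nfr$sample, "popB"), ]), cl)
  cm <- build_count_matrix(merge_intervals(rbind(pkA, pkB)), nfr)
  res <- differential_nfr(cm, cm$samples[startsWith(cm$samples, "popA")],
                          cm$samples[startsWith(cm$samples, "popB")])
  enh <- active_enhancers(res, "popA-enriched", ds$k27_peaks, cutsA,
                          ds$genome, ds$tss)
  expect_gt(nrow(enh), 5)
  expect_true(all(enh$end - enh$start == 400L))
  expect_true(all(enh$k27_cluster == 1L))
  expect_true(all(repeat_fraction(get_seq(ds$genome, enh)) <= 0.70))
  padded <- gintervals(ds$tss$chrom, pmax(ds$tss$start - 500L, 0L),
                       ds$tss$end + 500L)
  expect_false(any(overlaps_any(enh, padded)))
  # every enhancer descends from a popA-enriched differential region
  expect_true(all(overlaps_any(enh, res[res$call == "popA-enriched", ])))
  # K27 classification against truth: planted support is always cluster 1,
  # absent support (flank gaps beyond 1500 bp by construction) cluster 2
  truth1 <- ds$truth[ds$truth$population == "popA" & ds$truth$k27 == 1, ]
  truth0 <- ds$truth[ds$truth$population == "popA" & ds$truth$k27 == 0, ]
  expect_true(all(classify_k27(truth1, ds$k27_peaks) == 1L))
  expect_true(all(classify_k27(truth0, ds$k27_peaks) == 2L))
  expect_false(any(overlaps_any(enh, truth0)))
  # most K27-supported planted enhancers survive the whole funnel
  expect_gt(mean(overlaps_any(truth1, enh)), 0.7)
})
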