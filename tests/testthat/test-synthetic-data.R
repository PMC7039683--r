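test_that("same seed gives byte-identical outputs; different seed differs", {
  spec <- synthetic_spec(seed = 3, n_chroms = 1, chrom_length = 150000L,
                         n_enhancers_popA = 6L, n_enhancers_popB = 4L,
                         n_shared = 4L, n_background_snps = 1100L, n_genes = 8L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  make_dataset(spec, dir = d1)
  make_dataset(spec, dir = d2)
  f1 <- sort(list.files(d1))
  expect_identical(f1, sort(list.files(d2)))
  h1 <- unname(tools::md5sum(file.path(d1, f1)))
  h2 <- unname(tools::md5sum(file.path(d2, f1)))
  expect_identical(h1, h2)

  d3 <- withr::local_tempdir()
  spec2 <- spec
  spec2$seed <- 4
  make_dataset(spec2, dir = d3)
  expect_false(identical(h1, unname(tools::md5sum(file.path(d3, f1)))))
})

test_that("empty popA spec yields no popA truth rows", {
  spec <- synthetic_spec(seed = 5, n_chroms = 1, chrom_length = 120000L,
                         n_enhancers_popA = 0L, n_enhancers_popB = 5L,
                         n_shared = 3L, n_test_snps = 0L,
                         n_background_snps = 0L, n_genes = 5L)
  ds <- make_dataset(spec)
  expect_equal(sum(ds$truth$population == "popA"), 0)
})

test_that("outputs parse back through the package readers", {
  spec <- synthetic_spec(seed = 9, n_chroms = 1, chrom_length = 150000L,
                         n_enhancers_popA = 5L, n_enhancers_popB = 3L,
                         n_shared = 3L, n_background_snps = 1050L, n_genes = 6L)
  d <- withr::local_tempdir()
  ds <- make_dataset(spec, dir = d)
  g <- read_fasta(file.path(d, "genome.fa"))
  expect_identical(genome_lengths(g), genome_lengths(ds$genome))
  fr <- read_fragments(file.path(d, "fragments.tsv"))
  expect_equal(nrow(fr), nrow(ds$fragments))
  expect_gt(nrow(read_bed(file.path(d, "k27_peaks.bed"))), 0)
  expect_equal(nrow(read_bed(file.path(d, "tss.bed"))), 6)
  sn <- read_snp_table(file.path(d, "snps.tsv"))
  expect_true(all(sn$ref != sn$alt))
  expect_length(read_pwms(file.path(d, "motifs.txt")), 5)
  # SNP ref alleles match the genome
  idx <- sample.int(nrow(sn), 50)
  got <- toupper(substring(g[sn$chrom[idx]], sn$pos[idx], sn$pos[idx]))
  expect_identical(unname(got), sn$ref[idx])
})

test_that("fragment lengths are bimodal: one mode < 100, one near nucleosomal", {
  ds <- small_dataset()
  len <- ds$fragments$length
  h <- table(cut(len, breaks = seq(0, max(len) + 20, by = 20)))
  short <- len[len < 100]
  long <- len[len >= 147]
  expect_gt(length(short), 100)
  expect_gt(length(long), 100)
  nl_mean <- ds$spec$nucleosomal_length_mean
  expect_lt(abs(stats::median(long) - nl_mean), 15)
  # a clear density dip between the two modes
  mids <- mean(len >= 110 & len < 147)
  expect_lt(mids, 0.25 * mean(len < 100))
})

test_that("the planted SNP disrupts its motif by the recorded margin", {
  ds <- small_dataset()
  row <- ds$truth[!is.na(ds$truth$snp_id), ]
  expect_equal(nrow(row), 1)
  inst <- ds$motif_instances[ds$motif_instances$enhancer_id == row$enhancer_id, ][1, ]
  x <- ds$pwms[[inst$pwm_id]]
  col <- row$snp_pos - 1L - inst$start + 1L
  lod <- x$lom
  delta <- unname(lod[col, row$snp_alt] - lod[col, row$snp_ref])
  expect_equal(delta, row$snp_motif_delta)
  expect_lt(delta, -1) # a real disruption, not a tie
  # ref allele is the consensus base actually planted in the genome
  expect_identical(toupper(substring(ds$genome[[row$chrom]], row$snp_pos,
                                     row$snp_pos)), row$snp_ref)
})

test_that("plant_motif degenerate, boundary, and error cases", {
  x <- toy_pwm("T1", "GATTACA", 0.9)
  s <- strrep("T", 30)
  out <- plant_motif(s, x, 0, mode = "consensus")
  expect_identical(substr(out, 1, 7), "GATTACA")
  expect_identical(substr(out, 8, 30), substr(s, 8, 30))
  out2 <- plant_motif(s, x, 23, mode = "consensus")
  expect_identical(substr(out2, 24, 30), "GATTACA")
  expect_identical(substr(out2, 1, 23), substr(s, 1, 23))
  expect_error(plant_motif(s, x, 24), "does not fit")
})

test_that("planted instances rescan above threshold far more often than background", {
  set.seed(21)
  x <- toy_pwm("T2", "GCCTGAGGCA", 0.92)
  hit_rate <- function(seqs) mean(vapply(seqs, function(s)
    nrow(scan_pwm(s, x, 0.8)) > 0, logical(1)))
  planted <- vapply(1:300, function(i)
    plant_motif(random_dna(40), x, 15), character(1))
  background <- vapply(1:300, function(i) random_dna(40), character(1))
  expect_gt(hit_rate(planted), 0.7)
  expect_lt(hit_rate(background), 0.1)
})

test_that("population-specific regions receive the stated fragment bias", {
  ds <- small_dataset()
  nfr <- select_nfr_fragments(ds$fragments)
  truthA <- ds$truth[ds$truth$population == "popA", ]
  inA <- nfr[startsWith(nfr$sample, "popA"), ]
  inB <- nfr[startsWith(nfr$sample, "popB"), ]
  cntA <- sum(overlaps_any(gintervals(inA$chrom, inA$start, inA$end), truthA))
  cntB <- sum(overlaps_any(gintervals(inB$chrom, inB$start, inB$end), truthA))
  expect_gt(cntA / max(cntB, 1), 3) # ~4-fold by construction
})
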