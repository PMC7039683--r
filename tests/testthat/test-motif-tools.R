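test_that("pwm construction validates and normalizes", {
  m <- matrix(c(8, 1, 1, 0), nrow = 4, ncol = 4, byrow = TRUE)
  x <- pwm("P1", m)
  expect_true(all(abs(rowSums(x$mat) - 1) < 1e-6))
  expect_error(pwm("P2", m[, 1:3]), "4 columns")
  expect_error(pwm("P3", m[1:3, ]), "width")
  expect_error(pwm("P4", -m), "negative")
})

test_that("JASPAR-style reading round-trips through writing", {
  pwms <- default_pwms()
  f <- withr::local_tempfile(fileext = ".txt")
  write_pwms(pwms, f)
  back <- read_pwms(f)
  expect_identical(names(back), names(pwms))
  # probabilities are re-regularized on reading, so agreement is approximate
  # but consensus and shape are preserved
  for (nm in names(pwms)) {
    expect_equal(back[[nm]]$mat, pwms[[nm]]$mat, tolerance = 0.05)
    expect_identical(pwm_consensus(back[[nm]]), pwm_consensus(pwms[[nm]]))
  }
  # bracketed single record with row letters
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">MA0001.1 TEST",
               "A [ 10  0  0  5 ]", "C [  0 10  0  5 ]",
               "G [  0  0 10  0 ]", "T [  0  0  0  0 ]"), f2)
  p <- read_pwms(f2)[[1]]
  expect_equal(pwm_width(p), 4)
  expect_identical(pwm_consensus(p), "ACGA")
})

test_that("scan_pwm: consensus scores 1, anti-consensus 0, oracle agreement", {
  x <- toy_pwm("S", "GATTACAG")
  cons <- pwm_consensus(x)
  hit <- scan_pwm(cons, x, 0)
  plus <- hit[hit$strand == "+", ]
  expect_equal(plus$relative_score, 1.0)
  anti <- paste(c("A", "C", "G", "T")[apply(x$mat, 1, which.min)], collapse = "")
  h2 <- scan_pwm(anti, x, -Inf)
  expect_equal(min(h2$relative_score), 0.0)

  # exhaustive per-position oracle on random sequence, both strands
  set.seed(33)
  s <- random_dna(1000)
  hits <- scan_pwm(s, x, 0.8)
  w <- pwm_width(x)
  oracle <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") s else reverse_complement(s)
    for (i in 1:(nchar(q) - w + 1)) {
      word <- strsplit(substr(q, i, i + w - 1), "")[[1]]
      raw <- sum(x$lom[cbind(seq_len(w), match(word, c("A", "C", "G", "T")))])
      rel <- (raw - x$min_score) / (x$max_score - x$min_score)
      if (rel >= 0.8) {
        st <- if (strand == "+") i - 1L else nchar(s) - w - (i - 1L)
        oracle[[length(oracle) + 1]] <- data.frame(start = st, strand = strand,
                                                   raw = raw)
      }
    }
  }
  oracle <- do.call(rbind, oracle)
  if (is.null(oracle)) {
    expect_equal(nrow(hits), 0)
  } else {
    o <- order(oracle$start, oracle$strand)
    expect_equal(hits$start, oracle$start[o])
    expect_equal(hits$raw_logodds, oracle$raw[o], tolerance = 1e-12)
  }
  # strand consistency: scanning the reverse complement mirrors hits
  hits_rc <- scan_pwm(reverse_complement(s), x, 0.8)
  expect_equal(sort(nchar(s) - hits$end), sort(hits_rc$start))
  expect_equal(nrow(hits), nrow(hits_rc))
})

test_that("relative score is invariant to uniformly scaled background odds", {
  x2 <- toy_pwm("B1", "GATTACA")
  # multiplying all background odds by a constant shifts every log-odds by
  # the same amount per column; the min-max normalization cancels it
  x3 <- x2
  x3$lom <- x3$lom - log(3.7)
  w <- pwm_width(x2)
  x3$min_score <- x3$min_score - w * log(3.7)
  x3$max_score <- x3$max_score - w * log(3.7)
  set.seed(2)
  s <- random_dna(200)
  h2 <- scan_pwm(s, x2, -Inf)
  h3 <- scan_pwm(s, x3, -Inf)
  expect_equal(h2$relative_score, h3$relative_score, tolerance = 1e-9)
})

test_that("motif_presence and combinations match brute force", {
  ds <- small_dataset()
  truthA <- ds$truth[ds$truth$population == "popA", ]
  pres <- motif_presence(truthA, ds$genome, ds$pwms)
  # planted popA motifs are found in most elements
  expect_gt(pres$fraction[["GRHL_like"]], 0.6)
  expect_gt(pres$fraction[["TFAP_like"]], 0.6)
  # the popB motif is rare in popA elements and flagged
  expect_lt(pres$fraction[["SOX_like"]], 0.3)
  m <- pres$matrix
  comb <- motif_combinations(m, 2)
  # brute force over all pairs
  ids <- colnames(m)
  for (r in sample(nrow(comb), 4)) {
    cc <- strsplit(comb$combination[r], "+", fixed = TRUE)[[1]]
    expect_equal(comb$count[r], sum(m[, cc[1]] == 1 & m[, cc[2]] == 1))
  }
  comb3 <- motif_combinations(m, 3)
  expect_equal(nrow(comb3), choose(length(ids), 3))
  # an element with all motifs contributes to every combination
  m2 <- rbind(m, 1)
  expect_true(all(motif_combinations(m2, 2)$count >=
                    motif_combinations(m, 2)$count))
  # disjoint halves give zero pair count
  md <- cbind(a = rep(c(1, 0), each = 5), b = rep(c(0, 1), each = 5))
  expect_equal(motif_combinations(md, 2)$count, 0L)
})

test_that("motif_enrichment equals the closed-form hypergeometric", {
  ds <- small_dataset()
  truthA <- ds$truth[ds$truth$population == "popA", ]
  truthB <- ds$truth[ds$truth$population == "popB", ]
  enr <- motif_enrichment(truthA, truthB, ds$genome, ds$pwms)
  # direct formula for one motif
  presA <- motif_presence(truthA, ds$genome, ds$pwms, presence_min = 0)
  presB <- motif_presence(truthB, ds$genome, ds$pwms, presence_min = 0)
  kf <- colSums(presA$matrix)[1]
  kb <- colSums(presB$matrix)[1]
  nf <- nrow(presA$matrix); nb <- nrow(presB$matrix)
  pexp <- sum(stats::dhyper(kf:min(kf + kb, nf), kf + kb,
                            nf + nb - kf - kb, nf))
  expect_equal(enr$pvalue[1], pexp, tolerance = 1e-9)
  # identical fg and bg give fold 1
  same <- motif_enrichment(truthA, truthA, ds$genome, ds$pwms)
  expect_true(all(abs(same$fold[!is.na(same$fold)] - 1) < 1e-12))
  expect_error(motif_enrichment(truthA[0, ], truthB, ds$genome, ds$pwms),
               "non-empty")
})

test_that("footprint: profile length, uniform null, planted protection", {
  set.seed(55)
  x <- toy_pwm("F", "GATTACAGG")
  w <- pwm_width(x)
  hits <- data.frame(chrom = "c1", start = s <- seq(1000L, 96000L, by = 1000L),
                     end = s + w, strand = rep(c("+", "-"), length.out = length(s)),
                     pwm_id = "F")
  # uniform cuts: protection near 1
  uni <- data.frame(chrom = "c1", pos = sample.int(100000L, 20000) - 1L)
  fp <- footprint(uni, hits)
  expect_length(fp$cut_counts, 201 + w)
  expect_lt(abs(fp$protection - 1), 0.1)
  # cuts depleted inside motifs: protection < 0.5
  inmotif <- rep(FALSE, nrow(uni))
  for (i in seq_len(nrow(hits)))
    inmotif <- inmotif | (uni$pos >= hits$start[i] & uni$pos < hits$end[i])
  depleted <- uni[!inmotif | stats::runif(nrow(uni)) < 0.1, ]
  fp2 <- footprint(depleted, hits)
  expect_lt(fp2$protection, 0.5)
  expect_error(footprint(uni, hits[0, ]), "no motif hits")
})

test_that("allele_effect applies the 5.0 / 2.0 lost-site rule", {
  # craft a sharp PWM whose consensus scores far above 5 and any single
  # substitution at a key column drops the raw score below 2
  m <- matrix(0.001, nrow = 6, ncol = 4)
  cons <- c(3, 1, 4, 4, 1, 2) # GATTCG
  m[cbind(1:6, cons)] <- 0.997
  x <- pwm("SHARP", m, pseudocount = 0)
  consensus <- pwm_consensus(x)
  set.seed(66)
  chr <- paste0(random_dna(30), consensus, random_dna(30))
  g <- structure(c(c1 = chr), class = "genome")
  pos0 <- 30L + 2L # third motif column (a key base)
  ref <- substr(chr, pos0 + 1, pos0 + 1)
  alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
  snp <- data.frame(chrom = "c1", pos0 = pos0, ref = ref, alt = alt)
  eff <- allele_effect(snp, g, list(x))
  expect_identical(eff$lost, "SHARP")
  expect_length(eff$gained, 0)
  # identical alleles: nothing lost or gained
  snp2 <- snp; snp2$alt <- ref
  eff2 <- allele_effect(snp2, g, list(x))
  expect_length(eff2$lost, 0)
  expect_length(eff2$gained, 0)
  # mirrored rule: swapping alleles turns the loss into a gain
  chr3 <- chr
  substr(chr3, pos0 + 1, pos0 + 1) <- alt
  g3 <- structure(c(c1 = chr3), class = "genome")
  snp3 <- data.frame(chrom = "c1", pos0 = pos0, ref = alt, alt = ref)
  eff3 <- allele_effect(snp3, g3, list(x))
  expect_identical(eff3$gained, "SHARP")
  # threshold-gap case: ref above 5 but alt between 2 and 5 is neither
  # (verified directly on the score table)
  tab <- eff$table
  expect_true(all(tab$status[tab$ref_raw >= 5 & tab$alt_raw >= 2 &
                               tab$alt_rel >= 0.8] != "lost"))
})

test_that("build_network links TFs through elements near their target genes", {
  tf <- data.frame(tf = c("TF_A", "TF_B", "TF_C"),
                   pwm_id = c("mA", "mB", NA), stringsAsFactors = FALSE)
  pres <- matrix(c(1, 0, 1, 0, 1, 1), nrow = 3,
                 dimnames = list(c("e1", "e2", "e3"), c("mA", "mB")))
  eg <- data.frame(element_id = c("e1", "e2", "e3"),
                   gene = c("TF_B", "TF_A", "TF_B"), stringsAsFactors = FALSE)
  expect_warning(net <- build_network(tf, pres, eg), "TF_C")
  # edge A->B: elements near gene TF_B carrying motif mA = e1, e3 -> weight 2
  ab <- net[net$from == "TF_A" & net$to == "TF_B", ]
  expect_equal(ab$weight, 2)
  # brute-force triple join over all pairs
  for (r in seq_len(nrow(net))) {
    a <- net$from[r]; b <- net$to[r]
    carriers <- rownames(pres)[pres[, tf$pwm_id[tf$tf == a]] == 1]
    targets <- eg$element_id[eg$gene == b]
    expect_equal(net$weight[r], length(intersect(carriers, targets)))
  }
  # no annotated elements: edgeless
  expect_warning(net0 <- build_network(tf, pres[0, , drop = FALSE],
                                       eg[0, ]), "TF_C")
  expect_equal(nrow(net0), 0)
})
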