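test_that("build_negative_set matches GC/repeat and avoids exclusions", {
  ds <- small_dataset()
  truthA <- ds$truth[ds$truth$population == "popA", ][1:8, ]
  pos <- toupper(get_seq(ds$genome, truthA))
  ts <- build_negative_set(pos, ds$genome, ratio = 10, gc_tolerance = 0.05,
                           repeat_tolerance = 0.10, exclusions = truthA,
                           seed = 4)
  expect_length(ts$negatives, 80)
  expect_false(any(overlaps_any(ts$negative_intervals, truthA)))
  gcn <- gc_fraction(ts$negatives)
  gcp <- rep(gc_fraction(pos), each = 10)
  expect_true(all(abs(gcn - gcp) <= 0.05 + 1e-12))
  rpn <- repeat_fraction(ts$negatives)
  rpp <- rep(repeat_fraction(pos), each = 10)
  expect_true(all(abs(rpn - rpp) <= 0.10 + 1e-12))
  # deterministic given the seed
  ts2 <- build_negative_set(pos, ds$genome, ratio = 10, exclusions = truthA,
                            seed = 4)
  expect_identical(ts$negatives, ts2$negatives)
  # unmatchable tolerance errors out with the offending bin
  expect_error(build_negative_set(strrep("G", 400), ds$genome, ratio = 2,
                                  gc_tolerance = 0.001, max_tries = 50,
                                  seed = 1),
               "failed to match")
})

test_that("training recovers a planted motif and satisfies model identities", {
  fx <- small_model()
  model <- fx$model
  ts <- fx$ts
  # 5-fold CV recovers the planted motif signal
  cv <- cross_validate(ts, gkm_params(), folds = 5, seed = 2)
  expect_gte(cv$auROC, 0.85)
  # model invariant: the weight of an l-mer equals its kernel-route
  # decision contribution (dual route, pairwise kernel, SV-side norms)
  set.seed(5)
  kmers <- c(substr(pwm_consensus(fx$motif), 1, 10),
             vapply(1:5, function(i) random_dna(10), character(1)))
  w_feature <- score_sequence(kmers, model)
  w_kernel <- vapply(kmers, kmer_weight_oracle, numeric(1), model = model)
  expect_equal(w_feature, unname(w_kernel), tolerance = 1e-6)
  # score additivity: a sequence's score is the sum of its l-mer weights
  s <- random_dna(19)
  windows <- substring(s, 1:10, 10:19)
  expect_equal(score_sequence(s, model), sum(score_sequence(windows, model)),
               tolerance = 1e-9)
  # all-N scores zero
  expect_equal(score_sequence(strrep("N", 30), model), 0)
  expect_error(score_sequence("ACGT", model), "shorter")
  # top weights enriched for the planted consensus word
  top <- gkm_kmer_weights(model, top_n = 20)
  cons <- pwm_consensus(fx$motif)
  overlap <- vapply(top$kmer, function(u)
    grepl(substr(u, 2, 9), cons, fixed = TRUE) ||
      grepl(substr(reverse_complement(u), 2, 9), cons, fixed = TRUE),
    logical(1))
  expect_gt(mean(overlap), 0.5)
})

test_that("swapping class labels negates the weights", {
  fx <- small_model()
  swapped <- gkm_training_set(fx$ts$negatives, fx$ts$positives)
  m2 <- gkm_train(swapped, gkm_params())
  set.seed(6)
  probe <- vapply(1:8, function(i) random_dna(25), character(1))
  expect_equal(score_sequence(probe, m2), -score_sequence(probe, fx$model),
               tolerance = 1e-6)
})

test_that("degenerate one-class input errors", {
  expect_error(gkm_training_set(c("ACGTACGTACGTACGT"), character(0)),
               "non-empty")
  expect_error(gkm_training_set(character(0), c("ACGTACGTACGTACGT")),
               "non-empty")
})

test_that("cross_validate: separable limit, label-shuffle null, AUC oracle", {
  set.seed(41)
  # perfectly separable: positives all share a strong word
  pos <- vapply(1:15, function(i)
    paste0(random_dna(10), "GATTACAGATTACA", random_dna(10)), character(1))
  neg <- vapply(1:15, function(i) random_dna(34), character(1))
  cv <- cross_validate(gkm_training_set(pos, neg), gkm_params(), folds = 5,
                       seed = 1)
  expect_equal(cv$auROC, 1.0)
  expect_error(cross_validate(gkm_training_set(pos, neg), folds = 20), "folds")

  # shuffled labels: auROC near chance across seeds
  all_seqs <- c(pos, neg)
  aurocs <- vapply(1:10, function(sd) {
    set.seed(sd)
    pick <- sample(30, 15)
    cross_validate(gkm_training_set(all_seqs[pick], all_seqs[-pick]),
                   gkm_params(), folds = 3, seed = sd)$auROC
  }, numeric(1))
  expect_gt(mean(aurocs >= 0.25 & aurocs <= 0.75), 0.7)
  expect_lt(abs(mean(aurocs) - 0.5), 0.15)

  # trapezoidal auROC equals the rank-statistic oracle
  set.seed(9)
  sc <- rnorm(60)
  lab <- rbinom(60, 1, 0.4)
  r <- enhancerscan:::.roc_pr(sc, lab)
  expect_equal(r$auROC, auc_oracle(sc, lab), tolerance = 1e-12)
})

test_that("serialized weight tables score by lookup with zero for absent words", {
  fx <- small_model()
  d <- withr::local_tempdir()
  write_gkm_model(fx$model, file.path(d, "m"), top_n = 500)
  wt <- read_gkm_model(file.path(d, "m"))
  expect_s3_class(wt, "gkm_weights")
  # the top stored k-mer scores identically through both routes
  top1 <- wt$kmer[1]
  expect_equal(score_sequence(top1, wt), score_sequence(top1, fx$model),
               tolerance = 1e-9)
  # a word absent from the truncated table scores zero through the table
  absent <- setdiff(c("AAAAAAAAAA", "ACACACACAC", "AAAAATTTTT"), wt$kmer)[1]
  expect_equal(score_sequence(absent, wt), 0)
})
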