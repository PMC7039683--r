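# Shared fixtures, built once per test session.

# a tiny strong PWM for crafted tests
toy_pwm <- function(id = "TOY", consensus = "ACGTACGT", strength = 0.91) {
  b <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix((1 - strength) / 3, nrow = length(b), ncol = 4)
  m[cbind(seq_along(b), b)] <- strength
  pwm(id, m)
}

# small synthetic dataset, cached across test files
.fixture_env <- new.env(parent = emptyenv())

small_dataset <- function() {
  if (is.null(.fixture_env$small)) {
    spec <- synthetic_spec(seed = 7, n_chroms = 2, chrom_length = 250000L,
                           n_enhancers_popA = 20L, n_enhancers_popB = 12L,
                           n_shared = 15L, n_background_snps = 1200L,
                           n_genes = 20L)
    .fixture_env$small <- make_dataset(spec)
  }
  .fixture_env$small
}

# a small trained model on motif-planted positives, cached
small_model <- function() {
  if (is.null(.fixture_env$model)) {
    set.seed(11)
    motif <- toy_pwm("PLANT", "GATTACAGAT", 0.95)
    pos <- vapply(1:30, function(i) {
      s <- random_dna(120)
      plant_motif(s, motif, sample.int(110, 1) - 1L)
    }, character(1))
    neg <- vapply(1:120, function(i) random_dna(120), character(1))
    ts <- gkm_training_set(pos, neg)
    .fixture_env$model <- list(ts = ts, model = gkm_train(ts, gkm_params()),
                               motif = motif)
  }
  .fixture_env$model
}
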