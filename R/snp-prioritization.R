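## deltaSVM scoring of SNPs, the locus-resampling null (1000 SNPs within
## 100 kb), and empirical plus Bonferroni-corrected p-values.
##
## The test is lower-tailed by default: the hypothesis is disruption of an
## enhancer (negative delta), and the empirical p is the fraction of null
## SNPs with a delta at or below the observed one (ties count against
## significance).

#' deltaSVM of a single-nucleotide variant
#'
#' Difference of [score_sequence()] between the alternate- and
#' reference-allele windows centered on the SNP.  With word length `l` and
#' a `2*l - 1` bp window (default 19 for l = 10), exactly the `l` words
#' covering the SNP contribute.
#'
#' @param snp single-row data frame: `chrom`, `pos0` (0-based), `ref`,
#'   `alt`.
#' @param genome named character vector.
#' @param model a `gkm_model`.
#' @param window odd window length (default 19).
#' @return the deltaSVM value (alt minus ref).
#' @export
delta_svm <- function(snp, genome, model, window = 19L) {
  if (window %% 2 == 0) stop("window must be odd")
  half <- (window - 1L) %/% 2L
  clen <- genome_lengths(genome)[[snp$chrom]]
  if (snp$pos0 < half || snp$pos0 + half + 1L > clen)
    stop("SNP ", snp$id, " closer than ", half, " bp to a chromosome end")
  iv <- gintervals(snp$chrom, snp$pos0 - half, snp$pos0 + half + 1L)
  refwin <- toupper(get_seq(genome, iv))
  if (substr(refwin, half + 1L, half + 1L) != snp$ref)
    stop("reference base mismatch at ", snp$chrom, ":", snp$pos0 + 1L,
         " (genome has ", substr(refwin, half + 1L, half + 1L),
         ", table says ", snp$ref, ")")
  altwin <- refwin
  substr(altwin, half + 1L, half + 1L) <- snp$alt
  sc <- score_sequence(c(refwin, altwin), model)
  sc[2] - sc[1]
}

#' Sample the locus null-SNP set
#'
#' Draws `n` SNPs within `radius` of the locus center, either from a
#' supplied catalog (without replacement, excluding the tested ids) or as
#' uniform random positions with a random non-reference alternate base.
#' Deterministic given the seed.
#'
#' @param chrom chromosome of the locus.
#' @param center 0-based center position.
#' @param genome named character vector.
#' @param radius locus radius in bp (default 100 kb).
#' @param n null size (default 1000).
#' @param seed RNG seed.
#' @param catalog optional SNP data frame (from [read_snp_table()]).
#' @param exclude_ids SNP ids never to include (the tested SNPs).
#' @return SNP data frame with `pos0` column.
#' @export
sample_null_snps <- function(chrom, center, genome, radius = 100000L, n = 1000L,
                             seed = 1L, catalog = NULL, exclude_ids = character(0)) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  lo <- center - radius
  hi <- center + radius
  if (!is.null(catalog)) {
    cand <- catalog[catalog$chrom == chrom & catalog$pos0 >= lo &
                      catalog$pos0 <= hi & !(catalog$id %in% exclude_ids), ,
                    drop = FALSE]
    if (nrow(cand) < n)
      stop("catalog holds only ", nrow(cand), " SNPs within ", radius,
           " bp of the locus; need ", n)
    out <- cand[sort(sample.int(nrow(cand), n)), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  clen <- genome_lengths(genome)[[chrom]]
  lo <- max(lo, 10L)
  hi <- min(hi, clen - 11L)
  if (hi - lo + 1L < n)
    stop("locus region holds fewer than ", n, " candidate positions")
  pos0 <- sort(sample(lo:hi, n))
  ref <- toupper(substring(genome[[chrom]], pos0 + 1L, pos0 + 1L))
  ok <- ref %in% c("A", "C", "G", "T")
  while (any(!ok)) { # resample positions landing on N
    pos0[!ok] <- sample(lo:hi, sum(!ok))
    ref <- toupper(substring(genome[[chrom]], pos0 + 1L, pos0 + 1L))
    ok <- ref %in% c("A", "C", "G", "T")
  }
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
                character(1), USE.NAMES = FALSE)
  data.frame(chrom = chrom, pos = pos0 + 1L, ref = ref, alt = alt,
             id = sprintf("null%05d", seq_len(n)), pos0 = pos0,
             stringsAsFactors = FALSE)
}

#' Empirical and Bonferroni-corrected p-values
#'
#' `empirical_p = count_le / n_null`; `bonferroni_p = min(1,
#' empirical_p * n_tests)`.  No smoothing is applied, matching the
#' published arithmetic (2 of 1000 null SNPs lower, 14 tests: 0.028).
#'
#' @param count_le number of null deltas at or below the observed delta.
#' @param n_null null-set size.
#' @param n_tests number of tested SNPs (Bonferroni factor).
#' @return list with `empirical_p` and `bonferroni_p`.
#' @export
empirical_p <- function(count_le, n_null, n_tests) {
  stopifnot(count_le >= 0, count_le <= n_null, n_tests >= 1)
  ep <- count_le / n_null
  list(empirical_p = ep, bonferroni_p = min(1, ep * n_tests))
}

#' Prioritize tested SNPs against a shared locus null
#'
#' Scores every tested SNP and the null set with [delta_svm()], counts
#' null deltas at or below each observed delta (`tail = "lower"`,
#' default), at or above it (`"upper"`), or the smaller tail doubled
#' (`"two.sided"`), and applies the empirical/Bonferroni rule with
#' `n_tests` equal to the number of tested SNPs.
#'
#' @param snps SNP data frame (with `pos0`).
#' @param model a `gkm_model`.
#' @param genome named character vector.
#' @param null_snps SNP data frame of the shared null
#'   (see [sample_null_snps()]).
#' @param window deltaSVM window (default 19).
#' @param tail test direction (default `"lower"`).
#' @param alpha outlier call threshold on the Bonferroni p (default 0.05).
#' @return data frame sorted by `bonferroni_p` then `-|delta|`: `id`,
#'   `delta`, `count_le`, `empirical_p`, `bonferroni_p`, `outlier`,
#'   `rank`; the null deltas are attached as attribute `null_deltas`.
#' @export
prioritize <- function(snps, model, genome, null_snps, window = 19L,
                       tail = c("lower", "upper", "two.sided"), alpha = 0.05) {
  tail <- match.arg(tail)
  if (nrow(snps) < 1) stop("no SNPs to test")
  delta <- vapply(seq_len(nrow(snps)), function(i)
    delta_svm(snps[i, ], genome, model, window), numeric(1))
  null_delta <- vapply(seq_len(nrow(null_snps)), function(i)
    delta_svm(null_snps[i, ], genome, model, window), numeric(1))
  n <- length(null_delta)
  count_le <- vapply(delta, function(d) switch(tail,
    lower = sum(null_delta <= d),
    upper = sum(null_delta >= d),
    two.sided = min(2 * min(sum(null_delta <= d), sum(null_delta >= d)), n)),
    numeric(1))
  ep <- count_le / n
  bp <- pmin(1, ep * nrow(snps))
  out <- data.frame(id = snps$id, chrom = snps$chrom, pos = snps$pos0 + 1L,
                    delta = delta, count_le = as.integer(count_le),
                    empirical_p = ep, bonferroni_p = bp,
                    outlier = bp < alpha, stringsAsFactors = FALSE)
  out <- out[order(out$bonferroni_p, -abs(out$delta)), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  attr(out, "null_deltas") <- null_delta
  attr(out, "n_tests") <- nrow(snps)
  out
}
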