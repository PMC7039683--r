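## Deep-homology testing for noncoding elements: affine-gap global
## alignment of a test sequence against biological and shuffled controls,
## with percent identity, null-character (dash) counts, and >= 5 bp
## perfect-identity block statistics, summarized as z-scores of the test
## against the control distribution.

#' Affine-gap global alignment
#'
#' Needleman-Wunsch with affine gaps (a gap of length g costs
#' `gap_open + (g - 1) * gap_extend`); deterministic tie-breaking prefers
#' a diagonal step, then a gap in `b`, then a gap in `a`.
#'
#' @param a,b DNA strings (non-empty).
#' @param match,mismatch,gap_open,gap_extend scoring (defaults +1, -1, -5,
#'   -1).
#' @return object of class `alignment`: aligned strings `a`, `b`
#'   (with `-`), `score`, `percent_identity` (identical columns as a
#'   percentage of the longer input, a symmetric measure),
#'   `n_null_chars` (total dashes),
#'   `identity_blocks` (maximal runs of >= 5 identical gap-free columns).
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap_open = -5,
                         gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  r <- nw_align_cpp(a, b, match, mismatch, gap_open, gap_extend)
  structure(list(a = r$a, b = r$b, score = r$score,
                 percent_identity = .pct_identity(r$a, r$b),
                 n_null_chars = .count_dashes(c(r$a, r$b)),
                 identity_blocks = identity_blocks(list(a = r$a, b = r$b))),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: score %.1f, identity %.1f%%, %d dashes, %d identity blocks\n",
              x$score, x$percent_identity, x$n_null_chars, x$identity_blocks))
  invisible(x)
}

# identity relative to the longer input sequence: symmetric, and gap
# columns cannot inflate the denominator
.pct_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  longer <- max(sum(ca != "-"), sum(cb != "-"))
  100 * sum(ca == cb & ca != "-") / longer
}

.count_dashes <- function(rows) sum(vapply(strsplit(rows, ""), function(x)
  sum(x == "-"), numeric(1)))

#' Count perfect-identity blocks in a pairwise alignment
#'
#' Maximal runs of identical, gap-free columns of length at least
#' `block_len` (default 5).
#'
#' @param alignment list or `alignment` with aligned strings `a` and `b`.
#' @param block_len minimal run length.
#' @param exact count only runs of exactly `block_len` (default FALSE).
#' @return integer block count.
#' @export
identity_blocks <- function(alignment, block_len = 5L, exact = FALSE) {
  ca <- strsplit(alignment$a, "")[[1]]
  cb <- strsplit(alignment$b, "")[[1]]
  id <- ca == cb & ca != "-"
  r <- rle(id)
  runs <- r$lengths[r$values]
  if (exact) sum(runs == block_len) else sum(runs >= block_len)
}

#' Fisher-Yates shuffle of a sequence
#'
#' The classic backward Fisher-Yates permutation driven by `runif`;
#' uniform over permutations, deterministic per seed, preserves the
#' character multiset.
#'
#' @param seq character string.
#' @param seed optional RNG seed (global RNG state is restored).
#' @return the shuffled string.
#' @export
fisher_yates_shuffle <- function(seq, seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed, kind = "Mersenne-Twister")
  }
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  if (n < 2) return(seq)
  for (i in n:2) {
    j <- 1L + floor(stats::runif(1) * i)
    tmp <- x[i]; x[i] <- x[j]; x[j] <- tmp
  }
  paste(x, collapse = "")
}

#' Build the control set for a homology test
#'
#' Controls are the minus strand (reverse complement), the non-biological
#' reverse, and `n_shuffles` Fisher-Yates shuffles; shuffle seeds are
#' recorded.
#'
#' @param seq plus-strand sequence.
#' @param n_shuffles number of shuffled controls (default 3).
#' @param seed base seed; shuffle i uses `seed + i`.
#' @return object of class `control_set`: `plus`, `minus`, `reverse`,
#'   `shuffles`, `shuffle_seeds`.
#' @export
make_controls <- function(seq, n_shuffles = 3L, seed = 1L) {
  seeds <- seed + seq_len(n_shuffles)
  structure(list(plus = seq,
                 minus = reverse_complement(seq),
                 reverse = paste(rev(strsplit(seq, "")[[1]]), collapse = ""),
                 shuffles = vapply(seeds, function(s) fisher_yates_shuffle(seq, s),
                                   character(1)),
                 shuffle_seeds = seeds),
            class = "control_set")
}

#' Progressive three-way alignment
#'
#' Aligns the closest pair first (highest pairwise percent identity), then
#' aligns the third sequence against the resulting 2-row profile with
#' average-column scoring.  Reports the dash count over all three rows and
#' over the third row alone.
#'
#' @param a,b,c DNA strings.
#' @param ... scoring parameters passed to the aligners.
#' @return list: `rows` (3 aligned strings, input order), `score`,
#'   `n_null_chars`, `n_null_chars_third` (dashes in the row aligned
#'   last).
#' @export
three_way_align <- function(a, b, c, ...) {
  seqs <- c(a, b, c)
  if (any(!nzchar(seqs))) stop("sequences must be non-empty")
  pid <- c(ab = global_align(a, b, ...)$percent_identity,
           ac = global_align(a, c, ...)$percent_identity,
           bc = global_align(b, c, ...)$percent_identity)
  pair <- switch(names(which.max(pid)),
                 ab = c(1L, 2L, 3L), ac = c(1L, 3L, 2L), bc = c(2L, 3L, 1L))
  al <- global_align(seqs[pair[1]], seqs[pair[2]], ...)
  args <- list(...)
  prof <- do.call(nw_profile_cpp, c(list(c(al$a, al$b), seqs[pair[3]]),
                                    list(match = if (is.null(args$match)) 1 else args$match,
                                         mismatch = if (is.null(args$mismatch)) -1 else args$mismatch,
                                         gap_open = if (is.null(args$gap_open)) -5 else args$gap_open,
                                         gap_extend = if (is.null(args$gap_extend)) -1 else args$gap_extend)))
  rows <- character(3)
  rows[pair] <- prof$rows
  list(rows = rows, score = prof$score,
       n_null_chars = .count_dashes(prof$rows),
       n_null_chars_third = .count_dashes(prof$rows[3]))
}

#' Shuffle-controlled homology report
#'
#' For the test sequence and each control (minus strand, reverse,
#' Fisher-Yates shuffles) against every reference: pairwise percent
#' identity and identity-block count; when two or more references are
#' given, the three-way null-character count of (ref1, ref2, query).
#' Control mean and s.d. and the test's z-score are reported per
#' statistic.
#'
#' @param test_seq plus-strand test sequence.
#' @param reference_seqs named character vector (>= 1).
#' @param n_shuffles shuffled controls (default 3).
#' @param seed shuffle seed base.
#' @param ... alignment scoring parameters.
#' @return object of class `homology_report`: `table` (one row per query
#'   x statistic source), `zscores`, `controls`.
#' @export
homology_report <- function(test_seq, reference_seqs, n_shuffles = 3L,
                            seed = 1L, ...) {
  if (length(reference_seqs) < 1) stop("need at least one reference")
  if (is.null(names(reference_seqs)))
    names(reference_seqs) <- paste0("ref", seq_along(reference_seqs))
  ctl <- make_controls(unname(test_seq), n_shuffles, seed)
  queries <- stats::setNames(c(ctl$plus, ctl$minus, ctl$reverse, ctl$shuffles),
                             c("test", "minus", "reverse",
                               paste0("shuffle", seq_len(n_shuffles))))
  rows <- list()
  for (q in names(queries)) {
    ident <- blocks <- numeric(0)
    for (r in names(reference_seqs)) {
      al <- global_align(reference_seqs[[r]], queries[[q]], ...)
      ident <- c(ident, al$percent_identity)
      blocks <- c(blocks, al$identity_blocks)
    }
    tw <- if (length(reference_seqs) >= 2)
      three_way_align(reference_seqs[[1]], reference_seqs[[2]], queries[[q]], ...)
    else NULL
    rows[[q]] <- data.frame(query = q,
                            mean_identity = mean(ident),
                            identity_blocks = sum(blocks),
                            null_chars = if (is.null(tw)) NA_real_ else tw$n_null_chars,
                            null_chars_query = if (is.null(tw)) NA_real_ else tw$n_null_chars_third,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  isctl <- tab$query != "test"
  z <- vapply(c("mean_identity", "identity_blocks", "null_chars", "null_chars_query"),
              function(colname) {
                v <- tab[[colname]]
                if (all(is.na(v))) return(NA_real_)
                mu <- mean(v[isctl]); sdev <- stats::sd(v[isctl])
                if (is.na(sdev) || sdev == 0) return(NA_real_)
                (v[!isctl] - mu) / sdev
              }, numeric(1))
  structure(list(table = tab, zscores = z,
                 control_mean = colMeans(tab[isctl, -1, drop = FALSE]),
                 control_sd = vapply(tab[isctl, -1, drop = FALSE], stats::sd,
                                     numeric(1)),
                 seed = seed),
            class = "homology_report")
}

#' @export
print.homology_report <- function(x, ...) {
  cat("homology report (z-scores of test vs", sum(x$table$query != "test"),
      "controls):\n")
  print(round(x$zscores, 2))
  invisible(x)
}
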