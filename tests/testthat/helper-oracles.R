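# Independent oracle implementations used to cross-check the package's
# production routes.  These are deliberately naive and share no code with
# the implementations they verify.

# explicit gapped k-mer feature map: environment of (subset, word) -> count
gkm_feature_map <- function(s, l, k, rc = FALSE) {
  ss <- toupper(s)
  if (rc) ss <- c(ss, reverse_complement(ss))
  subs <- utils::combn(l, k, simplify = FALSE)
  out <- new.env(parent = emptyenv())
  for (s1 in ss) {
    n <- nchar(s1)
    if (n < l) next
    for (i in 1:(n - l + 1)) {
      w <- substr(s1, i, i + l - 1)
      if (grepl("[^ACGT]", w)) next
      ch <- strsplit(w, "")[[1]]
      for (j in seq_along(subs)) {
        key <- paste(j, paste(ch[subs[[j]]], collapse = ""), sep = ":")
        out[[key]] <- (if (is.null(out[[key]])) 0 else out[[key]]) + 1
      }
    }
  }
  out
}

gkm_feature_dot <- function(e1, e2) {
  s <- 0
  for (k in ls(e1)) if (!is.null(e2[[k]])) s <- s + e1[[k]] * e2[[k]]
  s
}

gkm_kernel_oracle <- function(a, b, l, k, rc = FALSE) {
  gkm_feature_dot(gkm_feature_map(a, l, k, rc), gkm_feature_map(b, l, k, rc))
}

# rank-statistic (Mann-Whitney) AUC
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  (sum(vapply(pos, function(p) sum(p > neg) + 0.5 * sum(p == neg), numeric(1)))) /
    (length(pos) * length(neg))
}

# dual-route l-mer weight: sum over support vectors of beta * K_pair(u, sv),
# using the pairwise mismatch-coefficient kernel (independent of the
# feature-vector path used by score_sequence)
kmer_weight_oracle <- function(u, model) {
  p <- model$params
  sum(vapply(seq_along(model$sv_sequences), function(i)
    model$sv_beta[i] * gkm_kernel(u, model$sv_sequences[i], p), numeric(1)))
}

# memoized forward recursion for affine-gap global alignment score
# (state: 0 none/diag, 1 gap-in-b open, 2 gap-in-a open)
nw_score_oracle <- function(a, b, match = 1, mismatch = -1, gap_open = -5,
                            gap_extend = -1) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, st) {
    if (i > length(ca) && j > length(cb)) return(0)
    key <- paste(i, j, st)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- -Inf
    if (i <= length(ca) && j <= length(cb))
      best <- max(best, (if (ca[i] == cb[j]) match else mismatch) +
                    rec(i + 1, j + 1, 0L))
    if (i <= length(ca))
      best <- max(best, (if (st == 1L) gap_extend else gap_open) +
                    rec(i + 1, j, 1L))
    if (j <= length(cb))
      best <- max(best, (if (st == 2L) gap_extend else gap_open) +
                    rec(i, j + 1, 2L))
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, 0L)
}

# brute-force midpoint membership counts
count_matrix_oracle <- function(regions, fragments) {
  samples <- sort(unique(fragments$sample))
  m <- matrix(0L, nrow(regions), length(samples), dimnames = list(NULL, samples))
  for (f in seq_len(nrow(fragments))) {
    mid <- (fragments$start[f] + fragments$end[f]) %/% 2L
    for (r in seq_len(nrow(regions))) {
      if (fragments$chrom[f] == regions$chrom[r] && mid >= regions$start[r] &&
          mid < regions$end[r])
        m[r, fragments$sample[f]] <- m[r, fragments$sample[f]] + 1L
    }
  }
  m
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

mutate_seq <- function(s, rate) {
  b <- strsplit(s, "")[[1]]
  hit <- which(stats::runif(length(b)) < rate)
  b[hit] <- vapply(b[hit], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  paste(b, collapse = "")
}
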