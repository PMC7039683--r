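## Gapped k-mer SVM: exact kernel, GC/repeat-matched negative-set
## construction, dual training on the precomputed normalized Gram matrix,
## cross-validated ROC/PR, l-mer weight extraction and sequence scoring.
##
## The kernel counts gapped k-mers (k informative columns of an l bp word)
## shared between all l-mer pairs of two sequences; equivalently
## K(A,B) = sum over pairs of f(m) with f(m) = C(l - m, k) for Hamming
## distance m.  With rc_collapse each sequence's l-mer multiset is
## augmented with reverse complements, making every score strand-invariant.

#' Gapped k-mer parameters
#'
#' @param l word length (default 10).
#' @param k informative columns (default 6).
#' @param rc_collapse collapse reverse-complement strands (default TRUE).
#' @param svm_c soft-margin constant (default 1).
#' @return object of class `gkm_params`.
#' @export
gkm_params <- function(l = 10L, k = 6L, rc_collapse = TRUE, svm_c = 1.0) {
  if (k > l) stop("k must satisfy k <= l")
  if (k < 1 || l > 12) stop("need 1 <= k <= l <= 12")
  structure(list(l = as.integer(l), k = as.integer(k),
                 rc_collapse = isTRUE(rc_collapse), svm_c = svm_c),
            class = "gkm_params")
}

#' Gapped k-mer mismatch coefficient
#'
#' The number of gapped k-mers (k of l positions) shared by two l-mers
#' differing at `m` positions: `choose(l - m, k)` for `m <= l - k`, else 0.
#'
#' @param m number of mismatching positions.
#' @param l word length.
#' @param k informative columns.
#' @return integer coefficient.
#' @export
mismatch_coefficient <- function(m, l = 10L, k = 6L) {
  if (any(k > l)) stop("k must satisfy k <= l")
  if (any(m < 0 | m > l)) stop("need 0 <= m <= l")
  ifelse(m <= l - k, choose(l - m, k), 0)
}

#' Gapped k-mer string kernel for a sequence pair
#'
#' @param seqA,seqB DNA strings of length at least `l`; l-mers containing
#'   non-ACGT characters are skipped.
#' @param params a [gkm_params()].
#' @param normalize return `K(A,B) / sqrt(K(A,A) K(B,B))` (default FALSE).
#' @return kernel value.
#' @export
gkm_kernel <- function(seqA, seqB, params = gkm_params(), normalize = FALSE) {
  if (nchar(seqA) < params$l || nchar(seqB) < params$l)
    stop("sequences must be at least l bp")
  kab <- gkm_pair_kernel_cpp(seqA, seqB, params$l, params$k, params$rc_collapse)
  if (!normalize) return(kab)
  kaa <- gkm_pair_kernel_cpp(seqA, seqA, params$l, params$k, params$rc_collapse)
  kbb <- gkm_pair_kernel_cpp(seqB, seqB, params$l, params$k, params$rc_collapse)
  kab / sqrt(kaa * kbb)
}

#' Unnormalized gapped k-mer Gram matrix
#'
#' Computed through the explicit feature map (exact integer counts); equal
#' to evaluating [gkm_kernel()] on every pair.
#'
#' @param seqs character vector of sequences.
#' @param params a [gkm_params()].
#' @return numeric matrix.
#' @export
gkm_gram <- function(seqs, params = gkm_params()) {
  if (any(nchar(seqs) < params$l)) stop("all sequences must be at least l bp")
  gkm_gram_cpp(as.character(seqs), params$l, params$k, params$rc_collapse)
}

#' Construct a training set
#' @param positives,negatives character vectors of sequences.
#' @param negative_intervals optional intervals the negatives came from.
#' @return object of class `gkm_training_set`.
#' @export
gkm_training_set <- function(positives, negatives, negative_intervals = NULL) {
  if (length(positives) == 0 || length(negatives) == 0)
    stop("positives and negatives must be non-empty")
  structure(list(positives = as.character(positives),
                 negatives = as.character(negatives),
                 negative_intervals = negative_intervals),
            class = "gkm_training_set")
}

#' Sample a GC- and repeat-matched negative set from the genome
#'
#' For each positive, `ratio` random genomic windows of the same length are
#' drawn whose GC and repeat fractions are within the tolerances of that
#' positive, avoiding the excluded intervals (by default the positives'
#' own loci, when given) and previously drawn windows.
#'
#' @param positives character vector of positive sequences.
#' @param genome soft-masked genome.
#' @param ratio negatives per positive (default 10).
#' @param gc_tolerance,repeat_tolerance per-sequence matching tolerances.
#' @param exclusions interval data frame to avoid (e.g. positive loci).
#' @param seed RNG seed.
#' @param max_tries draws attempted per negative before giving up.
#' @return a `gkm_training_set`.
#' @export
build_negative_set <- function(positives, genome, ratio = 10L,
                               gc_tolerance = 0.05, repeat_tolerance = 0.10,
                               exclusions = NULL, seed = 1L, max_tries = 2000L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  lens <- genome_lengths(genome)
  chroms <- names(lens)
  gc_pos <- gc_fraction(positives)
  rep_pos <- repeat_fraction(positives)
  taken <- if (!is.null(exclusions))
    exclusions[, c("chrom", "start", "end")] else
      data.frame(chrom = character(0), start = integer(0), end = integer(0))
  negs <- character(0)
  ivs <- list()
  for (i in seq_along(positives)) {
    w <- nchar(positives[i])
    got <- 0L
    for (t in seq_len(max_tries)) {
      ch <- sample(chroms, 1, prob = lens)
      st <- sample.int(lens[[ch]] - w, 1) - 1L
      cand <- gintervals(ch, st, st + w)
      if (any(overlaps_any(cand, taken))) next
      s <- get_seq(genome, cand)
      if (grepl("N", s, fixed = TRUE)) next
      if (abs(gc_fraction(s) - gc_pos[i]) > gc_tolerance) next
      if (abs(repeat_fraction(s) - rep_pos[i]) > repeat_tolerance) next
      negs <- c(negs, s)
      ivs[[length(ivs) + 1]] <- cand
      taken <- rbind(taken, cand)
      got <- got + 1L
      if (got == ratio) break
    }
    if (got < ratio)
      stop("failed to match negatives for positive ", i,
           " (GC ", round(gc_pos[i], 3), ", repeat ", round(rep_pos[i], 3),
           ") after ", max_tries, " tries")
  }
  gkm_training_set(positives, negs, do.call(rbind, ivs))
}

# normalized Gram + labels -> fitted dual solution
.gkm_fit <- function(Kn, y, svm_c, tol = 1e-3, max_iter = 2000000L) {
  if (length(unique(y)) < 2) stop("degenerate one-class training input")
  fit <- smo_train_cpp(Kn, as.integer(y), svm_c, tol, max_iter)
  if (!fit$converged)
    warning("SMO did not fully converge; results may be slightly off")
  fit
}

#' Train a gapped k-mer SVM
#'
#' Solves the soft-margin dual exactly on the precomputed normalized Gram
#' matrix and extracts the feature-space weight vector from which any
#' l-mer weight (and hence any sequence score) follows:
#' `w(u) = sum_sv (alpha y)_sv K(u, sv) / sqrt(K(sv, sv))` -- the
#' unnormalized decision contribution of the single word `u`, bias
#' excluded.
#'
#' @param training_set a [gkm_training_set()].
#' @param params a [gkm_params()].
#' @param gram optional precomputed unnormalized Gram matrix over
#'   `c(positives, negatives)` (from [gkm_gram()]), to avoid recomputation.
#' @return object of class `gkm_model`: `params`, `bias`, `alpha`,
#'   support-sequence info, and the internal feature weight vector.
#' @export
gkm_train <- function(training_set, params = gkm_params(), gram = NULL) {
  seqs <- c(training_set$positives, training_set$negatives)
  y <- c(rep(1L, length(training_set$positives)),
         rep(-1L, length(training_set$negatives)))
  G <- if (is.null(gram)) gkm_gram(seqs, params) else gram
  d <- sqrt(diag(G))
  Kn <- G / tcrossprod(d)
  fit <- .gkm_fit(Kn, y, params$svm_c)
  alpha <- fit$alpha
  sv <- which(alpha > 1e-12)
  beta <- alpha[sv] * y[sv] / d[sv] # SV-side normalization only
  v <- gkm_weight_vector_cpp(seqs[sv], beta, params$l, params$k, params$rc_collapse)
  structure(list(params = params, bias = fit$bias, alpha = alpha, y = y,
                 sv_index = sv, sv_sequences = seqs[sv], sv_beta = beta,
                 sv_norms = d[sv], n_pos = length(training_set$positives),
                 n_neg = length(training_set$negatives),
                 iterations = fit$iterations, v = v),
            class = "gkm_model")
}

#' @export
print.gkm_model <- function(x, ...) {
  cat("gapped k-mer SVM: l =", x$params$l, ", k =", x$params$k,
      ", rc_collapse =", x$params$rc_collapse, "\n",
      length(x$sv_index), "support vectors from", x$n_pos, "positives /",
      x$n_neg, "negatives; bias", signif(x$bias, 4), "\n")
  invisible(x)
}

#' Score sequences with a trained model
#'
#' The score of a sequence is the sum over its l-mers of the l-mer weights
#' `w(u)` (bias excluded); l-mers containing non-ACGT characters contribute
#' zero.  Equivalent to the unnormalized kernel decision sum.
#'
#' @param seqs character vector, each at least `l` bp.
#' @param model a `gkm_model` (or `gkm_weights` read back from disk).
#' @return numeric scores.
#' @export
score_sequence <- function(seqs, model) {
  if (inherits(model, "gkm_weights")) return(.score_with_table(seqs, model))
  stopifnot(inherits(model, "gkm_model"))
  p <- model$params
  if (any(nchar(seqs) < p$l)) stop("sequence shorter than l")
  gkm_score_seqs_cpp(as.character(seqs), model$v, p$l, p$k, p$rc_collapse)
}

#' l-mer weight table of a trained model
#'
#' Weights for every canonical l-mer (with rc collapsing the canonical
#' word is the lexicographic minimum of the word and its reverse
#' complement, and `w(u) == w(rc(u))`).
#'
#' @param model a `gkm_model`.
#' @param top_n return only the `top_n` weights by absolute value
#'   (default: all).
#' @return data frame `kmer`, `weight`, sorted by decreasing weight.
#' @export
gkm_kmer_weights <- function(model, top_n = Inf) {
  p <- model$params
  w <- gkm_all_lmer_scores_cpp(model$v, p$l, p$k, p$rc_collapse)
  codes <- 0:(4^p$l - 1)
  if (p$rc_collapse) {
    rc <- .rc_codes(codes, p$l)
    keep <- codes <= rc
  } else keep <- rep(TRUE, length(codes))
  codes <- codes[keep]
  w <- w[keep]
  if (is.finite(top_n) && top_n < length(w)) {
    o <- order(-abs(w))[seq_len(top_n)]
    codes <- codes[o]
    w <- w[o]
  }
  o <- order(-w)
  data.frame(kmer = decode_kmers_cpp(as.numeric(codes[o]), p$l),
             weight = w[o], stringsAsFactors = FALSE)
}

# vectorized reverse-complement of 2-bit codes, in R (independent of C++)
.rc_codes <- function(codes, l) {
  r <- numeric(length(codes))
  c2 <- codes
  for (i in seq_len(l)) {
    r <- r * 4 + (3 - c2 %% 4)
    c2 <- c2 %/% 4
  }
  r
}

#' Serialize a model as a k-mer weight table plus JSON header
#'
#' @param model a `gkm_model`.
#' @param prefix output path prefix; writes `<prefix>_weights.tsv` and
#'   `<prefix>_header.json`.
#' @param top_n number of weights to keep (default all canonical l-mers).
#' @export
write_gkm_model <- function(model, prefix, top_n = Inf) {
  tab <- gkm_kmer_weights(model, top_n)
  utils::write.table(tab, paste0(prefix, "_weights.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hdr <- list(l = model$params$l, k = model$params$k,
              rc_collapse = model$params$rc_collapse, svm_c = model$params$svm_c,
              bias = model$bias, n_pos = model$n_pos, n_neg = model$n_neg)
  jsonlite::write_json(hdr, paste0(prefix, "_header.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}

#' Read a serialized k-mer weight table
#' @param prefix path prefix used by [write_gkm_model()].
#' @return object of class `gkm_weights` usable with [score_sequence()];
#'   l-mers absent from the table score 0.
#' @export
read_gkm_model <- function(prefix) {
  tab <- utils::read.delim(paste0(prefix, "_weights.tsv"), stringsAsFactors = FALSE)
  hdr <- jsonlite::read_json(paste0(prefix, "_header.json"), simplifyVector = TRUE)
  structure(list(kmer = tab$kmer, weight = tab$weight, l = hdr$l,
                 rc_collapse = hdr$rc_collapse, bias = hdr$bias),
            class = "gkm_weights")
}

.score_with_table <- function(seqs, wt) {
  l <- wt$l
  key <- wt$kmer
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < l) stop("sequence shorter than l")
    kmers <- toupper(substring(s, 1:(n - l + 1), l:n))
    ok <- !grepl("[^ACGT]", kmers)
    kmers <- kmers[ok]
    if (wt$rc_collapse) {
      rc <- reverse_complement(kmers)
      kmers <- ifelse(kmers <= rc, kmers, rc)
    }
    m <- match(kmers, key)
    sum(wt$weight[m], na.rm = TRUE)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Decision values for new sequences via the kernel route
#'
#' `f(s) = sum_sv (alpha y)_sv K'(s, sv) + b` with the fully normalized
#' kernel.  This is the route used for cross-validated prediction; for
#' variant scoring use [score_sequence()], whose values are unnormalized.
#'
#' @param seqs character vector.
#' @param model a `gkm_model`.
#' @return numeric decision values.
#' @export
gkm_decision <- function(seqs, model) {
  p <- model$params
  self <- gkm_self_kernels_cpp(as.character(seqs), p$l, p$k, p$rc_collapse)
  raw <- gkm_score_seqs_cpp(as.character(seqs), model$v, p$l, p$k, p$rc_collapse)
  raw / sqrt(self) + model$bias
}

# trapezoidal auROC and step-interpolated auPRC from scores + 0/1 labels
.roc_pr <- function(scores, labels) {
  o <- order(-scores)
  lab <- labels[o]
  tp <- cumsum(lab)
  fp <- cumsum(1 - lab)
  P <- sum(lab)
  N <- sum(1 - lab)
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auroc <- sum(diff(fpr) * (utils::head(tpr, -1) + tpr[-1]) / 2)
  prec <- tp / (tp + fp)
  rec <- tp / P
  ap <- sum(prec[lab == 1] / P) # step interpolation = average precision
  list(auROC = auroc, auPRC = ap,
       roc_points = data.frame(fpr = fpr, tpr = tpr),
       pr_points = data.frame(recall = rec, precision = prec))
}

#' Stratified k-fold cross-validation
#'
#' Builds the Gram matrix once, trains on each fold complement, predicts
#' the held-out fold through the kernel, and pools the held-out decision
#' values into one ROC / PR curve.
#'
#' @param training_set a [gkm_training_set()].
#' @param params a [gkm_params()].
#' @param folds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param gram optional precomputed unnormalized Gram matrix over
#'   `c(positives, negatives)`.
#' @return list: `auROC`, `auPRC`, `roc_points`, `pr_points`, `folds`.
#' @export
cross_validate <- function(training_set, params = gkm_params(), folds = 5L,
                           seed = 1L, gram = NULL) {
  np <- length(training_set$positives)
  nn <- length(training_set$negatives)
  if (folds > np || folds > nn) stop("folds exceed class size")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister")
  seqs <- c(training_set$positives, training_set$negatives)
  y <- c(rep(1L, np), rep(-1L, nn))
  G <- if (is.null(gram)) gkm_gram(seqs, params) else gram
  d <- sqrt(diag(G))
  Kn <- G / tcrossprod(d)
  foldid <- integer(np + nn)
  foldid[y == 1] <- sample(rep(seq_len(folds), length.out = np))
  foldid[y == -1] <- sample(rep(seq_len(folds), length.out = nn))
  scores <- numeric(np + nn)
  for (f in seq_len(folds)) {
    tr <- which(foldid != f)
    te <- which(foldid == f)
    fit <- .gkm_fit(Kn[tr, tr], y[tr], params$svm_c)
    ay <- fit$alpha * y[tr]
    scores[te] <- as.numeric(Kn[te, tr, drop = FALSE] %*% ay) + fit$bias
  }
  res <- .roc_pr(scores, as.integer(y == 1))
  res$folds <- foldid
  res$scores <- scores
  res
}
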