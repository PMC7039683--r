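## Nucleosome-free-region selection, Tn5 cut-site handling, a simple
## deterministic peak caller over smoothed cut density, fragment counting,
## and differential accessibility between two cell populations.

#' Select nucleosome-free fragments
#'
#' Retains fragments strictly shorter than `max_len` (default 100 bp, the
#' sub-nucleosomal cutoff).
#'
#' @param fragments fragment data frame (`chrom`, `start`, `end`, ...).
#' @param max_len strict upper bound on fragment length.
#' @return the filtered data frame.
#' @export
select_nfr_fragments <- function(fragments, max_len = 100L) {
  len <- fragments$end - fragments$start
  fragments[len < max_len, , drop = FALSE]
}

#' Tn5 cut sites from stranded reads
#'
#' Plus-strand reads cut at their 5' position shifted by +4; minus-strand
#' reads at their 5' position (the interval end) shifted by -5.
#'
#' @param reads data frame with `chrom`, `start`, `end`, `strand`.
#' @return data frame `chrom`, `pos` (0-based cut positions).
#' @export
shift_cut_sites <- function(reads) {
  if (is.null(reads$strand) || any(is.na(reads$strand)) ||
      any(!reads$strand %in% c("+", "-")))
    stop("cut-site shifting requires stranded records ('+' or '-')")
  pos <- ifelse(reads$strand == "+", reads$start + 4L, reads$end - 5L)
  data.frame(chrom = reads$chrom, pos = as.integer(pos), stringsAsFactors = FALSE)
}

#' Both Tn5 cut sites of paired fragments
#'
#' A sequenced fragment carries a plus-strand cut at its left end and a
#' minus-strand cut at its right end; this expands fragments to the two
#' shifted cut positions (+4 / -5).
#'
#' @param fragments fragment data frame.
#' @return data frame `chrom`, `pos`.
#' @export
fragment_cut_sites <- function(fragments) {
  n <- nrow(fragments)
  reads <- data.frame(chrom = rep(fragments$chrom, 2),
                      start = c(fragments$start, fragments$start),
                      end = c(fragments$end, fragments$end),
                      strand = rep(c("+", "-"), each = n),
                      stringsAsFactors = FALSE)
  shift_cut_sites(reads)
}

# centered running mean with window w over a numeric vector
.runmean <- function(x, w) {
  cs <- cumsum(c(0, x))
  n <- length(x)
  half <- w %/% 2
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Call peaks from cut-site density
#'
#' Smooths the per-base cut density with a centered running mean, estimates
#' a local background over a wide span (floored at the genome-wide mean),
#' and reports maximal runs where the smoothed density reaches
#' `min_fold` times the background.  Runs separated by less than the
#' smoothing window are merged; runs shorter than `min_width` are dropped.
#' Fully deterministic.
#'
#' @param cut_sites data frame `chrom`, `pos`.
#' @param chrom_lengths named integer vector.
#' @param smooth_window smoothing window (bp).
#' @param min_fold required fold over local background.
#' @param background_span local background span (bp).
#' @param min_width minimal peak width (bp).
#' @return interval data frame of peaks with a `score` column (mean
#'   smoothed density).
#' @export
call_peaks <- function(cut_sites, chrom_lengths, smooth_window = 150L,
                       min_fold = 4, background_span = 10000L, min_width = 100L) {
  if (nrow(cut_sites) == 0)
    return(gintervals(character(0), integer(0), integer(0), score = numeric(0)))
  gmean <- nrow(cut_sites) / sum(chrom_lengths)
  out <- list()
  for (ch in names(chrom_lengths)) {
    pos <- cut_sites$pos[cut_sites$chrom == ch]
    if (length(pos) == 0) next
    dens <- tabulate(pos + 1L, nbins = chrom_lengths[[ch]])
    sm <- .runmean(dens, smooth_window)
    bg <- pmax(.runmean(dens, background_span), gmean, 1e-9)
    hot <- sm >= min_fold * bg
    if (!any(hot)) next
    r <- rle(hot)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- data.frame(start = starts[r$values] - 1L, end = ends[r$values])
    # merge runs separated by less than the smoothing window
    if (nrow(runs) > 1) {
      keep <- list(runs[1, ])
      for (i in 2:nrow(runs)) {
        last <- keep[[length(keep)]]
        if (runs$start[i] - last$end < smooth_window)
          keep[[length(keep)]]$end <- runs$end[i]
        else keep[[length(keep) + 1]] <- runs[i, ]
      }
      runs <- do.call(rbind, keep)
    }
    runs <- runs[runs$end - runs$start >= min_width, , drop = FALSE]
    if (nrow(runs) == 0) next
    score <- vapply(seq_len(nrow(runs)), function(i)
      mean(sm[(runs$start[i] + 1L):runs$end[i]]), numeric(1))
    out[[ch]] <- gintervals(ch, runs$start, runs$end, score = score)
  }
  if (length(out) == 0)
    return(gintervals(character(0), integer(0), integer(0), score = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count fragments per region and sample
#'
#' A fragment is assigned to a region when its midpoint
#' (`floor((start + end) / 2)`) lies inside it (half-open).  Regions must be
#' disjoint; merge overlapping peaks first.  Library sizes are the
#' genome-wide per-sample fragment totals, not just the counted subset.
#'
#' @param regions disjoint interval data frame.
#' @param fragments fragment data frame with a `sample` column.
#' @return object of class `count_matrix`: `regions`, `samples`, `counts`
#'   (regions x samples), `library_sizes`.
#' @export
build_count_matrix <- function(regions, fragments) {
  if (nrow(regions) > 1) {
    o <- order(regions$chrom, regions$start)
    r <- regions[o, ]
    same <- r$chrom[-1] == r$chrom[-nrow(r)]
    if (any(same & r$start[-1] < r$end[-nrow(r)]))
      stop("regions overlap; merge them first (see merge_intervals)")
  }
  samples <- sort(unique(fragments$sample))
  counts <- matrix(0L, nrow = nrow(regions), ncol = length(samples),
                   dimnames = list(NULL, samples))
  mid <- (fragments$start + fragments$end) %/% 2L
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    ro <- ri[order(regions$start[ri])]
    fi <- which(fragments$chrom == ch)
    if (length(fi) == 0) next
    idx <- findInterval(mid[fi], regions$start[ro])
    inside <- idx >= 1 & mid[fi] < regions$end[ro][pmax(idx, 1L)]
    tab <- table(factor(ro[idx[inside]], levels = seq_len(nrow(regions))),
                 factor(fragments$sample[fi][inside], levels = samples))
    counts <- counts + as.matrix(unclass(tab))
  }
  structure(list(regions = regions, samples = samples, counts = counts,
                 library_sizes = vapply(samples, function(s)
                   sum(fragments$sample == s), numeric(1))),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count matrix:", nrow(x$counts), "regions x", length(x$samples),
      "samples; library sizes", paste(x$library_sizes, collapse = ", "), "\n")
  invisible(x)
}

#' Differential accessibility between two sample groups
#'
#' Log2 fold changes are computed on library-size-normalized group means
#' with a pseudocount; the per-region test is a two-sided binomial exact
#' test on pooled group counts conditioned on the region total (expected
#' split proportional to group library sizes), with BH adjustment across
#' regions.  A region is called population-enriched when
#' `|log2fc| > lfc_threshold` and `qvalue < fdr_threshold`.
#'
#' @param cm a `count_matrix`.
#' @param groupA,groupB character vectors of sample names.
#' @param lfc_threshold log2 fold-change threshold (default 0.5).
#' @param fdr_threshold BH FDR threshold (default 0.01).
#' @param pseudocount added to normalized means before log2 (default 1).
#' @return data frame: interval columns plus `countA`, `countB`, `log2fc`,
#'   `pvalue`, `qvalue`, `call` in `{popA-enriched, popB-enriched, shared}`.
#' @export
differential_nfr <- function(cm, groupA, groupB, lfc_threshold = 0.5,
                             fdr_threshold = 0.01, pseudocount = 1) {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(groupA) < 1 || length(groupB) < 1)
    stop("each group needs at least one sample")
  miss <- setdiff(c(groupA, groupB), cm$samples)
  if (length(miss) > 0) stop("unknown sample(s): ", paste(miss, collapse = ", "))
  lib <- cm$library_sizes
  if (any(lib[c(groupA, groupB)] == 0)) stop("zero library size")
  scale <- mean(lib[c(groupA, groupB)])
  normed <- sweep(cm$counts[, c(groupA, groupB), drop = FALSE], 2,
                  lib[c(groupA, groupB)] / scale, "/")
  mA <- rowMeans(normed[, groupA, drop = FALSE])
  mB <- rowMeans(normed[, groupB, drop = FALSE])
  log2fc <- log2((mA + pseudocount) / (mB + pseudocount))
  xA <- rowSums(cm$counts[, groupA, drop = FALSE])
  xB <- rowSums(cm$counts[, groupB, drop = FALSE])
  pA <- sum(lib[groupA]) / sum(lib[c(groupA, groupB)])
  pvalue <- vapply(seq_along(xA), function(i) {
    n <- xA[i] + xB[i]
    if (n == 0) return(1)
    stats::binom.test(xA[i], n, p = pA)$p.value
  }, numeric(1))
  qvalue <- stats::p.adjust(pvalue, "BH")
  call <- rep("shared", length(xA))
  call[log2fc > lfc_threshold & qvalue < fdr_threshold] <- "popA-enriched"
  call[log2fc < -lfc_threshold & qvalue < fdr_threshold] <- "popB-enriched"
  out <- cm$regions[, c("chrom", "start", "end")]
  out$countA <- xA
  out$countB <- xB
  out$log2fc <- log2fc
  out$pvalue <- pvalue
  out$qvalue <- qvalue
  out$call <- call
  rownames(out) <- NULL
  out
}
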