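## Position weight matrices: scanning, enrichment, per-element motif
## combinations, Tn5 footprint aggregation, allele-specific site gain/loss,
## and the TF -> target-motif network.
##
## Score conventions: raw scores are natural-log odds against the background
## model with a pseudocount; the relative score is the min-max-normalized
## log-odds, (score - min) / (max - min), as used by the JASPAR scan tools.

#' Construct a position weight matrix object
#'
#' @param id motif identifier.
#' @param mat numeric matrix, width x 4, column order A, C, G, T.  May hold
#'   counts or probabilities; rows are renormalized with the pseudocount.
#' @param background base composition (A, C, G, T), default uniform.
#' @param pseudocount added to every cell before per-position normalization.
#' @return object of class `pwm` with the probability matrix (`mat`),
#'   log-odds matrix (`lom`) and attainable score range.
#' @export
pwm <- function(id, mat, background = rep(0.25, 4), pseudocount = 0.01) {
  mat <- as.matrix(mat)
  if (ncol(mat) != 4) stop("PWM matrix must have 4 columns (A, C, G, T)")
  if (nrow(mat) < 4) stop("PWM width must be >= 4")
  if (any(mat < 0)) stop("negative PWM entries")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-6)
    stop("background must be 4 probabilities summing to 1")
  p <- sweep(mat + pseudocount, 1, rowSums(mat) + 4 * pseudocount, "/")
  colnames(p) <- c("A", "C", "G", "T")
  lom <- sweep(log(p), 2, log(background), "-")
  structure(list(id = id, mat = p, background = background,
                 pseudocount = pseudocount, lom = lom,
                 min_score = sum(apply(lom, 1, min)),
                 max_score = sum(apply(lom, 1, max))),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm", x$id, "width", nrow(x$mat), " consensus", pwm_consensus(x), "\n")
  invisible(x)
}

#' Width of a PWM
#' @param x a `pwm`.
#' @export
pwm_width <- function(x) nrow(x$mat)

#' Consensus sequence (per-position argmax base; ties to the first of A<C<G<T)
#' @param x a `pwm`.
#' @export
pwm_consensus <- function(x) {
  paste(c("A", "C", "G", "T")[apply(x$mat, 1, which.max)], collapse = "")
}

#' Read PWMs from a JASPAR-style text file
#'
#' Accepts records of the form
#' ```
#' >MA0001.1 NAME
#' A [ 10  2  0 ]
#' C [  1  8  0 ]
#' G [  0  1 12 ]
#' T [  1  1  0 ]
#' ```
#' (brackets and row letters optional; four rows per record).
#'
#' @param path motif file.
#' @param background,pseudocount passed to [pwm()].
#' @return list of `pwm` objects, named by id.
#' @export
read_pwms <- function(path, background = rep(0.25, 4), pseudocount = 0.01) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no '>' motif headers in ", path)
  out <- list()
  for (i in seq_along(hdr)) {
    from <- hdr[i] + 1
    to <- if (i < length(hdr)) hdr[i + 1] - 1 else length(lines)
    rows <- lines[from:to]
    if (length(rows) != 4) stop("motif record ", i, " does not have 4 matrix rows")
    id <- sub("\\s.*$", "", sub("^>\\s*", "", lines[hdr[i]]))
    nums <- lapply(rows, function(r) {
      r <- gsub("^[ACGTacgt]\\s*", "", trimws(r))
      r <- gsub("[][]", " ", r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]])
    })
    w <- unique(lengths(nums))
    if (length(w) != 1) stop("ragged matrix rows in motif ", id)
    m <- t(do.call(rbind, nums)) # rows A,C,G,T in file -> width x 4
    out[[id]] <- pwm(id, m, background = background, pseudocount = pseudocount)
  }
  out
}

#' Write PWMs in JASPAR-style format
#' @param pwms list of `pwm` objects.
#' @param path output file.
#' @export
write_pwms <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$id), con)
    for (b in 1:4)
      writeLines(sprintf("%s [ %s ]", c("A", "C", "G", "T")[b],
                         paste(formatC(p$mat[, b], format = "f", digits = 6),
                               collapse = " ")), con)
  }
  invisible(path)
}

# per-position raw log-odds on the plus strand of `seq`; NA where the
# window contains a non-ACGT base
.pwm_raw_scores <- function(seq, x) {
  w <- pwm_width(x)
  n <- nchar(seq)
  if (n < w) return(numeric(0))
  code <- match(strsplit(toupper(seq), "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
  np <- n - w + 1L
  idx <- outer(seq_len(np) - 1L, seq_len(w), "+") # np x w matrix of 1-based pos
  bm <- matrix(code[idx], np, w)
  sc <- matrix(x$lom[cbind(rep(seq_len(w), each = np), as.vector(bm))], np, w)
  rowSums(sc)
}

#' Scan a sequence with a PWM on both strands
#'
#' @param seq DNA string.
#' @param x a `pwm`.
#' @param min_relative report hits with relative score at or above this
#'   threshold (default 0.8, the standard 80% profile-score cutoff).
#' @param chrom,offset optional genomic anchoring: hit coordinates are
#'   reported as `offset + position` on chromosome `chrom`.
#' @return data frame of hits: `start`, `end` (0-based half-open within the
#'   sequence unless anchored), `strand`, `pwm_id`, `raw_logodds`,
#'   `relative_score`.  Overlapping hits are all reported.
#' @export
scan_pwm <- function(seq, x, min_relative = 0.8, chrom = NA_character_, offset = 0L) {
  w <- pwm_width(x)
  n <- nchar(seq)
  if (n < w) stop("sequence shorter than motif width")
  rng <- x$max_score - x$min_score
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else reverse_complement(seq)
    raw <- .pwm_raw_scores(s, x)
    rel <- (raw - x$min_score) / rng
    keep <- which(!is.na(rel) & rel >= min_relative)
    if (length(keep) == 0) next
    start <- if (strand == "+") keep - 1L else n - w - (keep - 1L)
    res[[strand]] <- data.frame(chrom = chrom, start = as.integer(offset) + start,
                                end = as.integer(offset) + start + w,
                                strand = strand, pwm_id = x$id,
                                raw_logodds = raw[keep], relative_score = rel[keep],
                                stringsAsFactors = FALSE)
  }
  if (length(res) == 0)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      strand = character(0), pwm_id = character(0),
                      raw_logodds = numeric(0), relative_score = numeric(0)))
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Motif presence across a set of elements
#'
#' @param elements interval data frame.
#' @param genome named character vector.
#' @param pwms list of `pwm` objects.
#' @param min_relative scan threshold.
#' @param presence_min motifs present in fewer than this fraction of
#'   elements are flagged (default 0.05).
#' @return list with `matrix` (binary, elements x motifs), `fraction`
#'   (per-motif presence fraction) and `flagged` (motif ids below
#'   `presence_min`).
#' @export
motif_presence <- function(elements, genome, pwms, min_relative = 0.8,
                           presence_min = 0.05) {
  seqs <- get_seq(genome, elements)
  ids <- vapply(pwms, `[[`, character(1), "id")
  m <- matrix(0L, nrow = length(seqs), ncol = length(pwms),
              dimnames = list(NULL, ids))
  for (j in seq_along(pwms))
    m[, j] <- vapply(seqs, function(s)
      as.integer(nrow(scan_pwm(s, pwms[[j]], min_relative)) > 0), integer(1),
      USE.NAMES = FALSE)
  frac <- colMeans(m)
  list(matrix = m, fraction = frac, flagged = ids[frac < presence_min])
}

#' Count elements carrying every motif of each order-2 or order-3 combination
#'
#' @param presence binary matrix (elements x motifs), e.g.
#'   `motif_presence()$matrix`.
#' @param order combination size, 2 or 3.
#' @return data frame `combination`, `count`, sorted by descending count.
#' @export
motif_combinations <- function(presence, order = 2) {
  ids <- colnames(presence)
  if (order > length(ids)) stop("order exceeds number of motifs")
  combos <- utils::combn(ids, order, simplify = FALSE)
  count <- vapply(combos, function(cc)
    sum(rowSums(presence[, cc, drop = FALSE]) == length(cc)), numeric(1))
  out <- data.frame(combination = vapply(combos, paste, character(1), collapse = "+"),
                    count = as.integer(count), stringsAsFactors = FALSE)
  out[order(-out$count, out$combination), , drop = FALSE]
}

#' Known-motif enrichment of a foreground element set over a background
#'
#' Presence-fraction fold change with a hypergeometric p-value (drawing the
#' foreground from the pooled element universe) and BH adjustment across
#' motifs.
#'
#' @param fg_elements,bg_elements interval data frames.
#' @param genome named character vector.
#' @param pwms list of `pwm` objects.
#' @param min_relative scan threshold.
#' @return data frame: `pwm_id`, `fg_fraction`, `bg_fraction`, `fold`,
#'   `pvalue`, `qvalue`.
#' @export
motif_enrichment <- function(fg_elements, bg_elements, genome, pwms,
                             min_relative = 0.8) {
  if (nrow(fg_elements) == 0 || nrow(bg_elements) == 0)
    stop("foreground and background must be non-empty")
  fg <- motif_presence(fg_elements, genome, pwms, min_relative, presence_min = 0)
  bg <- motif_presence(bg_elements, genome, pwms, min_relative, presence_min = 0)
  nf <- nrow(fg$matrix); nb <- nrow(bg$matrix)
  kf <- colSums(fg$matrix); kb <- colSums(bg$matrix)
  fold <- ifelse(kb == 0, ifelse(kf == 0, NA_real_, Inf),
                 (kf / nf) / (kb / nb))
  p <- stats::phyper(kf - 1, kf + kb, nf + nb - kf - kb, nf, lower.tail = FALSE)
  data.frame(pwm_id = names(kf), fg_fraction = kf / nf, bg_fraction = kb / nb,
             fold = fold, pvalue = p, qvalue = stats::p.adjust(p, "BH"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate Tn5 cut-site counts around motif hits
#'
#' Cut positions must already be strand-shifted (+4 / -5).  Offsets are
#' relative to the motif start and orientation-normalized: minus-strand hits
#' are counted on the reflected axis.  The profile covers offsets
#' `-flank .. width + flank` (length `width + 2 * flank + 1`).
#'
#' @param cut_sites data frame with `chrom`, `pos` (0-based cut positions).
#' @param hits motif hit data frame (from [scan_pwm()] with genomic
#'   anchoring): `chrom`, `start`, `end`, `strand`, `pwm_id`.
#' @param flank flanking span in bp (default 100).
#' @return object of class `footprint_profile`: `pwm_id`, `offsets`,
#'   `cut_counts`, `flank_mean`, `core_mean`, `protection`
#'   (= core mean / flank mean; < 1 indicates protection).
#' @export
footprint <- function(cut_sites, hits, flank = 100L) {
  if (nrow(hits) == 0) stop("no motif hits to aggregate")
  w <- unique(hits$end - hits$start)
  if (length(w) != 1) stop("hits mix motif widths; footprint one motif at a time")
  offs <- seq(-flank, w + flank)
  counts <- stats::setNames(numeric(length(offs)), offs)
  bychrom <- split(cut_sites$pos, cut_sites$chrom)
  for (i in seq_len(nrow(hits))) {
    pos <- bychrom[[hits$chrom[i]]]
    if (is.null(pos)) next
    o <- if (hits$strand[i] == "-") (w - 1L) - (pos - hits$start[i])
         else pos - hits$start[i]
    o <- o[o >= -flank & o <= w + flank]
    if (length(o) > 0)
      counts <- counts + tabulate(o + flank + 1L, nbins = length(offs))
  }
  core <- counts[offs >= 0 & offs < w]
  flk <- counts[offs < 0 | offs >= w]
  structure(list(pwm_id = hits$pwm_id[1], offsets = offs, cut_counts = counts,
                 flank_mean = mean(flk), core_mean = mean(core),
                 protection = mean(core) / mean(flk)),
            class = "footprint_profile")
}

#' @export
print.footprint_profile <- function(x, ...) {
  cat("footprint profile for", x$pwm_id, ":",
      sprintf("core %.2f, flank %.2f, protection %.3f\n",
              x$core_mean, x$flank_mean, x$protection))
  invisible(x)
}

#' Allele-specific binding-site gain and loss
#'
#' Compares PWM hits in the reference- and alternate-allele windows centred
#' on a SNP.  A site is *lost* when the reference window carries a detected
#' site (relative score at or above `min_relative`) with raw log-odds at or
#' above `score_hi` at some (motif, start, strand), while the alternate
#' window scores below `score_lo` there, or the site is no longer detected.
#' *Gained* is the mirror image.
#'
#' @param snp single-row SNP data frame (`chrom`, `pos0`, `ref`, `alt`).
#' @param genome named character vector.
#' @param pwms list of `pwm` objects.
#' @param window odd window length (default 19).
#' @param score_hi,score_lo raw log-odds thresholds (defaults 5.0 and 2.0).
#' @param min_relative detection threshold (default 0.8).
#' @return list with `lost`, `gained` (pwm ids) and `table`, the per-site
#'   score table.
#' @export
allele_effect <- function(snp, genome, pwms, window = 19L, score_hi = 5.0,
                          score_lo = 2.0, min_relative = 0.8) {
  stopifnot(window %% 2 == 1)
  half <- (window - 1L) %/% 2L
  iv <- gintervals(snp$chrom, snp$pos0 - half, snp$pos0 + half + 1L)
  refwin <- get_seq(genome, iv)
  if (toupper(substr(refwin, half + 1L, half + 1L)) != snp$ref)
    stop("reference base mismatch at ", snp$chrom, ":", snp$pos0 + 1L)
  altwin <- refwin
  substr(altwin, half + 1L, half + 1L) <- snp$alt
  tab <- list()
  for (x in pwms) {
    if (pwm_width(x) > window) next
    hr <- scan_pwm(refwin, x, min_relative = -Inf)
    ha <- scan_pwm(altwin, x, min_relative = -Inf)
    key <- paste(hr$start, hr$strand)
    m <- match(key, paste(ha$start, ha$strand))
    tab[[x$id]] <- data.frame(pwm_id = x$id, start = hr$start, strand = hr$strand,
                              ref_raw = hr$raw_logodds, alt_raw = ha$raw_logodds[m],
                              ref_rel = hr$relative_score,
                              alt_rel = ha$relative_score[m],
                              stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, tab)
  if (is.null(tab))
    return(list(lost = character(0), gained = character(0), table = NULL))
  lost <- tab$ref_rel >= min_relative & tab$ref_raw >= score_hi &
    (tab$alt_raw < score_lo | tab$alt_rel < min_relative)
  gained <- tab$alt_rel >= min_relative & tab$alt_raw >= score_hi &
    (tab$ref_raw < score_lo | tab$ref_rel < min_relative)
  tab$status <- ifelse(lost, "lost", ifelse(gained, "gained", "."))
  rownames(tab) <- NULL
  list(lost = unique(tab$pwm_id[lost]), gained = unique(tab$pwm_id[gained]),
       table = tab)
}

#' Build the TF -> target-motif regulatory network
#'
#' Directed edge `a -> b` whenever some element assigned to the gene of TF
#' `b` contains the motif of TF `a`; the edge weight is the number of such
#' elements.
#'
#' @param tf_table data frame: `tf`, `pwm_id`, and optionally `gene` (the
#'   TF's own gene id; defaults to the TF name).
#' @param presence binary elements x motifs matrix with element ids as
#'   rownames.
#' @param element_genes data frame: `element_id`, `gene`.
#' @return data frame of directed edges `from`, `to`, `weight`; TFs without
#'   a motif trigger a warning and stay isolated.
#' @export
build_network <- function(tf_table, presence, element_genes) {
  if (is.null(tf_table$gene)) tf_table$gene <- tf_table$tf
  nomotif <- is.na(tf_table$pwm_id) | !(tf_table$pwm_id %in% colnames(presence))
  if (any(nomotif))
    warning("TF(s) without a scanned motif are isolated nodes: ",
            paste(tf_table$tf[nomotif], collapse = ", "))
  edges <- list()
  for (ia in which(!nomotif)) {
    carriers <- rownames(presence)[presence[, tf_table$pwm_id[ia]] == 1]
    for (ib in seq_len(nrow(tf_table))) {
      n <- length(intersect(carriers,
                            element_genes$element_id[element_genes$gene ==
                                                       tf_table$gene[ib]]))
      if (n > 0)
        edges[[length(edges) + 1]] <- data.frame(from = tf_table$tf[ia],
                                                 to = tf_table$tf[ib],
                                                 weight = n,
                                                 stringsAsFactors = FALSE)
    }
  }
  if (length(edges) == 0)
    return(data.frame(from = character(0), to = character(0), weight = integer(0)))
  out <- do.call(rbind, edges)
  rownames(out) <- NULL
  out
}
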