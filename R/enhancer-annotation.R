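## From differential NFRs to "active enhancer" sets: H3K27Ac integration
## (direct overlap or flanked regions between close peaks), TSS removal,
## signal-maximizing 400 bp resizing, repeat filtering, and nearest-gene
## assignment.

#' Regions flanked by close H3K27Ac peaks
#'
#' The inter-peak gaps between adjacent peaks on a chromosome whose length
#' is within `[min_gap, max_gap]` (default up to 1500 bp).
#'
#' @param k27_peaks interval data frame of H3K27Ac peaks.
#' @param max_gap maximal gap length (default 1500).
#' @param min_gap minimal gap length (default 0).
#' @return interval data frame of flanked regions.
#' @export
flanked_regions <- function(k27_peaks, max_gap = 1500L, min_gap = 0L) {
  out <- list()
  for (ch in unique(k27_peaks$chrom)) {
    p <- k27_peaks[k27_peaks$chrom == ch, , drop = FALSE]
    p <- p[order(p$start), , drop = FALSE]
    if (nrow(p) < 2) next
    gs <- p$end[-nrow(p)]
    ge <- p$start[-1]
    len <- ge - gs
    keep <- len > 0 & len <= max_gap & len >= min_gap
    if (any(keep)) out[[ch]] <- gintervals(ch, gs[keep], ge[keep])
  }
  if (length(out) == 0) return(gintervals(character(0), integer(0), integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' H3K27Ac cluster labels for NFRs
#'
#' Cluster 1 (K27-high) when the NFR overlaps (>= 1 bp) an H3K27Ac peak or
#' a flanked region in at least one of the supplied peak tracks; cluster 2
#' otherwise.  Multiple tracks model "supported at either stage".
#'
#' @param nfrs interval data frame.
#' @param k27_tracks a single peak interval data frame or a list of them.
#' @param max_gap,min_gap passed to [flanked_regions()].
#' @param mode `"union"` (default: support in any track suffices) or
#'   `"intersection"` (all tracks required).
#' @return integer vector of cluster labels (1 or 2) along `nfrs`.
#' @export
classify_k27 <- function(nfrs, k27_tracks, max_gap = 1500L, min_gap = 0L,
                         mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  if (is.data.frame(k27_tracks)) k27_tracks <- list(k27_tracks)
  hits <- vapply(k27_tracks, function(pk) {
    support <- rbind(pk[, c("chrom", "start", "end")],
                     flanked_regions(pk, max_gap, min_gap))
    overlaps_any(nfrs, support)
  }, logical(nrow(nfrs)))
  hits <- matrix(hits, nrow = nrow(nfrs))
  supported <- if (mode == "union") rowSums(hits) > 0 else rowSums(hits) == ncol(hits)
  ifelse(supported, 1L, 2L)
}

#' Remove elements overlapping transcription start sites
#'
#' Point TSSs are padded by `pad` on both sides (default 500 bp); elements
#' with any overlap of a padded TSS are dropped.
#'
#' @param elements interval data frame.
#' @param tss interval data frame (point TSSs as 1 bp intervals).
#' @param pad symmetric padding in bp.
#' @return the retained elements.
#' @export
remove_tss_overlaps <- function(elements, tss, pad = 500L) {
  if (nrow(tss) == 0 || nrow(elements) == 0) return(elements)
  padded <- gintervals(tss$chrom, pmax(tss$start - pad, 0L), tss$end + pad)
  elements[!overlaps_any(elements, padded), , drop = FALSE]
}

#' Resize an NFR to the 400 bp window maximizing cut-site signal
#'
#' Among all `width` bp windows whose center lies within the NFR, returns
#' the one with the largest summed cut density; ties resolve to the
#' leftmost window.  Windows are clipped (with a warning) at chromosome
#' bounds.
#'
#' @param nfr single-row interval data frame.
#' @param cut_sites data frame `chrom`, `pos`.
#' @param chrom_lengths named integer vector.
#' @param width target width (default 400).
#' @return single-row interval data frame of width `width`.
#' @export
resize_to_width <- function(nfr, cut_sites, chrom_lengths, width = 400L) {
  ch <- nfr$chrom[1]
  half <- width %/% 2L
  centers <- nfr$start[1]:(nfr$end[1] - 1L)
  starts <- centers - half
  lo <- min(starts)
  hi <- max(starts) + width
  clen <- chrom_lengths[[ch]]
  pos <- cut_sites$pos[cut_sites$chrom == ch & cut_sites$pos >= lo &
                         cut_sites$pos < hi]
  dens <- tabulate(pos - lo + 1L, nbins = hi - lo)
  cs <- cumsum(c(0, dens))
  sums <- cs[starts - lo + width + 1L] - cs[starts - lo + 1L]
  best <- starts[which.max(sums)] # which.max takes the first (leftmost) tie
  if (best < 0 || best + width > clen) {
    warning("resized window clipped at chromosome bounds for ", ch)
    best <- min(max(best, 0L), clen - width)
  }
  gintervals(ch, best, best + width)
}

#' Remove elements exceeding a repeat fraction
#'
#' Elements whose soft-masked (lowercase) fraction is strictly greater
#' than `max_repeat` are dropped.
#'
#' @param elements interval data frame.
#' @param genome soft-masked genome.
#' @param max_repeat threshold (default 0.70).
#' @return the retained elements.
#' @export
repeat_filter <- function(elements, genome, max_repeat = 0.70) {
  if (nrow(elements) == 0) return(elements)
  rf <- repeat_fraction(get_seq(genome, elements))
  elements[rf <= max_repeat, , drop = FALSE]
}

#' Assign up to two nearest genes within a distance cutoff
#'
#' Distances are measured from the element midpoint to gene TSS positions;
#' the nearest at most `max_genes` genes within `max_dist` are returned,
#' nearest first, distance ties broken by lexicographic gene id.
#'
#' @param element single-row interval data frame.
#' @param gene_tss interval data frame with `name` (gene id); `start` is
#'   the TSS position.
#' @param max_dist distance cutoff in bp (default 100 kb).
#' @param max_genes maximal number of genes (default 2).
#' @return character vector of gene ids (possibly empty).
#' @export
assign_genes <- function(element, gene_tss, max_dist = 100000L, max_genes = 2L) {
  mid <- (element$start[1] + element$end[1]) %/% 2L
  g <- gene_tss[gene_tss$chrom == element$chrom[1], , drop = FALSE]
  if (nrow(g) == 0) return(character(0))
  d <- abs(g$start - mid)
  keep <- d <= max_dist
  if (!any(keep)) return(character(0))
  g <- g[keep, , drop = FALSE]
  d <- d[keep]
  o <- order(d, g$name)
  g$name[o][seq_len(min(max_genes, length(o)))]
}

#' Build the active-enhancer set from differential NFRs
#'
#' The composition of the annotation pipeline: keep regions enriched in the
#' target population, require H3K27Ac support (cluster 1), resize to
#' `width` bp maximizing cut density, drop TSS-overlapping elements, drop
#' high-repeat elements, and assign up to two nearby genes.
#'
#' @param differential output of [differential_nfr()].
#' @param which_call which call to keep (default `"popA-enriched"`).
#' @param k27_tracks peak track(s) for [classify_k27()].
#' @param cut_sites cut sites of the target population.
#' @param genome soft-masked genome.
#' @param tss TSS intervals with gene `name`s.
#' @param width element width (default 400).
#' @param max_gap flanked-region gap bound (default 1500).
#' @param tss_pad TSS padding (default 500).
#' @param max_repeat repeat-fraction bound (default 0.70).
#' @param max_dist,max_genes gene-assignment rule (defaults 100 kb, 2).
#' @return interval data frame of active enhancers with `source_start`,
#'   `source_end`, `k27_cluster`, `atac_signal`, `genes` columns.
#' @export
active_enhancers <- function(differential, which_call = "popA-enriched",
                             k27_tracks, cut_sites, genome, tss,
                             width = 400L, max_gap = 1500L, tss_pad = 500L,
                             max_repeat = 0.70, max_dist = 100000L,
                             max_genes = 2L) {
  chrom_lengths <- genome_lengths(genome)
  nfrs <- differential[differential$call == which_call, , drop = FALSE]
  if (nrow(nfrs) == 0) return(NULL)
  cl <- classify_k27(nfrs, k27_tracks, max_gap = max_gap)
  nfrs <- nfrs[cl == 1L, , drop = FALSE]
  if (nrow(nfrs) == 0) return(NULL)
  resized <- do.call(rbind, lapply(seq_len(nrow(nfrs)), function(i)
    resize_to_width(nfrs[i, ], cut_sites, chrom_lengths, width)))
  resized$source_start <- nfrs$start
  resized$source_end <- nfrs$end
  resized$k27_cluster <- 1L
  pos_by_chrom <- split(cut_sites$pos, cut_sites$chrom)
  resized$atac_signal <- vapply(seq_len(nrow(resized)), function(i) {
    p <- pos_by_chrom[[resized$chrom[i]]]
    if (is.null(p)) 0 else sum(p >= resized$start[i] & p < resized$end[i])
  }, numeric(1))
  resized <- remove_tss_overlaps(resized, tss, pad = tss_pad)
  resized <- repeat_filter(resized, genome, max_repeat)
  if (nrow(resized) == 0) return(resized)
  resized$genes <- vapply(seq_len(nrow(resized)), function(i)
    paste(assign_genes(resized[i, ], tss, max_dist, max_genes), collapse = ","),
    character(1))
  rownames(resized) <- NULL
  resized
}
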