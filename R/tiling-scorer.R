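## Genome tiling, model scoring of tiles, percentile binning of the ranked
## tile list, and annotation enrichment of the top bins.

#' Tile a genome into overlapping fixed-width windows
#'
#' Per chromosome, tiles start at 0, `step`, `2*step`, ...; tiles that
#' would extend past the chromosome end are dropped (400 bp tiles every
#' 100 bp give the standard 300 bp overlap).
#'
#' @param genome named character vector (or named lengths).
#' @param length tile width (default 400).
#' @param step start-to-start distance (default 100).
#' @return interval data frame of tiles.
#' @export
tile_genome <- function(genome, length = 400L, step = 100L) {
  stopifnot(step >= 1)
  lens <- if (is.numeric(genome)) genome else genome_lengths(genome)
  out <- lapply(names(lens), function(ch) {
    n <- lens[[ch]]
    if (n < length) return(NULL)
    starts <- seq(0L, n - length, by = step)
    gintervals(ch, starts, starts + length)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) return(gintervals(character(0), integer(0), integer(0)))
  rownames(res) <- NULL
  res
}

#' Score tiles with a trained gapped k-mer model
#'
#' @param tiles interval data frame.
#' @param genome named character vector.
#' @param model a `gkm_model`.
#' @return `tiles` with a `score` column ([score_sequence()] of each tile;
#'   all-N tiles score 0).
#' @export
score_tiles <- function(tiles, genome, model) {
  tiles$score <- score_sequence(get_seq(genome, tiles), model)
  tiles
}

#' Assign ranked tiles to top-percentile bins
#'
#' Tiles are ranked by descending score (ties broken by coordinate order);
#' cumulative bin sizes are `round(n * edge)`.  The default edges
#' reproduce the 0.1% / 0.2% / 0.5% / 1% / 1.5% / 2% bins; everything
#' below the last edge is labelled `"rest"`.
#'
#' @param tiles scored tiles (with `score`).
#' @param bin_edges increasing cumulative quantile edges.
#' @return `tiles` with `rank` and `percentile_bin` columns.
#' @export
percentile_bins <- function(tiles,
                            bin_edges = c(0.001, 0.002, 0.005, 0.01, 0.015, 0.02)) {
  n <- nrow(tiles)
  if (n < 1) stop("no tiles")
  o <- order(-tiles$score, tiles$chrom, tiles$start)
  rank <- integer(n)
  rank[o] <- seq_len(n)
  sizes <- round(n * bin_edges)
  labels <- paste0(c("top ", paste0(100 * utils::head(bin_edges, -1), "-")),
                   100 * bin_edges, "%")
  bin <- rep("rest", n)
  prev <- 0
  for (i in seq_along(sizes)) {
    sel <- rank > prev & rank <= sizes[i]
    bin[sel] <- labels[i]
    prev <- sizes[i]
  }
  tiles$rank <- rank
  tiles$percentile_bin <- bin
  tiles
}

#' Annotation enrichment of the top tile bin
#'
#' Fold enrichment = (fraction of top-bin tiles overlapping the
#' annotation) / (fraction of all tiles overlapping it), with a one-sided
#' binomial p-value.  Annotations never touched by any tile give `NA`.
#'
#' @param binned_tiles output of [percentile_bins()].
#' @param annotations named list of interval data frames.
#' @param top_bin bin label to test (default the first bin present).
#' @return data frame: `annotation`, `n_top`, `n_top_hit`, `all_fraction`,
#'   `top_fraction`, `fold`, `pvalue`.
#' @export
annotation_enrichment <- function(binned_tiles, annotations,
                                  top_bin = binned_tiles$percentile_bin[binned_tiles$rank == 1]) {
  top <- binned_tiles[binned_tiles$percentile_bin == top_bin, , drop = FALSE]
  res <- lapply(names(annotations), function(nm) {
    ann <- annotations[[nm]]
    hit_all <- overlaps_any(binned_tiles, ann)
    p_all <- mean(hit_all)
    hit_top <- overlaps_any(top, ann)
    if (p_all == 0)
      return(data.frame(annotation = nm, n_top = nrow(top),
                        n_top_hit = sum(hit_top), all_fraction = 0,
                        top_fraction = NA_real_, fold = NA_real_,
                        pvalue = NA_real_))
    p_top <- mean(hit_top)
    pv <- stats::binom.test(sum(hit_top), nrow(top), p = p_all,
                            alternative = "greater")$p.value
    data.frame(annotation = nm, n_top = nrow(top), n_top_hit = sum(hit_top),
               all_fraction = p_all, top_fraction = p_top,
               fold = p_top / p_all, pvalue = pv)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
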