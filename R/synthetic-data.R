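## Deterministic generator for a miniature two-population study universe:
## genome with soft-masked repeat stretches, motif-planted enhancers,
## sub-nucleosomal + nucleosomal ATAC fragments for two cell populations,
## H3K27Ac peaks overlapping or flanking a subset of enhancers, TSS/gene
## annotations, a SNP catalog with one planted motif-disrupting variant,
## and a pair of diverged "reference species" homolog sequences.
##
## All randomness flows through one Mersenne-Twister stream keyed by the
## spec's seed; the draw order is: genome bases, repeat stretches, enhancer
## placement, motif planting, H3K27Ac placement, genes/TSS, fragments
## (population-major, replicate-minor, enhancer order, then background),
## SNPs, homolog mutation.  Identical specs therefore give byte-identical
## outputs.

#' Default synthetic motif set
#'
#' Five synthetic PWMs loosely modeled on TF families active in embryonic
#' surface epithelia (GRHL-, KLF-, TFAP2-like for population A; a SOX-like
#' motif for population B; one "housekeeping" motif planted in shared
#' regions).  Column information content alternates between a strong core
#' (`strength_core`) and weaker flanks (`strength_flank`): perfectly
#' uniform width-10 columns would place two-mismatch words exactly on the
#' 80% relative-score threshold, which makes rescan rates numerically
#' unstable; heterogeneous columns avoid that degeneracy and are closer to
#' real TF motifs anyway.
#'
#' @param strength_core,strength_flank consensus-base probabilities for
#'   alternating columns.
#' @return named list of `pwm` objects.
#' @export
default_pwms <- function(strength_core = 0.95, strength_flank = 0.85) {
  mk <- function(id, consensus) {
    b <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
    strength <- rep(c(strength_core, strength_flank), length.out = length(b))
    m <- matrix((1 - strength) / 3, nrow = length(b), ncol = 4)
    m[cbind(seq_along(b), b)] <- strength
    pwm(id, m)
  }
  list(GRHL_like = mk("GRHL_like", "AACCGGTTTC"),
       KLF_like  = mk("KLF_like",  "GGGGTGTGGC"),
       TFAP_like = mk("TFAP_like", "GCCTGAGGCA"),
       SOX_like  = mk("SOX_like",  "CATTGTTTAC"),
       HK_like   = mk("HK_like",   "TGACGTCATC"))
}

#' Specification of a synthetic dataset
#'
#' Holds every parameter needed to regenerate a test universe
#' deterministically.  Defaults describe a compact but realistic universe:
#' a 2 Mb genome at 41% GC with ~10% soft-masked repeat, 160 enhancers
#' (60 A-specific, 40 B-specific, 60 shared), 400 bp elements, sub-100 bp
#' nucleosome-free fragments at 30 per region per replicate with a 4-fold
#' population bias for specific regions, ~200 bp nucleosomal fragments,
#' H3K27Ac support for 80% of population-A and shared enhancers, and a
#' 3000-SNP catalog around one planted motif-disrupting variant.
#'
#' @param seed integer RNG seed.
#' @param n_chroms,chrom_length genome shape.
#' @param background_gc background GC fraction.
#' @param repeat_density,repeat_length_range soft-masked repeat simulation.
#' @param motif_set named list of `pwm` objects (see [default_pwms()]).
#' @param motifs_per_enhancer planted instances per population-A enhancer.
#' @param n_enhancers_popA,n_enhancers_popB,n_shared region counts.
#' @param enhancer_length element length in bp.
#' @param fragment_depth expected sub-100 bp fragments per open region per
#'   replicate in the population where the region is active.
#' @param specific_fold accessibility fold bias of population-specific
#'   regions (active over inactive population).
#' @param n_replicates replicates per population.
#' @param nfr_length_range sub-nucleosomal fragment length range (bp).
#' @param nucleosomal_length_mean,nucleosomal_length_sd mono-nucleosome
#'   fragment length distribution (bp).
#' @param nucleosomal_fraction nucleosomal fragments per open region,
#'   relative to `fragment_depth`.
#' @param background_fragments_per_kb genome-wide noise fragments per kb
#'   per replicate.
#' @param footprint_keep probability of keeping a fragment whose Tn5 cut
#'   falls inside a planted motif instance (models TF protection).
#' @param k27_active_fraction fraction of population-A/shared enhancers
#'   given H3K27Ac support.
#' @param k27_flank_gap maximal inter-peak gap (bp) for flank-mode support;
#'   per-side gaps are drawn so the total gap stays at or below this.
#' @param k27_peak_length H3K27Ac peak length (bp).
#' @param n_genes TSS/gene count.
#' @param n_background_snps SNP catalog size around the planted locus.
#' @param n_test_snps tested SNPs (1 planted disruptive + decoys).
#' @param snp_radius catalog radius around the planted SNP (bp).
#' @param homolog_divergence per-base substitution rate for the two
#'   synthetic reference-species homologs.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_chroms = 4L, chrom_length = 500000L,
                           background_gc = 0.41, repeat_density = 0.10,
                           repeat_length_range = c(200L, 2000L),
                           motif_set = default_pwms(), motifs_per_enhancer = 3L,
                           n_enhancers_popA = 60L, n_enhancers_popB = 40L,
                           n_shared = 60L, enhancer_length = 400L,
                           fragment_depth = 30, specific_fold = 4,
                           n_replicates = 2L, nfr_length_range = c(40L, 99L),
                           nucleosomal_length_mean = 200,
                           nucleosomal_length_sd = 20,
                           nucleosomal_fraction = 0.5,
                           background_fragments_per_kb = 1,
                           footprint_keep = 0.2,
                           k27_active_fraction = 0.8, k27_flank_gap = 1500L,
                           k27_peak_length = 400L, n_genes = 40L,
                           n_background_snps = 3000L, n_test_snps = 14L,
                           snp_radius = 100000L, homolog_divergence = 0.25) {
  spec <- as.list(environment())
  stopifnot(n_enhancers_popA >= 0, n_enhancers_popB >= 0, n_shared >= 0,
            background_gc >= 0 && background_gc <= 1,
            k27_active_fraction >= 0 && k27_active_fraction <= 1,
            specific_fold >= 1, enhancer_length > 0)
  structure(spec, class = "synthetic_spec")
}

#' Plant a motif instance into a sequence
#'
#' Replaces `seq[position .. position + width)` (0-based) with bases drawn
#' column-wise from the PWM probabilities (`mode = "sample"`, uses the
#' current RNG stream) or with the consensus (`mode = "consensus"`).
#'
#' @param seq DNA string.
#' @param x a `pwm`.
#' @param position 0-based start of the replacement.
#' @param mode `"sample"` or `"consensus"`.
#' @return the modified sequence; only the planted window differs.
#' @export
plant_motif <- function(seq, x, position, mode = c("sample", "consensus")) {
  mode <- match.arg(mode)
  w <- pwm_width(x)
  if (position < 0 || position + w > nchar(seq))
    stop("motif does not fit: position ", position, " + width ", w,
         " exceeds sequence length ", nchar(seq))
  bases <- c("A", "C", "G", "T")
  inst <- if (mode == "consensus") pwm_consensus(x)
  else paste(vapply(seq_len(w), function(i)
    sample(bases, 1, prob = x$mat[i, ]), character(1)), collapse = "")
  paste0(substr(seq, 1, position), inst,
         substr(seq, position + w + 1, nchar(seq)))
}

# random DNA string with given GC, uppercase
.random_dna <- function(n, gc) {
  codes <- sample.int(4L, n, replace = TRUE,
                      prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
  intToUtf8(c(65L, 67L, 71L, 84L)[codes])
}

#' Generate a synthetic dataset
#'
#' @param spec a [synthetic_spec()].
#' @param dir optional output directory; when given, all components are
#'   written as plain-text files (`genome.fa`, `fragments.tsv`,
#'   `k27_peaks.bed`, `tss.bed`, `snps.tsv`, `motifs.txt`, `refs.fa`,
#'   `truth.tsv`, `motif_instances.tsv`).
#' @return list with the in-memory components (`genome`, `fragments`,
#'   `k27_peaks`, `tss`, `snps`, `truth`, `motif_instances`, `refs`,
#'   `pwms`, and `paths` when `dir` was given).
#' @export
make_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed, kind = "Mersenne-Twister")

  chroms <- paste0("chr", seq_len(spec$n_chroms))
  L <- spec$chrom_length

  ## 1. background genome
  genome <- stats::setNames(vapply(chroms, function(ch)
    .random_dna(L, spec$background_gc), character(1)), chroms)

  ## 2. soft-masked repeat stretches
  n_rep <- round(L * spec$repeat_density / mean(spec$repeat_length_range))
  for (ch in chroms) {
    if (n_rep == 0) next
    len <- sample(spec$repeat_length_range[1]:spec$repeat_length_range[2],
                  n_rep, replace = TRUE)
    start <- vapply(len, function(l) sample.int(L - l, 1), integer(1))
    for (i in seq_len(n_rep))
      substr(genome[[ch]], start[i] + 1L, start[i] + len[i]) <-
        tolower(substr(genome[[ch]], start[i] + 1L, start[i] + len[i]))
  }

  ## 3. enhancer placement on a non-overlapping slot grid
  n_enh <- spec$n_enhancers_popA + spec$n_enhancers_popB + spec$n_shared
  slot <- 10000L
  margin <- 5000L
  slots_per_chrom <- (L - 2L * margin) %/% slot
  slot_tab <- expand.grid(chrom = chroms, slot = seq_len(slots_per_chrom) - 1L,
                          stringsAsFactors = FALSE)
  if (n_enh > nrow(slot_tab))
    stop("cannot place ", n_enh, " non-overlapping enhancers; ",
         "increase chrom_length or n_chroms")
  pick <- slot_tab[sample.int(nrow(slot_tab), n_enh), , drop = FALSE]
  offset <- sample.int(slot - spec$enhancer_length - 5400L, n_enh, replace = TRUE)
  enh <- gintervals(pick$chrom,
                    margin + pick$slot * slot + offset,
                    margin + pick$slot * slot + offset + spec$enhancer_length)
  enh$population <- rep(c("popA", "popB", "shared"),
                        c(spec$n_enhancers_popA, spec$n_enhancers_popB, spec$n_shared))
  enh <- enh[order(enh$chrom, enh$start), , drop = FALSE]
  rownames(enh) <- NULL
  enh$enhancer_id <- sprintf("enh%03d_%s", seq_len(n_enh), enh$population)

  ## 4. motif planting
  pwms <- spec$motif_set
  popA_motifs <- utils::head(names(pwms), 3)
  popB_motif <- if (length(pwms) >= 4) names(pwms)[4] else names(pwms)[1]
  shared_motif <- if (length(pwms) >= 5) names(pwms)[5] else names(pwms)[length(pwms)]
  instances <- list()
  planted <- character(n_enh)
  first_A <- which(enh$population == "popA")[1]
  for (i in seq_len(n_enh)) {
    ids <- switch(enh$population[i],
                  popA = rep(popA_motifs, length.out = spec$motifs_per_enhancer),
                  popB = popB_motif,
                  shared = shared_motif)
    seq_i <- get_seq(genome, enh[i, ])
    pos_used <- integer(0)
    width_used <- integer(0)
    for (j in seq_along(ids)) {
      x <- pwms[[ids[j]]]
      w <- pwm_width(x)
      for (try in 1:50) {
        pos <- sample.int(spec$enhancer_length - w, 1) - 1L
        ok <- all(pos + w <= pos_used | pos >= pos_used + width_used)
        if (ok) break
      }
      if (!ok) next
      # the very first instance of the first population-A enhancer carries
      # the consensus, so the planted disruptive SNP has a guaranteed ref
      mode <- if (!is.na(first_A) && i == first_A && j == 1)
        "consensus" else "sample"
      seq_i <- plant_motif(seq_i, x, pos, mode = mode)
      pos_used <- c(pos_used, pos)
      width_used <- c(width_used, w)
      instances[[length(instances) + 1]] <-
        data.frame(enhancer_id = enh$enhancer_id[i], chrom = enh$chrom[i],
                   start = enh$start[i] + pos, end = enh$start[i] + pos + w,
                   strand = "+", pwm_id = ids[j], stringsAsFactors = FALSE)
    }
    planted[i] <- paste(ids, collapse = ",")
    substr(genome[[enh$chrom[i]]], enh$start[i] + 1L, enh$end[i]) <- seq_i
  }
  instances <- if (length(instances)) do.call(rbind, instances) else
    data.frame(enhancer_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), strand = character(0),
               pwm_id = character(0))
  enh$motifs <- planted

  ## 5. H3K27Ac peaks: overlap mode or symmetric flanking with total
  ##    inter-peak gap <= k27_flank_gap
  k27 <- list()
  enh$k27 <- 0L
  elig <- enh$population %in% c("popA", "shared")
  for (i in which(elig)) {
    if (stats::runif(1) > spec$k27_active_fraction) next
    enh$k27[i] <- 1L
    pl <- spec$k27_peak_length
    if (stats::runif(1) < 0.5) { # overlap mode
      k27[[length(k27) + 1]] <- data.frame(chrom = enh$chrom[i],
                                           start = enh$start[i] - 100L,
                                           end = enh$end[i] + 100L)
    } else { # flank mode
      side_max <- (spec$k27_flank_gap - spec$enhancer_length) %/% 2L
      g <- sample(100:side_max, 1)
      k27[[length(k27) + 1]] <- data.frame(chrom = enh$chrom[i],
                                           start = enh$start[i] - g - pl,
                                           end = enh$start[i] - g)
      k27[[length(k27) + 1]] <- data.frame(chrom = enh$chrom[i],
                                           start = enh$end[i] + g,
                                           end = enh$end[i] + g + pl)
    }
  }
  k27 <- if (length(k27)) do.call(rbind, k27) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0))
  k27 <- k27[order(k27$chrom, k27$start), , drop = FALSE]
  rownames(k27) <- NULL
  if (nrow(k27) > 0) k27$name <- sprintf("k27_%03d", seq_len(nrow(k27)))

  ## 6. genes / TSS (kept clear of enhancers so the TSS filter does not
  ##    silently eat planted elements)
  tss_pos <- integer(0); tss_chrom <- character(0)
  while (length(tss_pos) < spec$n_genes) {
    ch <- sample(chroms, 1)
    p <- sample.int(L - 2000L, 1) + 1000L
    near <- enh$chrom == ch & p > (enh$start - 1500L) & p < (enh$end + 1500L)
    if (!any(near)) {
      tss_pos <- c(tss_pos, p)
      tss_chrom <- c(tss_chrom, ch)
    }
  }
  tss <- gintervals(tss_chrom, tss_pos, tss_pos + 1L,
                    strand = sample(c("+", "-"), spec$n_genes, replace = TRUE))
  tss$name <- sprintf("gene%03d", seq_len(spec$n_genes))
  tss <- tss[order(tss$chrom, tss$start), , drop = FALSE]
  rownames(tss) <- NULL
  tss <- tss[, c("chrom", "start", "end", "name", "strand")]

  ## 7. fragments
  frag <- list()
  motif_by_enh <- split(instances, instances$enhancer_id)
  for (pop in c("popA", "popB")) {
    for (rep_i in seq_len(spec$n_replicates)) {
      sample_id <- sprintf("%s_rep%d", pop, rep_i)
      for (i in seq_len(n_enh)) {
        mult <- switch(enh$population[i],
                       shared = 1,
                       popA = if (pop == "popA") 1 else 1 / spec$specific_fold,
                       popB = if (pop == "popB") 1 else 1 / spec$specific_fold)
        n_nfr <- stats::rpois(1, spec$fragment_depth * mult)
        if (n_nfr > 0) {
          len <- sample(spec$nfr_length_range[1]:spec$nfr_length_range[2],
                        n_nfr, replace = TRUE)
          st <- enh$start[i] - 20L +
            vapply(len, function(l)
              sample.int(spec$enhancer_length + 40L - l, 1), integer(1))
          keep <- rep(TRUE, n_nfr)
          mi <- motif_by_enh[[enh$enhancer_id[i]]]
          if (!is.null(mi) && nrow(mi) > 0 && spec$footprint_keep < 1) {
            cut1 <- st + 4L
            cut2 <- st + len - 5L
            incut <- function(p) {
              hit <- rep(FALSE, length(p))
              for (r in seq_len(nrow(mi)))
                hit <- hit | (p >= mi$start[r] & p < mi$end[r])
              hit
            }
            bad <- incut(cut1) | incut(cut2)
            keep[bad] <- stats::runif(sum(bad)) < spec$footprint_keep
          }
          if (any(keep))
            frag[[length(frag) + 1]] <-
              data.frame(chrom = enh$chrom[i], start = st[keep],
                         end = st[keep] + len[keep], strand = "+",
                         sample = sample_id, stringsAsFactors = FALSE)
        }
        n_nuc <- stats::rpois(1, spec$fragment_depth * mult * spec$nucleosomal_fraction)
        if (n_nuc > 0) {
          len <- pmax(147L, round(stats::rnorm(n_nuc, spec$nucleosomal_length_mean,
                                               spec$nucleosomal_length_sd)))
          st <- enh$start[i] - 300L +
            vapply(len, function(l)
              sample.int(spec$enhancer_length + 600L, 1), integer(1))
          frag[[length(frag) + 1]] <-
            data.frame(chrom = enh$chrom[i], start = st, end = st + len,
                       strand = "+", sample = sample_id, stringsAsFactors = FALSE)
        }
      }
      n_bg <- round(spec$n_chroms * L / 1000 * spec$background_fragments_per_kb)
      if (n_bg > 0) {
        ch <- sample(chroms, n_bg, replace = TRUE)
        short <- stats::runif(n_bg) < 0.5
        len <- integer(n_bg)
        len[short] <- sample(spec$nfr_length_range[1]:spec$nfr_length_range[2],
                             sum(short), replace = TRUE)
        len[!short] <- pmax(147L, round(stats::rnorm(sum(!short),
                                                     spec$nucleosomal_length_mean,
                                                     spec$nucleosomal_length_sd)))
        st <- vapply(len, function(l) sample.int(L - l - 1L, 1), integer(1))
        frag[[length(frag) + 1]] <-
          data.frame(chrom = ch, start = st, end = st + len, strand = "+",
                     sample = sample_id, stringsAsFactors = FALSE)
      }
    }
  }
  fragments <- do.call(rbind, frag)
  fragments <- fragments[order(fragments$sample, fragments$chrom, fragments$start), ]
  rownames(fragments) <- NULL
  fragments$length <- fragments$end - fragments$start

  ## 8. SNPs: one planted motif-disrupting variant + decoys + catalog
  enh$snp_id <- NA_character_
  enh$snp_pos <- NA_integer_
  enh$snp_ref <- NA_character_
  enh$snp_alt <- NA_character_
  enh$snp_motif_delta <- NA_real_
  snps <- NULL
  iA <- which(enh$population == "popA")[1]
  if (!is.na(iA) && spec$n_test_snps >= 1) {
    inst1 <- instances[instances$enhancer_id == enh$enhancer_id[iA], ][1, ]
    x <- pwms[[inst1$pwm_id]]
    col <- which.max(apply(x$mat, 1, max))
    pos0 <- inst1$start + col - 1L
    ref <- substr(genome[[inst1$chrom]], pos0 + 1L, pos0 + 1L) # consensus (planted)
    worst <- c("A", "C", "G", "T")[which.min(x$mat[col, ])]
    delta <- x$lom[col, worst] - x$lom[col, toupper(ref)]
    center <- pos0
    lo <- max(1000L, center - spec$snp_radius)
    hi <- min(L - 1000L, center + spec$snp_radius)
    n_decoy <- spec$n_test_snps - 1L
    cand <- setdiff(lo:hi, pos0)
    in_enh <- enh$chrom == inst1$chrom
    for (r in which(in_enh)) cand <- cand[cand < enh$start[r] | cand >= enh$end[r]]
    decoy_pos <- sort(sample(cand, n_decoy))
    cat_pos <- sort(sample(setdiff(cand, decoy_pos), spec$n_background_snps))
    mkalt <- function(refb) vapply(refb, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1), USE.NAMES = FALSE)
    all_pos <- c(pos0, decoy_pos, cat_pos)
    refs <- toupper(substring(genome[[inst1$chrom]], all_pos + 1L, all_pos + 1L))
    ok <- refs %in% c("A", "C", "G", "T")
    alts <- character(length(all_pos))
    alts[1] <- worst
    alts[-1] <- mkalt(refs[-1])
    snps <- data.frame(chrom = inst1$chrom, pos = all_pos + 1L, ref = refs,
                       alt = alts,
                       id = c("snp_planted",
                              sprintf("snp_test%02d", seq_len(n_decoy)),
                              sprintf("snp_bg%05d", seq_len(spec$n_background_snps))),
                       assoc_p = c(stats::runif(spec$n_test_snps, 1e-8, 1e-5),
                                   stats::runif(spec$n_background_snps, 0.2, 1)),
                       set = c(rep("test", spec$n_test_snps),
                               rep("background", spec$n_background_snps)),
                       stringsAsFactors = FALSE)
    snps <- snps[ok, , drop = FALSE]
    rownames(snps) <- NULL
    snps$pos0 <- snps$pos - 1L # in-memory convenience; recomputed on reading
    enh$snp_id[iA] <- "snp_planted"
    enh$snp_pos[iA] <- pos0 + 1L
    enh$snp_ref[iA] <- refs[1]
    enh$snp_alt[iA] <- worst
    enh$snp_motif_delta[iA] <- delta
  }

  ## 9. homolog references: two diverged copies of the first popA enhancer
  refs_fa <- character(0)
  if (!is.na(iA)) {
    src <- toupper(get_seq(genome, enh[iA, ]))
    mutate <- function(s, rate) {
      b <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(length(b)) < rate)
      b[hit] <- vapply(b[hit], function(x)
        sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
      paste(b, collapse = "")
    }
    refs_fa <- c(ref_species1 = mutate(src, spec$homolog_divergence),
                 ref_species2 = mutate(src, spec$homolog_divergence))
  }

  truth <- enh[, c("enhancer_id", "chrom", "start", "end", "population", "k27",
                   "motifs", "snp_id", "snp_pos", "snp_ref", "snp_alt",
                   "snp_motif_delta")]
  out <- list(genome = structure(genome, class = "genome"),
              fragments = fragments, k27_peaks = k27, tss = tss, snps = snps,
              truth = truth, motif_instances = instances,
              refs = refs_fa, pwms = pwms, spec = spec)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(genome = file.path(dir, "genome.fa"),
                  fragments = file.path(dir, "fragments.tsv"),
                  k27_peaks = file.path(dir, "k27_peaks.bed"),
                  tss = file.path(dir, "tss.bed"),
                  snps = file.path(dir, "snps.tsv"),
                  motifs = file.path(dir, "motifs.txt"),
                  refs = file.path(dir, "refs.fa"),
                  truth = file.path(dir, "truth.tsv"),
                  motif_instances = file.path(dir, "motif_instances.tsv"))
    write_fasta(out$genome, paths$genome)
    utils::write.table(fragments[, c("chrom", "start", "end", "strand", "sample")],
                       paths$fragments, sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(k27, paths$k27_peaks)
    write_bed(tss, paths$tss)
    if (!is.null(snps))
      utils::write.table(snps[, setdiff(names(snps), "pos0")], paths$snps,
                         sep = "\t", quote = FALSE, row.names = FALSE)
    write_pwms(pwms, paths$motifs)
    if (length(refs_fa)) write_fasta(refs_fa, paths$refs)
    utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(instances, paths$motif_instances, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    out$paths <- paths
  }
  out
}
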