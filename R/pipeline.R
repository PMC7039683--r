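## Config-driven orchestration: a JSON key-value config holds every
## threshold with the published defaults; run_all() executes the stages in
## dependency order and writes a checksum manifest plus a provenance
## record, so a rerun with the same config is bit-identical.

#' Default pipeline configuration
#'
#' All thresholds default to the published parameters: 100 bp fragment
#' cutoff, |log2FC| > 0.5 at FDR < 0.01, 1500 bp H3K27Ac flank gap,
#' 400 bp elements with 70% repeat cap, 10x GC/repeat-matched negatives,
#' l = 10 / k = 6, 400/100 tiling, 19 bp deltaSVM windows, 1000-SNP null
#' within 100 kb, and 0.8 / 5.0 / 2.0 motif-score thresholds.
#'
#' @param input_dir dataset directory (see [make_dataset()] layout).
#' @param output_dir where stage outputs are written.
#' @param seed master seed for every stochastic stage.
#' @param simulate regenerate the dataset into `input_dir` first.
#' @param overrides named list of config values to replace.
#' @return named list (class `pipeline_config`).
#' @export
pipeline_config <- function(input_dir, output_dir, seed = 1L, simulate = FALSE,
                            overrides = list()) {
  cfg <- list(
    input_dir = input_dir, output_dir = output_dir, seed = as.integer(seed),
    simulate = simulate,
    nfr_max_len = 100, lfc_threshold = 0.5, fdr_threshold = 0.01,
    peak_smooth_window = 150, peak_min_fold = 4, peak_background_span = 10000,
    k27_max_gap = 1500, element_width = 400, tss_pad = 500, max_repeat = 0.70,
    gene_max_dist = 100000, gene_max_n = 2,
    negative_ratio = 10, gc_tolerance = 0.05, repeat_tolerance = 0.10,
    gkm_l = 10, gkm_k = 6, rc_collapse = TRUE, svm_c = 1.0, cv_folds = 5,
    tile_length = 400, tile_step = 100,
    delta_window = 19, null_n = 1000, null_radius = 100000,
    motif_min_relative = 0.8, site_score_hi = 5.0, site_score_lo = 2.0,
    footprint_flank = 100,
    homology_shuffles = 3, align_match = 1, align_mismatch = -1,
    align_gap_open = -5, align_gap_extend = -1)
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Read / write a pipeline config as JSON
#' @param path JSON file.
#' @rdname pipeline_config_io
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' @param config a `pipeline_config`.
#' @rdname pipeline_config_io
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.stage_msg <- function(...) message("[enhancerscan] ", ...)

#' Run the full pipeline on a dataset directory
#'
#' Stages, in dependency order: (optional) simulate; NFR selection, peak
#' calling and differential accessibility; active-enhancer annotation;
#' gapped k-mer SVM training with cross-validation; genome tiling and
#' percentile-bin enrichment; deltaSVM SNP prioritization; motif presence,
#' combinations and enrichment; Tn5 footprint; homology report.  Every
#' output is recorded in `manifest.json` (md5 checksums) together with a
#' provenance record (config hash, seed, package version).
#'
#' @param config a [pipeline_config()].
#' @return invisibly, the output directory; side effect: files under
#'   `config$output_dir`.
#' @export
run_all <- function(config) {
  cfg <- config
  indir <- cfg$input_dir
  outdir <- cfg$output_dir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  if (isTRUE(cfg$simulate)) {
    .stage_msg("simulate: generating synthetic dataset (seed ", cfg$seed, ")")
    spec <- do.call(synthetic_spec,
                    c(list(seed = cfg$seed), cfg$spec_overrides %||% list()))
    make_dataset(spec, dir = indir)
  }
  need <- c(genome = "genome.fa", fragments = "fragments.tsv",
            k27 = "k27_peaks.bed", tss = "tss.bed", snps = "snps.tsv",
            motifs = "motifs.txt")
  paths <- file.path(indir, need)
  names(paths) <- names(need)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0)
    stop("missing input file(s): ", paste(missing, collapse = ", "))

  genome <- read_fasta(paths[["genome"]])
  fragments <- read_fragments(paths[["fragments"]])
  k27 <- read_bed(paths[["k27"]])
  tss <- read_bed(paths[["tss"]])
  snps <- read_snp_table(paths[["snps"]])
  pwms <- read_pwms(paths[["motifs"]])
  chrom_lengths <- genome_lengths(genome)
  outputs <- character(0)

  ## --- accessibility ---
  .stage_msg("nfr: ", nrow(fragments), " fragments in")
  nfr <- select_nfr_fragments(fragments, cfg$nfr_max_len)
  .stage_msg("nfr: ", nrow(nfr), " sub-", cfg$nfr_max_len, " bp fragments kept")
  samples <- sort(unique(fragments$sample))
  pops <- unique(sub("_rep.*$", "", samples))
  if (length(pops) != 2) stop("expected exactly two populations, got: ",
                              paste(pops, collapse = ", "))
  cuts_by_pop <- lapply(pops, function(p)
    fragment_cut_sites(nfr[startsWith(nfr$sample, p), ]))
  names(cuts_by_pop) <- pops
  peaks <- lapply(pops, function(p)
    call_peaks(cuts_by_pop[[p]], chrom_lengths, cfg$peak_smooth_window,
               cfg$peak_min_fold, cfg$peak_background_span))
  union_peaks <- merge_intervals(do.call(rbind, peaks))
  .stage_msg("peaks: ", paste(vapply(peaks, nrow, integer(1)), collapse = " / "),
             " per population; ", nrow(union_peaks), " in the union")
  cm <- build_count_matrix(union_peaks, nfr)
  groupA <- samples[startsWith(samples, pops[1])]
  groupB <- samples[startsWith(samples, pops[2])]
  diff <- differential_nfr(cm, groupA, groupB, cfg$lfc_threshold, cfg$fdr_threshold)
  outputs <- c(outputs, .write_tsv(diff, file.path(outdir, "differential_nfr.tsv")))
  .stage_msg("differential: ", sum(diff$call == "popA-enriched"), " ", pops[1],
             "-enriched / ", sum(diff$call == "popB-enriched"), " ", pops[2],
             "-enriched / ", sum(diff$call == "shared"), " shared")

  ## --- enhancer annotation ---
  enh <- active_enhancers(diff, "popA-enriched", k27, cuts_by_pop[[pops[1]]],
                          genome, tss, width = cfg$element_width,
                          max_gap = cfg$k27_max_gap, tss_pad = cfg$tss_pad,
                          max_repeat = cfg$max_repeat,
                          max_dist = cfg$gene_max_dist, max_genes = cfg$gene_max_n)
  if (is.null(enh) || nrow(enh) == 0)
    stop("no active enhancers survived annotation; nothing to train on")
  .stage_msg("enhancers: ", nrow(enh), " active elements")
  outputs <- c(outputs, .write_tsv(enh, file.path(outdir, "active_enhancers.tsv")))
  write_bed(enh, file.path(outdir, "active_enhancers.bed"))
  outputs <- c(outputs, file.path(outdir, "active_enhancers.bed"))

  ## --- gkm training ---
  params <- gkm_params(cfg$gkm_l, cfg$gkm_k, cfg$rc_collapse, cfg$svm_c)
  posseq <- toupper(get_seq(genome, enh))
  ts <- build_negative_set(posseq, genome, ratio = cfg$negative_ratio,
                           gc_tolerance = cfg$gc_tolerance,
                           repeat_tolerance = cfg$repeat_tolerance,
                           exclusions = enh, seed = cfg$seed)
  G <- gkm_gram(c(ts$positives, ts$negatives), params)
  model <- gkm_train(ts, params, gram = G)
  cv <- cross_validate(ts, params, folds = cfg$cv_folds, seed = cfg$seed, gram = G)
  .stage_msg(sprintf("train: %d positives, %d negatives; CV auROC %.3f, auPRC %.3f",
                     length(ts$positives), length(ts$negatives), cv$auROC, cv$auPRC))
  write_gkm_model(model, file.path(outdir, "gkm_model"), top_n = 5000)
  outputs <- c(outputs, file.path(outdir, "gkm_model_weights.tsv"),
               file.path(outdir, "gkm_model_header.json"))
  outputs <- c(outputs, .write_tsv(
    data.frame(metric = c("auROC", "auPRC"), value = c(cv$auROC, cv$auPRC)),
    file.path(outdir, "cv_metrics.tsv")))

  ## --- tiling ---
  tiles <- tile_genome(genome, cfg$tile_length, cfg$tile_step)
  tiles <- percentile_bins(score_tiles(tiles, genome, model))
  enr <- annotation_enrichment(tiles, list(active_enhancers = enh, k27_peaks = k27))
  .stage_msg("tiles: ", nrow(tiles), " scored; top-bin enhancer fold ",
             signif(enr$fold[1], 3))
  outputs <- c(outputs, .write_tsv(tiles[tiles$percentile_bin != "rest", ],
                                   file.path(outdir, "top_tiles.tsv")))
  outputs <- c(outputs, .write_tsv(enr, file.path(outdir, "tile_enrichment.tsv")))

  ## --- deltaSVM prioritization ---
  test_snps <- if (!is.null(snps$set)) snps[snps$set == "test", ] else snps
  catalog <- if (!is.null(snps$set)) snps[snps$set == "background", ] else NULL
  center <- round(stats::median(test_snps$pos0))
  null_snps <- sample_null_snps(test_snps$chrom[1], center, genome,
                                radius = cfg$null_radius, n = cfg$null_n,
                                seed = cfg$seed, catalog = catalog,
                                exclude_ids = test_snps$id)
  pri <- prioritize(test_snps, model, genome, null_snps, window = cfg$delta_window)
  .stage_msg("delta: top SNP ", pri$id[1], " (delta ", signif(pri$delta[1], 3),
             ", Bonferroni p ", signif(pri$bonferroni_p[1], 3), ")")
  outputs <- c(outputs, .write_tsv(pri, file.path(outdir, "snp_prioritization.tsv")))

  ## --- motifs ---
  pres <- motif_presence(enh, genome, pwms, cfg$motif_min_relative)
  rownames(pres$matrix) <- sprintf("enh_%04d", seq_len(nrow(enh)))
  comb2 <- motif_combinations(pres$matrix, 2)
  neg_iv <- ts$negative_intervals
  menr <- motif_enrichment(enh, neg_iv, genome, pwms, cfg$motif_min_relative)
  outputs <- c(outputs, .write_tsv(
    data.frame(pwm_id = names(pres$fraction), fraction = pres$fraction),
    file.path(outdir, "motif_presence.tsv")))
  outputs <- c(outputs, .write_tsv(comb2, file.path(outdir, "motif_combinations.tsv")))
  outputs <- c(outputs, .write_tsv(menr, file.path(outdir, "motif_enrichment.tsv")))
  .stage_msg("motifs: ", paste(sprintf("%s %.2f", names(pres$fraction),
                                       pres$fraction), collapse = ", "))

  ## --- footprint for the most enriched motif ---
  topmotif <- menr$pwm_id[which.max(ifelse(is.finite(menr$fold), menr$fold, -Inf))]
  hits <- do.call(rbind, lapply(seq_len(nrow(enh)), function(i)
    scan_pwm(get_seq(genome, enh[i, ]), pwms[[topmotif]],
             cfg$motif_min_relative, chrom = enh$chrom[i], offset = enh$start[i])))
  fp <- if (!is.null(hits) && nrow(hits) > 0)
    footprint(cuts_by_pop[[pops[1]]], hits, cfg$footprint_flank) else NULL
  if (!is.null(fp)) {
    outputs <- c(outputs, .write_tsv(
      data.frame(offset = fp$offsets, cuts = as.numeric(fp$cut_counts)),
      file.path(outdir, "footprint_profile.tsv")))
    .stage_msg(sprintf("footprint: %s protection %.3f", topmotif, fp$protection))
  }

  ## --- homology ---
  refs_path <- file.path(indir, "refs.fa")
  if (file.exists(refs_path)) {
    refs <- read_fasta(refs_path)
    # test the element containing the top-prioritized SNP (fall back to the
    # first element when that SNP lies outside the annotated set)
    top_iv <- gintervals(pri$chrom[1], pri$pos[1] - 1L, pri$pos[1])
    hit <- which(overlaps_any(enh, top_iv))
    test_el <- if (length(hit) > 0) enh[hit[1], ] else enh[1, ]
    hr <- homology_report(toupper(get_seq(genome, test_el)), unclass(refs),
                          n_shuffles = cfg$homology_shuffles, seed = cfg$seed,
                          match = cfg$align_match, mismatch = cfg$align_mismatch,
                          gap_open = cfg$align_gap_open,
                          gap_extend = cfg$align_gap_extend)
    outputs <- c(outputs, .write_tsv(hr$table, file.path(outdir, "homology_report.tsv")))
    outputs <- c(outputs, .write_tsv(
      data.frame(statistic = names(hr$zscores), z = as.numeric(hr$zscores)),
      file.path(outdir, "homology_zscores.tsv")))
    .stage_msg("homology: identity z ", signif(hr$zscores[["mean_identity"]], 3))
  }

  ## --- provenance + manifest ---
  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  prov <- list(config_hash = unname(tools::md5sum(
    {tmp <- tempfile(); writeLines(cfg_json, tmp); tmp})),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("enhancerscan")),
    r_version = R.version.string)
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE)
  sums <- tools::md5sum(sort(outputs))
  names(sums) <- basename(names(sums))
  jsonlite::write_json(as.list(sums), file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Command-line entry point
#'
#' Subcommands: `simulate`, `run-all` (plus `config` to emit a default
#' config).  Typical use:
#' `Rscript -e 'enhancerscan::enhancerscan_cli()' run-all --config cfg.json`
#' or via the installed script in `inst/scripts/enhancerscan`.
#'
#' @param args character vector (defaults to `commandArgs(TRUE)`).
#' @export
enhancerscan_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: enhancerscan <simulate|run-all|config> [--config FILE]",
    "  [--in DIR] [--out DIR] [--seed INT]", sep = "\n")
  if (length(args) < 1) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(seed = 1L, `in` = "dataset", out = "results", config = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg <- if (!is.null(opt$config)) read_config(opt$config) else
    pipeline_config(opt$`in`, opt$out, seed = as.integer(opt$seed))
  if (cmd == "simulate") {
    make_dataset(synthetic_spec(seed = as.integer(opt$seed)), dir = opt$`in`)
    .stage_msg("dataset written to ", opt$`in`)
  } else if (cmd == "run-all") {
    run_all(cfg)
  } else if (cmd == "config") {
    write_config(cfg, file.path(".", "enhancerscan_config.json"))
    .stage_msg("default config written to enhancerscan_config.json")
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
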