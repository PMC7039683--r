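# enhancerscan

Tissue-specific enhancer discovery and noncoding variant prioritization
from chromatin accessibility, in one tested R package.

## The problem

Genome-wide association studies flag noncoding loci, but cannot tell a
functional variant — one that damages a tissue-specific enhancer — from the
linked passengers around it. A route that has worked well for embryonic
surface epithelia (periderm, palate and oral epithelium) is:

1. **Find open chromatin per sorted cell population.** ATAC-seq fragments
   shorter than 100 bp mark nucleosome-free regions (NFRs); differential
   accessibility between the sorted population and its complement
   (|log2 FC| > 0.5, FDR < 0.01 on a conditional binomial test with BH
   adjustment) yields population-enriched NFRs.
2. **Keep the active ones.** Elements that overlap H3K27Ac peaks, or sit
   between peaks separated by at most 1500 bp, lose TSS overlaps, are
   resized to the 400 bp window maximizing Tn5 cut density, and drop
   elements that are more than 70% repeat-masked.
3. **Learn their sequence grammar.** A gapped k-mer support vector machine
   (word length *l* = 10, *k* = 6 informative columns) is trained against a
   10-fold larger GC- and repeat-matched random genomic background. The
   kernel is
   `K(A,B) = Σ_{u∈A, v∈B} f(m(u,v))`, `f(m) = C(l−m, k)`,
   evaluated both by mismatch counting and exactly, via the explicit
   gapped k-mer feature map. Every 10-mer `u` gets a weight
   `w(u) = Σ_sv (αy)_sv K(u, sv)/√K(sv,sv)`.
4. **Score variants.** A SNP's **deltaSVM** is the weight-sum difference
   between the alternate and reference alleles over the 19 bp window
   centred on it; significance comes from a resampling null of 1000 SNPs
   within 100 kb, with Bonferroni correction over the tested SNPs
   (e.g. 2 of 1000 null SNPs lower and 14 tests → p = 0.028).
5. **Interpret.** PWM scanning at the 80% relative-score threshold,
   allele-specific site loss (raw log-odds ≥ 5.0 in one allele, < 2.0 or
   undetected in the other), Tn5 footprint aggregation (+4/−5 shifted
   cuts, ±100 bp flanks), genome tiling (400 bp / 100 bp step) with
   top-percentile-bin enrichment, and a shuffle-controlled deep-homology
   test (minus strand, reverse, and Fisher–Yates controls; null-character
   and ≥5 bp identity-block statistics with z-scores).

`enhancerscan` implements this whole route, plus a deterministic
synthetic-data generator that emulates the sorted-cell inputs (two
populations, planted motifs, H3K27Ac support, a planted motif-disrupting
SNP) so every stage is testable without external sequencing data.

## Worked example

```r
library(enhancerscan)

cfg <- pipeline_config("dataset", "results_demo", seed = 1, simulate = TRUE)
run_all(cfg)
```

This generates the default synthetic universe (2 Mb genome, 60 + 40 + 60
enhancers, two replicates per population) and runs every stage, printing:

```
[enhancerscan] simulate: generating synthetic dataset (seed 1)
[enhancerscan] nfr: 29020 fragments in
[enhancerscan] nfr: 17788 sub-100 bp fragments kept
[enhancerscan] peaks: 160 / 158 per population; 160 in the union
[enhancerscan] differential: 60 popA-enriched / 41 popB-enriched / 59 shared
[enhancerscan] enhancers: 43 active elements
[enhancerscan] train: 43 positives, 430 negatives; CV auROC 0.923, auPRC 0.758
[enhancerscan] tiles: 19988 scored; top-bin enhancer fold 58.3
[enhancerscan] delta: top SNP snp_planted (delta -38.9, Bonferroni p 0)
[enhancerscan] motifs: GRHL_like 0.91, KLF_like 0.88, TFAP_like 0.93, SOX_like 0.37, HK_like 0.26
[enhancerscan] footprint: KLF_like protection 0.279
[enhancerscan] homology: identity z 12.6
```

Reading the output: all 60 planted population-A enhancers fall in called
differential regions; 43 survive H3K27Ac/TSS/repeat filtering; five-fold
cross-validated auROC of the classifier is 0.92; the planted
motif-disrupting SNP is the top-ranked of the 14 tested variants with an
empirical p of 0/1000; the three planted population-A motifs are present
in ~90% of the final elements; Tn5 cuts inside the most enriched motif are
depleted ~3.6-fold (protection 0.28); and the element containing the top
SNP shows strong homology (z ≈ 13) to the two synthetic "reference
species" sequences.
`results_demo/` holds one TSV per stage plus `manifest.json` (md5 of every
output; reruns with the same config are bit-identical).

## Package tour

| Module | Key functions |
| --- | --- |
| Coordinates & I/O | `read_fasta`, `read_bed`, `read_snp_table`, `gc_fraction`, `repeat_fraction`, `reverse_complement` |
| Synthetic data | `synthetic_spec`, `make_dataset`, `plant_motif`, `default_pwms` |
| Accessibility | `select_nfr_fragments`, `shift_cut_sites`, `call_peaks`, `build_count_matrix`, `differential_nfr` |
| Enhancer annotation | `flanked_regions`, `classify_k27`, `remove_tss_overlaps`, `resize_to_width`, `repeat_filter`, `assign_genes`, `active_enhancers` |
| gkm-SVM | `gkm_kernel`, `gkm_gram`, `build_negative_set`, `gkm_train`, `cross_validate`, `score_sequence`, `gkm_kmer_weights` |
| Tiling | `tile_genome`, `score_tiles`, `percentile_bins`, `annotation_enrichment` |
| Variant scoring | `delta_svm`, `sample_null_snps`, `empirical_p`, `prioritize` |
| Motifs | `read_pwms`, `scan_pwm`, `motif_presence`, `motif_combinations`, `motif_enrichment`, `footprint`, `allele_effect`, `build_network` |
| Homology | `global_align`, `three_way_align`, `fisher_yates_shuffle`, `make_controls`, `identity_blocks`, `homology_report` |
| Orchestration | `pipeline_config`, `run_all`, `enhancerscan_cli` |

The methods vignette (`vignettes/enhancerscan-methods.Rmd`) documents the
models, parameter choices, numerical conventions, and what the synthetic
world does and does not establish.
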