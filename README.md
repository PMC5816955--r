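# gonadomics

Multi-omic analysis toolkit for the gonadotrope response to
gonadotropin-releasing hormone (GnRH).

The LbT2 mouse gonadotrope line is the workhorse model for studying how
pituitary gonadotropes decode pulsatile GnRH into gonadotropin gene
expression. Characterizing that response end to end takes four assays —
bulk RNA-seq for the population-level induced program, ATAC-seq for the
open-chromatin landscape behind it, droplet single-cell RNA-seq for
cell-to-cell response variation, and qPCR for targeted validation — and
a series of bespoke computations connecting them. gonadomics implements
those computations as tested, reusable R functions, together with a
synthetic multi-omic generator (with recorded ground truth) so every
stage can be exercised and validated at the study's scale without any
external download.

## What's inside

| Stage | Functions | Model |
|---|---|---|
| Synthetic data | `sim_config()`, `simulate_sc_counts()`, `simulate_bulk_counts()`, `simulate_atac()`, `simulate_qpcr_ct()` | NB counts, var = mu + phi mu^2; five-phase cosine marker profiles; planted immediate-early program; nucleosomal fragment mixture; planted TF footprints |
| Bulk DE | `moderated_t_test()`, `bh_fdr()`, `select_de()`, `tpm()` | eBayes-moderated t on log2-CPM (TMM-normalized), s~^2 = (d0 s0^2 + d s^2)/(d0 + d); BH FDR; \|log2FC\| >= 2 at q < 0.05 with a 16-fold tier |
| Single cell | `cell_normalize()`, `umi_rank_curve()`, `split_half()`, `pseudobulk_vs_bulk()`, `noise_decomposition()`, `sseq_de()` | length-free per-cell TPM; Poisson noise floor CV = 1/sqrt(mu); shrinkage-dispersion NB exact test conditional on the gene total |
| Cell cycle | `phase_scores()`, `assign_and_order()`, `phase_conditioned_response()` | five-phase gene-set scoring (two z-score steps, correlation refinement), cyclic argmax assignment and progression ordering, phase-conditioned Kruskal-Wallis / Wilcoxon testing |
| ATAC | `estimate_periodicity()`, `classify_peaks()`, `top_peaks()`, `tss_profile()`, `max_peak_per_gene()`, `pwm_scan()`, `detect_notch()` | detrended length-histogram autocorrelation; summit-precedence feature classes; TSS meta-profile; nearest-TSS max score; log-odds PWM scan; flank-validated footprint notches |
| qPCR | `ct_to_units()`, `summarize_replicates()` | E = 2500 x 1.93^(Ct_ref − Ct_gene), Rps11 reference, Ct-scale replicate averaging |

I/O covers the field's plain-text formats: Cell Ranger MatrixMarket
triplets, count TSVs, GTF, BED, narrowPeak, phase-set TSVs, FASTA.

## Worked example

```r
library(gonadomics)

cfg  <- sim_config(n_genes = 2000, n_cells_per_condition = 300, seed = 1)
sim  <- simulate_sc_counts(cfg)          # vehicle + GnRH droplet matrices
bulk <- simulate_bulk_counts(cfg, sim$truth)

de <- select_de(moderated_t_test(bulk$counts, bulk$groups))
sum(de$selected); sum(de$tier16fold)
#> selected: 98 of 2000 | 16-fold tier: 37
head(de[de$selected, c("gene_id", "logCPM", "log2FC", "t", "q")], 3)
#>      gene_id   logCPM   log2FC        t            q
#> 5  gene00005 7.728772 2.468271 10.40335 5.583007e-24
#> 19 gene00019 9.804215 3.961640 16.69766 7.315622e-61
#> 43 gene00043 9.106521 4.062669 17.12348 5.960469e-64

split_half(sim$vehicle, seed = 1)$r
#> 0.9961
pseudobulk_vs_bulk(sim$vehicle,
                   bulk$counts[, bulk$groups == "vehicle"],
                   bulk$gene_length)$r
#> 0.997

ps <- assign_and_order(phase_scores(
  log2_sctpm(sim$vehicle, genes = unique(unlist(sim$truth$phase_sets))),
  sim$truth$phase_sets))
ps
#> phase_scores: 300 cells x 5 phases
#> assignment:
#> G1/S    S G2/M    M M/G1
#>   61   72   57   57   53

estimate_periodicity(simulate_fragment_lengths(2e5, cfg), seed = 1)$period
#> 199                      # bp, the planted ~200 bp nucleosomal spacing

ct_to_units(22, 22)
#> 2500                     # arbitrary units at delta-Ct = 0
```

The 98 selected genes are the recovered planted immediate-early
program (100 genes planted at 4- to 32-fold); the split-half and
pseudobulk correlations are the two reproducibility diagnostics of a
healthy droplet run; the phase table shows the five-phase assignment
of the 300 vehicle cells.

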