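---
title: "Models and methods behind gonadomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gonadomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gonadomics)
```

gonadomics packages the computational stages used to characterize the
LbT2 gonadotrope response to gonadotropin-releasing hormone (GnRH)
across four assays — bulk RNA-seq, droplet single-cell RNA-seq,
ATAC-seq and qPCR — together with a synthetic-data generator that
reproduces the statistical structure those stages assume. This
vignette explains the models, the parameters that matter, the
numerical choices, and what the synthetic data can and cannot tell you
about real data.

## The synthetic-data generator

Every stage in the package is testable without external downloads
because `simulate_ground_truth()` draws a complete generative model
and records it:

* **Counts.** Gene counts are negative binomial with variance
  $\mu + \phi\mu^2$; the dispersion $\phi$ (default 0.3, a typical
  droplet-scale biological CV of ~0.55 at high expression) degenerates
  to Poisson at 0. The same parameterization is used by the
  single-cell DE stage, so simulator and estimator speak one language.
* **Abundances and depth.** Relative gene abundances are log-normal
  (sdlog 1.8 over 10,000 genes) and the mean cell depth is 20,000
  UMIs. These two values were fixed together so that a cell detects
  roughly 4,000 of 10,000 genes — the study-scale density of a good
  droplet run at ~2,000 cells per condition. Per-cell library-size
  factors are log-normal(0, 0.3); the source study reports no per-cell
  depth model, so this is a generic droplet-like choice.
* **Cell cycle.** Each cell draws one of five phases
  (G1/S, S, G2/M, M, M/G1; default equal fractions). Marker genes
  (default 40 per phase, drawn from above-median abundance because
  real cycle genes are well expressed) are multiplied by a
  cosine-shaped profile: amplitude 4 at the marker's own phase, a
  ~1.9x shoulder at cyclically adjacent phases, 1 elsewhere. This
  mirrors the observed behavior of M-phase genes such as *Cenpf*,
  which peak at M and remain high at G2/M.
* **Treatment response.** A planted immediate-early program: 100
  responder genes with $|\log_2 FC| \sim U(2, 5)$, 85% upregulated,
  drawn from the 50th–90th abundance percentile. The band and the cap
  keep the planted program's share of total library mass near 5%, as
  a real 40-minute early-gene response does; a heavier program would
  distort library-size normalization in a way the real experiment
  does not.
* **Bulk.** Replicate read counts are proportional to the
  phase-averaged gene mean times the treatment effect times transcript
  length (read counting is length-biased; UMI counting is not), scaled
  to $10^7$ reads, with replicate NB dispersion 0.05.
* **ATAC.** A 10 Mb toy chromosome carries 200 non-overlapping genes
  with exon/intron structure. Peaks (default 300) are planted 60% at
  promoters of an "expressed" subset, 20% in first introns, 20%
  intergenic; promoter peak scores increase with the assigned
  expression level so the accessibility–expression association is
  recoverable. Fragment lengths mix a smooth exponential
  subnucleosomal component (55%) with Gaussian mono-, di- and
  tri-nucleosomal components at 200/400/600 bp. Planted footprints
  thin Tn5 insertions inside a 12 bp notch by 90% and embed the SP1
  consensus in the peak sequence.
* **qPCR.** Ct values follow
  $\mathrm{Ct} = \mathrm{baseline} - \log_{1.93}(\mathrm{expression})$
  plus Gaussian technical noise, capped at the 40-cycle assay limit,
  three technical replicates per biological replicate.

Everything planted — phase memberships and multipliers, responder
fold changes, footprint positions, peak classes — is returned as
ground truth, which is what the recovery tests consume.

**What the generator does not emulate:** doublets, ambient RNA,
empty-droplet barcodes, batch effects, realistic genome sequence
beyond the planted motifs, or chromatin changes with treatment. A
green test suite therefore demonstrates that the estimators recover
the effects they model, not that they are robust to every artifact of
real data.

## Bulk differential expression

`moderated_t_test()` is a two-group comparison on
$\log_2(\mathrm{CPM} + 0.5)$ with empirical-Bayes variance shrinkage.
The pooled per-gene variance $s_g^2$ (df $d = n_A + n_B - 2$) is
shrunk toward a prior $s_0^2$ with prior df $d_0$:

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},\qquad
\tilde t_g = \frac{\log_2 FC_g}{\tilde s_g\sqrt{1/n_A + 1/n_B}},$$

with $\tilde t_g$ referred to a t distribution on $d_0 + d$ df. The
prior is fit by the method of moments on $\log s_g^2$ (the excess of
$\mathrm{var}(\log s_g^2)$ over $\psi'(d/2)$ identifies
$\psi'(d_0/2)$, inverted by Newton iteration); a non-positive excess
means no detectable spread and $d_0 = \infty$; a non-finite moment
falls back to $d_0 = 4$. Setting `prior_df = 0` recovers the ordinary
pooled t-test exactly, and the whole stage is cross-checked against
`limma::eBayes` in the test suite.

Two deliberate simplifications and one addition:

* Voom's mean–variance precision weights are **not** reproduced. The
  downstream product of this stage is the fold-change/FDR gene list;
  on the generator's data the unweighted moderated t delivers that
  list with near-nominal error rates, and the simplification keeps
  the stage self-contained.
* The fold-change filter is applied after testing
  (`select_de()`: q < 0.05 and $|\log_2 FC| \ge 2$, with a 16-fold
  tier flag), not folded into a composite null.
* CPM uses TMM effective library sizes (`edgeR::calcNormFactors`,
  `normalize = TRUE`) by default. With a strongly asymmetric induced
  program, plain total-count CPM attributes the compositional shift
  to every unchanged gene; TMM is the standard companion of this
  model family and removes that bias. Pass `normalize = FALSE` to see
  the raw behavior.

`bh_fdr()` delegates to `stats::p.adjust(method = "BH")` (NAs are
excluded from the number of tests and propagated); the test suite
pins it against a brute-force implementation of the step-up
definition on 1,000 random vectors.

## Single-cell stage

Per-cell normalization (`cell_normalize()`) scales each cell to
$10^6$ total counts with **no** length term — UMI counts carry no
length bias — while bulk `tpm()` keeps the length term. The two
scales meet in `pseudobulk_vs_bulk()` on $\log_2(x+1)$, where the
length discrepancy behaves as a near-affine offset and correlation is
meaningful.

`split_half()` randomly halves the cells, averages per-gene TPM per
half, and correlates the halves on $\log_2(\mathrm{mean}+1)$ over
genes detected in the dataset. With ~1,000 cells per half at study
depth this exceeds 0.99; with 4 shallow cells it collapses, which the
tests exercise as a counterexample.

`noise_decomposition()` contrasts each gene's CV across cells with
the Poisson technical floor $1/\sqrt{\mu}$; NB genes sit above the
line with asymptote $\sqrt{\phi}$.

`sseq_de()` is the shrinkage NB exact test:

1. per-gene method-of-moments dispersion on size-factor-normalized
   counts, $\hat\phi_g = \max\{0, (s_g^2-\mu_g)/\mu_g^2\}$;
2. shrinkage $\tilde\phi_g = \delta\xi + (1-\delta)\hat\phi_g$ toward
   a common target with a plug-in weight that, with the target at the
   mean, evaluates to $(G-2)/(G-1)$ — i.e. near-complete shrinkage,
   the regime this method family operates in for droplet data;
3. a two-sided exact NB test of equal group means conditional on the
   gene total: group sums are NB with effective sizes
   $S^2/(\tilde\phi\sum s_c^2)$, the conditional distribution over all
   splits of the total is enumerated, and the p-value sums
   probabilities no larger than the observed split's (method of small
   p-values), with a binomial conditional in the Poisson limit.

Two numerical points. The shrinkage **target** is computed over genes
with mean normalized count of at least 1: at lower means the moment
estimator is strongly upward-biased and would drag the common
dispersion up, making every test conservative. And exact-test
p-values are discrete; calibration statements in the tests are made
on adequately measured genes, where the conditional support is
near-continuous. Correctness of the conditional enumeration is
anchored by an exhaustive brute-force oracle in the test suite.

Size factors are per-cell totals (matching `cell_normalize()`) rather
than median-of-ratios, because droplet matrices are too zero-rich for
ratio medians.

## Cell-cycle scoring and ordering

`phase_scores()` follows the gene-set scoring idea of Macosko et al.:
standardize each gene across cells; average over the set to get a raw
phase score; optionally refine each set to genes correlating with
their own phase score at $r \ge 0.3$ (the published choice; both the
refinement and its threshold are exposed); then z-score each phase
across cells and finally the five scores within each cell (sample-sd
convention throughout). Zero-variance degeneracies are defined as
score 0 with a warning rather than NaN.

`assign_and_order()` assigns the argmax phase (ties to the cyclically
earlier phase) and ranks cells by traversing phases in cyclic order,
ordering within a phase by the contrast (next-phase z minus
previous-phase z, ascending). Any monotone within-phase traversal
would satisfy the cyclic-order invariants; this contrast is the
package's choice and is isolated in one function. The tests verify
cyclic-shift covariance: relabeling phases by a cyclic shift shifts
assignments and preserves within-phase order.

`phase_conditioned_response()` operationalizes the "response is
cell-cycle independent" claim: per gene, (a) Kruskal–Wallis for a
phase effect within each condition and (b) Wilcoxon rank-sum for a
treatment effect within each phase, BH-corrected jointly; strata
under 3 cells are flagged and skipped. One caveat the tests account
for: per-cell TPM normalization couples every gene weakly to the
planted marker program (a cell's markers consume library share), so
"phase-independent" genes carry a ~1% compositional phase signature.
At the study's gene count this is below detection at practical cell
numbers, and the tests assert "overwhelmingly non-significant" rather
than a per-gene universal.

## ATAC analytics

`estimate_periodicity()` histograms fragment lengths at 1 bp,
subtracts a 151 bp running median, and takes the lag (120–350 bp)
maximizing the autocorrelation of the detrended histogram, with a
bin-permutation null for significance. Bins at or below 100 bp are
zeroed first: the subnucleosomal tagmentation spike is too sharp for
the running median to absorb, and its cross-product with the
mononucleosome peak otherwise dominates the lag profile (on the
generator's data it produces a spurious ~150 bp maximum; real ATAC
length distributions have the same feature).

`classify_peaks()` labels each peak at its summit with precedence
promoter > exon > intron > intergenic. The promoter window is
(−1000, +100) bp around the TSS, strand-aware — the source analyses
never define "immediate promoter", so the window is a configurable
argument. Summit-point classification avoids multi-label ambiguity
for peaks spanning feature boundaries.

`tss_profile()` maps fragment midpoints (not Tn5 cut sites — cut-site
offsets belong to alignment-level processing, which is out of scope)
into strand-oriented TSS-relative coordinates, bins at 50 bp over
±3 kb, and normalizes the outermost 10% of bins to mean 1.

`max_peak_per_gene()` assigns each peak to the gene with the nearest
TSS (summit distance; ties to the leftmost TSS for determinism) and
keeps the maximal score per gene, with absent genes scored 0 — the
per-gene accessibility estimate used for the
accessibility–expression landscape.

`detect_notch()` calls transcription-factor footprints: maximal runs
where insertion coverage falls below half a local running baseline,
validated against 20 bp flanks (dip depth ratio ≥ 0.5, width
6–30 bp). Two guards keep calls honest in count noise: the flank mean
must reach half the peak-wide mean (a footprint lives in *otherwise
open* chromatin, not in a peak's sparse tails), and the summed notch
counts must be Poisson-incompatible with the flank rate at
$\alpha = 10^{-4}$. An optional PWM (`pwm_scan()`, log-odds on both
strands, N scoring $-\infty$ unless neutralized) requires a motif
match overlapping the notch, as in the SP1 example that motivates the
operation.

## qPCR units

`ct_to_units()` is the assay's fixed formula
$E = 2500 \times 1.93^{\mathrm{Ct}_{\mathrm{ref}} - \mathrm{Ct}_{\mathrm{gene}}}$
(reference *Rps11*). The constants are treated as fixed assay
calibration. Technical replicates are averaged on the Ct scale before
the transform — the standard convention; averaging on the E scale
would upweight jittered-low Ct values. Genes at the 40-cycle cap are
flagged below detection.

## Problem sizes and design choices in the tests

The acceptance-level checks run the generator at the study's scale:
2,000 cells per condition over 10,000 genes, 4 bulk replicates at
$10^7$ reads, 200,000 fragment lengths, five seeds with medians
reported. Module tests use 1,500-gene/250-cell configurations, which
keep the full suite to a few minutes on one CPU while leaving every
recovery margin wide. Where a bound concerns a rate (false footprint
calls per 100 peaks), the tests evaluate it on enough peaks for the
rate to be measurable.

## Known limitations

* The moderated-t stage is not voom: strongly depth-heterogeneous
  bulk designs would benefit from precision weights it does not have.
* The exact NB test enumerates the conditional support; for a gene
  with a conditional total in the millions this is linear in the
  total and would warrant a normal approximation that is not
  implemented.
* The cell ordering is a discrete five-phase traversal, not a
  continuous pseudotime.
* Footprint detection operates on the package's insertion-count
  coverage; it has not been tuned for externally produced coverage
  tracks with different smoothing.
* Human-to-mouse marker mapping is out of scope; phase sets are
  supplied as gene identifiers matching the expression matrix.
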