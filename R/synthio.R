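#' Simulation configuration for the synthetic multi-omic generator
#'
#' Builds and validates the parameter set shared by all synthetic
#' generators. Defaults emulate the study design the analyses assume:
#' two conditions (vehicle and GnRH), ~2,000 cells per condition over
#' 10,000 genes at a depth giving roughly 4,000 detected genes per cell,
#' four bulk replicates per condition, five cell-cycle phases with
#' multiplicative marker profiles, ~100 treatment-responsive genes, and an
#' ATAC fragment model with ~200 bp nucleosomal periodicity.
#'
#' Counts are negative binomial with variance `mu + phi * mu^2`
#' (dispersion `phi`); `phi = 0` degenerates to Poisson. Per-cell
#' library-size factors are log-normal(0, `libsize_sdlog`).
#'
#' @param n_genes Number of genes.
#' @param n_cells_per_condition Cells simulated per condition.
#' @param n_bulk_replicates_per_condition Bulk replicates per condition.
#' @param mean_depth_per_cell Expected UMI total per cell before the
#'   library-size factor.
#' @param base_mean_meanlog,base_mean_sdlog Log-normal parameters of the
#'   relative gene abundances (normalized to sum to one).
#' @param dispersion Negative-binomial dispersion `phi`, a scalar recycled
#'   over genes or one value per gene. `0` gives Poisson counts.
#' @param phase_fractions Probabilities of the five cell-cycle phases
#'   (G1/S, S, G2/M, M, M/G1); must sum to 1.
#' @param phase_marker_counts Marker genes per phase set.
#' @param phase_effect Multiplicative amplitude (>= 1) of a marker gene at
#'   its own phase; adjacent phases get a cosine shoulder.
#' @param n_response_genes Number of treatment-responsive genes.
#' @param response_log2fc_range Range of |log2 fold change| for responders.
#' @param response_up_fraction Fraction of responders that are upregulated.
#' @param libsize_sdlog Log-normal sd of per-cell library-size factors.
#' @param gene_length_meanlog,gene_length_sdlog Log-normal parameters of
#'   transcript lengths (bp), used for bulk length bias and TPM.
#' @param bulk_depth_per_replicate Expected read total per bulk replicate.
#' @param bulk_dispersion NB dispersion of bulk replicate counts.
#' @param nucleosome_spacing Nucleosomal fragment-length period (bp).
#' @param subnucleosomal_fraction Mixture weight of the short,
#'   subnucleosomal fragment-length component.
#' @param n_atac_genes Genes in the toy ATAC genome.
#' @param genome_length Toy chromosome length (bp).
#' @param n_peaks Number of accessibility peaks.
#' @param peak_class_mix Named fractions of peaks planted at promoters,
#'   in introns, and intergenically; must sum to 1.
#' @param frags_per_peak Expected fragments per peak.
#' @param background_fragment_fraction Extra fragments scattered uniformly
#'   over the genome, as a fraction of the peak fragment total.
#' @param n_footprints Number of peaks carrying a planted TF footprint.
#' @param footprint_width Width (bp) of each planted footprint notch.
#' @param footprint_depth Fraction of insertions removed inside a
#'   footprint (the planted dip depth).
#' @param footprint_motif Motif sequence planted at each footprint (the
#'   SP1 consensus by default).
#' @param seed Integer seed; identical seeds give bit-identical outputs.
#'
#' @return A list of class `sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 500, n_cells_per_condition = 50)
#' cfg$phase_fractions
sim_config <- function(n_genes = 10000,
                       n_cells_per_condition = 2000,
                       n_bulk_replicates_per_condition = 4,
                       mean_depth_per_cell = 20000,
                       base_mean_meanlog = 0,
                       base_mean_sdlog = 1.8,
                       dispersion = 0.3,
                       phase_fractions = rep(0.2, 5),
                       phase_marker_counts = 40,
                       phase_effect = 4,
                       n_response_genes = 100,
                       response_log2fc_range = c(2, 5),
                       response_up_fraction = 0.85,
                       libsize_sdlog = 0.3,
                       gene_length_meanlog = log(2000),
                       gene_length_sdlog = 0.5,
                       bulk_depth_per_replicate = 1e7,
                       bulk_dispersion = 0.05,
                       nucleosome_spacing = 200,
                       subnucleosomal_fraction = 0.55,
                       n_atac_genes = 200,
                       genome_length = 1e7,
                       n_peaks = 300,
                       peak_class_mix = c(promoter = 0.6, intron = 0.2,
                                          intergenic = 0.2),
                       frags_per_peak = 2000,
                       background_fragment_fraction = 0.1,
                       n_footprints = 20,
                       footprint_width = 12,
                       footprint_depth = 0.9,
                       footprint_motif = "GGGGCGGGGC",
                       seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  num_fields <- c("n_genes", "n_cells_per_condition",
                  "n_bulk_replicates_per_condition", "mean_depth_per_cell",
                  "base_mean_meanlog", "base_mean_sdlog", "dispersion",
                  "phase_fractions", "phase_marker_counts", "phase_effect",
                  "n_response_genes", "response_log2fc_range",
                  "response_up_fraction", "libsize_sdlog",
                  "gene_length_meanlog", "gene_length_sdlog",
                  "bulk_depth_per_replicate", "bulk_dispersion",
                  "nucleosome_spacing", "subnucleosomal_fraction",
                  "n_atac_genes", "genome_length", "n_peaks",
                  "peak_class_mix", "frags_per_peak",
                  "background_fragment_fraction", "n_footprints",
                  "footprint_width", "footprint_depth", "seed")
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || any(!is.finite(v)))
      stop("sim_config field '", f, "' must be finite numeric", call. = FALSE)
  }
  counts <- c("n_genes", "n_cells_per_condition",
              "n_bulk_replicates_per_condition", "mean_depth_per_cell",
              "phase_marker_counts", "n_atac_genes", "genome_length",
              "frags_per_peak")
  for (f in counts) {
    if (any(cfg[[f]] <= 0))
      stop("sim_config field '", f, "' must be positive", call. = FALSE)
  }
  if (length(cfg$phase_fractions) != 5L ||
      abs(sum(cfg$phase_fractions) - 1) > 1e-8 ||
      any(cfg$phase_fractions < 0))
    stop("phase_fractions must be 5 non-negative probabilities summing to 1",
         call. = FALSE)
  if (any(cfg$dispersion < 0) || cfg$bulk_dispersion < 0)
    stop("dispersions must be >= 0", call. = FALSE)
  if (cfg$phase_effect < 1)
    stop("phase_effect must be >= 1", call. = FALSE)
  if (abs(sum(cfg$peak_class_mix) - 1) > 1e-8 || any(cfg$peak_class_mix < 0))
    stop("peak_class_mix must be non-negative and sum to 1", call. = FALSE)
  if (cfg$subnucleosomal_fraction < 0 || cfg$subnucleosomal_fraction > 1)
    stop("subnucleosomal_fraction must lie in [0, 1]", call. = FALSE)
  if (cfg$footprint_depth <= 0 || cfg$footprint_depth > 1)
    stop("footprint_depth must lie in (0, 1]", call. = FALSE)
  invisible(cfg)
}

# Cyclic distance between phase indices 1..5.
phase_distance <- function(i, j) {
  d <- abs(i - j)
  pmin(d, 5L - d)
}

# Cosine-shaped multiplier profile: amplitude A at the marker's own phase,
# a shoulder at cyclically adjacent phases, baseline 1 two phases away.
phase_multiplier_profile <- function(amplitude) {
  prof <- matrix(1, 5, 5, dimnames = list(marker = CC_PHASES,
                                          cell = CC_PHASES))
  for (i in 1:5) for (j in 1:5) {
    shape <- max(0, cos(2 * pi * phase_distance(i, j) / 5))
    prof[i, j] <- 1 + (amplitude - 1) * shape
  }
  prof
}

#' Draw the generative ground truth shared by all synthetic assays
#'
#' Samples the gene-level parameters: relative abundances (log-normal),
#' per-gene dispersions, transcript lengths, phase-marker membership with
#' a cosine multiplier profile, and treatment log2 fold changes for a
#' planted responder set. Markers and responders are drawn from genes with
#' above-median base abundance, mirroring the fact that cell-cycle genes
#' and immediate-early genes are well expressed.
#'
#' @param config A [sim_config()].
#' @return A list of class `ground_truth` with elements `gene_ids`, `mu`
#'   (expected counts per cell at unit size factor, phase-averaged
#'   multipliers excluded), `phi`, `gene_length`, `phase_sets` (list of 5
#'   marker id vectors), `multiplier` (genes x 5 matrix), `beta` (log2FC,
#'   0 for non-responders), `responders`, and the config used.
#' @export
simulate_ground_truth <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  G <- config$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(G))

  w <- rlnorm(G, config$base_mean_meanlog, config$base_mean_sdlog)
  w <- w / sum(w)
  mu <- config$mean_depth_per_cell * w
  phi <- rep_len(config$dispersion, G)
  gene_length <- pmax(200, round(rlnorm(G, config$gene_length_meanlog,
                                        config$gene_length_sdlog)))

  # markers come from well-expressed genes (cycle genes are abundant);
  # responders from a mid-high abundance band so the planted program,
  # like a real immediate-early response, barely shifts library
  # composition
  eligible <- which(mu > median(mu))
  n_mark <- rep_len(config$phase_marker_counts, 5L)
  if (length(eligible) < sum(n_mark))
    stop("not enough above-median genes for phase markers", call. = FALSE)
  picks <- sample(eligible, sum(n_mark))
  phase_sets <- vector("list", 5L)
  names(phase_sets) <- CC_PHASES
  at <- 0L
  marker_phase <- integer(G)   # 0 = not a marker
  for (k in 1:5) {
    idx <- picks[(at + 1L):(at + n_mark[k])]
    phase_sets[[k]] <- gene_ids[idx]
    marker_phase[idx] <- k
    at <- at + n_mark[k]
  }
  band <- quantile(mu, c(0.5, 0.9))
  resp_pool <- setdiff(which(mu >= band[1] & mu <= band[2]), picks)
  if (length(resp_pool) < config$n_response_genes)
    stop("not enough mid-abundance genes for responders", call. = FALSE)
  responders <- sample(resp_pool, config$n_response_genes)

  prof <- phase_multiplier_profile(config$phase_effect)
  multiplier <- matrix(1, G, 5, dimnames = list(gene_ids, CC_PHASES))
  is_marker <- marker_phase > 0L
  multiplier[is_marker, ] <- prof[marker_phase[is_marker], , drop = FALSE]

  beta <- numeric(G)
  if (config$n_response_genes > 0) {
    mag <- runif(config$n_response_genes, config$response_log2fc_range[1],
                 config$response_log2fc_range[2])
    sign <- ifelse(runif(config$n_response_genes) <
                     config$response_up_fraction, 1, -1)
    beta[responders] <- sign * mag
  }

  structure(list(gene_ids = gene_ids, mu = mu, phi = phi,
                 gene_length = gene_length, phase_sets = phase_sets,
                 multiplier = multiplier, beta = beta,
                 responders = gene_ids[responders], config = config),
            class = "ground_truth")
}

# NB draws with per-gene dispersion, vectorized over a genes x cells mean
# matrix; phi = 0 rows are Poisson.
rnbinom_matrix <- function(lambda, phi) {
  G <- nrow(lambda); C <- ncol(lambda)
  out <- matrix(0L, G, C, dimnames = dimnames(lambda))
  pois <- phi == 0
  if (any(!pois)) {
    sz <- 1 / phi[!pois]
    out[!pois, ] <- rnbinom(sum(!pois) * C, mu = as.vector(lambda[!pois, ,
                                                                  drop = FALSE]),
                            size = sz)
  }
  if (any(pois)) {
    out[pois, ] <- rpois(sum(pois) * C,
                         as.vector(lambda[pois, , drop = FALSE]))
  }
  storage.mode(out) <- "integer"
  out
}

#' Simulate one condition's droplet single-cell count matrix
#'
#' Each cell draws a phase from `phase_fractions` and a log-normal
#' library-size factor; expected counts are
#' `s_c * mu_g * m[g, phase_c] * 2^(beta_g * treated)` and counts are
#' negative binomial with per-gene dispersion (Poisson when zero).
#'
#' @param truth A [simulate_ground_truth()] result.
#' @param treated Logical; apply the treatment log2 fold changes?
#' @param seed Integer seed for the per-cell draws.
#' @param label Prefix for cell barcodes.
#' @return A list with `counts` (sparse genes x cells dgCMatrix),
#'   `phase` (factor, true phase per cell), `size_factor`.
#' @export
simulate_condition <- function(truth, treated = FALSE, seed = 1L,
                               label = if (treated) "gnrh" else "vehicle") {
  stopifnot(inherits(truth, "ground_truth"))
  cfg <- truth$config
  set.seed(seed)
  C <- cfg$n_cells_per_condition
  phase <- sample.int(5L, C, replace = TRUE, prob = cfg$phase_fractions)
  s <- rlnorm(C, 0, cfg$libsize_sdlog)
  lambda <- outer(truth$mu, s)              # genes x cells
  lambda <- lambda * truth$multiplier[, phase, drop = FALSE]
  if (treated) lambda <- lambda * 2^truth$beta
  counts <- rnbinom_matrix(lambda, truth$phi)
  dimnames(counts) <- list(truth$gene_ids,
                           sprintf("%s_cell%04d", label, seq_len(C)))
  list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                            "CsparseMatrix"),
       phase = factor(CC_PHASES[phase], levels = CC_PHASES),
       size_factor = s)
}

#' Simulate single-cell UMI count matrices for both conditions
#'
#' Draws the shared ground truth, then one droplet count matrix per
#' condition (vehicle and treated). Per-condition cell draws use seeds
#' derived from `config$seed` so the whole object is reproducible.
#'
#' @param config A [sim_config()].
#' @return A list with sparse matrices `vehicle` and `gnrh`, per-cell
#'   truth (`phase_vehicle`, `phase_gnrh`, `size_factor_vehicle`,
#'   `size_factor_gnrh`) and the shared `truth`.
#' @export
#' @examples
#' sim <- simulate_sc_counts(sim_config(n_genes = 200,
#'                                      n_cells_per_condition = 30))
#' dim(sim$vehicle)
simulate_sc_counts <- function(config) {
  truth <- simulate_ground_truth(config)
  veh <- simulate_condition(truth, treated = FALSE,
                            seed = config$seed + 1000L)
  trt <- simulate_condition(truth, treated = TRUE,
                            seed = config$seed + 2000L)
  list(vehicle = veh$counts, gnrh = trt$counts,
       phase_vehicle = veh$phase, phase_gnrh = trt$phase,
       size_factor_vehicle = veh$size_factor,
       size_factor_gnrh = trt$size_factor,
       truth = truth)
}

#' Simulate bulk RNA-seq replicate counts from shared ground truth
#'
#' Expected replicate counts are proportional to the phase-averaged gene
#' mean times the treatment effect times transcript length (read counts
#' carry length bias, unlike UMI counts), scaled to
#' `bulk_depth_per_replicate`, with NB replicate noise
#' (`bulk_dispersion`). Gene identifiers are shared with the single-cell
#' output.
#'
#' @param config A [sim_config()]; `n_bulk_replicates_per_condition < 2`
#'   triggers a warning (the DE stage needs >= 2).
#' @param truth Optional [simulate_ground_truth()]; drawn from `config`
#'   when omitted.
#' @param seed Seed for the replicate draws (default derived from the
#'   config seed).
#' @return A list with `counts` (genes x samples integer matrix),
#'   `groups` (factor vehicle/gnrh), `gene_length`, `truth`.
#' @export
simulate_bulk_counts <- function(config, truth = NULL, seed = NULL) {
  if (is.null(truth)) truth <- simulate_ground_truth(config)
  cfg <- truth$config
  if (cfg$bulk_depth_per_replicate <= 0)
    stop("bulk depth must be positive: an all-zero matrix is not usable",
         call. = FALSE)
  n_rep <- cfg$n_bulk_replicates_per_condition
  if (n_rep < 2)
    warning("fewer than 2 bulk replicates per condition; ",
            "differential expression requires >= 2")
  if (is.null(seed)) seed <- cfg$seed + 3000L
  set.seed(seed)

  phase_avg <- as.vector(truth$multiplier %*% cfg$phase_fractions)
  base <- truth$mu * phase_avg * truth$gene_length
  mk <- function(treated) {
    m <- base * if (treated) 2^truth$beta else 1
    m <- m / sum(m) * cfg$bulk_depth_per_replicate
    lam <- matrix(rep(m, n_rep), ncol = n_rep)
    rnbinom_matrix(lam, rep(cfg$bulk_dispersion, length(m)))
  }
  counts <- cbind(mk(FALSE), mk(TRUE))
  dimnames(counts) <- list(truth$gene_ids,
                           c(sprintf("vehicle_rep%d", seq_len(n_rep)),
                             sprintf("gnrh_rep%d", seq_len(n_rep))))
  list(counts = counts,
       groups = factor(rep(c("vehicle", "gnrh"), each = n_rep),
                       levels = c("vehicle", "gnrh")),
       gene_length = setNames(truth$gene_length, truth$gene_ids),
       truth = truth)
}

#' Sample fragment lengths from the nucleosomal mixture model
#'
#' Lengths are a mixture of a short subnucleosomal component (gamma,
#' mode near 60-80 bp) and mono-, di- and tri-nucleosomal Gaussian
#' components centered at 1x, 2x and 3x `nucleosome_spacing` with weights
#' 0.6/0.3/0.1 of the nucleosomal mass. Lengths are clamped to
#' [10, 1000] bp.
#'
#' @param n Number of lengths.
#' @param config A [sim_config()] (uses `nucleosome_spacing` and
#'   `subnucleosomal_fraction`).
#' @return Integer vector of fragment lengths (bp).
#' @export
simulate_fragment_lengths <- function(n, config = sim_config()) {
  validate_sim_config(config)
  sp <- config$nucleosome_spacing
  comp_p <- c(config$subnucleosomal_fraction,
              (1 - config$subnucleosomal_fraction) * c(0.6, 0.3, 0.1))
  comp <- sample.int(4L, n, replace = TRUE, prob = comp_p)
  len <- numeric(n)
  i <- comp == 1L
  # smooth exponential decay, as in real tagmentation libraries; no
  # bump that could masquerade as a period
  len[i] <- 30 + stats::rexp(sum(i), rate = 1 / 50)
  for (k in 2:4) {
    i <- comp == k
    len[i] <- rnorm(sum(i), (k - 1) * sp, 10 + 5 * (k - 1))
  }
  as.integer(pmin(1000, pmax(10, round(len))))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Non-overlapping toy genes laid left to right with random gaps; exons
# partition a prefix of the span (first exon starts at the span start).
place_toy_genes <- function(cfg) {
  n <- cfg$n_atac_genes
  starts <- integer(n); ends <- integer(n)
  pos <- 10000L
  glen <- as.integer(round(runif(n, 2000, 15000)))
  gaps <- as.integer(round(runif(n, 8000, 30000)))
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + glen[i] - 1L
    pos <- ends[i] + gaps[i]
  }
  if (pos >= cfg$genome_length)
    stop("toy genome too short for requested gene count", call. = FALSE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gene_id <- sprintf("tgene%04d", seq_len(n))
  gr <- GenomicRanges::GRanges("chrT", IRanges::IRanges(starts, ends),
                               strand = strand, gene_id = gene_id)
  exons <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(2:6, 1)
    # alternating exon/intron blocks inside the span
    cuts <- sort(sample(seq(starts[i] + 200L, ends[i] - 200L, by = 50L),
                        2L * k - 2L))
    bnd <- c(starts[i], cuts, ends[i])
    ex_start <- bnd[seq(1, length(bnd), by = 2)]
    ex_end <- bnd[seq(2, length(bnd), by = 2)]
    exons[[i]] <- IRanges::IRanges(ex_start, ex_end)
  }
  exons_gr <- GenomicRanges::GRangesList(lapply(seq_len(n), function(i)
    GenomicRanges::GRanges("chrT", exons[[i]], strand = strand[i])))
  names(exons_gr) <- gene_id
  list(genes = gr, exons = exons_gr)
}

#' Simulate a toy ATAC-seq experiment
#'
#' Builds a single-chromosome toy genome of non-overlapping genes, plants
#' accessibility peaks at promoters of an "expressed" gene subset, inside
#' introns, and at intergenic sites (mix set by `peak_class_mix`), and
#' draws paired-end style fragments whose midpoints concentrate in peaks
#' and whose lengths follow [simulate_fragment_lengths()]. Peak scores
#' increase with the expression level assigned to the peak's gene, so
#' accessibility-expression integration is recoverable. A subset of
#' promoter peaks carries a planted transcription-factor footprint: Tn5
#' insertions inside the notch are thinned by `footprint_depth` and the
#' footprint motif is embedded in the peak sequence.
#'
#' @param config A [sim_config()].
#' @return A list with `genes` (list of `genes` GRanges and `exons`
#'   GRangesList), `peaks` (GRanges with `score`, `summit_offset`,
#'   `peak_id`, `class_planted`), `fragments` (GRanges), `peak_seqs`
#'   (named character), and `truth` (expressed set, per-gene expression
#'   level, footprint table).
#' @export
simulate_atac <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed + 4000L)
  models <- place_toy_genes(config)
  genes <- models$genes
  n_gene <- length(genes)

  n_class <- round(config$n_peaks * config$peak_class_mix)
  n_class[1] <- config$n_peaks - sum(n_class[-1])
  expressed <- sort(sample.int(n_gene, min(n_gene, n_class[["promoter"]])))
  expr_level <- setNames(numeric(n_gene), genes$gene_id)
  expr_level[expressed] <- rlnorm(length(expressed), 3, 1)

  tss <- ifelse(as.character(GenomicRanges::strand(genes)) == "+",
                GenomicRanges::start(genes), GenomicRanges::end(genes))

  width <- as.integer(round(runif(config$n_peaks, 400, 800)))
  center <- integer(config$n_peaks)
  planted <- character(config$n_peaks)
  score <- numeric(config$n_peaks)
  # promoter peaks: centered ~ on the TSS of expressed genes
  np <- length(expressed)
  center[seq_len(np)] <- tss[expressed] +
    as.integer(round(runif(np, -50, 50)))
  planted[seq_len(np)] <- "promoter"
  score[seq_len(np)] <- pmax(5, 40 + 15 * scale(log(expr_level[expressed]))[, 1] +
                               rnorm(np, 0, 4))
  # intronic peaks: inside a random gene's first intron
  ni <- n_class[["intron"]]
  if (ni > 0) {
    host <- sample.int(n_gene, ni, replace = TRUE)
    for (j in seq_len(ni)) {
      ex <- models$exons[[host[j]]]
      # midpoint between first and second exon
      intron_start <- GenomicRanges::end(ex)[1] + 1L
      intron_end <- GenomicRanges::start(ex)[2] - 1L
      center[np + j] <- as.integer((intron_start + intron_end) %/% 2L)
    }
    planted[np + seq_len(ni)] <- "intron"
    score[np + seq_len(ni)] <- pmax(2, rnorm(ni, 20, 6))
  }
  # intergenic peaks: in gaps between gene bodies
  ng <- config$n_peaks - np - ni
  if (ng > 0) {
    gaps <- GenomicRanges::gaps(GenomicRanges::reduce(
      GenomicRanges::granges(genes), ignore.strand = TRUE))
    gaps <- gaps[GenomicRanges::width(gaps) > 5000 &
                   as.character(GenomicRanges::strand(gaps)) == "*"]
    pick <- sample(seq_along(gaps), ng, replace = TRUE)
    center[np + ni + seq_len(ng)] <-
      as.integer(GenomicRanges::start(gaps)[pick] +
                   round(GenomicRanges::width(gaps)[pick] *
                           runif(ng, 0.3, 0.7)))
    planted[np + ni + seq_len(ng)] <- "intergenic"
    score[np + ni + seq_len(ng)] <- pmax(2, rnorm(ng, 15, 5))
  }

  peak_start <- center - width %/% 2L
  peak_end <- peak_start + width - 1L
  peaks <- GenomicRanges::GRanges("chrT",
                                  IRanges::IRanges(peak_start, peak_end))
  peaks$score <- round(score, 3)
  peaks$summit_offset <- center - peak_start
  peaks$peak_id <- sprintf("peak%04d", seq_len(config$n_peaks))
  peaks$class_planted <- planted

  # planted footprints in the strongest promoter peaks
  nf <- min(config$n_footprints, np)
  fp_peaks <- order(score[seq_len(np)], decreasing = TRUE)[seq_len(nf)]
  fp_offset <- peaks$summit_offset[fp_peaks] - 30L
  footprints <- data.frame(peak_id = peaks$peak_id[fp_peaks],
                           peak_index = fp_peaks,
                           notch_start = fp_offset,
                           notch_end = fp_offset + config$footprint_width - 1L,
                           motif = config$footprint_motif,
                           stringsAsFactors = FALSE)

  # peak sequences, motif planted at the notch
  peak_seqs <- vapply(width, random_dna, character(1))
  names(peak_seqs) <- peaks$peak_id
  motif <- config$footprint_motif
  for (j in seq_len(nf)) {
    s <- peak_seqs[[fp_peaks[j]]]
    at <- fp_offset[j] + 1L
    substr(s, at, at + nchar(motif) - 1L) <- motif
    peak_seqs[[fp_peaks[j]]] <- s
  }

  # fragments: midpoints gaussian around summits; insertions (fragment
  # ends) inside a footprint notch are thinned by footprint_depth
  n_frag <- rpois(config$n_peaks, config$frags_per_peak)
  frag_list <- vector("list", config$n_peaks + 1L)
  notch_abs <- cbind(peak_start[footprints$peak_index] + footprints$notch_start,
                     peak_start[footprints$peak_index] + footprints$notch_end)
  fp_of_peak <- match(seq_len(config$n_peaks), footprints$peak_index)
  for (i in seq_len(config$n_peaks)) {
    m <- n_frag[i]
    if (m == 0) { frag_list[[i]] <- NULL; next }
    mid <- as.integer(round(rnorm(m, center[i], width[i] / 6)))
    len <- simulate_fragment_lengths(m, config)
    fs <- mid - len %/% 2L
    fe <- fs + len - 1L
    if (!is.na(fp_of_peak[i])) {
      ns <- notch_abs[fp_of_peak[i], 1]; ne <- notch_abs[fp_of_peak[i], 2]
      hit <- (fs >= ns & fs <= ne) | (fe >= ns & fe <= ne)
      drop <- hit & (runif(m) < config$footprint_depth)
      fs <- fs[!drop]; fe <- fe[!drop]
    }
    keep <- fs >= 1L & fe <= config$genome_length
    frag_list[[i]] <- IRanges::IRanges(fs[keep], fe[keep])
  }
  n_bg <- rpois(1, config$background_fragment_fraction * sum(n_frag))
  bg_mid <- as.integer(round(runif(n_bg, 1000, config$genome_length - 1000)))
  bg_len <- simulate_fragment_lengths(n_bg, config)
  frag_list[[config$n_peaks + 1L]] <-
    IRanges::IRanges(bg_mid - bg_len %/% 2L,
                     bg_mid - bg_len %/% 2L + bg_len - 1L)
  all_rng <- do.call(c, frag_list[!vapply(frag_list, is.null, logical(1))])
  fragments <- GenomicRanges::GRanges("chrT", all_rng)

  list(genes = models, peaks = peaks, fragments = fragments,
       peak_seqs = peak_seqs,
       truth = list(expressed = genes$gene_id[expressed],
                    expr_level = expr_level, footprints = footprints,
                    config = config))
}

#' Simulate a qPCR Ct table from ground truth
#'
#' Ct values follow `baseline - log(expression, 1.93) + noise`: the assay
#' efficiency implied by the arbitrary-unit formula used downstream.
#' The reference gene is assigned a fixed high expression; genes with zero
#' expression are capped at the 40-cycle limit. Three technical replicates
#' per biological replicate by default.
#'
#' @param truth A [simulate_ground_truth()] result.
#' @param genes Gene ids to assay (default: first 8 responders).
#' @param reference_gene Reference gene name (added to the table).
#' @param n_biological Biological replicates per condition.
#' @param n_technical Technical replicates per well.
#' @param noise_sd Gaussian technical noise on Ct (cycles).
#' @param bio_sdlog Log-normal biological variability of expression.
#' @param baseline Ct of a gene at expression 1 (arbitrary origin; it
#'   cancels in [ct_to_units()]).
#' @param seed Integer seed.
#' @return data.frame with columns sample, condition, gene, replicate, ct.
#' @export
simulate_qpcr_ct <- function(truth, genes = NULL,
                             reference_gene = "Rps11",
                             n_biological = 4, n_technical = 3,
                             noise_sd = 0.2, bio_sdlog = 0.1,
                             baseline = 32, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  if (n_technical < 1) stop("need >= 1 technical replicate", call. = FALSE)
  set.seed(seed)
  cfg <- truth$config
  if (is.null(genes)) genes <- head(truth$responders, 8)
  missing <- setdiff(genes, truth$gene_ids)
  if (length(missing))
    stop("genes not present in ground truth: ",
         paste(missing, collapse = ", "), call. = FALSE)
  phase_avg <- as.vector(truth$multiplier %*% cfg$phase_fractions)
  base_expr <- setNames(truth$mu * phase_avg, truth$gene_ids)
  ref_expr <- as.numeric(quantile(base_expr, 0.9))

  rows <- list()
  for (cond in c("vehicle", "gnrh")) {
    for (b in seq_len(n_biological)) {
      bio <- rlnorm(1, 0, bio_sdlog)
      samp <- sprintf("%s_bio%d", cond, b)
      for (g in c(reference_gene, genes)) {
        if (g == reference_gene) {
          e <- ref_expr * bio
        } else {
          fc <- if (cond == "gnrh") 2^truth$beta[match(g, truth$gene_ids)] else 1
          e <- base_expr[[g]] * fc * bio
        }
        ct_true <- if (e <= 0) 40 else min(40, baseline - log(e, base = 1.93))
        ct <- pmin(40, ct_true + rnorm(n_technical, 0, noise_sd))
        rows[[length(rows) + 1L]] <-
          data.frame(sample = samp, condition = cond, gene = g,
                     replicate = seq_len(n_technical), ct = ct,
                     stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
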