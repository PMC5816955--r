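test_that("periodicity estimator is exact on constructed delta peaks", {
  lengths <- rep(c(200L, 400L, 600L), times = c(5000, 2500, 1000))
  res <- estimate_periodicity(lengths, seed = 1)
  expect_equal(res$period, 200L)
  expect_lt(res$p_value, 0.05)
})

test_that("uniform fragment lengths show no significant period", {
  set.seed(4)
  res <- estimate_periodicity(sample(50:700, 5e4, replace = TRUE),
                              seed = 1)
  expect_gt(res$p_value, 0.05)
})

test_that("periodicity is invariant to fragment order and subsampling", {
  cfg <- sim_config(seed = 14)
  len <- simulate_fragment_lengths(1e5, cfg)
  base <- estimate_periodicity(len, seed = 1)$period
  shuf <- estimate_periodicity(rev(len), seed = 1)$period
  expect_equal(shuf, base)
  set.seed(2)
  subs <- sapply(1:10, function(i)
    estimate_periodicity(sample(len, 3e4), seed = i)$period)
  expect_true(all(abs(subs - base) <= 10))
  expect_error(estimate_periodicity(len[1:500]), ">= 1000")
})

test_that("peak classification follows the precedence rule at the summit", {
  genes <- list(
    genes = GenomicRanges::GRanges("chrT",
                                   IRanges::IRanges(1000, 5000),
                                   strand = "+", gene_id = "g1"),
    exons = GenomicRanges::GRangesList(
      g1 = GenomicRanges::GRanges("chrT",
                                  IRanges::IRanges(c(1000, 3000),
                                                   c(1500, 3500)),
                                  strand = "+")))
  mk_peak <- function(summit) {
    p <- GenomicRanges::GRanges("chrT",
                                IRanges::IRanges(summit - 100,
                                                 summit + 100))
    p$summit_offset <- 101L
    p$score <- 10
    p
  }
  cls <- function(summit)
    as.character(classify_peaks(mk_peak(summit), genes)$class)
  expect_equal(cls(950), "promoter")     # within (-1000, +100) of TSS
  expect_equal(cls(1050), "promoter")    # downstream part of the window
  expect_equal(cls(1300), "exon")
  expect_equal(cls(2000), "intron")      # inside span, outside exons
  expect_equal(cls(8000), "intergenic")
  expect_warning(
    out <- classify_peaks(
      GenomicRanges::GRanges("chrX", IRanges::IRanges(5, 10),
                             summit_offset = 3L, score = 1),
      genes),
    "absent")
  expect_equal(as.character(out$class), "intergenic")
})

test_that("classification fractions sum to one and recover the planted mix", {
  cfg <- small_cfg(seed = 26)
  atac <- simulate_atac(cfg)
  out <- classify_peaks(atac$peaks, atac$genes)
  expect_equal(sum(out$fractions), 1)
  planted <- prop.table(table(atac$peaks$class_planted))
  expect_lt(abs(out$fractions[["promoter"]] - planted[["promoter"]]),
            0.05)
  expect_lt(abs((out$fractions[["promoter"]] + out$fractions[["intron"]]) -
                  (planted[["promoter"]] + planted[["intron"]])), 0.05)
})

test_that("top peak selection is score-ordered with deterministic ties", {
  p <- GenomicRanges::GRanges("chrT",
                              IRanges::IRanges(c(300, 100, 200),
                                               c(350, 150, 250)))
  p$score <- c(5, 9, 1)
  p$summit_offset <- 25L
  out <- top_peaks(p, 2)
  expect_equal(out$score, c(9, 5))
  p$score <- c(7, 7, 7)
  out2 <- top_peaks(p, 2)
  expect_equal(GenomicRanges::start(out2), c(100, 200))
  expect_equal(length(top_peaks(p, 0)), 0L)
  expect_warning(out3 <- top_peaks(p, 10), "available")
  expect_equal(length(out3), 3L)
})

test_that("TSS profile orients minus-strand genes and finds central enrichment", {
  genes <- list(genes = GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(10000, 50000), c(15000, 55000)),
    strand = c("+", "-"), gene_id = c("gp", "gm")))
  # one fragment 100 bp 3' of the minus-strand TSS (genomically below it)
  tssm <- 55000
  fr <- GenomicRanges::GRanges("chrT",
                               IRanges::IRanges(tssm - 125, tssm - 76))
  prof <- tss_profile(fr, genes)
  hit <- prof$bin_center[prof$density > 0]
  expect_true(hit > 0 && abs(hit - 100) <= 50)

  # fragments centered exactly on each TSS pile into the central bins
  frc <- GenomicRanges::GRanges("chrT",
                                IRanges::IRanges(c(10000 - 50, 55000 - 50),
                                                 c(10000 + 49, 55000 + 49)))
  prof2 <- tss_profile(frc, genes)
  expect_equal(abs(prof2$bin_center[which.max(prof2$density)]), 25)

  cfg <- small_cfg(seed = 27)
  atac <- simulate_atac(cfg)
  prof3 <- tss_profile(atac$fragments, atac$genes)
  expect_gt(attr(prof3, "enrichment"), 2)
})

test_that("max peak score per gene assigns every peak exactly once", {
  genes <- list(genes = GenomicRanges::GRanges(
    "chrT", IRanges::IRanges(c(1000, 9000), c(2000, 9900)),
    strand = "+", gene_id = c("g1", "g2")))
  p <- GenomicRanges::GRanges("chrT",
                              IRanges::IRanges(c(900, 1500, 8500),
                                               c(1100, 1700, 8700)))
  p$summit_offset <- c(101L, 101L, 101L)
  p$score <- c(50, 80, 30)
  out <- max_peak_per_gene(p, genes)
  expect_equal(out$score[out$gene_id == "g1"], 80)
  expect_equal(out$score[out$gene_id == "g2"], 30)
  expect_equal(sum(out$n_peaks), length(p))
  # a gene with no peak anywhere near still appears, scored 0
  genes3 <- list(genes = suppressWarnings(
    c(genes$genes,
      GenomicRanges::GRanges("chr9", IRanges::IRanges(1, 10),
                             strand = "+", gene_id = "lonely"))))
  out3 <- max_peak_per_gene(p, genes3)
  expect_equal(out3$score[out3$gene_id == "lonely"], 0)
})

test_that("accessibility integrates with expression on planted data", {
  cfg <- small_cfg(seed = 28)
  atac <- simulate_atac(cfg)
  best <- max_peak_per_gene(atac$peaks, atac$genes)
  expr <- atac$truth$expr_level[best$gene_id]
  expressed <- expr > 0
  expect_gt(median(best$score[expressed]),
            median(best$score[!expressed]))
  ct <- suppressWarnings(
    cor.test(best$score, expr, method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("PWM scan agrees with the brute-force enumeration oracle", {
  set.seed(12)
  seqn <- paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE),
                collapse = "")
  pwm <- pwm_from_consensus("GGCGGG")
  for (thr in c(2, 4, max(apply(pwm, 2, max)) * 6 / 6)) {
    mine <- pwm_scan(seqn, pwm, thr)
    oracle <- oracle_pwm_scan(seqn, pwm, thr)
    oracle <- oracle[order(oracle$pos, oracle$strand), ]
    expect_equal(mine$pos, oracle$pos)
    expect_equal(mine$strand, oracle$strand)
    expect_equal(mine$score, oracle$score, tolerance = 1e-10)
  }
})

test_that("PWM scan finds planted words exactly at the stringent threshold", {
  word <- "GGGGCGGGGC"
  set.seed(5)
  bg <- sample(c("A", "T"), 500, replace = TRUE)  # no G/C background
  seqn <- paste(bg, collapse = "")
  substr(seqn, 101, 110) <- word
  substr(seqn, 301, 310) <- word
  pwm <- pwm_from_consensus(word)
  thr <- sum(apply(pwm, 2, max))
  hits <- pwm_scan(seqn, pwm, thr)
  expect_equal(hits$pos[hits$strand == "+"], c(101L, 301L))
})

test_that("palindromic motifs match both strands at the same positions", {
  pwm <- pwm_from_consensus("GAATTC")   # EcoRI palindrome
  set.seed(8)
  seqn <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
  hits <- pwm_scan(seqn, pwm, 4)
  fwd <- hits$pos[hits$strand == "+"]
  rev <- hits$pos[hits$strand == "-"]
  expect_setequal(fwd, rev)
})

test_that("notch detection matches direct arithmetic on constructed coverage", {
  flat <- rep(30, 200)
  expect_equal(nrow(detect_notch(flat)), 0L)

  notched <- flat
  notched[100:111] <- 5
  out <- detect_notch(notched)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 100L)
  expect_equal(out$width, 12L)
  expect_equal(out$dip_ratio, 1 - 5 / 30, tolerance = 1e-12)

  # too short a peak yields no calls rather than an error
  expect_equal(nrow(detect_notch(notched[1:30])), 0L)
})

test_that("motif confirmation gates notch calls", {
  cov <- rep(30, 200)
  cov[100:111] <- 3
  seqn <- paste(rep("A", 200), collapse = "")
  pwm <- pwm_from_consensus("GGGGCGGGGC")
  expect_equal(nrow(detect_notch(cov, pwm = pwm, sequence = seqn)), 0L)
  substr(seqn, 101, 110) <- "GGGGCGGGGC"
  out <- detect_notch(cov, pwm = pwm, sequence = seqn)
  expect_equal(nrow(out), 1L)
  expect_equal(out$motif_pos, 101L)
  expect_error(detect_notch(cov, pwm = pwm), "sequence required")
})

test_that("planted footprints are recalled with few false calls", {
  # full peak complement: a 1-per-100-peaks false-call bound needs a
  # few hundred unplanted peaks to be measurable
  cfg <- sim_config(seed = 29)
  atac <- simulate_atac(cfg)
  fp <- atac$truth$footprints
  found <- 0L
  for (i in seq_len(nrow(fp))) {
    pk <- atac$peaks[fp$peak_index[i]]
    cov <- peak_coverage(atac$fragments, pk)
    calls <- detect_notch(cov)
    hit <- any(calls$start <= fp$notch_end[i] + 3 &
                 calls$end >= fp$notch_start[i] - 3)
    found <- found + hit
  }
  expect_gte(found / nrow(fp), 0.9)

  unplanted <- setdiff(seq_along(atac$peaks), fp$peak_index)
  false_calls <- sum(vapply(unplanted, function(i) {
    nrow(detect_notch(peak_coverage(atac$fragments, atac$peaks[i])))
  }, numeric(1)))
  expect_lte(false_calls, ceiling(length(unplanted) / 100))
})
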