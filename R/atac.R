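#' Dominant fragment-length periodicity
#'
#' Estimates the nucleosomal period of an ATAC fragment-length
#' distribution: lengths are histogrammed at 1-bp bins over 0-1000 bp,
#' detrended by subtracting a 151-bp running median, and the dominant
#' period is the lag maximizing the autocorrelation of the detrended
#' histogram over `lag_range`. The steep sub-nucleosomal tagmentation
#' spike below `min_length` is excluded from the autocorrelation: it is
#' too sharp for the running median to absorb and its cross-product with
#' the mononucleosome peak would otherwise dominate the lag profile.
#' Significance is assessed against a permutation null that shuffles the
#' detrended histogram bins.
#'
#' @param lengths Integer fragment lengths (bp); at least 1,000 for a
#'   stable estimate.
#' @param lag_range Lag search window in bp (default 120-350).
#' @param min_length Histogram bins at or below this length (bp) are
#'   zeroed before the autocorrelation (default 100).
#' @param n_perm Permutations for the null (default 200).
#' @param seed Optional seed for the permutations.
#' @return A list with `period` (bp), `acf` (autocorrelation at the
#'   period), `p_value`, and the `acf_profile` over all searched lags.
#' @export
estimate_periodicity <- function(lengths, lag_range = c(120L, 350L),
                                 min_length = 100L, n_perm = 200L,
                                 seed = NULL) {
  lengths <- lengths[is.finite(lengths)]
  if (length(lengths) < 1000)
    stop("need >= 1000 fragments for a stable periodicity estimate",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  h <- tabulate(pmin(1000L, pmax(1L, as.integer(round(lengths)))),
                nbins = 1000L)
  x <- h - runmed(h, 151, endrule = "median")
  if (min_length > 0) x[seq_len(min(min_length, length(x)))] <- 0
  lags <- seq.int(lag_range[1], lag_range[2])
  n <- length(x)
  denom <- sum(x^2)
  if (denom == 0) return(list(period = NA_integer_, acf = NA_real_,
                              p_value = 1, acf_profile = NULL))
  ac <- function(v) vapply(lags, function(l)
    sum(v[1:(n - l)] * v[(l + 1):n]) / denom, numeric(1))
  prof <- ac(x)
  best <- which.max(prof)
  null_max <- vapply(seq_len(n_perm), function(i) max(ac(sample(x))),
                     numeric(1))
  p <- (1 + sum(null_max >= prof[best])) / (1 + n_perm)
  list(period = lags[best], acf = prof[best], p_value = p,
       acf_profile = setNames(prof, lags))
}

# Summit positions of peaks as width-1 GRanges (midpoint fallback).
peak_summits <- function(peaks) {
  off <- peaks$summit_offset
  if (is.null(off)) off <- GenomicRanges::width(peaks) %/% 2L + 1L
  pos <- GenomicRanges::start(peaks) + off - 1L
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
                         IRanges::IRanges(pos, pos))
}

# TSS of each gene as width-1 GRanges, strand-aware.
gene_tss <- function(genes) {
  pos <- ifelse(as.character(GenomicRanges::strand(genes)) == "-",
                GenomicRanges::end(genes), GenomicRanges::start(genes))
  GenomicRanges::GRanges(GenomeInfoDb::seqnames(genes),
                         IRanges::IRanges(pos, pos),
                         strand = GenomicRanges::strand(genes),
                         gene_id = genes$gene_id)
}

#' Classify peaks by genomic feature
#'
#' Assigns each peak, at its summit (midpoint if no summit is recorded),
#' one class with precedence promoter > exon > intron > intergenic. The
#' promoter window is strand-aware around the TSS (default -1000 to +100
#' bp). Peaks on chromosomes absent from the annotation are intergenic
#' with a warning.
#'
#' @param peaks GRanges of peaks (optionally with `summit_offset`).
#' @param genes A gene-model list (`genes` GRanges + `exons`
#'   GRangesList), as from [read_gtf()] or [simulate_atac()].
#' @param promoter_window `c(upstream, downstream)` in bp relative to the
#'   TSS; upstream is negative.
#' @return A list with `class` (factor per peak) and `fractions` (named
#'   fractions over the four classes, summing to 1).
#' @export
classify_peaks <- function(peaks, genes,
                           promoter_window = c(-1000L, 100L)) {
  classes <- c("promoter", "exon", "intron", "intergenic")
  pts <- peak_summits(peaks)
  gr <- genes$genes
  missing_chr <- !(as.character(GenomeInfoDb::seqnames(pts)) %in%
                     as.character(unique(GenomeInfoDb::seqnames(gr))))
  if (any(missing_chr))
    warning(sum(missing_chr),
            " peak(s) on chromosomes absent from the annotation")
  prom <- GenomicRanges::promoters(gene_tss(gr),
                                   upstream = abs(promoter_window[1]),
                                   downstream = promoter_window[2])
  exons <- unlist(genes$exons)
  # cross-chromosome comparisons already warned about above
  in_prom <- suppressWarnings(
    IRanges::overlapsAny(pts, prom, ignore.strand = TRUE))
  in_exon <- suppressWarnings(
    IRanges::overlapsAny(pts, exons, ignore.strand = TRUE))
  in_gene <- suppressWarnings(
    IRanges::overlapsAny(pts, gr, ignore.strand = TRUE))
  cls <- ifelse(in_prom, "promoter",
                ifelse(in_exon, "exon",
                       ifelse(in_gene, "intron", "intergenic")))
  cls <- factor(cls, levels = classes)
  frac <- as.numeric(table(cls)) / length(cls)
  names(frac) <- classes
  list(class = cls, fractions = frac)
}

#' Select the strongest peaks
#'
#' The `n` highest-score peaks, ties broken by (chromosome, start) for
#' determinism. Requesting more peaks than exist returns all with a
#' warning.
#'
#' @param peaks GRanges with a `score` column.
#' @param n Number of peaks to keep (default 2000, the most prominent
#'   open-chromatin regions examined for feature classification).
#' @return GRanges subset in selection order.
#' @export
top_peaks <- function(peaks, n = 2000L) {
  if (n > length(peaks)) {
    warning("requested ", n, " peaks but only ", length(peaks),
            " available")
    n <- length(peaks)
  }
  if (n == 0) return(peaks[0])
  ord <- order(-peaks$score,
               as.character(GenomeInfoDb::seqnames(peaks)),
               GenomicRanges::start(peaks))
  peaks[ord[seq_len(n)]]
}

#' TSS meta-profile of fragment midpoints
#'
#' Maps fragment midpoints into TSS-relative coordinates (negated on
#' minus-strand genes so upstream is always negative), bins them over a
#' symmetric window, and normalizes the binned density so the outermost
#' 10% of bins average 1 (flanking background = 1).
#'
#' @param fragments GRanges of fragments.
#' @param genes Gene-model list (uses the TSS and strand).
#' @param window Half-width of the profile window in bp (default 3000).
#' @param bin Bin width in bp (default 50).
#' @return data.frame with `bin_center` and normalized `density`;
#'   `enrichment` attribute = center bin over edge mean.
#' @export
tss_profile <- function(fragments, genes, window = 3000L, bin = 50L) {
  tss <- gene_tss(genes$genes)
  mid <- GenomicRanges::start(fragments) +
    GenomicRanges::width(fragments) %/% 2L
  mids <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(fragments),
                                 IRanges::IRanges(mid, mid))
  win <- GenomicRanges::resize(tss, width = 2L * window + 1L,
                               fix = "center")
  hits <- GenomicRanges::findOverlaps(mids, win, ignore.strand = TRUE)
  if (!length(hits)) {
    warning("no fragments within any TSS window; flat zero profile")
    centers <- seq(-window + bin / 2, window - bin / 2, by = bin)
    return(data.frame(bin_center = centers,
                      density = rep(0, length(centers))))
  }
  g <- S4Vectors::subjectHits(hits)
  rel <- mid[S4Vectors::queryHits(hits)] -
    GenomicRanges::start(tss)[g]
  neg <- as.character(GenomicRanges::strand(tss))[g] == "-"
  rel[neg] <- -rel[neg]
  edges <- seq(-window, window, by = bin)
  cnt <- tabulate(findInterval(rel, edges, rightmost.closed = TRUE),
                  nbins = length(edges) - 1L)
  n_edge <- max(1L, round(0.1 * length(cnt) / 2))
  edge_mean <- mean(cnt[c(seq_len(n_edge),
                          seq(length(cnt) - n_edge + 1L, length(cnt)))])
  dens <- if (edge_mean > 0) cnt / edge_mean else cnt
  out <- data.frame(bin_center = edges[-length(edges)] + bin / 2,
                    density = dens)
  center_bin <- which.min(abs(out$bin_center))
  attr(out, "enrichment") <- if (edge_mean > 0)
    dens[center_bin] else NA_real_
  out
}

#' Best accessibility score per gene
#'
#' Assigns every peak (at its summit) to the gene with the nearest TSS
#' (ties broken toward the leftmost TSS for determinism) and keeps the
#' maximum assigned peak score per gene; genes with no assigned peak
#' score 0. This is the per-gene chromatin accessibility estimate used
#' for the accessibility-expression landscape.
#'
#' @param peaks GRanges with `score` (and optionally `summit_offset`).
#' @param genes Gene-model list.
#' @return data.frame: `gene_id`, `score`, `n_peaks` assigned.
#' @export
max_peak_per_gene <- function(peaks, genes) {
  tss <- gene_tss(genes$genes)
  spos <- GenomicRanges::start(peak_summits(peaks))
  tpos <- GenomicRanges::start(tss)
  schr <- as.character(GenomeInfoDb::seqnames(peaks))
  tchr <- as.character(GenomeInfoDb::seqnames(tss))
  assign_gene <- integer(length(peaks))
  for (ch in unique(schr)) {
    pi <- which(schr == ch)
    ti <- which(tchr == ch)
    if (!length(ti)) { assign_gene[pi] <- NA_integer_; next }
    tp <- tpos[ti]
    o <- order(tp, ti)        # leftmost TSS first among equals
    tp <- tp[o]; tio <- ti[o]
    for (p in pi) {
      d <- abs(tp - spos[p])
      assign_gene[p] <- tio[which.min(d)]  # first (leftmost) on ties
    }
  }
  score <- setNames(numeric(length(tss)), tss$gene_id)
  npk <- setNames(integer(length(tss)), tss$gene_id)
  ok <- !is.na(assign_gene)
  for (p in which(ok)) {
    g <- assign_gene[p]
    score[g] <- max(score[g], peaks$score[p])
    npk[g] <- npk[g] + 1L
  }
  data.frame(gene_id = names(score), score = unname(score),
             n_peaks = unname(npk), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Build a log-odds position weight matrix
#'
#' From a base count matrix (rows A, C, G, T; JASPAR-style) with a
#' pseudocount, against a uniform background, or from a literal
#' consensus word.
#'
#' @param counts 4 x w numeric matrix with rownames A, C, G, T.
#' @param pseudocount Added to every count cell.
#' @param background Background base probability (uniform 0.25).
#' @return 4 x w log2-odds matrix of class `pwm`.
#' @export
pwm_from_counts <- function(counts, pseudocount = 0.5,
                            background = 0.25) {
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  p <- sweep(counts + pseudocount, 2, colSums(counts + pseudocount), "/")
  lo <- log2(p / background)
  class(lo) <- c("pwm", "matrix")
  lo
}

#' @rdname pwm_from_counts
#' @param word Consensus DNA word (A/C/G/T).
#' @export
pwm_from_consensus <- function(word, pseudocount = 0.5,
                               background = 0.25) {
  bases <- strsplit(toupper(word), "")[[1]]
  if (!all(bases %in% c("A", "C", "G", "T")))
    stop("consensus word must be over A/C/G/T", call. = FALSE)
  cnt <- matrix(0, 4, length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  cnt[cbind(match(bases, rownames(cnt)), seq_along(bases))] <- 1
  pwm_from_counts(cnt, pseudocount, background)
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

pwm_scores_one_strand <- function(seq_int, pwm, n_neutral) {
  w <- ncol(pwm)
  L <- length(seq_int)
  if (L < w) return(numeric(0))
  n_pos <- L - w + 1L
  sc <- numeric(n_pos)
  for (j in seq_len(w)) {
    b <- seq_int[j:(j + n_pos - 1L)]
    col <- pwm[, j]
    v <- ifelse(is.na(b), if (n_neutral) 0 else -Inf, col[b])
    sc <- sc + v
  }
  sc
}

#' Scan a sequence with a PWM on both strands
#'
#' Computes the log-odds score at every offset on both strands and
#' returns positions scoring at least `threshold`. `N` bases contribute
#' `-Inf` unless `n_neutral = TRUE` (contribution 0). Positions are
#' 1-based starts of the match on the forward sequence, for both
#' strands.
#'
#' @param sequence DNA string over A/C/G/T/N.
#' @param pwm A 4 x w log-odds matrix (see [pwm_from_counts()]).
#' @param threshold Minimum log-odds score reported.
#' @param n_neutral Treat `N` as score-neutral?
#' @return data.frame: `pos`, `strand`, `score`, ordered by position.
#' @export
pwm_scan <- function(sequence, pwm, threshold, n_neutral = FALSE) {
  sequence <- toupper(sequence)
  w <- ncol(pwm)
  map <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  fwd <- map[strsplit(sequence, "")[[1]]]
  sc_f <- pwm_scores_one_strand(fwd, pwm, n_neutral)
  rev_seq <- revcomp(sequence)
  rev_int <- map[strsplit(rev_seq, "")[[1]]]
  sc_r_revcoord <- pwm_scores_one_strand(rev_int, pwm, n_neutral)
  # map reverse-strand offsets back to forward coordinates
  L <- nchar(sequence)
  pf <- which(sc_f >= threshold)
  pr <- which(sc_r_revcoord >= threshold)
  out <- rbind(
    data.frame(pos = pf, strand = rep("+", length(pf)),
               score = sc_f[pf]),
    data.frame(pos = L - w + 2L - pr, strand = rep("-", length(pr)),
               score = sc_r_revcoord[pr]))
  out[order(out$pos, out$strand), , drop = FALSE]
}

#' Per-base Tn5 insertion coverage within a peak
#'
#' Counts fragment end points (both insertions of each fragment) at each
#' base of the peak; the footprint detector operates on this vector.
#'
#' @param fragments GRanges of fragments.
#' @param peak A single-range GRanges.
#' @return Integer vector, one count per base of the peak.
#' @export
peak_coverage <- function(fragments, peak) {
  stopifnot(length(peak) == 1)
  s <- GenomicRanges::start(peak); e <- GenomicRanges::end(peak)
  fr <- fragments[as.character(GenomeInfoDb::seqnames(fragments)) ==
                    as.character(GenomeInfoDb::seqnames(peak))]
  ins <- c(GenomicRanges::start(fr), GenomicRanges::end(fr))
  ins <- ins[ins >= s & ins <= e]
  tabulate(ins - s + 1L, nbins = e - s + 1L)
}

#' Detect transcription-factor footprint notches in peak coverage
#'
#' A footprint is a short run of sharply depressed coverage inside an
#' otherwise open region. Candidate notches are maximal runs where the
#' coverage falls below `(1 - min_depth_ratio)` times a local running
#' baseline; each run is then validated against the mean coverage of
#' `flank`-bp windows immediately left and right, keeping runs whose
#' width lies within `width_range` and whose dip depth ratio
#' `1 - notch_mean / flank_mean` is at least `min_depth_ratio`. A
#' footprint must sit in *otherwise open* chromatin, so the flank mean
#' must also reach `min_flank_frac` of the peak-wide mean coverage: this
#' rejects spurious dips in the sparse decaying tails of a peak. Each
#' surviving run is tested for Poisson depletion: the summed notch
#' counts must be improbably low (`p < alpha`) under the flank rate, so
#' shallow-coverage noise does not produce calls. When a PWM and the
#' peak sequence are supplied, a call additionally requires a motif
#' match overlapping the notch.
#'
#' @param coverage Per-base coverage vector within one peak (e.g.
#'   [peak_coverage()]).
#' @param min_depth_ratio Minimum dip depth ratio (default 0.5).
#' @param width_range Allowed notch widths in bp (default 6-30).
#' @param flank Flank width for the local baseline (bp).
#' @param min_flank_frac Minimum flank mean coverage as a fraction of
#'   the peak-wide mean (default 0.5).
#' @param alpha Poisson depletion significance required for a call
#'   (default 1e-4).
#' @param pwm,sequence Optional PWM and peak sequence for motif
#'   confirmation.
#' @param pwm_threshold Log-odds threshold for the motif match (default:
#'   80% of the PWM's maximum achievable score).
#' @return data.frame of calls: `start`, `end`, `width`, `dip_ratio`,
#'   and when a PWM is used, `motif_pos`, `motif_score`, `motif_strand`.
#'   Peaks shorter than `min(width) + 2 * flank` return zero rows.
#' @export
detect_notch <- function(coverage, min_depth_ratio = 0.5,
                         width_range = c(6L, 30L), flank = 20L,
                         min_flank_frac = 0.5, alpha = 1e-4,
                         pwm = NULL, sequence = NULL,
                         pwm_threshold = NULL) {
  empty <- data.frame(start = integer(), end = integer(),
                      width = integer(), dip_ratio = numeric(),
                      p_depletion = numeric())
  n <- length(coverage)
  if (n < width_range[1] + 2L * flank) return(empty)
  k <- 2L * flank + 1L
  base <- as.numeric(stats::filter(coverage, rep(1 / k, k), sides = 2))
  base[is.na(base)] <- mean(coverage)
  low <- coverage < (1 - min_depth_ratio) * base
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cand <- which(r$values & r$lengths >= width_range[1] &
                  r$lengths <= width_range[2])
  rows <- list()
  for (i in cand) {
    a <- starts[i]; b <- ends[i]
    if (a <= 1L || b >= n) next   # notch at the peak edge: no flank
    lf <- coverage[max(1L, a - flank):(a - 1L)]
    rf <- coverage[(b + 1L):min(n, b + flank)]
    fm <- mean(c(lf, rf))
    if (fm <= 0 || fm < min_flank_frac * mean(coverage)) next
    dip <- 1 - mean(coverage[a:b]) / fm
    if (dip < min_depth_ratio) next
    # depletion must be statistically incompatible with the flank rate
    p_dep <- stats::ppois(sum(coverage[a:b]), (b - a + 1L) * fm)
    if (p_dep >= alpha) next
    call <- data.frame(start = a, end = b, width = b - a + 1L,
                       dip_ratio = dip, p_depletion = p_dep)
    if (!is.null(pwm)) {
      if (is.null(sequence))
        stop("sequence required for motif confirmation", call. = FALSE)
      if (is.null(pwm_threshold))
        pwm_threshold <- 0.8 * sum(apply(pwm, 2, max))
      m <- pwm_scan(sequence, pwm, pwm_threshold)
      w <- ncol(pwm)
      overl <- m[m$pos <= b & (m$pos + w - 1L) >= a, , drop = FALSE]
      if (!nrow(overl)) next
      bestm <- overl[which.max(overl$score), ]
      call$motif_pos <- bestm$pos
      call$motif_score <- bestm$score
      call$motif_strand <- bestm$strand
    }
    rows[[length(rows) + 1L]] <- call
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}
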