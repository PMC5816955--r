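#' Per-cell total-count normalization ("SC-TPM")
#'
#' Scales every cell to a total of 1e6. UMI counts carry no transcript
#' length bias, so no length term is used (unlike bulk [tpm()]). Cells
#' with zero total counts are dropped with a warning naming the barcodes.
#'
#' @param counts Sparse or dense genes x cells UMI count matrix.
#' @return Matrix of the same class with columns summing to 1e6.
#' @export
#' @examples
#' cell_normalize(cbind(c1 = c(1, 3)))
cell_normalize <- function(counts) {
  tot <- Matrix::colSums(counts)
  zero <- tot == 0
  if (any(zero)) {
    warning("dropping ", sum(zero), " zero-count cell(s): ",
            paste(head(colnames(counts)[zero], 5), collapse = ", "))
    counts <- counts[, !zero, drop = FALSE]
    tot <- tot[!zero]
  }
  if (inherits(counts, "sparseMatrix")) {
    counts %*% Matrix::Diagonal(x = 1e6 / tot, names = FALSE)
  } else {
    sweep(counts, 2, tot, "/") * 1e6
  }
}

#' Log2-transformed SC-TPM
#'
#' Cells are normalized against their full library totals first; an
#' optional gene subset is taken afterwards (so a marker-gene view keeps
#' the whole-transcriptome scaling).
#'
#' @param counts Genes x cells UMI count matrix.
#' @param genes Optional gene ids to keep (after normalization).
#' @return Dense matrix of `log2(SC-TPM + 1)`.
#' @export
log2_sctpm <- function(counts, genes = NULL) {
  x <- cell_normalize(counts)
  if (!is.null(genes)) x <- x[intersect(genes, rownames(x)), , drop = FALSE]
  m <- as.matrix(x)
  dimnames(m) <- dimnames(x)
  log2(m + 1)
}

#' UMI rank curve (barcode knee plot data)
#'
#' Per-cell UMI totals sorted in decreasing order; the drop-off shape is
#' the standard droplet coverage diagnostic.
#'
#' @param counts Genes x cells UMI count matrix.
#' @return Named numeric vector, monotone non-increasing.
#' @export
umi_rank_curve <- function(counts) {
  if (ncol(counts) < 1) stop("need at least one cell", call. = FALSE)
  sort(Matrix::colSums(counts), decreasing = TRUE)
}

#' Split-half reproducibility of per-gene mean expression
#'
#' Randomly partitions the cells into two equal halves (an odd cell is
#' dropped), averages SC-TPM per gene within each half, and reports the
#' Pearson correlation of `log2(mean + 1)` over genes detected in at
#' least one cell of the dataset.
#'
#' @param counts Genes x cells UMI count matrix (>= 4 cells).
#' @param seed Optional integer seed for the random split.
#' @return A list with `r`, the per-half gene means (`half1`, `half2`,
#'   on the TPM scale), and the half assignment.
#' @export
split_half <- function(counts, seed = NULL) {
  if (ncol(counts) < 4)
    stop("need >= 4 cells for a meaningful split", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(counts)
  n_use <- n - n %% 2L
  perm <- sample.int(n)[seq_len(n_use)]
  h1 <- perm[seq_len(n_use / 2)]
  h2 <- perm[(n_use / 2 + 1):n_use]
  tpm_all <- cell_normalize(counts)
  detected <- Matrix::rowSums(counts) > 0
  m1 <- Matrix::rowMeans(tpm_all[, h1, drop = FALSE])[detected]
  m2 <- Matrix::rowMeans(tpm_all[, h2, drop = FALSE])[detected]
  r <- cor(log2(m1 + 1), log2(m2 + 1))
  list(r = r, half1 = m1, half2 = m2,
       assignment = ifelse(seq_len(n) %in% h1, 1L,
                           ifelse(seq_len(n) %in% h2, 2L, NA_integer_)))
}

#' Pseudobulk versus bulk expression correlation
#'
#' Averages SC-TPM across all cells and compares with length-normalized
#' bulk TPM (averaged across bulk samples) on the `log2(x + 1)` scale
#' over genes detected in both assays.
#'
#' @param sc Genes x cells UMI count matrix.
#' @param bulk Genes x samples bulk count matrix (or vector).
#' @param lengths Per-gene transcript lengths for the bulk TPM.
#' @return A list with `r`, `n_genes` (shared detected genes), and the
#'   paired per-gene means (`sc_mean`, `bulk_mean`).
#' @export
pseudobulk_vs_bulk <- function(sc, bulk, lengths) {
  if (is.null(dim(bulk))) bulk <- cbind(sample = bulk)
  shared <- intersect(rownames(sc), rownames(bulk))
  sc_mean <- Matrix::rowMeans(cell_normalize(sc[shared, , drop = FALSE]))
  if (!is.null(names(lengths))) lengths <- lengths[shared]
  bulk_mean <- rowMeans(tpm(bulk[shared, , drop = FALSE], lengths))
  det <- sc_mean > 0 & bulk_mean > 0
  if (sum(det) < 50)
    warning("only ", sum(det), " shared detected genes")
  r <- cor(log2(sc_mean[det] + 1), log2(bulk_mean[det] + 1))
  list(r = r, n_genes = sum(det),
       sc_mean = sc_mean[det], bulk_mean = bulk_mean[det])
}

#' Poisson technical-noise decomposition
#'
#' Per-gene mean and coefficient of variation of raw UMI counts across
#' cells, against the Poisson technical-noise reference
#' `CV = 1 / sqrt(mu)`. Genes with zero mean are excluded; a gene is
#' flagged as showing excess (biological) variation when its CV exceeds
#' the Poisson line by more than `margin`.
#'
#' @param counts Raw (unnormalized) genes x cells UMI counts, >= 2 cells.
#' @param margin Relative excess over the Poisson CV needed for the flag.
#' @return data.frame: `gene_id`, `mean`, `cv`, `cv_poisson`, `excess`.
#' @export
noise_decomposition <- function(counts, margin = 0.1) {
  if (ncol(counts) < 2)
    stop("variance undefined with a single cell", call. = FALSE)
  mu <- Matrix::rowMeans(counts)
  keep <- mu > 0
  m <- counts[keep, , drop = FALSE]
  mu <- mu[keep]
  ex2 <- Matrix::rowMeans(m * m)
  s2 <- (ex2 - mu^2) * ncol(m) / (ncol(m) - 1)
  cv <- sqrt(pmax(s2, 0)) / mu
  cvp <- 1 / sqrt(mu)
  data.frame(gene_id = rownames(m), mean = mu, cv = cv, cv_poisson = cvp,
             excess = cv > cvp * (1 + margin),
             row.names = NULL, stringsAsFactors = FALSE)
}

# Method-of-moments NB dispersion on size-factor-normalized counts:
# phi_hat = max(0, (s^2 - mu) / mu^2).
dispersion_mom <- function(y) {
  mu <- rowMeans(y)
  s2 <- apply(y, 1, var)
  pmax(0, (s2 - mu) / mu^2)
}

# sSeq-style shrinkage of per-gene dispersions toward a common target.
# The target is the mean moment dispersion over adequately expressed
# genes (mean normalized count >= 1): at lower means the moment
# estimator (s^2 - mu)/mu^2 is strongly upward-biased and would drag
# the common dispersion up, making every exact test conservative. The
# plug-in weight compares the spread around the target with the spread
# around the mean at slightly different degrees of freedom; with target
# = mean it evaluates to (G-2)/(G-1), i.e. near-complete shrinkage, the
# regime sSeq operates in for droplet data.
shrink_dispersion <- function(phi_hat, mu_norm = NULL) {
  G <- length(phi_hat)
  well <- if (is.null(mu_norm)) rep(TRUE, G) else mu_norm >= 1
  if (sum(well) < 10) well <- rep(TRUE, G)
  xi <- mean(phi_hat[well])
  if (G < 3) return(list(phi = phi_hat, xi = xi, delta = 0))
  num <- sum((phi_hat[well] - xi)^2) / (sum(well) - 1)
  den <- sum((phi_hat[well] - mean(phi_hat[well]))^2) / (sum(well) - 2)
  delta <- if (den <= 0) 1 else min(1, max(0, num / den))
  list(phi = delta * xi + (1 - delta) * phi_hat, xi = xi, delta = delta)
}

# Exact NB test of equal group means conditional on the gene total.
# Under the null, group totals KA ~ NB(SA*q, size SA^2/(phi*sum sA^2)),
# KB likewise; the two-sided p sums conditional probabilities <= that of
# the observed split (method of small p-values).
nb_exact_test <- function(kA, kB, SA, SB, sA2, sB2, phi) {
  K <- kA + kB
  if (K == 0) return(NA_real_)
  q <- K / (SA + SB)
  muA <- SA * q; muB <- SB * q
  if (phi <= 0) {
    # Poisson limit: binomial conditional distribution
    pr <- stats::dbinom(0:K, K, muA / (muA + muB))
  } else {
    szA <- SA^2 / (phi * sA2)
    szB <- SB^2 / (phi * sB2)
    ks <- 0:K
    pr <- stats::dnbinom(ks, mu = muA, size = szA) *
      stats::dnbinom(K - ks, mu = muB, size = szB)
    tot <- sum(pr)
    if (tot <= 0) return(NA_real_)
    pr <- pr / tot
  }
  obs <- pr[kA + 1L]
  min(1, sum(pr[pr <= obs * (1 + 1e-12)]))
}

#' Shrinkage negative-binomial exact-test differential expression (sSeq)
#'
#' Droplet-appropriate two-group DE: cells are total-count size-factor
#' normalized, per-gene dispersions are estimated by the method of
#' moments (`phi_hat = max(0, (s^2 - mu)/mu^2)`) and shrunk toward their
#' mean with an sSeq-style plug-in weight, and each gene is tested with a
#' two-sided exact NB test of equal group means conditional on the gene
#' total, using the shrunk dispersion. Genes with zero counts in both
#' groups are skipped. BH FDR across tested genes.
#'
#' @param groupA,groupB Genes x cells UMI count matrices over the same
#'   genes (A = reference/control, B = treated; log2FC is B over A).
#' @param delta Optional fixed shrinkage weight in \[0, 1\] (default:
#'   plug-in estimate).
#' @param dispersion Optional fixed common dispersion overriding the
#'   shrinkage estimate entirely (useful for oracle comparisons).
#' @return data.frame: `gene_id`, `mean_normalized` counts per cell,
#'   `log2FC`, `phi_mom`, `phi_shrunk`, `p`, `q`; shrinkage details in
#'   `attr(, "shrinkage")`.
#' @export
sseq_de <- function(groupA, groupB, delta = NULL, dispersion = NULL) {
  genes <- rownames(groupA)
  if (!identical(genes, rownames(groupB)))
    stop("group matrices must share the same gene universe", call. = FALSE)
  totA <- Matrix::colSums(groupA); totB <- Matrix::colSums(groupB)
  if (any(c(totA, totB) == 0))
    stop("zero-count cells present; run cell_normalize/QC first",
         call. = FALSE)
  ref <- mean(c(totA, totB))
  sA <- totA / ref; sB <- totB / ref

  kA <- as.numeric(Matrix::rowSums(groupA))
  kB <- as.numeric(Matrix::rowSums(groupB))
  tested <- which(kA + kB > 0)

  # moment dispersions on normalized counts, pooled across both groups
  yA <- as.matrix(groupA[tested, , drop = FALSE]) %*% diag(1 / sA, length(sA))
  yB <- as.matrix(groupB[tested, , drop = FALSE]) %*% diag(1 / sB, length(sB))
  y <- cbind(yA, yB)
  phi_hat <- dispersion_mom(y)

  if (!is.null(dispersion)) {
    phi_use <- rep(dispersion, length(tested))
    shr <- list(xi = dispersion, delta = NA_real_)
  } else if (!is.null(delta)) {
    xi <- mean(phi_hat)
    phi_use <- delta * xi + (1 - delta) * phi_hat
    shr <- list(xi = xi, delta = delta)
  } else {
    mu_norm <- (kA[tested] + kB[tested]) / (sum(sA) + sum(sB))
    s <- shrink_dispersion(phi_hat, mu_norm)
    phi_use <- s$phi
    shr <- s[c("xi", "delta")]
  }

  SA <- sum(sA); SB <- sum(sB)
  sA2 <- sum(sA^2); sB2 <- sum(sB^2)
  p <- vapply(seq_along(tested), function(i)
    nb_exact_test(kA[tested[i]], kB[tested[i]], SA, SB, sA2, sB2,
                  phi_use[i]), numeric(1))
  mA <- kA[tested] / SA; mB <- kB[tested] / SB
  eps <- 0.5 / max(SA, SB)
  res <- data.frame(gene_id = genes[tested],
                    mean_normalized = (kA[tested] + kB[tested]) / (SA + SB),
                    log2FC = log2((mB + eps) / (mA + eps)),
                    phi_mom = phi_hat, phi_shrunk = phi_use,
                    p = p, q = bh_fdr(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "shrinkage") <- shr
  res
}
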