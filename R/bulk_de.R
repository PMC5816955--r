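#' Transcripts per million
#'
#' `TPM_g = (c_g / L_g) / sum_h(c_h / L_h) * 1e6` per sample column.
#' Columns with all-zero counts return all-zero TPM with a warning.
#'
#' @param counts Genes x samples count matrix (or vector).
#' @param lengths Per-gene transcript lengths (bp), positive, recycled or
#'   matched by gene names.
#' @return Matrix of TPM values; every non-degenerate column sums to 1e6.
#' @export
#' @examples
#' tpm(c(10, 10), c(1000, 2000))
tpm <- function(counts, lengths) {
  if (is.null(dim(counts))) counts <- cbind(sample = counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  lengths <- rep_len(lengths, nrow(counts))
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("gene lengths must be positive", call. = FALSE)
  rate <- counts / lengths
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning("all-zero count column(s): TPM set to zero")
    tot[zero] <- 1
  }
  sweep(rate, 2, tot, "/") * 1e6
}

#' Log2 counts per million
#'
#' `log2(count / libsize * 1e6 + pseudocount)`, the expression scale of
#' the moderated-t stage.
#'
#' @param counts Genes x samples count matrix.
#' @param pseudocount Added before the log (default 0.5).
#' @param normalize Apply TMM effective library sizes
#'   (via [edgeR::calcNormFactors()]) so that compositional shifts from a
#'   strong induction program do not masquerade as fold changes in the
#'   unchanged genes.
#' @return Matrix of log2-CPM values.
#' @export
log2_cpm <- function(counts, pseudocount = 0.5, normalize = TRUE) {
  lib <- colSums(counts)
  if (any(lib == 0)) stop("library size zero in some sample", call. = FALSE)
  if (normalize) lib <- lib * edgeR::calcNormFactors(counts, lib.size = lib)
  log2(sweep(counts, 2, lib, "/") * 1e6 + pseudocount)
}

# Invert the trigamma function by Newton iteration (monotone decreasing
# on (0, Inf)); used by the method-of-moments prior-df estimate.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2)
    y <- y + dif
    if (abs(dif / y) < 1e-8) break
  }
  y
}

# Method-of-moments fit of the scaled inverse chi-square prior for gene
# variances, on the log scale: var(log s^2) = trigamma(d/2) + trigamma(d0/2)
# under s^2 ~ s0^2 * F(d, d0). Returns d0 (possibly Inf) and s0^2.
fit_variance_prior <- function(s2, df_residual) {
  ok <- is.finite(s2) & s2 > 0
  z <- log(s2[ok])
  evar <- var(z) - trigamma(df_residual / 2)
  if (!is.finite(evar)) {
    d0 <- 4                        # fallback when moments are unusable
  } else if (evar <= 0) {
    d0 <- Inf                      # no excess spread: common variance
  } else {
    d0 <- 2 * trigamma_inverse(evar)
  }
  if (is.finite(d0)) {
    lg_s0 <- mean(z) - digamma(df_residual / 2) + log(df_residual / 2) -
      log(d0 / 2) + digamma(d0 / 2)
  } else {
    lg_s0 <- mean(z) - digamma(df_residual / 2) + log(df_residual / 2)
  }
  list(d0 = d0, s0_sq = exp(lg_s0))
}

#' Moderated two-group t-test on log2-CPM
#'
#' Per-gene two-sample comparison of group means of `log2(CPM + 0.5)`
#' with empirical-Bayes variance shrinkage: the pooled residual variance
#' `s_g^2` (df `d = nA + nB - 2`) is shrunk toward a prior `s0^2` with
#' prior df `d0`, both estimated from the distribution of `s_g^2` by the
#' method of moments on the log scale,
#' `s~_g^2 = (d0 s0^2 + d s_g^2) / (d0 + d)`, and the moderated t
#' statistic `log2FC / SE(s~_g)` is referred to a t distribution with
#' `d0 + d` degrees of freedom. With `prior_df = 0` this is the ordinary
#' two-sample pooled t-test. Precision weighting of observations (as in
#' voom) is deliberately not performed; see the package vignette.
#'
#' @param counts Genes x samples count matrix.
#' @param groups Two-level factor over samples; log2FC is level 2 minus
#'   level 1 (treated minus control when levels are ordered that way).
#' @param prior_df `NULL` to estimate `d0` from the data, or a fixed
#'   value (0 disables shrinkage, `Inf` equalizes all variances).
#' @param pseudocount,normalize Passed to [log2_cpm()].
#' @return A `data.frame` (one row per gene): `gene_id`, `logCPM` (mean
#'   log2-CPM), `log2FC`, `t`, `p`, `q` (BH), with the fitted prior in
#'   `attr(, "prior")`.
#' @export
moderated_t_test <- function(counts, groups, prior_df = NULL,
                             pseudocount = 0.5, normalize = TRUE) {
  groups <- as.factor(groups)
  if (nlevels(groups) != 2)
    stop("groups must have exactly two levels", call. = FALSE)
  nA <- sum(groups == levels(groups)[1])
  nB <- sum(groups == levels(groups)[2])
  if (nA < 2 || nB < 2)
    stop("need >= 2 replicates per group", call. = FALSE)

  E <- log2_cpm(counts, pseudocount, normalize)
  A <- E[, groups == levels(groups)[1], drop = FALSE]
  B <- E[, groups == levels(groups)[2], drop = FALSE]
  mA <- rowMeans(A); mB <- rowMeans(B)
  d <- nA + nB - 2
  s2 <- (rowSums((A - mA)^2) + rowSums((B - mB)^2)) / d

  if (is.null(prior_df)) {
    if (all(s2 < 1e-12)) {
      warning("zero residual variance in all genes; prior df set infinite")
      prior <- list(d0 = Inf, s0_sq = max(mean(s2), .Machine$double.eps))
    } else {
      prior <- fit_variance_prior(s2, d)
    }
  } else {
    s0 <- if (prior_df > 0) fit_variance_prior(s2, d)$s0_sq else NA_real_
    prior <- list(d0 = prior_df, s0_sq = s0)
  }

  if (is.infinite(prior$d0)) {
    s2_mod <- rep(prior$s0_sq, length(s2))
  } else if (prior$d0 == 0) {
    s2_mod <- s2
  } else {
    s2_mod <- (prior$d0 * prior$s0_sq + d * s2) / (prior$d0 + d)
  }
  se <- sqrt(s2_mod * (1 / nA + 1 / nB))
  lfc <- mB - mA
  tstat <- lfc / se
  df_total <- min(prior$d0 + d, 1e6)
  p <- 2 * pt(-abs(tstat), df = df_total)
  res <- data.frame(gene_id = rownames(counts), logCPM = rowMeans(E),
                    log2FC = lfc, t = tstat, p = p, q = bh_fdr(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "prior") <- c(prior, list(df_residual = d,
                                      df_total = df_total))
  res
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i}(p_(j) * m / j)`, capped
#' at 1 and order-preserving on the input index. `NA`/`NaN` p-values
#' propagate and are excluded from `m`.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return q-values aligned with the input.
#' @export
#' @examples
#' bh_fdr(c(0.005, 0.01, 0.03, 0.04))
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(pvalues))
  q[ok] <- p.adjust(pvalues[ok], method = "BH")
  q
}

#' Apply the fold-change / FDR selection rule
#'
#' Flags genes with `q < fdr_threshold` and `|log2FC| >= lfc_threshold`
#' (the ">=4-fold at FDR < 0.05" rule at the defaults), and
#' additionally marks the 16-fold tier (`|log2FC| >= 4`) among the
#' selected genes, the stringent list used for network analysis.
#'
#' @param results A [moderated_t_test()] (or [sseq_de()]) result.
#' @param lfc_threshold Minimum |log2FC| (default 2, i.e. 4-fold).
#' @param fdr_threshold Maximum q (default 0.05).
#' @return The input with logical columns `selected` and `tier16fold`.
#' @export
select_de <- function(results, lfc_threshold = 2, fdr_threshold = 0.05) {
  if (nrow(results) == 0) {
    results$selected <- logical(0)
    results$tier16fold <- logical(0)
    return(results)
  }
  sel <- !is.na(results$q) & results$q < fdr_threshold &
    abs(results$log2FC) >= lfc_threshold
  results$selected <- sel
  results$tier16fold <- sel & abs(results$log2FC) >= 4
  results
}
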