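# Independent oracles, deliberately naive: written from the definitions,
# not from the package internals.

# Benjamini-Hochberg step-up from the textbook definition:
# q_(i) = min_{j >= i} p_(j) * m / j, capped at 1.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# NB pmf written out via lgamma, size/mu parameterization.
oracle_nb_pmf <- function(k, mu, size) {
  p <- size / (size + mu)
  exp(lgamma(k + size) - lgamma(size) - lfactorial(k) +
        size * log(p) + k * log1p(-p))
}

# Exact conditional NB test by exhaustive enumeration of all splits of
# the conditional total; two-sided by summing probabilities no larger
# than the observed split's.
oracle_sseq_exact_p <- function(kA, kB, SA, SB, sA2, sB2, phi) {
  K <- kA + kB
  q <- K / (SA + SB)
  szA <- SA^2 / (phi * sA2)
  szB <- SB^2 / (phi * sB2)
  pr <- vapply(0:K, function(k)
    oracle_nb_pmf(k, SA * q, szA) * oracle_nb_pmf(K - k, SB * q, szB),
    numeric(1))
  pr <- pr / sum(pr)
  obs <- pr[kA + 1L]
  sum(pr[pr <= obs * (1 + 1e-12)])
}

# Position-by-position PWM scoring on both strands, nested loops.
oracle_pwm_scan <- function(sequence, pwm, threshold) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- strsplit(toupper(sequence), "")[[1]]
  w <- ncol(pwm)
  hits <- list()
  for (pos in seq_len(length(bases) - w + 1)) {
    sf <- 0
    sr <- 0
    for (j in seq_len(w)) {
      b <- bases[pos + j - 1]
      sf <- sf + pwm[b, j]
      # reverse strand: complement read right-to-left
      sr <- sr + pwm[comp[[bases[pos + w - j]]], j]
    }
    if (sf >= threshold)
      hits[[length(hits) + 1]] <- data.frame(pos = pos, strand = "+",
                                             score = sf)
    if (sr >= threshold)
      hits[[length(hits) + 1]] <- data.frame(pos = pos, strand = "-",
                                             score = sr)
  }
  if (!length(hits))
    return(data.frame(pos = integer(), strand = character(),
                      score = numeric()))
  do.call(rbind, hits)
}

# Small-but-structured config used across module tests.
small_cfg <- function(seed = 42, ...) {
  args <- list(n_genes = 1500, n_cells_per_condition = 250,
               n_atac_genes = 60, n_peaks = 90, frags_per_peak = 1200,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

cyclic_phase_distance <- function(a, b) {
  ia <- match(a, cc_phases())
  ib <- match(b, cc_phases())
  d <- abs(ia - ib)
  pmin(d, 5 - d)
}
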