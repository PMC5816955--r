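# Column z-score with the sample (n-1) sd convention; zero-variance
# columns come back as all zeros (flagged by the caller).
zscore_cols <- function(m, warn_label = NULL) {
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  flat <- sdv < .Machine$double.eps
  if (any(flat) && !is.null(warn_label))
    warning("zero variance in ", warn_label,
            "; normalized scores set to 0")
  sdv[flat] <- 1
  z <- sweep(sweep(m, 2, mu), 2, sdv, "/")
  z[, flat] <- 0
  z
}

#' Five-phase cell-cycle scores
#'
#' Scores every cell against the five phase gene sets (G1/S, S, G2/M, M,
#' M/G1), following the gene-set averaging idea of Macosko et al.:
#'
#' 1. standardize each gene's `log2(SC-TPM + 1)` expression across cells;
#' 2. raw phase score = mean standardized expression over the set's
#'    genes present in the matrix;
#' 3. optional refinement: keep only genes whose correlation with their
#'    phase's raw score is at least `refine_corr_threshold`, then
#'    recompute the scores (a phase losing all genes falls back to its
#'    unrefined set with a warning);
#' 4. z-score each phase across cells, then z-score the five scores
#'    within each cell (sample sd convention throughout).
#'
#' @param expr Genes x cells expression on the `log2(SC-TPM + 1)` scale
#'   (e.g. from [log2_sctpm()]).
#' @param sets Named list of marker gene ids per phase (e.g. from
#'   [read_phase_sets()] or the generator's ground truth). The standard
#'   use supplies the five canonical phases, which are reordered
#'   cyclically; any >= 2 named sets are accepted for the score
#'   computation itself, but [assign_and_order()] requires the five.
#' @param refine Apply the correlation refinement step?
#' @param refine_corr_threshold Minimum gene-to-score correlation kept.
#' @return An object of class `phase_scores`: list with `raw` and
#'   `normalized` (cells x 5 matrices), `sets_used`, `n_cells`.
#' @export
phase_scores <- function(expr, sets, refine = TRUE,
                         refine_corr_threshold = 0.3) {
  if (is.null(names(sets)) || length(sets) < 2)
    stop("sets must be a named list of >= 2 gene sets", call. = FALSE)
  if (all(CC_PHASES %in% names(sets))) sets <- sets[CC_PHASES]
  phases <- names(sets)
  expr <- as.matrix(expr)
  present <- lapply(phases, function(p) intersect(sets[[p]],
                                                  rownames(expr)))
  names(present) <- phases
  if (any(lengths(present) == 0))
    stop("phase set(s) with no genes in the matrix: ",
         paste(phases[lengths(present) == 0], collapse = ", "),
         call. = FALSE)

  use <- unique(unlist(present))
  z <- t(zscore_cols(t(expr[use, , drop = FALSE])))  # standardize genes

  score_from <- function(set_list) {
    out <- sapply(set_list, function(g)
      colMeans(z[g, , drop = FALSE]))
    dimnames(out) <- list(colnames(expr), phases)
    out
  }
  raw <- score_from(present)

  sets_used <- present
  if (refine) {
    for (k in phases) {
      genes <- present[[k]]
      if (length(genes) < 2) next
      rr <- apply(z[genes, , drop = FALSE], 1, function(v) {
        if (sd(v) < .Machine$double.eps || sd(raw[, k]) < .Machine$double.eps)
          return(0)
        cor(v, raw[, k])
      })
      keep <- genes[rr >= refine_corr_threshold]
      if (length(keep) == 0) {
        warning("no genes survive refinement for phase ", k,
                "; falling back to the unrefined set")
      } else {
        sets_used[[k]] <- keep
      }
    }
    raw <- score_from(sets_used)
  }

  norm1 <- zscore_cols(raw, warn_label = "phase score across cells")
  norm2 <- t(zscore_cols(t(norm1), warn_label = "within-cell scores"))
  structure(list(raw = raw, normalized = norm2, sets_used = sets_used,
                 n_cells = ncol(expr)),
            class = "phase_scores")
}

#' @export
print.phase_scores <- function(x, ...) {
  cat("phase_scores:", x$n_cells, "cells x", ncol(x$raw), "phases\n")
  if (!is.null(x$assigned)) {
    cat("assignment:\n")
    print(table(x$assigned))
  }
  invisible(x)
}

#' Assign phases and order cells by cell-cycle progression
#'
#' Each cell is assigned the phase with the highest within-cell
#' normalized score (ties go to the cyclically earlier phase). Cells are
#' then ranked along the cycle: grouped by assigned phase in the cyclic
#' order G1/S, S, G2/M, M, M/G1, and within a phase ordered by the
#' contrast (score of the next phase minus score of the previous phase,
#' cyclically) ascending, which yields a smooth traversal from cells
#' entering the phase to cells leaving it.
#'
#' @param scores A [phase_scores()] object.
#' @return The object with `assigned` (factor per cell) and `rank`
#'   (integer permutation of cells; 1 = earliest in the cycle).
#' @export
assign_and_order <- function(scores) {
  stopifnot(inherits(scores, "phase_scores"))
  z <- scores$normalized
  if (!identical(colnames(z), CC_PHASES))
    stop("assignment and ordering require the five canonical phases",
         call. = FALSE)
  assigned <- apply(z, 1, which.max)   # which.max: first (earlier) on tie
  nxt <- c(2:5, 1)
  prv <- c(5, 1:4)
  contrast <- z[cbind(seq_len(nrow(z)), nxt[assigned])] -
    z[cbind(seq_len(nrow(z)), prv[assigned])]
  ord <- order(assigned, contrast)
  rank <- integer(nrow(z))
  rank[ord] <- seq_len(nrow(z))
  scores$assigned <- factor(CC_PHASES[assigned], levels = CC_PHASES)
  names(scores$assigned) <- rownames(z)
  scores$rank <- setNames(rank, rownames(z))
  scores$contrast <- contrast
  scores
}

#' Phase-conditioned treatment response of individual genes
#'
#' For each gene: per phase x condition cell count, mean and SD of
#' `log2(SC-TPM + 1)`; and two test families, (a) a Kruskal-Wallis test
#' of a phase effect within each condition and (b) a Wilcoxon rank-sum
#' test of the treatment effect within each phase. All p-values are
#' BH-adjusted jointly over genes x tests. Strata with fewer than 3
#' cells in a condition are flagged and their tests skipped.
#'
#' @param expr Genes x cells `log2(SC-TPM + 1)` matrix over the pooled
#'   (both-condition) cell set.
#' @param assigned Factor of assigned phases per cell (from
#'   [assign_and_order()], computed on the pooled cells).
#' @param treatment Factor per cell (level 1 = vehicle, level 2 =
#'   treated).
#' @param genes Gene ids to summarize and test.
#' @return A list with `summary` (gene x phase x condition n/mean/sd
#'   rows) and `tests` (gene, test type, stratum, statistic, p, q).
#' @export
phase_conditioned_response <- function(expr, assigned, treatment, genes) {
  expr <- as.matrix(expr)
  treatment <- as.factor(treatment)
  if (nlevels(treatment) != 2)
    stop("treatment must have two levels", call. = FALSE)
  if (length(assigned) != ncol(expr) || length(treatment) != ncol(expr))
    stop("assigned/treatment must match the cell count", call. = FALSE)
  genes <- intersect(genes, rownames(expr))
  if (!length(genes)) stop("no requested genes in the matrix", call. = FALSE)

  summ <- list(); tests <- list()
  for (g in genes) {
    v <- expr[g, ]
    for (ph in CC_PHASES) for (cond in levels(treatment)) {
      idx <- assigned == ph & treatment == cond
      summ[[length(summ) + 1L]] <- data.frame(
        gene = g, phase = ph, condition = cond, n = sum(idx),
        mean = if (any(idx)) mean(v[idx]) else NA_real_,
        sd = if (sum(idx) > 1) sd(v[idx]) else NA_real_,
        flagged = sum(idx) < 3, stringsAsFactors = FALSE)
    }
    # (a) phase effect within condition
    for (cond in levels(treatment)) {
      idx <- treatment == cond
      ph <- droplevels(assigned[idx])
      ok_ph <- names(which(table(ph) >= 3))
      use <- idx & assigned %in% ok_ph
      if (length(ok_ph) >= 2 && sd(v[use]) > 0) {
        kw <- kruskal.test(v[use], droplevels(assigned[use]))
        tests[[length(tests) + 1L]] <- data.frame(
          gene = g, test = "phase_within_condition", stratum = cond,
          statistic = unname(kw$statistic), p = kw$p.value,
          stringsAsFactors = FALSE)
      }
    }
    # (b) treatment effect within phase
    for (ph in CC_PHASES) {
      idx <- assigned == ph
      nA <- sum(idx & treatment == levels(treatment)[1])
      nB <- sum(idx & treatment == levels(treatment)[2])
      if (nA >= 3 && nB >= 3 && sd(v[idx]) > 0) {
        wt <- suppressWarnings(wilcox.test(v[idx] ~ treatment[idx]))
        tests[[length(tests) + 1L]] <- data.frame(
          gene = g, test = "treatment_within_phase", stratum = ph,
          statistic = unname(wt$statistic), p = wt$p.value,
          stringsAsFactors = FALSE)
      }
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else
    data.frame(gene = character(), test = character(),
               stratum = character(), statistic = numeric(), p = numeric())
  tests$q <- bh_fdr(tests$p)
  list(summary = do.call(rbind, summ), tests = tests)
}
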