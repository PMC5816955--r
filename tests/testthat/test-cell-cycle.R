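test_that("the two z-score steps match the hand-computed two-cell case", {
  expr <- matrix(c(2, 0, 0, 2), nrow = 2,
                 dimnames = list(c("g1", "g2"), c("c1", "c2")))
  sets <- list(P1 = "g1", P2 = "g2")
  ps <- phase_scores(expr, sets, refine = FALSE)
  s <- 1 / sqrt(2)
  expect_equal(unname(ps$normalized),
               matrix(c(s, -s, -s, s), nrow = 2), tolerance = 1e-12)
})

test_that("degenerate identical cells give zero scores with a warning", {
  expr <- matrix(1, nrow = 4, ncol = 3,
                 dimnames = list(sprintf("g%d", 1:4),
                                 sprintf("c%d", 1:3)))
  sets <- setNames(as.list(sprintf("g%d", 1:4))[c(1, 2, 3, 4, 1)],
                   cc_phases())
  w <- testthat::capture_warnings(
    ps <- phase_scores(expr, sets, refine = FALSE))
  expect_true(any(grepl("zero variance", w)))
  expect_true(all(ps$normalized == 0))
})

test_that("phase scores peak at the true phase on planted data", {
  sim <- simulate_sc_counts(small_cfg(seed = 61))
  tr <- sim$truth
  expr <- log2_sctpm(sim$vehicle, genes = unique(unlist(tr$phase_sets)))
  ps <- phase_scores(expr, tr$phase_sets)
  truep <- as.character(sim$phase_vehicle)
  for (k in cc_phases()) {
    in_k <- truep == k
    expect_gt(mean(ps$normalized[in_k, k]),
              max(colMeans(ps$normalized[in_k, setdiff(cc_phases(), k),
                                         drop = FALSE])))
  }
})

test_that("scores are invariant to cell order and to irrelevant genes", {
  sim <- simulate_sc_counts(small_cfg(seed = 62,
                                      n_cells_per_condition = 120))
  tr <- sim$truth
  markers <- unique(unlist(tr$phase_sets))
  expr <- log2_sctpm(sim$vehicle, genes = markers)
  ps <- phase_scores(expr, tr$phase_sets)
  perm <- sample(ncol(expr))
  ps_p <- phase_scores(expr[, perm], tr$phase_sets)
  expect_equal(ps_p$normalized, ps$normalized[perm, ], tolerance = 1e-9)

  # diluting a set with phase-irrelevant genes: refinement removes them
  flat <- setdiff(tr$gene_ids, c(markers, tr$responders))[1:10]
  expr2 <- log2_sctpm(sim$vehicle, genes = c(markers, flat))
  sets2 <- tr$phase_sets
  sets2[["S"]] <- c(sets2[["S"]], flat)
  ps_r <- phase_scores(expr2, sets2, refine = TRUE)
  expect_true(all(!flat %in% ps_r$sets_used[["S"]]))
  expect_gt(cor(ps_r$normalized[, "S"], ps$normalized[, "S"]), 0.98)
})

test_that("refinement falling through to the unrefined set warns", {
  set.seed(3)
  expr <- matrix(rnorm(5 * 40), nrow = 5,
                 dimnames = list(sprintf("g%d", 1:5),
                                 sprintf("c%d", 1:40)))
  sets <- setNames(list("g1", "g2", "g3", "g4", c("g5", "g1")),
                   cc_phases())
  # singleton sets always self-correlate; the two-gene set of
  # independent noise genes can lose both members
  expect_warning(
    try(phase_scores(expr, sets, refine = TRUE,
                     refine_corr_threshold = 1.01), silent = TRUE),
    "falling back|zero variance")
})

test_that("assignment takes the argmax with cyclic-earlier tie-break", {
  z <- rbind(c(2, 0, 0, 0, 0),
             c(0, 0, 1, 1, 0))   # tie: G2/M before M
  colnames(z) <- cc_phases()
  rownames(z) <- c("c1", "c2")
  ps <- structure(list(raw = z, normalized = z, n_cells = 2),
                  class = "phase_scores")
  out <- assign_and_order(ps)
  expect_equal(as.character(out$assigned),
               c("G1/S", "G2/M"))
})

test_that("within-phase ordering follows the next-minus-previous contrast", {
  # two S cells; the one leaning toward G2/M comes later
  z <- rbind(c(0.1, 2.0, 1.0, 0, -1),
             c(0.8, 2.0, 0.2, 0, -1))
  colnames(z) <- cc_phases()
  rownames(z) <- c("later", "earlier")
  ps <- structure(list(raw = z, normalized = z, n_cells = 2),
                  class = "phase_scores")
  out <- assign_and_order(ps)
  expect_true(all(out$assigned == "S"))
  expect_lt(out$rank[["earlier"]], out$rank[["later"]])
})

test_that("progression rank is cyclic-shift covariant", {
  sim <- simulate_sc_counts(small_cfg(seed = 63,
                                      n_cells_per_condition = 150))
  tr <- sim$truth
  expr <- log2_sctpm(sim$vehicle, genes = unique(unlist(tr$phase_sets)))
  ps <- assign_and_order(phase_scores(expr, tr$phase_sets))
  # relabel phases by one cyclic step and rebuild
  shift <- c(2:5, 1)
  z2 <- ps$normalized[, shift]
  colnames(z2) <- cc_phases()
  ps2 <- structure(list(raw = z2, normalized = z2,
                        n_cells = ps$n_cells), class = "phase_scores")
  out2 <- assign_and_order(ps2)
  expect_equal(match(as.character(out2$assigned), cc_phases()),
               ((match(as.character(ps$assigned), cc_phases()) - 2) %% 5) + 1)
  # within-phase relative order is preserved under the relabeling
  for (k in seq_along(cc_phases())) {
    cells <- which(match(as.character(ps$assigned), cc_phases()) == k)
    if (length(cells) > 1) {
      expect_equal(order(ps$rank[cells]), order(out2$rank[cells]))
    }
  }
})

test_that("phase assignment recovers planted phases", {
  sim <- simulate_sc_counts(small_cfg(seed = 64))
  tr <- sim$truth
  expr <- log2_sctpm(cbind(sim$vehicle, sim$gnrh),
                     genes = unique(unlist(tr$phase_sets)))
  ps <- assign_and_order(phase_scores(expr, tr$phase_sets))
  truep <- c(as.character(sim$phase_vehicle),
             as.character(sim$phase_gnrh))
  d <- cyclic_phase_distance(as.character(ps$assigned), truep)
  expect_gte(mean(d == 0), 0.8)
  expect_gte(mean(d <= 1), 0.95)
  # confusions concentrate between cyclically adjacent phases
  if (any(d > 0)) expect_gt(mean(d[d > 0] == 1), 0.5)
  # rank is a permutation
  expect_setequal(ps$rank, seq_len(ncol(expr)))
})

test_that("phase-conditioned response separates the three planted gene types", {
  cfg <- small_cfg(seed = 65, n_genes = 4000,
                   n_cells_per_condition = 400)
  sim <- simulate_sc_counts(cfg)
  tr <- sim$truth
  pooled <- cbind(sim$vehicle, sim$gnrh)
  treatment <- factor(rep(c("vehicle", "gnrh"),
                          times = c(ncol(sim$vehicle), ncol(sim$gnrh))),
                      levels = c("vehicle", "gnrh"))
  ps <- assign_and_order(phase_scores(
    log2_sctpm(pooled, genes = unique(unlist(tr$phase_sets))),
    tr$phase_sets))

  m_marker <- tr$phase_sets[["M"]][1]
  responders <- tr$responders[order(-abs(tr$beta[match(
    tr$responders, tr$gene_ids)]))][1:3]
  null_genes <- setdiff(tr$gene_ids[order(-tr$mu)],
                        c(unlist(tr$phase_sets), tr$responders))[1:10]
  genes <- c(m_marker, responders, null_genes)
  expr <- log2_sctpm(pooled, genes = genes)
  out <- phase_conditioned_response(expr, ps$assigned, treatment, genes)
  tst <- out$tests

  # planted M marker: phase effect significant, mean maximal at M
  pm <- tst[tst$gene == m_marker & tst$test == "phase_within_condition", ]
  expect_true(all(pm$q < 0.05))
  sm <- out$summary[out$summary$gene == m_marker &
                      out$summary$condition == "vehicle", ]
  expect_equal(sm$phase[which.max(sm$mean)], "M")

  # phase-independent responders: treatment effect in every populated
  # phase, essentially no phase effect within either condition (nominal
  # alpha plus the small TPM compositional coupling allow a stray hit)
  pr <- tst[tst$gene %in% responders, ]
  expect_true(all(pr$q[pr$test == "treatment_within_phase"] < 0.05))
  expect_gte(mean(pr$p[pr$test == "phase_within_condition"] > 0.05),
             5 / 6)

  # inert genes: overwhelmingly non-significant (nominal alpha plus the
  # small TPM compositional coupling to the planted markers)
  pn <- tst[tst$gene %in% null_genes, ]
  expect_gte(mean(pn$q > 0.05), 0.8)
})
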