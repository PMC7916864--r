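test_that("Nei distance anchors: identity, disjoint fixation, dual-route agreement", {
  # identical frequency vectors -> D = 0
  d <- rbind(c(0L, 1L, 2L, 1L), c(2L, 1L, 0L, 1L))
  gm <- gm_from_dosage(rbind(d, d))
  meta <- meta_for(gm, group = c("A", "A", "B", "B"))
  expect_equal(nei_distance(gm, meta, "A", "B"), 0)

  # fixed for opposite alleles everywhere -> infinite, flagged
  gm2 <- gm_from_dosage(rbind(c(0L, 0L), c(0L, 0L), c(2L, 2L), c(2L, 2L)))
  meta2 <- meta_for(gm2, group = c("A", "A", "B", "B"))
  expect_warning(dd <- nei_distance(gm2, meta2, "A", "B"), "infinite")
  expect_identical(dd, Inf)

  # against an independent per-locus re-implementation
  sim <- sim_structured(c(A = 30, B = 30), fst = 0.05, n_loci = 20000, seed = 2)
  got <- nei_distance(sim$gm, sim$metadata, "A", "B")
  pa <- variant_freq(sim$gm, sim$metadata$sample[sim$metadata$group == "A"])
  pb <- variant_freq(sim$gm, sim$metadata$sample[sim$metadata$group == "B"])
  expect_lt(abs(got - nei_direct(pa, pb)) / nei_direct(pa, pb), 1e-10)
})

test_that("Weir-Cockerham theta anchors: fixation, duplication invariance, null", {
  # fixed difference -> theta = 1
  gm <- gm_from_dosage(rbind(
    matrix(0L, 5, 50), matrix(2L, 5, 50)
  ))
  meta <- meta_for(gm, group = rep(c("A", "B"), each = 5))
  expect_equal(wc_fst(gm, meta), 1)

  # same genotypes copied into both groups -> theta <= 0
  set.seed(3)
  block <- matrix(rbinom(8 * 200, 2, 0.3), 8, 200)
  gm2 <- gm_from_dosage(rbind(block, block))
  meta2 <- meta_for(gm2, group = rep(c("A", "B"), each = 8))
  expect_lte(wc_fst(gm2, meta2), 0)

  # duplicating every individual changes the ratio-of-sums theta by < 0.01
  sim <- sim_structured(c(A = 25, B = 25), fst = 0.1, n_loci = 5000, seed = 6)
  th1 <- wc_fst(sim$gm, sim$metadata)
  dup <- geno_matrix(
    rbind(sim$gm$dosage, sim$gm$dosage),
    sim$gm$variants,
    samples = c(sim$gm$samples, paste0(sim$gm$samples, "_dup"))
  )
  meta_dup <- dplyr::bind_rows(
    sim$metadata,
    dplyr::mutate(sim$metadata, sample = paste0(sample, "_dup"))
  )
  th2 <- wc_fst(dup, meta_dup)
  expect_lt(abs(th1 - th2), 0.01)

  expect_error(
    wc_fst(gm_from_dosage(matrix(0L, 4, 3)),
           meta_for(gm_from_dosage(matrix(0L, 4, 3)),
                    group = rep(c("A", "B"), each = 2))),
    "monomorphic"
  )
})

test_that("pairwise divergence table is symmetric-complete over groups", {
  sim <- sim_structured(c(A = 10, B = 10, C = 10), fst = 0.1,
                        n_loci = 800, seed = 7)
  tab <- pair_divergence(sim$gm, sim$metadata)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$nei_d >= 0))
  expect_true(all(c("nei_d", "fst") %in% names(tab)))
})

test_that("AMOVA separates clone groups and respects df accounting", {
  # two groups of exact clones: all variance among groups
  d <- rbind(
    matrix(rep(c(0L, 2L, 0L, 2L), 4), 4, byrow = TRUE),
    matrix(rep(c(2L, 0L, 2L, 0L), 4), 4, byrow = TRUE)
  )
  gm <- gm_from_dosage(d)
  meta <- meta_for(gm, group = rep(c("A", "B"), each = 4))
  fit <- amova(dosage_dist2(gm), meta, n_perm = 99, seed = 1)
  tab <- tidy(fit)
  expect_equal(tab$pct[tab$stratum == "among_groups"], 100)
  expect_equal(tab$variance[tab$stratum == "within_groups"], 0)
  expect_equal(sum(tab$df), nrow(meta) - 1)
  expect_lt(abs(sum(tab$pct) - 100), 0.5)
})

test_that("AMOVA components are invariant to sample ordering", {
  sim <- sim_structured(
    c(A = 8, B = 8, C = 8), fst = 0.08, n_loci = 400,
    supergroup = c("f1", "f1", "f2"), seed = 9
  )
  d2 <- dosage_dist2(sim$gm)
  fit1 <- amova(d2, sim$metadata, n_perm = 0)
  perm <- sample(nrow(d2))
  fit2 <- amova(d2[perm, perm], sim$metadata[perm, ], n_perm = 0)
  expect_equal(tidy(fit1)$variance, tidy(fit2)$variance)
  expect_equal(tidy(fit1)$SS, tidy(fit2)$SS)
})

test_that("AMOVA detects genuine structure with small permutation p", {
  sim <- sim_structured(
    c(A = 10, B = 10, C = 10), fst = 0.1, n_loci = 1000,
    supergroup = c("f1", "f1", "f2"), seed = 10
  )
  fit <- amova(dosage_dist2(sim$gm), sim$metadata, n_perm = 199, seed = 2)
  g <- glance(fit)
  expect_lt(g$p_among_groups, 0.05)
  expect_gt(g$pct_among_groups, 2)
})

test_that("tidy and glance expose the AMOVA strata and summary", {
  sim <- sim_structured(c(A = 6, B = 6), fst = 0.05, n_loci = 200, seed = 11)
  fit <- amova(dosage_dist2(sim$gm), sim$metadata, n_perm = 49, seed = 3)
  tab <- tidy(fit)
  expect_setequal(tab$stratum, c("among_groups", "within_groups"))
  expect_named(
    glance(fit),
    c("n_samples", "n_perm", "total_variance", "pct_among_groups",
      "p_among_groups", "p_among_supergroups")
  )
})
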