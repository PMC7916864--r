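test_that("composite D matches hand-traced arithmetic on small tables", {
  # two AABB and two aabb: D = N/(N-1) * (ΣXY/(2N) - 2 pA pB)
  #                          = 4/3 * (8/8 - 2 * 0.25) = 2/3
  tab <- matrix(0, 3, 3)
  tab[1, 1] <- 2
  tab[3, 3] <- 2
  expect_equal(composite_d(tab), 4 / 3 * (1 - 0.5))

  # positive association by construction (identical genotypes at both loci,
  # all three classes present)
  tab2 <- diag(c(2, 2, 2))
  expect_gt(composite_d(tab2), 0)

  expect_error(composite_d(matrix(c(4, 0, 0, 0, 0, 0, 0, 0, 0), 3)),
               "monomorphic")
  expect_error(composite_d(matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 0), 3)),
               "at least 2")
})

test_that("composite D is centred on zero for loci in linkage equilibrium", {
  set.seed(55)
  ds <- replicate(1000, {
    x <- rbinom(100, 2, 0.4)
    y <- rbinom(100, 2, 0.3)
    tab <- table(factor(x, 0:2), factor(y, 0:2))
    tryCatch(composite_d(tab), error = function(e) NA)
  })
  expect_lt(abs(mean(ds, na.rm = TRUE)), 0.003)
})

test_that("the haplotype-sample-size correction has its fixed points", {
  expect_equal(correct_r2(1, 10), 1)
  expect_equal(correct_r2(1, 200), 1)
  expect_equal(correct_r2(1 / 50, 50), 0)
  expect_equal(correct_r2(0.5, 50), (0.5 - 1 / 50) / (1 - 1 / 50))
  expect_equal(correct_r2(-0.1, 50), 0) # clamped
})

test_that("pair r2 is symmetric and invariant to REF/ALT relabeling", {
  set.seed(19)
  for (k in 1:5) {
    d <- matrix(rbinom(40 * 2, 2, runif(1, 0.2, 0.6)), 40, 2)
    d[sample(40, 3), 1] <- NA
    gm <- gm_from_dosage(d)
    a <- pair_r2(gm, 1, 2)$r2
    b <- pair_r2(gm, 2, 1)$r2
    expect_equal(a, b)
    flip <- gm
    flip$dosage[, 1] <- 2L - flip$dosage[, 1]
    expect_equal(pair_r2(flip, 1, 2)$r2, a)
  }
  gm2 <- geno_matrix(
    matrix(c(0L, 1L, 2L, 1L), 2),
    variants = data.frame(scaffold = c("s1", "s2"), pos = c(1L, 1L),
                          ref = "A", alt = "G")
  )
  expect_error(pair_r2(gm2, 1, 2), "scaffold")
})

test_that("perfect LD between identical adjacent columns scores r2 = 1", {
  set.seed(23)
  x <- rbinom(30, 2, 0.5)
  gm <- gm_from_dosage(cbind(x, x, x))
  expect_equal(pair_r2(gm, 1, 2)$r2, 1)
  res <- adjacent_r2(gm)
  expect_equal(res$mean_r2, 1)
  expect_equal(res$mean_distance, 1e4)
})

test_that("adjacent r2 is invariant to sample order and exceeds long-range r2 under linkage", {
  sim <- sim_wright_fisher(50, 80, 5e6, 1e-8, 30, 600, seed = 35)
  gm <- apply_filters(sim$gm, filter_spec(min_qual = NULL))
  a <- adjacent_r2(gm)
  perm <- sample(n_samples(gm))
  gm_perm <- geno_matrix(gm$dosage[perm, ], gm$variants,
                         samples = gm$samples[perm])
  b <- adjacent_r2(gm_perm)
  expect_equal(a$mean_r2, b$mean_r2)

  bins <- ld_decay(gm, 2e6, 1e6,
                   config = ld_config(n_snps = Inf, min_scaffold_length = 0))
  expect_gt(a$mean_r2, bins$mean_r2[bins$bin_low == 1e6])
})

test_that("decay bins partition distances correctly", {
  sim <- sim_wright_fisher(40, 30, 2e6, 1e-8, 20, 150, seed = 44)
  gm <- apply_filters(sim$gm, filter_spec(min_qual = NULL))
  bins <- ld_decay(gm, 1e5, 1e4,
                   config = ld_config(n_snps = Inf, min_scaffold_length = 0))
  expect_equal(nrow(bins), 10)
  expect_equal(bins$bin_low, seq(0, 9e4, 1e4))
  nz <- bins[bins$n_pairs > 0, ]
  expect_true(all(nz$median_distance >= nz$bin_low &
                    nz$median_distance <= nz$bin_high))
  expect_error(
    ld_decay(gm, 1e5, 3e4,
             config = ld_config(n_snps = Inf, min_scaffold_length = 0)),
    "divide"
  )
})

test_that("unlinked loci give flat decay curves", {
  # loci on distinct scaffolds interleaved -> same-scaffold pairs only,
  # all independent; bin means should not differ systematically
  means <- sapply(1:5, function(s) {
    gm <- sim_hw_genotypes(40, 100, spacing = 2e5, n_scaffolds = 2, seed = s)
    bins <- ld_decay(gm, 2e7, 4e6,
                     config = ld_config(n_snps = Inf, min_scaffold_length = 0))
    bins$mean_r2
  })
  m <- rowMeans(means)
  expect_lt(max(m) - min(m), 0.02)
})

test_that("group-restricted LD recomputes frequencies within the group", {
  # locus pair monomorphic in group A but polymorphic overall is skipped
  d <- rbind(
    matrix(0L, 10, 2),
    cbind(rbinom(10, 2, 0.5), rbinom(10, 2, 0.5))
  )
  gm <- gm_from_dosage(d)
  meta <- meta_for(gm, group = rep(c("A", "B"), each = 10))
  expect_error(adjacent_r2(gm, meta, group = "A"), "usable")
})

test_that("LD-decay SNP subsampling is seeded and restricted to long scaffolds", {
  gm <- sim_hw_genotypes(10, 200, spacing = 1e4, n_scaffolds = 3, seed = 61)
  # scaffold spans are ~2 Mb; min length 3 Mb excludes everything
  expect_error(
    ld_decay(gm, 1e5, 1e4, config = ld_config(min_scaffold_length = 3e6)),
    "min_scaffold_length"
  )
  cfg <- ld_config(n_snps = 150, min_scaffold_length = 0, seed = 5)
  b1 <- ld_decay(gm, 1e5, 1e4, config = cfg)
  b2 <- ld_decay(gm, 1e5, 1e4, config = cfg)
  expect_identical(b1, b2)
})
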