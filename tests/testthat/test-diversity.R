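test_that("group MAF and heterozygosity follow their definitions", {
  # every variant has dosages {0, 0, 2, 2}: MAF 0.5, zero heterozygotes
  d <- matrix(rep(c(0L, 0L, 2L, 2L), 6), nrow = 4)
  gm <- gm_from_dosage(d)
  res <- group_maf_het(gm, meta_for(gm), "g1")
  expect_equal(res$mean_maf, 0.5)
  expect_equal(res$het_pct, 0)

  # a fully heterozygous sample scores 100%
  gm1 <- gm_from_dosage(matrix(1L, nrow = 1, ncol = 8))
  expect_equal(group_maf_het(gm1, meta_for(gm1), "g1")$het_pct, 100)
})

test_that("group mean MAF recovers the truth-record frequencies", {
  sim <- sim_structured(c(A = 40), fst = 0.02, n_loci = 10000, seed = 31)
  est <- group_maf_het(sim$gm, sim$metadata, "A")$mean_maf
  truth <- mean(pmin(sim$truth$pop_freq[, 1], 1 - sim$truth$pop_freq[, 1]))
  expect_lt(abs(est - truth), 0.005)
})

test_that("F_HOM hits its algebraic anchors", {
  # 40 samples, exact frequency 0.5 at every variant; sample 1 all het.
  n <- 40
  m <- 30
  d <- matrix(rep(c(0L, 2L), each = 1, times = n / 2 * m), nrow = n)
  d[seq(2, n, 2), ] <- 2L
  d[seq(1, n, 2), ] <- 0L
  d[1, ] <- 1L
  d[2, ] <- 1L # keep p = 0.5: samples 1,2 het, 19 hom-ref, 19 hom-alt
  gm <- gm_from_dosage(d)
  p <- variant_freq(gm)
  expect_true(all(p == 0.5))
  fh <- f_hom(gm)
  # closed form: E_hom_j = 1 - 0.5 * 2N/(2N-1); F = (0 - mE)/(m - mE)
  e_hom <- 1 - 2 * 0.5 * 0.5 * (2 * n) / (2 * n - 1)
  expect_equal(fh$f_hom[1], (0 - m * e_hom) / (m - m * e_hom))
  expect_lt(fh$f_hom[1], -0.9) # approaches -1 with large N
  # an all-homozygous sample scores exactly 1
  expect_equal(fh$f_hom[3], 1)
})

test_that("F_HOM is centred at 0 under Hardy-Weinberg and scale-invariant", {
  gm <- sim_hw_genotypes(20, 4000, seed = 17)
  fh <- f_hom(gm)
  expect_lt(abs(mean(fh$f_hom)), 0.02)
  # duplicating every variant (fresh coordinates) leaves F_HOM unchanged
  dd <- cbind(gm$dosage, gm$dosage)
  gm2 <- geno_matrix(
    dd,
    variants = data.frame(
      scaffold = rep(c("scaf1", "scaf2"), each = n_variants(gm)),
      pos = rep(gm$variants$pos, 2), ref = "A", alt = "G"
    ),
    samples = gm$samples
  )
  expect_equal(f_hom(gm2)$f_hom, fh$f_hom)
})

test_that("tabular F_PED matches path counting on designed and random pedigrees", {
  # parent-offspring mating: offspring of (sire x daughter) has F = 0.25
  ped <- tibble::tibble(
    individual = c("A", "B", "C", "X"),
    sire = c(NA, NA, "A", "A"),
    dam = c(NA, NA, "B", "C"),
    generation = c(0, 0, 1, 2)
  )
  expect_equal(f_ped(ped, "X")$f_ped, 0.25)
  expect_equal(f_ped(ped, c("A", "B", "C"))$f_ped, c(0, 0, 0))

  for (s in 1:3) {
    rp <- sim_pedigree(founders = 6, depth = 4, scheme = "random", seed = s)
    got <- f_ped(rp)
    oracle <- vapply(rp$individual, function(i) path_counting_f(rp, i), 0)
    expect_equal(got$f_ped, unname(oracle))
  }
  expect_error(f_ped(ped, "nope"), "not in pedigree")
  cyc <- tibble::tibble(individual = c("a", "b"), sire = c("b", "a"),
                        dam = c(NA, NA))
  expect_error(f_ped(cyc), "cycle")
})

test_that("inbreeding correlations are Pearson, pairwise-complete, and flag zero variance", {
  x <- rnorm(50)
  tab <- tibble::tibble(sample = paste0("s", 1:50),
                        f_hom = x, f_roh = x, f_ped = rnorm(50))
  res <- inbreeding_correlations(tab)
  expect_equal(res$r[res$measure_a == "f_hom" & res$measure_b == "f_roh"], 1)
  set.seed(99)
  big <- tibble::tibble(a = rnorm(1000), b = rnorm(1000))
  expect_lt(abs(inbreeding_correlations(big)$r), 0.07)
  expect_warning(
    res0 <- inbreeding_correlations(tibble::tibble(a = rep(1, 5), b = rnorm(5))),
    "zero variance"
  )
  expect_true(is.na(res0$r))
})

test_that("pedigree-driven inbreeding contrast shows up in genomic F_HOM", {
  # inbred line: planted autozygosity raises homozygosity -> higher F_HOM
  gm <- sim_hw_genotypes(20, 1500, spacing = 1e4, seed = 41)
  tracts <- tibble::tibble(
    sample = paste0("s", 1:10), scaffold = "scaf1",
    start = 1e6, end = 8e6
  )
  gm <- plant_roh(gm, tracts)
  f_true <- c(rep(8e6 / 15e6, 10), rep(0, 10))
  fh <- f_hom(gm)
  expect_gt(cor(fh$f_hom, f_true), 0.5)
})
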