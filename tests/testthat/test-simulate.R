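test_that("generators are reproducible under a fixed seed", {
  a <- sim_structured(c(A = 10, B = 10), fst = 0.1, n_loci = 100, seed = 5)
  b <- sim_structured(c(A = 10, B = 10), fst = 0.1, n_loci = 100, seed = 5)
  expect_identical(a$gm$dosage, b$gm$dosage)
  expect_identical(a$truth$pop_freq, b$truth$pop_freq)
  w1 <- sim_wright_fisher(20, 10, 1e6, 1e-8, 10, 50, seed = 5)
  w2 <- sim_wright_fisher(20, 10, 1e6, 1e-8, 10, 50, seed = 5)
  expect_identical(w1$gm$dosage, w2$gm$dosage)
})

test_that("Balding-Nichols realized differentiation converges to the target Fst", {
  th <- vapply(1:3, function(s) {
    sim <- sim_structured(c(A = 50, B = 50), fst = 0.1, n_loci = 20000,
                          seed = s)
    wc_fst(sim$gm, sim$metadata)
  }, 0)
  expect_lt(abs(mean(th) - 0.1), 0.02)
})

test_that("without structure the allele-frequency spread is binomial sampling only", {
  # K = 1, tiny Fst: across replicate draws of one group, the realized
  # frequency variance at a locus should match p(1-p)/2n.
  sims <- lapply(1:60, function(s) {
    sim_structured(c(A = 25), fst = 1e-4, K = 1, n_loci = 50,
                   maf_range = c(0.3, 0.3001), seed = 1000 + s)
  })
  freqs <- vapply(sims, function(s) variant_freq(s$gm), numeric(50))
  v <- mean(apply(freqs, 1, var))
  expect_lt(abs(v - 0.3 * 0.7 / 50), 0.002)
})

test_that("admixed offspring group sits between its parent groups", {
  adm <- rbind(c(1, 0), c(0, 1), c(0.5, 0.5))
  sim <- sim_structured(
    c(A = 30, B = 30, AB = 30), fst = c(0.15, 0.15), K = 2,
    admixture = adm, n_loci = 5000, seed = 8
  )
  d_ab <- nei_distance(sim$gm, sim$metadata, "A", "B")
  d_a_mix <- nei_distance(sim$gm, sim$metadata, "A", "AB")
  d_b_mix <- nei_distance(sim$gm, sim$metadata, "B", "AB")
  expect_lt(d_a_mix, d_ab)
  expect_lt(d_b_mix, d_ab)
})

test_that("one generation of drift has variance p(1-p)/(2Ne)", {
  ne <- 50
  p0 <- 0.4
  reps <- vapply(1:1000, function(s) {
    with(sim_wright_fisher(
      ne = ne, n_generations = 1, chrom_length = 1e5, recomb_rate = 0,
      sample_size = ne, n_loci = 1, init_freq_range = c(p0, p0),
      drop_fixed = FALSE, seed = s
    ), mean(gm$dosage) / 2)
  }, 0)
  # variance of the change beyond the initial binomial draw of gen 0
  # total variance after init + 1 WF generation = p(1-p)/(2Ne) * 2
  v_expected <- 2 * p0 * (1 - p0) / (2 * ne)
  expect_lt(abs(var(reps) - v_expected), 0.2 * v_expected)
})

test_that("zero recombination drives all pairs toward a common r2 plateau", {
  sim <- sim_wright_fisher(
    ne = 30, n_generations = 120, chrom_length = 1e6, recomb_rate = 0,
    sample_size = 30, n_loci = 60, seed = 21
  )
  gm <- apply_filters(sim$gm, filter_spec(min_maf = 0.1, min_qual = NULL))
  bins <- ld_decay(gm, 1e6, 2e5,
                   config = ld_config(n_snps = Inf, min_scaffold_length = 0))
  usable <- bins[bins$n_pairs > 5, ]
  expect_gt(min(usable$mean_r2), 0.25) # high LD at every distance
  expect_lt(max(usable$mean_r2) - min(usable$mean_r2), 0.35)
})

test_that("planted tracts are homozygous, error-injected, and otherwise inert", {
  gm0 <- sim_hw_genotypes(4, 400, spacing = 1e4, seed = 3)
  tract <- data.frame(sample = "s1", scaffold = "scaf1",
                      start = 1e6, end = 3e6)
  gm1 <- plant_roh(gm0, tract)
  in_tract <- gm1$variants$pos >= 1e6 & gm1$variants$pos <= 3e6
  expect_true(all(gm1$dosage["s1", in_tract] %in% c(0L, 2L)))
  expect_identical(gm1$dosage["s1", !in_tract], gm0$dosage["s1", !in_tract])
  expect_identical(gm1$dosage["s2", ], gm0$dosage["s2", ])

  het_frac <- vapply(1:40, function(s) {
    g <- plant_roh(gm0, tract, error_rate = 0.05, seed = s)
    mean(g$dosage["s1", in_tract] == 1L)
  }, 0)
  expect_lt(abs(mean(het_frac) - 0.05), 0.01)

  expect_identical(plant_roh(gm0, tract[0, ])$dosage, gm0$dosage)
  expect_error(
    plant_roh(gm0, data.frame(sample = "s1", scaffold = "scaf1",
                              start = c(1e6, 2e6), end = c(2.5e6, 3e6))),
    "overlapping"
  )
})

test_that("designed pedigrees carry their textbook inbreeding coefficients", {
  fs <- sim_pedigree(founders = 4, scheme = "full-sib")
  expect_equal(fs$f_expected[fs$generation == 2], rep(0.25, 2))
  expect_equal(fs$f_expected[fs$generation == 0], rep(0, 4))
  hs <- sim_pedigree(founders = 6, scheme = "half-sib")
  expect_equal(hs$f_expected[hs$generation == 2], rep(0.125, 2))
  expect_error(sim_pedigree(founders = 1), "founders")
  # tabular method agrees with the design values
  expect_equal(f_ped(fs)$f_ped, fs$f_expected)
  expect_equal(f_ped(hs)$f_ped, hs$f_expected)
})
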