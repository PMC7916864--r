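test_that("a fully heterozygous sample yields no segments", {
  gm <- gm_from_dosage(matrix(1L, nrow = 1, ncol = 100))
  expect_equal(nrow(detect_roh(gm, params = roh_params(min_length = 0))), 0)
})

test_that("a planted tract is recovered with tight boundaries", {
  gm0 <- sim_hw_genotypes(3, 1000, spacing = 1e4, seed = 13) # 10 Mb scaffold
  tract <- data.frame(sample = "s1", scaffold = "scaf1",
                      start = 3e6, end = 5e6)
  gm <- plant_roh(gm0, tract)
  segs <- detect_roh(gm, samples = "s1")
  expect_equal(nrow(segs), 1)
  span <- c(max(segs$start, tract$start), min(segs$end, tract$end))
  overlap <- span[2] - span[1] + 1
  expect_gt(overlap / (tract$end - tract$start + 1), 0.95)
  expect_lt(tract$start - segs$start, 1e5) # limited spill beyond the tract
  expect_lt(segs$end - tract$end, 1e5)
})

test_that("one heterozygote splits a run when the window error budget is zero", {
  # hand-built: 200 homozygous SNPs with a single het in the middle
  d <- matrix(0L, nrow = 1, ncol = 200)
  d[1, 100] <- 1L
  gm <- gm_from_dosage(d, spacing = 1e4)
  segs <- detect_roh(gm, params = roh_params(min_snps = 20, error_rate = 0.01,
                                             min_length = 0))
  # budget floor(0.01 * 20) = 0, so windows containing SNP 100 all fail
  expect_equal(nrow(segs), 2)
  expect_equal(segs$start, c(1e4, 101e4))
  expect_equal(segs$end, c(99e4, 200e4))
  # a larger budget bridges the het
  segs2 <- detect_roh(gm, params = roh_params(min_snps = 20, error_rate = 0.05,
                                              min_length = 0))
  expect_equal(nrow(segs2), 1)
})

test_that("missing calls are non-informative and do not break runs", {
  d <- matrix(0L, nrow = 1, ncol = 100)
  d[1, seq(10, 90, 10)] <- NA
  gm <- gm_from_dosage(d, spacing = 1e4)
  segs <- detect_roh(gm, params = roh_params(min_length = 0))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 100)
})

test_that("detection ignores REF/ALT labelling and scaffolds shorter than a window", {
  d <- matrix(rep(c(0L, 2L), 60), nrow = 1)
  gm <- gm_from_dosage(d, spacing = 1e4)
  segs_a <- detect_roh(gm, params = roh_params(min_length = 0))
  flipped <- gm
  flipped$dosage <- 2L - flipped$dosage
  segs_b <- detect_roh(flipped, params = roh_params(min_length = 0))
  expect_equal(segs_a, segs_b)

  tiny <- gm_from_dosage(matrix(0L, nrow = 1, ncol = 5))
  expect_equal(nrow(detect_roh(tiny)), 0)
})

test_that("F_ROH follows the definition and is monotone in the threshold", {
  segs <- tibble::tibble(
    sample = "s1", scaffold = "scaf1",
    start = 1, end = 80.2e6, n_snps = 1000, length = 80.2e6
  )
  expect_equal(f_roh(segs, 802e6, thresholds = 5e5)$f_roh, 0.1)
  expect_equal(f_roh(segs[0, ], 802e6, samples = "s1")$f_roh, rep(0, 3))

  gm0 <- sim_hw_genotypes(4, 3000, spacing = 1e4, seed = 29) # 30 Mb
  tracts <- tibble::tibble(
    sample = c("s1", "s1", "s2"), scaffold = "scaf1",
    start = c(2e6, 10e6, 5e6), end = c(2e6 + 8e5 - 1, 10e6 + 2.5e6 - 1, 5e6 + 6e5 - 1)
  )
  gm <- plant_roh(gm0, tracts)
  segs2 <- detect_roh(gm)
  span <- max(gm$variants$pos) - min(gm$variants$pos) + 1
  fr <- f_roh(segs2, span, samples = gm$samples)
  wide <- tidyr::pivot_wider(fr, id_cols = "sample",
                             names_from = "threshold", values_from = "f_roh")
  expect_true(all(wide$`5e+05` >= wide$`1e+06`))
  expect_true(all(wide$`1e+06` >= wide$`2e+06`))
  # planted fractions recovered at the 500 kb threshold
  planted_s1 <- (8e5 + 2.5e6) / span
  expect_lt(abs(wide$`5e+05`[wide$sample == "s1"] - planted_s1), 0.01)
  # only the 2.5 Mb tract survives the 2 Mb threshold
  expect_lt(abs(wide$`2e+06`[wide$sample == "s1"] - 2.5e6 / span), 0.01)
  expect_equal(wide$`2e+06`[wide$sample == "s3"], 0)

  expect_error(f_roh(segs, 1e6), "longer than callable")
})

test_that("segments for one sample never overlap after union-merging", {
  for (s in 1:5) {
    gm <- plant_roh(
      sim_hw_genotypes(2, 2000, spacing = 1e4, seed = s),
      data.frame(sample = "s1", scaffold = "scaf1",
                 start = c(1e6, 9e6), end = c(3e6, 12e6))
    )
    segs <- detect_roh(gm, samples = "s1")
    segs <- segs[order(segs$start), ]
    if (nrow(segs) > 1) {
      expect_true(all(segs$start[-1] > segs$end[-nrow(segs)]))
    }
  }
})
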