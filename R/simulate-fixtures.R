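#' Plant autozygous tracts into a genotype matrix
#'
#' Forces the genotypes of chosen samples to be homozygous within given
#' genomic tracts, emulating autozygosity. Within a tract every SNP is set
#' to the homozygote of the sample's scaffold-wide major allele (so allele
#' frequencies are disturbed as little as possible); with probability
#' `error_rate` a SNP is instead set heterozygous, emulating genotyping
#' error inside a true autozygous segment. Genotypes outside the tracts are
#' untouched.
#'
#' @param gm A [geno_matrix()].
#' @param tracts Data frame with columns `sample`, `scaffold`, `start`,
#'   `end` (bp, inclusive). Tracts must not overlap within a sample.
#' @param error_rate Per-SNP heterozygote injection probability in `[0, 0.5)`.
#' @param seed Integer seed (used only when `error_rate > 0`).
#' @return The modified [geno_matrix()].
#' @export
plant_roh <- function(gm, tracts, error_rate = 0, seed = NULL) {
  if (nrow(tracts) == 0) {
    return(gm)
  }
  if (!all(c("sample", "scaffold", "start", "end") %in% names(tracts))) {
    abort("tracts must have columns sample, scaffold, start, end")
  }
  split_tracts <- split(tracts, tracts$sample)
  for (tt in split_tracts) {
    tt <- tt[order(tt$scaffold, tt$start), ]
    by_scaf <- split(tt, tt$scaffold)
    for (sc in by_scaf) {
      if (nrow(sc) > 1 && any(sc$start[-1] <= sc$end[-nrow(sc)])) {
        abort(paste0("overlapping tracts for sample ", sc$sample[1]))
      }
    }
  }
  with_seed(seed, {
    d <- gm$dosage
    for (r in seq_len(nrow(tracts))) {
      i <- sample_index(gm, tracts$sample[r])
      on_scaf <- gm$variants$scaffold == tracts$scaffold[r]
      if (!any(on_scaf)) abort(paste0("unknown scaffold: ", tracts$scaffold[r]))
      in_tract <- on_scaf &
        gm$variants$pos >= tracts$start[r] & gm$variants$pos <= tracts$end[r]
      if (!any(in_tract)) next
      # sample's major allele on this scaffold decides the homozygote class
      mean_d <- mean(d[i, on_scaf], na.rm = TRUE)
      hom <- if (!is.nan(mean_d) && mean_d > 1) 2L else 0L
      vals <- rep(hom, sum(in_tract))
      if (error_rate > 0) {
        vals[runif(length(vals)) < error_rate] <- 1L
      }
      d[i, in_tract] <- vals
    }
    geno_matrix(d, gm$variants, samples = gm$samples, qual = gm$qual)
  })
}

#' Simulate an unstructured Hardy-Weinberg panel on an evenly spaced map
#'
#' Dense evenly spaced SNPs on one or more scaffolds with genotypes drawn
#' independently per locus as `Binomial(2, p)`, `p` uniform in `maf_range`.
#' No LD and no structure: a neutral background for planting autozygous
#' tracts ([plant_roh()]) or calibrating null distributions.
#'
#' @param n_samples Diploid samples.
#' @param n_snps SNPs per scaffold.
#' @param spacing Inter-SNP distance in bp.
#' @param maf_range Allele-frequency sampler range.
#' @param n_scaffolds Number of scaffolds.
#' @param seed Integer seed.
#' @return A [geno_matrix()] (samples `s1..sN`, scaffolds `scaf1..`).
#' @export
sim_hw_genotypes <- function(n_samples, n_snps, spacing = 1e4,
                             maf_range = c(0.2, 0.5), n_scaffolds = 1,
                             seed = NULL) {
  with_seed(seed, {
    total <- n_snps * n_scaffolds
    p <- runif(total, maf_range[1], maf_range[2])
    dosage <- matrix(
      rbinom(n_samples * total, 2, rep(p, each = n_samples)),
      nrow = n_samples
    )
    geno_matrix(
      dosage,
      variants = tibble::tibble(
        scaffold = rep(paste0("scaf", seq_len(n_scaffolds)), each = n_snps),
        pos = rep(as.integer(seq_len(n_snps) * spacing), n_scaffolds),
        ref = "A", alt = "G"
      ),
      samples = paste0("s", seq_len(n_samples))
    )
  })
}

#' Simulate a designed pedigree with known inbreeding coefficients
#'
#' Builds a pedigree from unrelated founders under one of three mating
#' schemes and records, for each individual, the inbreeding coefficient
#' implied by the design. `"full-sib"` mates pairs of founders and then a
#' full-sib pair from each family (offspring F = 0.25); `"half-sib"` mates
#' one sire to two dams and then a half-sib pair (offspring F = 0.125);
#' `"random"` mates randomly chosen non-identical parents from the previous
#' generation (first-generation offspring of unrelated founders have F = 0;
#' deeper random pedigrees get their exact F from the tabular method, see
#' [f_ped()]).
#'
#' @param founders Number of founder individuals (>= 2; even for the
#'   designed schemes).
#' @param depth Number of generations bred below the founders (>= 1;
#'   `"full-sib"`/`"half-sib"` designs use 2).
#' @param scheme One of `"random"`, `"full-sib"`, `"half-sib"`.
#' @param seed Integer seed (used by `"random"` only).
#' @return A tibble with columns `individual`, `sire`, `dam`, `generation`
#'   and `f_expected` (the design's analytically known inbreeding
#'   coefficient, `NA` where the design does not pin it down).
#' @export
#'
#' @examples
#' sim_pedigree(founders = 4, scheme = "full-sib")
sim_pedigree <- function(founders = 4, depth = 2,
                         scheme = c("random", "full-sib", "half-sib"),
                         seed = NULL) {
  scheme <- match.arg(scheme)
  if (founders < 2) abort("founders must be >= 2")
  ped <- tibble::tibble(
    individual = paste0("F", seq_len(founders)),
    sire = NA_character_, dam = NA_character_,
    generation = 0L, f_expected = 0
  )
  if (scheme == "full-sib") {
    n_fam <- founders %/% 2
    for (fam in seq_len(n_fam)) {
      s <- paste0("F", 2 * fam - 1)
      d <- paste0("F", 2 * fam)
      kids <- paste0("G1_", fam, "_", 1:2)
      ped <- dplyr::bind_rows(ped, tibble::tibble(
        individual = kids, sire = s, dam = d, generation = 1L, f_expected = 0
      ))
      ped <- dplyr::bind_rows(ped, tibble::tibble(
        individual = paste0("G2_", fam), sire = kids[1], dam = kids[2],
        generation = 2L, f_expected = 0.25
      ))
    }
  } else if (scheme == "half-sib") {
    n_fam <- founders %/% 3
    if (n_fam < 1) abort("half-sib scheme needs >= 3 founders")
    for (fam in seq_len(n_fam)) {
      s <- paste0("F", 3 * fam - 2)
      dams <- paste0("F", 3 * fam - c(1, 0))
      kids <- paste0("G1_", fam, "_", 1:2)
      ped <- dplyr::bind_rows(ped, tibble::tibble(
        individual = kids, sire = s, dam = dams, generation = 1L, f_expected = 0
      ))
      ped <- dplyr::bind_rows(ped, tibble::tibble(
        individual = paste0("G2_", fam), sire = kids[1], dam = kids[2],
        generation = 2L, f_expected = 0.125
      ))
    }
  } else {
    with_seed(seed, {
      prev <- ped$individual
      for (g in seq_len(depth)) {
        n_off <- max(2, length(prev))
        sires <- sample(prev, n_off, replace = TRUE)
        dams <- vapply(sires, function(s) sample(setdiff(prev, s), 1), "")
        kids <- paste0("G", g, "_", seq_len(n_off))
        f_exp <- if (g == 1) 0 else NA_real_
        ped <- dplyr::bind_rows(ped, tibble::tibble(
          individual = kids, sire = sires, dam = unname(dams),
          generation = g, f_expected = f_exp
        ))
        prev <- kids
      }
    })
  }
  ped
}
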