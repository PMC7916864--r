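#' Forward Wright-Fisher simulation with recombination
#'
#' Simulates `2 * ne` haplotypes of one chromosome forward in time for
#' `n_generations` under random union of gametes. Each gamete is formed from
#' a randomly chosen parent; the number of crossovers is Poisson with mean
#' `chrom_length * recomb_rate` (the map length in Morgans) and crossover
#' points are uniform on the chromosome. Initial haplotypes carry `n_loci`
#' independent loci at frequencies drawn uniformly from `init_freq_range`,
#' at positions uniform on the chromosome, so all LD observed at the end is
#' generated by drift and broken by recombination -- the ground truth for
#' LD-based effective-population-size estimation.
#'
#' @param ne Diploid effective population size (>= 2).
#' @param n_generations Generations to evolve.
#' @param chrom_length Chromosome length in base pairs.
#' @param recomb_rate Recombination rate in Morgans per base pair
#'   (1 cM/Mb = 1e-8).
#' @param sample_size Diploid individuals sampled (without replacement) from
#'   the final generation.
#' @param n_loci Segregating loci at generation 0.
#' @param init_freq_range Range of initial allele frequencies.
#' @param drop_fixed Drop loci fixed in the final sample (default `TRUE`).
#' @param seed Integer seed.
#'
#' @return A list with `gm` (a [geno_matrix()] on scaffold `"chr1"`) and
#'   `truth` (list with `ne`, `n_generations`, `map_length_morgans`, and the
#'   per-locus initial frequencies `init_freq`). Errors if every locus fixes
#'   before sampling.
#' @export
#'
#' @examples
#' sim <- sim_wright_fisher(
#'   ne = 50, n_generations = 20, chrom_length = 1e6,
#'   recomb_rate = 1e-8, sample_size = 20, n_loci = 100, seed = 7
#' )
#' sim$gm
sim_wright_fisher <- function(ne, n_generations, chrom_length, recomb_rate,
                              sample_size, n_loci,
                              init_freq_range = c(0.1, 0.9),
                              drop_fixed = TRUE, seed = NULL) {
  if (ne < 2) abort("ne must be >= 2")
  if (recomb_rate < 0) abort("recomb_rate must be >= 0")
  if (sample_size > ne) abort("sample_size cannot exceed ne")
  with_seed(seed, {
    pos <- sort(sample.int(chrom_length, n_loci))
    freq0 <- runif(n_loci, init_freq_range[1], init_freq_range[2])
    H <- matrix(
      rbinom(2 * ne * n_loci, 1, rep(freq0, each = 2 * ne)) == 1L,
      nrow = 2 * ne, ncol = n_loci
    )
    map_length <- chrom_length * recomb_rate

    for (gen in seq_len(n_generations)) {
      parent <- sample.int(ne, 2 * ne, replace = TRUE)
      n_xo <- rpois(2 * ne, map_length)
      which_hap <- sample.int(2, 2 * ne, replace = TRUE)
      # non-recombinant gametes: plain copies of one parental haplotype
      plain <- n_xo == 0
      src <- 2L * parent - 2L + which_hap
      Hnew <- H[src, , drop = FALSE]
      for (g in which(!plain)) {
        cuts <- sort(runif(n_xo[g], 0, chrom_length))
        seg <- findInterval(pos, cuts)
        use_first <- (seg + which_hap[g]) %% 2L == 0L
        h1 <- H[2L * parent[g] - 1L, ]
        h2 <- H[2L * parent[g], ]
        Hnew[g, ] <- ifelse(use_first, h1, h2)
      }
      H <- Hnew
    }

    ind <- sample.int(ne, sample_size)
    dosage <- H[2L * ind - 1L, , drop = FALSE] + H[2L * ind, , drop = FALSE]
    if (drop_fixed) {
      keep <- colSums(dosage) > 0 & colSums(dosage) < 2 * sample_size
      if (!any(keep)) {
        abort("all loci fixed before sampling; increase n_loci or reduce n_generations")
      }
      dosage <- dosage[, keep, drop = FALSE]
      pos <- pos[keep]
      freq0 <- freq0[keep]
    }
    gm <- geno_matrix(
      dosage,
      variants = tibble::tibble(
        scaffold = "chr1", pos = as.integer(pos), ref = "A", alt = "G"
      ),
      samples = paste0("ind", seq_len(sample_size))
    )
    list(gm = gm, truth = list(
      ne = ne, n_generations = n_generations,
      map_length_morgans = map_length, init_freq = freq0
    ))
  })
}
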