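#' Composite (Burrows) disequilibrium from unphased genotypes
#'
#' Unbiased estimator of the gametic disequilibrium `D` computable without
#' haplotype phase, from the 3x3 joint table of genotype classes at two
#' loci:
#' `D = N/(N-1) * ( (4 n_AABB + 2 n_AABb + 2 n_AaBB + n_AaBb) / (2N) - 2 p_A p_B )`
#' where rows/columns of `counts` index the ALT-allele dosage (0, 1, 2) at
#' each locus, `N` is the table total and `p_A`, `p_B` are the ALT allele
#' frequencies. The bracketed term sums gametic plus non-gametic
#' (cross-gamete, within-individual) allele associations; under random
#' union of gametes the non-gametic part has expectation zero, so the
#' composite estimates the gametic `D`. On phased-equivalent data (no
#' double heterozygotes) the realized non-gametic association equals the
#' gametic one, so the estimator equals exactly `2 N/(N-1)` times the
#' haplotype-count `D` -- an exact algebraic identity used as a test
#' oracle.
#'
#' @param counts 3x3 numeric matrix of genotype-pair counts; `counts[i, j]`
#'   is the number of samples with dosage `i-1` at locus A and `j-1` at
#'   locus B.
#' @return The composite D estimate (scalar). Errors if `N < 2` or either
#'   locus is monomorphic in the table.
#' @export
#'
#' @examples
#' # two AABB and two aabb samples
#' tab <- matrix(0, 3, 3)
#' tab[3, 3] <- 2; tab[1, 1] <- 2
#' composite_d(tab)
composite_d <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(3, 3))) abort("counts must be a 3x3 table")
  n <- sum(counts)
  if (n < 2) abort("need at least 2 samples")
  da <- rep(0:2, times = 3)
  db <- rep(0:2, each = 3)
  cnt <- as.vector(counts)
  p_a <- sum(cnt * da) / (2 * n)
  p_b <- sum(cnt * db) / (2 * n)
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1) {
    abort("monomorphic locus: composite D undefined")
  }
  (n / (n - 1)) * (sum(cnt * da * db) / (2 * n) - 2 * p_a * p_b)
}

# Vectorised composite-D r2 for aligned dosage vector pairs.
# xi, xj: matrices (samples x npairs); returns corrected r2 per pair (NA for
# monomorphic or <2 shared samples). Used by adjacent_r2 and the pair engine.
r2_pairs_aligned <- function(xi, xj) {
  ok <- !is.na(xi) & !is.na(xj)
  n <- colSums(ok)
  xi0 <- xi
  xj0 <- xj
  xi0[!ok] <- 0L
  xj0[!ok] <- 0L
  sx <- colSums(xi0)
  sy <- colSums(xj0)
  sxy <- colSums(xi0 * xj0)
  p_a <- sx / (2 * n)
  p_b <- sy / (2 * n)
  d <- (n / (n - 1)) * (sxy / (2 * n) - 2 * p_a * p_b)
  r2 <- d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  r2c <- correct_r2(r2, 2 * n)
  bad <- n < 2 | p_a <= 0 | p_a >= 1 | p_b <= 0 | p_b >= 1
  r2c[bad] <- NA_real_
  unname(r2c)
}

#' Sample-size correction for composite r2
#'
#' `r2_corrected = (r2 - 1/n) / (1 - 1/n)` with `n` the number of sampled
#' haplotypes (twice the diploid count used for the pair), then clamped to
#' `[0, 1]`. `r2 = 1` is a fixed point and `r2 = 1/n` maps to 0.
#'
#' @param r2 Uncorrected r2 value(s).
#' @param n_haplotypes Number of sampled haplotypes.
#' @return Corrected r2 in `[0, 1]`.
#' @export
correct_r2 <- function(r2, n_haplotypes) {
  out <- (r2 - 1 / n_haplotypes) / (1 - 1 / n_haplotypes)
  pmin(pmax(out, 0), 1)
}

#' r2 between two variants of a genotype matrix
#'
#' Composite-D based squared correlation for one variant pair: `r2 =
#' D^2 / (p_A p_a p_B p_b)` with [composite_d()] computed over the samples
#' non-missing at both loci, followed by the haplotype-sample-size
#' correction of [correct_r2()]. Both variants must lie on the same
#' scaffold and be polymorphic among the shared samples.
#'
#' @param gm A [geno_matrix()].
#' @param i,j Variant indices (columns of `gm$dosage`).
#' @param samples Optional sample subset.
#' @return A one-row tibble: `i`, `j`, `distance`, `r2`, `n_samples`.
#' @export
pair_r2 <- function(gm, i, j, samples = NULL) {
  v <- gm$variants
  if (v$scaffold[i] != v$scaffold[j]) abort("variants must share a scaffold")
  d <- gm$dosage
  if (!is.null(samples)) d <- d[sample_index(gm, samples), , drop = FALSE]
  xi <- d[, i]
  xj <- d[, j]
  ok <- !is.na(xi) & !is.na(xj)
  if (sum(ok) < 2) abort("fewer than 2 shared non-missing samples")
  r2 <- r2_pairs_aligned(cbind(xi), cbind(xj))
  tibble::tibble(
    i = i, j = j, distance = abs(v$pos[j] - v$pos[i]),
    r2 = r2, n_samples = sum(ok)
  )
}

#' LD between adjacent SNPs
#'
#' Computes the corrected composite r2 between each pair of consecutive
#' SNPs along every scaffold, using only the given group's samples (allele
#' frequencies are recomputed within the group; pairs monomorphic in the
#' group are skipped). Results are invariant to sample order.
#'
#' @param gm A [geno_matrix()].
#' @param metadata Optional metadata; with `group` selects that group's
#'   samples, otherwise all samples are used.
#' @param group Optional group label.
#' @param by Metadata column holding the label.
#' @return A one-row tibble: `group`, `n_pairs`, `mean_r2`, `sd_r2`,
#'   `mean_distance`.
#' @export
adjacent_r2 <- function(gm, metadata = NULL, group = NULL, by = "group") {
  ids <- if (is.null(group)) gm$samples else {
    metadata$sample[metadata[[by]] == group]
  }
  d <- gm$dosage[sample_index(gm, ids), , drop = FALSE]
  vi <- seq_len(n_variants(gm))
  same_scaf <- gm$variants$scaffold[-1] == gm$variants$scaffold[-length(vi)]
  i_idx <- vi[-length(vi)][same_scaf]
  j_idx <- vi[-1][same_scaf]
  if (length(i_idx) == 0) abort("need >= 2 SNPs on at least one scaffold")
  r2 <- r2_pairs_aligned(d[, i_idx, drop = FALSE], d[, j_idx, drop = FALSE])
  dist <- gm$variants$pos[j_idx] - gm$variants$pos[i_idx]
  ok <- !is.na(r2)
  if (sum(ok) < 2) abort("fewer than 2 usable adjacent pairs")
  tibble::tibble(
    group = group %||% "all",
    n_pairs = sum(ok),
    mean_r2 = mean(r2[ok]),
    sd_r2 = sd(r2[ok]),
    mean_distance = mean(dist[ok])
  )
}

#' LD analysis configuration
#'
#' Defaults mirror the standard whole-genome workflow: subsample 100,000
#' SNPs restricted to scaffolds of at least 10 Mb, assume 1 cM/Mb, and
#' report effective population size at 200, 150, 100, 50, 10 and 5
#' generations ago.
#'
#' @param n_snps SNPs to subsample (without replacement) before pair
#'   formation; `Inf` keeps everything.
#' @param min_scaffold_length Scaffolds shorter than this (bp span observed
#'   or declared) are excluded.
#' @param recomb_rate_cm_mb Recombination rate in cM per Mb.
#' @param generations Generations ago at which to report Ne.
#' @param seed Integer seed for the SNP subsample.
#' @return A list of class `ld_config`.
#' @export
ld_config <- function(n_snps = 1e5, min_scaffold_length = 1e7,
                      recomb_rate_cm_mb = 1,
                      generations = c(200, 150, 100, 50, 10, 5),
                      seed = NULL) {
  structure(
    list(
      n_snps = n_snps, min_scaffold_length = min_scaffold_length,
      recomb_rate_cm_mb = recomb_rate_cm_mb,
      generations = generations, seed = seed
    ),
    class = "ld_config"
  )
}

#' Distance-binned LD decay
#'
#' After optional SNP subsampling (seeded, restricted to scaffolds of at
#' least `min_scaffold_length` bp span), computes the corrected composite
#' r2 for all same-scaffold variant pairs with distance at most
#' `max_distance`, assigns pairs to half-open bins `[k*bin, (k+1)*bin)`
#' (pairs at exactly `max_distance` fall in the last bin), and summarises
#' each bin. Empty bins are retained with `n_pairs = 0` and `NA` summaries;
#' their median distance falls back to the bin midpoint. Pairs monomorphic
#' in the chosen samples are skipped.
#'
#' @param gm A [geno_matrix()].
#' @param max_distance Maximum pair distance in bp.
#' @param bin_size Bin width in bp; must divide `max_distance`.
#' @param metadata,group,by Optional group restriction as in
#'   [adjacent_r2()].
#' @param config An [ld_config()].
#' @return A tibble of class `ld_decay`: `bin_low`, `bin_high`, `n_pairs`,
#'   `mean_r2`, `sd_r2`, `median_distance`, plus a `group` column.
#' @export
#'
#' @examples
#' sim <- sim_wright_fisher(ne = 50, n_generations = 30, chrom_length = 2e6,
#'                          recomb_rate = 1e-8, sample_size = 25,
#'                          n_loci = 200, seed = 2)
#' ld_decay(sim$gm, max_distance = 1e6, bin_size = 2e5,
#'          config = ld_config(n_snps = Inf, min_scaffold_length = 0))
ld_decay <- function(gm, max_distance, bin_size, metadata = NULL,
                     group = NULL, by = "group", config = ld_config()) {
  if (max_distance %% bin_size != 0) {
    abort("bin_size must divide max_distance")
  }
  gm_use <- ld_subsample(gm, config)
  ids <- if (is.null(group)) gm_use$samples else {
    metadata$sample[metadata[[by]] == group]
  }
  d <- gm_use$dosage[sample_index(gm_use, ids), , drop = FALSE]

  n_bins <- max_distance / bin_size
  acc_n <- numeric(n_bins)
  acc_sum <- numeric(n_bins)
  acc_sumsq <- numeric(n_bins)
  dist_list <- vector("list", 0)

  for (sc in unique(gm_use$variants$scaffold)) {
    vi <- which(gm_use$variants$scaffold == sc)
    if (length(vi) < 2) next
    pos <- gm_use$variants$pos[vi]
    pr <- scaffold_pairs(pos, max_distance)
    if (nrow(pr) == 0) next
    # process pairs in blocks to bound the samples x pairs work matrices
    block <- 200000L
    starts <- seq(1L, nrow(pr), by = block)
    for (s0 in starts) {
      sl <- s0:min(s0 + block - 1L, nrow(pr))
      r2 <- r2_pairs_aligned(
        d[, vi[pr$i[sl]], drop = FALSE],
        d[, vi[pr$j[sl]], drop = FALSE]
      )
      dist <- pr$dist[sl]
      ok <- !is.na(r2)
      if (!any(ok)) next
      r2 <- r2[ok]
      dist <- dist[ok]
      bin <- pmin(dist %/% bin_size + 1, n_bins)
      acc_n <- acc_n + tabulate(bin, n_bins)
      acc_sum <- acc_sum + as.vector(tapply_sum(r2, bin, n_bins))
      acc_sumsq <- acc_sumsq + as.vector(tapply_sum(r2^2, bin, n_bins))
      dist_list[[length(dist_list) + 1]] <- tibble::tibble(bin = bin, dist = dist)
    }
  }
  dists <- dplyr::bind_rows(dist_list)
  med <- rep(NA_real_, n_bins)
  if (nrow(dists) > 0) {
    by_bin <- tapply(dists$dist, factor(dists$bin, levels = seq_len(n_bins)), median)
    med <- as.numeric(by_bin)
  }
  mean_r2 <- ifelse(acc_n > 0, acc_sum / acc_n, NA_real_)
  var_r2 <- ifelse(acc_n > 1,
    (acc_sumsq - acc_n * mean_r2^2) / (acc_n - 1), NA_real_
  )
  out <- tibble::tibble(
    group = group %||% "all",
    bin_low = (seq_len(n_bins) - 1) * bin_size,
    bin_high = seq_len(n_bins) * bin_size,
    n_pairs = as.integer(acc_n),
    mean_r2 = mean_r2,
    sd_r2 = sqrt(pmax(var_r2, 0)),
    median_distance = ifelse(is.na(med), (bin_size / 2) + (seq_len(n_bins) - 1) * bin_size, med)
  )
  class(out) <- c("ld_decay", class(out))
  out
}

# All same-scaffold index pairs with 0 < distance <= max_distance, built
# per anchor SNP against a sliding window of downstream SNPs.
scaffold_pairs <- function(pos, max_distance) {
  L <- length(pos)
  upper <- findInterval(pos + max_distance, pos)
  counts <- pmax(upper - seq_len(L), 0)
  i <- rep(seq_len(L), counts)
  j <- i + sequence(counts)
  tibble::tibble(i = i, j = j, dist = pos[j] - pos[i])
}

tapply_sum <- function(x, bin, n_bins) {
  out <- numeric(n_bins)
  agg <- tapply(x, factor(bin, levels = seq_len(n_bins)), sum)
  out[!is.na(agg)] <- agg[!is.na(agg)]
  out
}

# Restrict to long scaffolds and subsample SNPs per the LD config.
ld_subsample <- function(gm, config) {
  spans <- tapply(gm$variants$pos, gm$variants$scaffold, function(p) max(p) - min(p) + 1)
  long <- names(spans)[spans >= config$min_scaffold_length]
  keep <- gm$variants$scaffold %in% long
  if (!any(keep)) abort("no scaffold meets min_scaffold_length")
  gm <- subset_geno(gm, variants = keep)
  if (is.finite(config$n_snps) && config$n_snps < n_variants(gm)) {
    pick <- with_seed(
      config$seed,
      sort(sample.int(n_variants(gm), config$n_snps))
    )
    gm <- subset_geno(gm, variants = pick)
  }
  gm
}
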