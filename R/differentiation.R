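#' Nei's standard genetic distance between two groups
#'
#' `D = -ln I` with the normalised gene identity
#' `I = J_AB / sqrt(J_A * J_B)`, where `J_A = mean_j sum_alleles p^2`,
#' `J_B` likewise for group B, and `J_AB = mean_j sum_alleles p_A p_B`; the
#' J terms are averaged over loci before taking the ratio, and both alleles
#' of each bi-allelic locus contribute. Loci monomorphic in both groups
#' contribute identity 1. Loci without calls in either group are skipped.
#' If `I = 0` (fixed for opposite alleles everywhere) the distance is
#' `Inf`, flagged with a warning.
#'
#' @param gm A [geno_matrix()].
#' @param metadata Sample metadata tibble.
#' @param group_a,group_b Group labels.
#' @param by Metadata column holding the labels (default `"group"`).
#' @return Nei's D (non-negative scalar, possibly `Inf`).
#' @export
nei_distance <- function(gm, metadata, group_a, group_b, by = "group") {
  pa <- variant_freq(gm, metadata$sample[metadata[[by]] == group_a])
  pb <- variant_freq(gm, metadata$sample[metadata[[by]] == group_b])
  ok <- !is.nan(pa) & !is.nan(pb)
  if (!any(ok)) abort("no co-called loci between groups")
  pa <- pa[ok]
  pb <- pb[ok]
  j_a <- mean(pa^2 + (1 - pa)^2)
  j_b <- mean(pb^2 + (1 - pb)^2)
  j_ab <- mean(pa * pb + (1 - pa) * (1 - pb))
  i <- j_ab / sqrt(j_a * j_b)
  if (i <= 0) {
    warn("gene identity is 0; Nei distance is infinite")
    return(Inf)
  }
  -log(i)
}

#' Weir-Cockerham Fst (theta) between groups
#'
#' Multi-locus method-of-moments estimator computed as a ratio of sums of
#' the per-locus variance components `a` (among populations), `b` (among
#' individuals within populations) and `c` (within individuals):
#' `theta = sum(a) / sum(a + b + c)`. Components follow the standard
#' two-level formulation from per-group sample sizes, allele frequencies and
#' observed heterozygote fractions. Loci monomorphic across the pooled
#' groups are excluded (they contribute zero to both sums); theta can be
#' slightly negative in undifferentiated data.
#'
#' @param gm A [geno_matrix()].
#' @param metadata Sample metadata tibble.
#' @param groups Two or more group labels (default: all levels in
#'   `metadata[[by]]`); each group needs >= 2 samples.
#' @param by Metadata column holding the labels.
#' @return Multi-locus theta (scalar).
#' @export
#'
#' @examples
#' sim <- sim_structured(c(A = 25, B = 25), fst = 0.1,
#'                       n_loci = 2000, seed = 11)
#' wc_fst(sim$gm, sim$metadata)
wc_fst <- function(gm, metadata, groups = NULL, by = "group") {
  check_metadata(metadata)
  groups <- groups %||% unique(metadata[[by]])
  r <- length(groups)
  if (r < 2) abort("need at least two groups")
  per_group <- purrr::map(groups, function(g) {
    ids <- metadata$sample[metadata[[by]] == g]
    if (length(ids) < 2) abort(paste0("group '", g, "' has fewer than 2 samples"))
    d <- gm$dosage[sample_index(gm, ids), , drop = FALSE]
    list(
      n = colSums(!is.na(d)),
      p = colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d))),
      h = colMeans(d == 1L, na.rm = TRUE)
    )
  })
  n_i <- do.call(cbind, purrr::map(per_group, "n")) # loci x r
  p_i <- do.call(cbind, purrr::map(per_group, "p"))
  h_i <- do.call(cbind, purrr::map(per_group, "h"))

  ok <- rowSums(n_i >= 1) == r
  n_i <- n_i[ok, , drop = FALSE]
  p_i <- p_i[ok, , drop = FALSE]
  h_i <- h_i[ok, , drop = FALSE]

  n_bar <- rowMeans(n_i)
  n_c <- (r * n_bar - rowSums(n_i^2) / (r * n_bar)) / (r - 1)
  p_bar <- rowSums(n_i * p_i) / (r * n_bar)
  s2 <- rowSums(n_i * (p_i - p_bar)^2) / ((r - 1) * n_bar)
  h_bar <- rowSums(n_i * h_i) / (r * n_bar)

  a <- (n_bar / n_c) *
    (s2 - (p_bar * (1 - p_bar) - (r - 1) / r * s2 - h_bar / 4) / (n_bar - 1))
  b <- (n_bar / (n_bar - 1)) *
    (p_bar * (1 - p_bar) - (r - 1) / r * s2 - (2 * n_bar - 1) / (4 * n_bar) * h_bar)
  cc <- h_bar / 2

  poly <- p_bar > 0 & p_bar < 1
  denom <- sum((a + b + cc)[poly])
  if (!any(poly) || denom == 0) {
    abort("theta undefined: all loci monomorphic across the groups")
  }
  sum(a[poly]) / denom
}

#' Pairwise group differentiation (Nei's D and Weir-Cockerham Fst)
#'
#' @inheritParams wc_fst
#' @return A tibble with one row per unordered group pair: `group_a`,
#'   `group_b`, `nei_d`, `fst`.
#' @export
pair_divergence <- function(gm, metadata, groups = NULL, by = "group") {
  check_metadata(metadata)
  groups <- groups %||% unique(metadata[[by]])
  combos <- utils::combn(groups, 2)
  purrr::map(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]
    b <- combos[2, k]
    tibble::tibble(
      group_a = a, group_b = b,
      nei_d = nei_distance(gm, metadata, a, b, by = by),
      fst = wc_fst(gm, metadata, groups = c(a, b), by = by)
    )
  }) |>
    dplyr::bind_rows()
}

#' Individual-level squared distance matrix from dosages
#'
#' Mean squared difference of alternate-allele dosages over the loci where
#' both samples have calls -- the squared-distance matrix fed to [amova()].
#'
#' @param gm A [geno_matrix()].
#' @return A symmetric `n x n` matrix with zero diagonal.
#' @export
dosage_dist2 <- function(gm) {
  x <- gm$dosage
  miss <- is.na(x)
  x0 <- x
  x0[miss] <- 0L
  m <- 1 - miss
  storage.mode(x0) <- "double"
  n_shared <- tcrossprod(m)
  sq <- tcrossprod(x0^2, m)
  cross <- tcrossprod(x0)
  d2 <- (sq + t(sq) - 2 * cross) / n_shared
  dimnames(d2) <- list(gm$samples, gm$samples)
  diag(d2) <- 0
  d2
}
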