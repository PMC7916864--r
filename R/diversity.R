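#' Per-group diversity summary
#'
#' For each group (and optionally each supergroup and the pooled total)
#' computes the number of animals, the mean minor allele frequency over
#' variants (per-variant MAF recomputed within the group's non-missing
#' calls; variants with no calls in the group are skipped), the observed
#' heterozygosity as the percentage of non-missing genotype calls that are
#' heterozygous, and the mean excess-homozygosity inbreeding coefficient
#' [f_hom()] across the group's samples.
#'
#' @param gm A [geno_matrix()].
#' @param metadata Sample metadata tibble (`sample`, `group`, `supergroup`).
#' @param by Grouping column, `"group"` or `"supergroup"`.
#' @param include_total Append a pooled `"Total"` row.
#' @return A tibble with columns `group`, `n`, `mean_maf`, `het_pct`,
#'   `mean_f_hom`.
#' @export
#'
#' @examples
#' sim <- sim_structured(c(A = 15, B = 15), fst = c(0.05, 0.1),
#'                       n_loci = 400, seed = 3)
#' group_diversity(sim$gm, sim$metadata)
group_diversity <- function(gm, metadata, by = c("group", "supergroup"),
                            include_total = TRUE) {
  by <- match.arg(by)
  check_metadata(metadata)
  fh <- f_hom(gm)
  groups <- unique(metadata[[by]])
  rows <- purrr::map(groups, function(g) {
    ids <- metadata$sample[metadata[[by]] == g]
    mh <- group_maf_het(gm, metadata, g, by = by)
    tibble::tibble(
      group = g, n = length(ids),
      mean_maf = mh$mean_maf, het_pct = mh$het_pct,
      mean_f_hom = mean(fh$f_hom[fh$sample %in% ids])
    )
  })
  out <- dplyr::bind_rows(rows)
  if (include_total) {
    d <- gm$dosage[match(metadata$sample, gm$samples), , drop = FALSE]
    out <- dplyr::bind_rows(out, tibble::tibble(
      group = "Total", n = nrow(metadata),
      mean_maf = mean(variant_maf(gm, metadata$sample), na.rm = TRUE),
      het_pct = 100 * mean(d == 1L, na.rm = TRUE),
      mean_f_hom = mean(fh$f_hom[fh$sample %in% metadata$sample])
    ))
  }
  out
}

#' Group-level MAF and observed heterozygosity
#'
#' @inheritParams group_diversity
#' @param group Group label to summarise.
#' @return A one-row tibble with `mean_maf` and `het_pct`.
#' @export
group_maf_het <- function(gm, metadata, group, by = "group") {
  check_metadata(metadata)
  ids <- metadata$sample[metadata[[by]] == group]
  if (length(ids) == 0) abort(paste0("unknown group: ", group))
  d <- gm$dosage[sample_index(gm, ids), , drop = FALSE]
  maf <- variant_maf(gm, ids)
  tibble::tibble(
    mean_maf = mean(maf, na.rm = TRUE),
    het_pct = 100 * mean(d == 1L, na.rm = TRUE)
  )
}

#' Inbreeding from excess homozygosity (F_HOM)
#'
#' Method-of-moments inbreeding coefficient per sample:
#' `F = (O_hom - E_hom) / (m - E_hom)`, where `m` is the sample's number of
#' non-missing variants, `O_hom` its observed homozygote count, and
#' `E_hom = sum_j (1 - 2 p_j (1 - p_j) * 2N_j / (2N_j - 1))` the expected
#' homozygote count under Hardy-Weinberg with the small-sample correction,
#' with `p_j` the reference-panel alternate-allele frequency and `N_j` the
#' non-missing sample count at variant `j`. Hardy-Weinberg-consistent data
#' give F close to 0, heterozygote excess gives F < 0 (down to -1), complete
#' homozygosity gives F = 1.
#'
#' @param gm A [geno_matrix()].
#' @param samples Sample ids to evaluate (default all).
#' @param metadata Required for `freq_scope = "group"`.
#' @param freq_scope `"all"` (default) computes reference frequencies from
#'   the full sample set; `"group"` recomputes them within each sample's
#'   group.
#' @return A tibble with columns `sample`, `f_hom`, `n_variants`.
#' @export
f_hom <- function(gm, samples = NULL, metadata = NULL,
                  freq_scope = c("all", "group")) {
  freq_scope <- match.arg(freq_scope)
  samples <- samples %||% gm$samples
  if (freq_scope == "group") {
    if (is.null(metadata)) abort("freq_scope = 'group' requires metadata")
    check_metadata(metadata)
    groups <- metadata$group[match(samples, metadata$sample)]
    out <- purrr::map(unique(groups), function(g) {
      ids <- metadata$sample[metadata$group == g]
      f_hom_core(gm, intersect(samples, ids), ref_samples = ids)
    })
    res <- dplyr::bind_rows(out)
    return(res[match(samples, res$sample), ])
  }
  f_hom_core(gm, samples, ref_samples = gm$samples)
}

f_hom_core <- function(gm, samples, ref_samples) {
  p <- variant_freq(gm, ref_samples)
  dref <- gm$dosage[sample_index(gm, ref_samples), , drop = FALSE]
  n_call <- colSums(!is.na(dref))
  # per-variant expected homozygosity with the 2N/(2N-1) correction
  e_hom_j <- 1 - 2 * p * (1 - p) * (2 * n_call) / (2 * n_call - 1)
  usable <- n_call >= 1 & !is.nan(p)

  d <- gm$dosage[sample_index(gm, samples), , drop = FALSE]
  d[, !usable] <- NA
  obs <- !is.na(d)
  m <- rowSums(obs)
  if (any(m == 0)) {
    abort("sample with no non-missing calls")
  }
  o_hom <- rowSums(d == 0L | d == 2L, na.rm = TRUE)
  e_hom <- as.vector(obs %*% ifelse(usable, e_hom_j, 0))
  denom <- m - e_hom
  if (any(abs(denom) < 1e-12)) {
    abort("F_HOM undefined: expected homozygosity equals variant count")
  }
  tibble::tibble(
    sample = samples,
    f_hom = unname((o_hom - e_hom) / denom),
    n_variants = unname(m)
  )
}

#' Pedigree inbreeding coefficient (F_PED)
#'
#' Wright's inbreeding coefficient computed by the recursive tabular
#' (additive-relationship) method: individuals are sorted so parents precede
#' offspring, the numerator relationship matrix A is filled recursively, and
#' `F_i = a(sire_i, dam_i) / 2` with founder F = 0.
#'
#' @param pedigree Data frame with columns `individual`, `sire`, `dam`
#'   (`NA`/`"0"`/empty = unknown parent).
#' @param individuals Ids to report (default all).
#' @return A tibble with columns `individual`, `f_ped`.
#' @export
#'
#' @examples
#' ped <- sim_pedigree(founders = 4, scheme = "full-sib")
#' f_ped(ped)
f_ped <- function(pedigree, individuals = NULL) {
  ped <- tibble::as_tibble(pedigree)
  ped$sire[ped$sire %in% c("0", "")] <- NA
  ped$dam[ped$dam %in% c("0", "")] <- NA
  ids <- ped$individual
  if (anyDuplicated(ids)) abort("duplicate individuals in pedigree")
  unknown <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ids)
  if (length(unknown) > 0) {
    # parents not listed as individuals are treated as founders
    ped <- dplyr::bind_rows(
      tibble::tibble(individual = unknown, sire = NA_character_, dam = NA_character_),
      ped
    )
    ids <- ped$individual
  }
  ord <- pedigree_order(ped)
  ped <- ped[ord, ]
  n <- nrow(ped)
  si <- match(ped$sire, ped$individual)
  di <- match(ped$dam, ped$individual)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    a_sd <- if (!is.na(s) && !is.na(d)) A[s, d] else 0
    A[i, i] <- 1 + a_sd / 2
    j <- seq_len(i - 1)
    if (length(j) > 0) {
      a_js <- if (!is.na(s)) A[j, s] else rep(0, length(j))
      a_jd <- if (!is.na(d)) A[j, d] else rep(0, length(j))
      A[i, j] <- A[j, i] <- 0.5 * (a_js + a_jd)
    }
  }
  f <- diag(A) - 1
  res <- tibble::tibble(individual = ped$individual, f_ped = f)
  individuals <- individuals %||% pedigree$individual
  missing <- setdiff(individuals, res$individual)
  if (length(missing) > 0) {
    abort(paste0("individual(s) not in pedigree: ", paste(missing, collapse = ", ")))
  }
  res[match(individuals, res$individual), ]
}

# Topological sort (parents before offspring); errors on cycles.
pedigree_order <- function(ped) {
  n <- nrow(ped)
  si <- match(ped$sire, ped$individual)
  di <- match(ped$dam, ped$individual)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    s_ok <- is.na(si) | placed[ifelse(is.na(si), 1L, si)]
    d_ok <- is.na(di) | placed[ifelse(is.na(di), 1L, di)]
    ready <- !placed & s_ok & d_ok
    if (!any(ready)) break
    ord <- c(ord, which(ready))
    placed[ready] <- TRUE
  }
  if (length(ord) < n) abort("cycle detected in pedigree")
  ord
}

#' Correlations among inbreeding measures
#'
#' Pairwise Pearson correlations (pairwise-complete observations) between
#' per-sample inbreeding coefficients such as F_HOM, F_ROH and F_PED.
#' Measures with zero variance yield `NA` with a warning.
#'
#' @param measures Data frame with a `sample` column plus one numeric column
#'   per inbreeding measure.
#' @return A tibble with columns `measure_a`, `measure_b`, `r`, `n`.
#' @export
inbreeding_correlations <- function(measures) {
  m <- dplyr::select(tibble::as_tibble(measures), -dplyr::any_of("sample"))
  if (ncol(m) < 2) abort("need at least two measures")
  if (nrow(m) < 3) abort("need at least 3 samples")
  combos <- utils::combn(names(m), 2)
  purrr::map(seq_len(ncol(combos)), function(k) {
    a <- combos[1, k]
    b <- combos[2, k]
    ok <- stats::complete.cases(m[[a]], m[[b]])
    r <- if (sd(m[[a]][ok]) == 0 || sd(m[[b]][ok]) == 0) {
      warn(paste0("zero variance in ", a, " or ", b, "; correlation undefined"))
      NA_real_
    } else {
      cor(m[[a]][ok], m[[b]][ok])
    }
    tibble::tibble(measure_a = a, measure_b = b, r = r, n = sum(ok))
  }) |>
    dplyr::bind_rows()
}
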