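#' Variant filter specification
#'
#' Thresholds for site-level quality control. Defaults follow the common
#' whole-genome resequencing recipe for livestock panels: minor allele
#' frequency strictly greater than 0.05, per-site missing rate strictly less
#' than 0.1, site QUAL strictly greater than 30, bi-allelic SNPs only. All
#' inequalities are strict.
#'
#' @param min_maf Minimum minor allele frequency (exclusive), in `[0, 0.5]`.
#' @param max_missing Maximum fraction of samples with a missing call
#'   (exclusive), in `[0, 1]`.
#' @param min_qual Minimum site QUAL (phred, exclusive); `NULL` disables the
#'   quality filter.
#' @param biallelic_only Drop non-bi-allelic records on read (enforced by
#'   [read_vcf()]).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(min_maf = 0.05, max_missing = 0.1, min_qual = 30,
                        biallelic_only = TRUE) {
  if (min_maf < 0 || min_maf > 0.5) abort("min_maf must be in [0, 0.5]")
  if (max_missing < 0 || max_missing > 1) abort("max_missing must be in [0, 1]")
  structure(
    list(
      min_maf = min_maf, max_missing = max_missing,
      min_qual = min_qual, biallelic_only = isTRUE(biallelic_only)
    ),
    class = "filter_spec"
  )
}

#' Apply site filters to a genotype matrix
#'
#' Retains exactly the variants with MAF > `min_maf` (computed over
#' non-missing calls across all samples jointly), missing fraction <
#' `max_missing`, and QUAL > `min_qual`. The sample set is unchanged.
#' Filtering is idempotent: re-applying the same spec to the result is a
#' no-op.
#'
#' @param gm A [geno_matrix()].
#' @param spec A [filter_spec()].
#' @param qual Per-variant phred site quality; defaults to `gm$qual`. If
#'   neither is available the quality filter is skipped with a message.
#' @return A filtered [geno_matrix()]. Errors if no variant survives.
#' @export
#'
#' @examples
#' sim <- sim_structured(n_per_group = c(A = 10), fst = 0.05,
#'                       n_loci = 200, seed = 1)
#' filtered <- apply_filters(sim$gm, filter_spec(min_qual = NULL))
#' n_variants(filtered)
apply_filters <- function(gm, spec = filter_spec(), qual = gm$qual) {
  maf <- variant_maf(gm)
  miss <- variant_missing(gm)
  keep <- !is.nan(maf) & maf > spec$min_maf & miss < spec$max_missing
  if (!is.null(spec$min_qual)) {
    if (is.null(qual)) {
      inform("no site quality available; QUAL filter skipped")
    } else {
      keep <- keep & !is.na(qual) & qual > spec$min_qual
    }
  }
  if (!any(keep)) {
    abort("all variants removed by filters")
  }
  subset_geno(gm, variants = keep)
}
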