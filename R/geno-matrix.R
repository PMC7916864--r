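#' Genotype matrix container
#'
#' A `geno_matrix` holds unphased bi-allelic SNP genotypes as alternate-allele
#' dosages (0, 1, 2, or `NA` for a missing call) in a samples-by-variants
#' integer matrix, together with an ordered variant map (scaffold, 1-based
#' position, REF and ALT alleles). Variants are stored sorted by scaffold and
#' position; positions must be strictly increasing within a scaffold.
#'
#' @param dosage Integer matrix, samples in rows, variants in columns; values
#'   0/1/2 or `NA`.
#' @param variants Data frame with columns `scaffold`, `pos`, `ref`, `alt`,
#'   one row per column of `dosage`.
#' @param samples Character vector of sample ids; defaults to
#'   `rownames(dosage)`.
#' @param qual Optional numeric vector of per-site phred quality scores.
#'
#' @return An object of class `geno_matrix` with elements `dosage`,
#'   `variants` (a tibble) and `samples`.
#' @export
#'
#' @examples
#' gm <- geno_matrix(
#'   dosage = rbind(s1 = c(0L, 1L), s2 = c(2L, NA)),
#'   variants = data.frame(
#'     scaffold = "scaf1", pos = c(100L, 200L),
#'     ref = "A", alt = c("G", "T")
#'   )
#' )
#' gm
geno_matrix <- function(dosage, variants, samples = rownames(dosage),
                        qual = NULL) {
  dosage <- as.matrix(dosage)
  variants <- tibble::as_tibble(variants)
  required <- c("scaffold", "pos", "ref", "alt")
  if (!all(required %in% names(variants))) {
    abort(paste0(
      "`variants` must have columns ",
      paste(required, collapse = ", ")
    ))
  }
  if (nrow(variants) != ncol(dosage)) {
    abort("`variants` must have one row per column of `dosage`")
  }
  if (is.null(samples)) {
    samples <- paste0("sample", seq_len(nrow(dosage)))
  }
  if (length(samples) != nrow(dosage)) {
    abort("`samples` must have one id per row of `dosage`")
  }
  bad <- !(dosage %in% c(0L, 1L, 2L) | is.na(dosage))
  if (any(bad)) {
    abort("dosages must be 0, 1, 2 or NA")
  }
  storage.mode(dosage) <- "integer"
  variants$scaffold <- as.character(variants$scaffold)
  variants$pos <- as.integer(variants$pos)
  if (!is.null(qual) && length(qual) != nrow(variants)) {
    abort("`qual` must have one value per variant")
  }

  ord <- order(variants$scaffold, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  qual <- qual[ord]
  dup <- duplicated(variants[, c("scaffold", "pos")])
  if (any(dup)) {
    abort("duplicate scaffold/position pairs; positions must be strictly increasing")
  }

  rownames(dosage) <- samples
  colnames(dosage) <- paste0(variants$scaffold, ":", variants$pos)
  structure(
    list(
      dosage = dosage,
      variants = variants,
      samples = as.character(samples),
      qual = qual
    ),
    class = "geno_matrix"
  )
}

#' @export
#' @method print geno_matrix
print.geno_matrix <- function(x, ...) {
  cat(
    "<geno_matrix> ", length(x$samples), " samples x ",
    nrow(x$variants), " variants on ",
    length(unique(x$variants$scaffold)), " scaffold(s)\n",
    sep = ""
  )
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  missing call rate: %.3f\n", miss))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Number of samples / variants in a genotype matrix
#'
#' @param gm A [geno_matrix()].
#' @return An integer count.
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_samples
#' @export
n_variants <- function(gm) nrow(gm$variants)

#' Subset a genotype matrix
#'
#' @param gm A [geno_matrix()].
#' @param samples,variants Index vectors (logical, integer or, for samples,
#'   character ids); `NULL` keeps everything.
#' @return A [geno_matrix()].
#' @export
subset_geno <- function(gm, samples = NULL, variants = NULL) {
  si <- seq_along(gm$samples)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, gm$samples) else si[samples]
    if (anyNA(si)) abort("unknown sample id in `samples`")
  }
  vi <- seq_len(n_variants(gm))
  if (!is.null(variants)) vi <- vi[variants]
  geno_matrix(
    gm$dosage[si, vi, drop = FALSE],
    gm$variants[vi, , drop = FALSE],
    samples = gm$samples[si],
    qual = gm$qual[vi]
  )
}

#' Per-variant allele statistics
#'
#' `variant_freq()` returns the alternate-allele frequency computed over
#' non-missing calls; `variant_maf()` folds it to the minor-allele frequency;
#' `variant_missing()` returns the fraction of samples with a missing call.
#'
#' @param gm A [geno_matrix()].
#' @param samples Optional subset of sample ids over which to compute.
#' @return A numeric vector, one value per variant (`NaN` where no calls).
#' @export
variant_freq <- function(gm, samples = NULL) {
  d <- gm$dosage
  if (!is.null(samples)) {
    d <- d[match(samples, gm$samples), , drop = FALSE]
  }
  colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d)))
}

#' @rdname variant_freq
#' @export
variant_maf <- function(gm, samples = NULL) {
  p <- variant_freq(gm, samples)
  pmin(p, 1 - p)
}

#' @rdname variant_freq
#' @export
variant_missing <- function(gm, samples = NULL) {
  d <- gm$dosage
  if (!is.null(samples)) {
    d <- d[match(samples, gm$samples), , drop = FALSE]
  }
  colMeans(is.na(d))
}

sample_index <- function(gm, sample) {
  i <- match(sample, gm$samples)
  if (anyNA(i)) {
    abort(paste0("sample not found: ", paste(sample[is.na(i)], collapse = ", ")))
  }
  i
}

group_samples <- function(metadata, group) {
  check_metadata(metadata)
  ids <- metadata$sample[metadata$group == group]
  if (length(ids) == 0) abort(paste0("no samples in group '", group, "'"))
  ids
}

check_metadata <- function(metadata) {
  if (!all(c("sample", "group", "supergroup") %in% names(metadata))) {
    abort("metadata must have columns sample, group, supergroup")
  }
  if (anyDuplicated(metadata$sample)) {
    abort("metadata sample ids must be unique")
  }
  invisible(metadata)
}
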