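#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses GT fields from a VCF (v4.x, plain or bgzipped) via
#' \pkg{vcfR}. Only bi-allelic SNP records are retained: records whose ALT
#' contains a comma (multi-allelic) or whose REF/ALT is not a single
#' A/C/G/T base are dropped, and the number dropped is reported. Genotypes
#' are converted to alternate-allele dosages; `./.` (or any call containing
#' `.`) becomes `NA`. Site QUAL values are carried along for filtering.
#'
#' @param path Path to a VCF file.
#' @param metadata Optional sample metadata (columns `sample`, `group`,
#'   `supergroup`). Samples present in the VCF but absent from the metadata
#'   trigger a warning and are kept with group/supergroup `"unassigned"`.
#' @return A list with elements `gm` (a [geno_matrix()] whose `qual` holds
#'   site quality), `metadata` (a tibble covering every VCF sample) and
#'   `n_dropped` (records removed as multi-allelic/non-SNP).
#' @export
#'
#' @examples
#' # simulated demonstration data shipped with the package
#' vcf <- system.file("extdata", "mink_demo.vcf", package = "popgenld")
#' meta <- read_sample_metadata(
#'   system.file("extdata", "mink_demo_metadata.tsv", package = "popgenld")
#' )
#' res <- read_vcf(vcf, meta)
#' res$gm
read_vcf <- function(path, metadata = NULL) {
  if (!file.exists(path)) {
    abort(paste0("VCF not found: ", path))
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix) # single-record VCF gives a bare vector
  fix <- tibble::as_tibble(as.data.frame(fix, stringsAsFactors = FALSE))
  gt <- vcfR::extract.gt(v, element = "GT")

  snp <- !grepl(",", fix$ALT %||% "") &
    fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  snp[is.na(snp)] <- FALSE
  n_dropped <- sum(!snp)
  if (n_dropped > 0) {
    inform(paste0("read_vcf: dropped ", n_dropped, " multi-allelic/non-SNP record(s)"))
  }
  if (!any(snp)) abort("no bi-allelic SNP records in VCF")
  fix <- fix[snp, , drop = FALSE]
  gt <- gt[snp, , drop = FALSE]

  dosage <- gt_to_dosage(gt)
  qual <- suppressWarnings(as.numeric(fix$QUAL))

  gm <- geno_matrix(
    dosage = t(dosage),
    variants = tibble::tibble(
      scaffold = fix$CHROM, pos = as.integer(fix$POS),
      ref = fix$REF, alt = fix$ALT
    ),
    samples = colnames(gt),
    qual = qual
  )

  meta <- align_metadata(gm$samples, metadata)
  list(gm = gm, metadata = meta, n_dropped = n_dropped)
}

# GT strings ("0/1", "1|1", "./.") -> alt dosage matrix (variants x samples).
gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  d <- (a1 == "1") + (a2 == "1")
  d[a1 == "." | a2 == "." | is.na(gt)] <- NA
  matrix(as.integer(d), nrow = nrow(gt), dimnames = dimnames(gt))
}

align_metadata <- function(samples, metadata) {
  if (is.null(metadata)) {
    return(tibble::tibble(
      sample = samples, group = "unassigned", supergroup = "unassigned"
    ))
  }
  check_metadata(metadata)
  missing <- setdiff(samples, metadata$sample)
  if (length(missing) > 0) {
    warn(paste0(
      "samples absent from metadata kept as 'unassigned': ",
      paste(missing, collapse = ", ")
    ))
  }
  metadata <- tibble::as_tibble(metadata)
  dplyr::bind_rows(
    metadata[match(intersect(samples, metadata$sample), metadata$sample), ],
    tibble::tibble(sample = missing, group = "unassigned", supergroup = "unassigned")
  ) |>
    dplyr::arrange(match(.data$sample, samples))
}

#' Read sample metadata / pedigree tables
#'
#' `read_sample_metadata()` expects a TSV with header columns `sample`,
#' `group`, `supergroup`. `read_pedigree()` expects columns `individual`,
#' `sire`, `dam`, where `0`, `NA` or an empty string marks an unknown
#' (founder) parent and is normalised to `NA`.
#'
#' @param path Path to a tab-separated file.
#' @return A tibble.
#' @export
read_sample_metadata <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(.default = "c"))
  check_metadata(m)
  m
}

#' @rdname read_sample_metadata
#' @export
read_pedigree <- function(path) {
  p <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols(.default = "c"))
  if (!all(c("individual", "sire", "dam") %in% names(p))) {
    abort("pedigree must have columns individual, sire, dam")
  }
  p$sire[p$sire %in% c("0", "", NA)] <- NA
  p$dam[p$dam %in% c("0", "", NA)] <- NA
  p
}

#' Write a genotype matrix to disk
#'
#' `write_dosage_tsv()` writes a samples-as-rows dosage table (missing calls
#' as `NA`). `write_geno_vcf()` writes a minimal plain-text VCF v4.2 with GT
#' fields reconstructed from dosages (`0/0`, `0/1`, `1/1`, `./.`), suitable
#' for round-tripping through [read_vcf()].
#'
#' @param gm A [geno_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(gm, path) {
  tab <- tibble::as_tibble(gm$dosage, .name_repair = "minimal")
  names(tab) <- colnames(gm$dosage)
  tab <- dplyr::bind_cols(tibble::tibble(sample = gm$samples), tab)
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
write_geno_vcf <- function(gm, path) {
  gt_codes <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = n_variants(gm), ncol = n_samples(gm))
  d <- t(gm$dosage)
  ok <- !is.na(d)
  gt[ok] <- gt_codes[d[ok] + 1L]
  qual <- if (is.null(gm$qual)) rep(".", n_variants(gm)) else format(gm$qual, trim = TRUE)
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
      gm$samples
    ), collapse = "\t"),
    paste(
      gm$variants$scaffold, gm$variants$pos, ".",
      gm$variants$ref, gm$variants$alt, qual, "PASS", ".", "GT",
      apply(gt, 1, paste, collapse = "\t"),
      sep = "\t"
    )
  )
  writeLines(lines, path)
  invisible(path)
}
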