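# Small fixtures built in code.

# genotype matrix from an explicit dosage matrix, evenly spaced on one scaffold
gm_from_dosage <- function(d, spacing = 1e4, scaffold = "scaf1") {
  d <- as.matrix(d)
  geno_matrix(
    d,
    variants = data.frame(
      scaffold = scaffold,
      pos = seq_len(ncol(d)) * spacing,
      ref = "A", alt = "G"
    ),
    samples = paste0("s", seq_len(nrow(d)))
  )
}

# write a small VCF file with given genotype strings (variants x samples)
write_test_vcf <- function(path, chrom, pos, ref, alt, gt, qual = NULL,
                           samples = paste0("s", seq_len(ncol(gt)))) {
  qual <- qual %||% rep(99, length(pos))
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    vapply(seq_along(pos), function(i) {
      paste(c(chrom[i], pos[i], ".", ref[i], alt[i], qual[i], "PASS", ".",
              "GT", gt[i, ]), collapse = "\t")
    }, "")
  )
  writeLines(lines, path)
  path
}

meta_for <- function(gm, group = "g1", supergroup = "f1") {
  tibble::tibble(
    sample = gm$samples,
    group = rep_len(group, length(gm$samples)),
    supergroup = rep_len(supergroup, length(gm$samples))
  )
}
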