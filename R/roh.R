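#' ROH detection parameters
#'
#' Sliding-window parameters for run-of-homozygosity detection. The defaults
#' (20-SNP windows, genotyping error rate 0.01, step of one SNP) give a
#' per-window heterozygote budget of `floor(0.01 * 20) = 0`, i.e. a single
#' heterozygote breaks a run -- a deliberately strict setting appropriate
#' for high-coverage sequence data.
#'
#' @param min_snps Minimum window size in SNPs (>= 2); a reported segment
#'   also needs at least this many SNPs.
#' @param error_rate Assumed genotyping error rate in `[0, 0.5)`; a window
#'   with at most `floor(error_rate * min_snps)` heterozygotes counts as
#'   homozygous.
#' @param step Window step in SNPs (the detector slides one SNP at a time).
#' @param min_length Minimum segment length in bp to report (one of several
#'   thresholds is typically re-applied later via [f_roh()]).
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_snps = 20, error_rate = 0.01, step = 1,
                       min_length = 5e5) {
  if (min_snps < 2) abort("min_snps must be >= 2")
  if (error_rate < 0 || error_rate >= 0.5) abort("error_rate must be in [0, 0.5)")
  structure(
    list(
      min_snps = as.integer(min_snps), error_rate = error_rate,
      step = as.integer(step), min_length = min_length
    ),
    class = "roh_params"
  )
}

#' Detect runs of homozygosity
#'
#' Per sample and scaffold, slides a window of `min_snps` consecutive SNPs
#' one SNP at a time. A window is homozygous when its heterozygote count is
#' at most `floor(error_rate * min_snps)`; missing calls are non-informative
#' (they neither count as heterozygous nor break a run). Maximal unions of
#' overlapping homozygous windows become candidate segments spanning their
#' first to last SNP; segments shorter than `min_length` bp are discarded.
#' Scaffolds with fewer SNPs than the window size yield no segments.
#' Detection only looks at heterozygosity (dosage 1), so it is invariant to
#' REF/ALT relabeling.
#'
#' @param gm A [geno_matrix()].
#' @param samples Sample ids to scan (default all).
#' @param params A [roh_params()].
#' @return A tibble of segments: `sample`, `scaffold`, `start`, `end`,
#'   `n_snps`, `length` (`end - start + 1`).
#' @export
#'
#' @examples
#' sim <- sim_structured(c(A = 5), fst = 0.05, n_loci = 300,
#'                       n_scaffolds = 1, seed = 9)
#' gm <- plant_roh(sim$gm, data.frame(
#'   sample = "A_1", scaffold = "scaf1", start = 1e6, end = 6e7
#' ))
#' detect_roh(gm, samples = "A_1")
detect_roh <- function(gm, samples = NULL, params = roh_params()) {
  samples <- samples %||% gm$samples
  budget <- floor(params$error_rate * params$min_snps)
  w <- params$min_snps
  scafs <- split(seq_len(n_variants(gm)), gm$variants$scaffold)

  res <- purrr::map(samples, function(id) {
    i <- sample_index(gm, id)
    drow <- gm$dosage[i, ]
    segs <- purrr::map(scafs, function(vi) {
      L <- length(vi)
      if (L < w) {
        return(NULL)
      }
      het <- as.integer(!is.na(drow[vi]) & drow[vi] == 1L)
      # heterozygote count in each w-SNP window via cumulative sums
      cs <- c(0L, cumsum(het))
      win_het <- cs[(w + 1):(L + 1)] - cs[1:(L - w + 1)]
      hom_win <- win_het <= budget
      if (!any(hom_win)) {
        return(NULL)
      }
      r <- rle(hom_win)
      ends_run <- cumsum(r$lengths)
      starts_run <- ends_run - r$lengths + 1
      keep <- which(r$values)
      pos <- gm$variants$pos[vi]
      purrr::map(keep, function(k) {
        first <- starts_run[k]
        last <- ends_run[k] + w - 1
        tibble::tibble(
          scaffold = gm$variants$scaffold[vi[1]],
          start = pos[first], end = pos[last],
          n_snps = last - first + 1L
        )
      }) |>
        dplyr::bind_rows()
    })
    segs <- dplyr::bind_rows(segs)
    if (nrow(segs) == 0) {
      return(NULL)
    }
    segs$sample <- id
    segs
  })
  out <- dplyr::bind_rows(res)
  if (nrow(out) == 0) {
    return(tibble::tibble(
      sample = character(), scaffold = character(), start = integer(),
      end = integer(), n_snps = integer(), length = numeric()
    ))
  }
  out$length <- as.numeric(out$end) - as.numeric(out$start) + 1
  out <- out[out$length >= params$min_length & out$n_snps >= w, ]
  dplyr::select(
    out, "sample", "scaffold", "start", "end", "n_snps", "length"
  ) |>
    dplyr::arrange(.data$sample, .data$scaffold, .data$start)
}

#' Genomic inbreeding from ROH (F_ROH)
#'
#' `F_ROH = sum(length of segments >= threshold) / L`, with `L` the callable
#' genome length in bp. One row is returned per sample and threshold;
#' samples listed in `samples` but carrying no qualifying segment get
#' F_ROH = 0. F_ROH is non-increasing in the threshold.
#'
#' @param segments Segment tibble from [detect_roh()].
#' @param callable_length Callable genome length `L` in bp (> 0).
#' @param thresholds Minimum segment lengths in bp (default 500 kb, 1 Mb,
#'   2 Mb).
#' @param samples Sample ids to report (default: those present in
#'   `segments`).
#' @return A tibble: `sample`, `threshold`, `n_segments`, `total_length`,
#'   `f_roh`.
#' @export
f_roh <- function(segments, callable_length,
                  thresholds = c(5e5, 1e6, 2e6), samples = NULL) {
  if (callable_length <= 0) abort("callable_length must be > 0")
  if (nrow(segments) > 0 && any(segments$length > callable_length)) {
    abort("segment longer than callable_length")
  }
  samples <- samples %||% unique(segments$sample)
  grid <- tidyr::expand_grid(sample = samples, threshold = thresholds)
  dplyr::left_join(
    grid,
    dplyr::bind_rows(purrr::map(thresholds, function(th) {
      segments |>
        dplyr::filter(.data$length >= th) |>
        dplyr::group_by(.data$sample) |>
        dplyr::summarise(
          n_segments = dplyr::n(),
          total_length = sum(.data$length), .groups = "drop"
        ) |>
        dplyr::mutate(threshold = th)
    })),
    by = c("sample", "threshold")
  ) |>
    dplyr::mutate(
      n_segments = dplyr::coalesce(.data$n_segments, 0L),
      total_length = dplyr::coalesce(.data$total_length, 0),
      f_roh = .data$total_length / callable_length
    )
}
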