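#' Effective population size from a mean r2 (Sved's expectation)
#'
#' Inverts Sved's drift expectation `E[r2] = 1 / (1 + 4 Ne c)`:
#' `Ne = (1/r2 - 1) / (4c)`. The r2 supplied should already carry the
#' haplotype-sample-size correction ([correct_r2()]), so no additional
#' `1/n` term appears in the expectation.
#'
#' @param r2 Mean corrected r2 in `(0, 1)`.
#' @param c_morgans Recombination distance between the loci in Morgans
#'   (> 0).
#' @return The Ne estimate. `r2 >= 1` returns 0 with a warning; `r2 <= 0`
#'   is an error.
#' @export
#'
#' @examples
#' ne_from_r2(0.2, 0.01) # (5 - 1) / 0.04 = 100
ne_from_r2 <- function(r2, c_morgans) {
  if (any(c_morgans <= 0)) abort("c_morgans must be > 0")
  if (any(r2 <= 0)) abort("r2 must be > 0 for Ne estimation")
  out <- (1 / r2 - 1) / (4 * c_morgans)
  if (any(r2 >= 1)) {
    warn("r2 >= 1: Ne bounded at 0")
    out[r2 >= 1] <- 0
  }
  out
}

#' Sved's forward expectation
#'
#' `E[r2] = 1 / (1 + 4 Ne c)` -- the inverse of [ne_from_r2()], exposed for
#' round-trip checks and simulation design.
#'
#' @param ne Effective population size.
#' @param c_morgans Recombination distance in Morgans.
#' @return Expected r2.
#' @export
sved_r2 <- function(ne, c_morgans) {
  1 / (1 + 4 * ne * c_morgans)
}

#' Ne trajectory from LD-decay bins
#'
#' For each requested number of generations ago `t`, the informative
#' recombination distance is `c = 1/(2t)` Morgans (LD at distance `c`
#' reflects Ne about `1/(2c)` generations ago). The target physical
#' distance follows from the configured cM/Mb rate; the bin whose median
#' pair distance is nearest the target is selected, and Ne is computed from
#' that bin's mean r2 with `c` taken as the bin's realized median distance
#' (in Morgans). Bins with no pairs are ignored; if no bin lies within a
#' factor of 2 of the target distance the point is omitted with a warning.
#'
#' @param bins An [ld_decay()] tibble (or several rows bound together for
#'   one group).
#' @param config An [ld_config()] supplying `recomb_rate_cm_mb` and
#'   `generations`.
#' @return A tibble: `generations_ago`, `c_morgans`, `target_distance`,
#'   `median_distance`, `mean_r2`, `ne`, with class `ne_trajectory`.
#' @export
ne_trajectory <- function(bins, config = ld_config()) {
  usable <- bins[!is.na(bins$mean_r2) & bins$n_pairs > 0, ]
  if (nrow(usable) == 0) abort("no usable LD bins")
  morgans_per_bp <- config$recomb_rate_cm_mb / 100 / 1e6
  rows <- purrr::map(config$generations, function(t) {
    c_target <- 1 / (2 * t)
    bp_target <- c_target / morgans_per_bp
    k <- which.min(abs(usable$median_distance - bp_target))
    med <- usable$median_distance[k]
    if (med > 2 * bp_target || med < bp_target / 2) {
      warn(sprintf(
        "no LD bin within a factor of 2 of the %g-generation target (%.3g bp); point omitted",
        t, bp_target
      ))
      return(NULL)
    }
    r2 <- usable$mean_r2[k]
    if (r2 <= 0) {
      warn(sprintf("non-positive mean r2 at t = %g; point omitted", t))
      return(NULL)
    }
    c_used <- med * morgans_per_bp
    tibble::tibble(
      generations_ago = t,
      c_morgans = c_used,
      target_distance = bp_target,
      median_distance = med,
      mean_r2 = r2,
      ne = ne_from_r2(min(r2, 1), c_used)
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ne_trajectory", class(out))
  out
}

#' SNP density implied by an LD decay distance
#'
#' Number of evenly spaced markers needed so that adjacent markers sit
#' within the distance at which LD remains useful:
#' `floor(genome_size / decay_distance)`. For a 2.4 Gb genome whose mean r2
#' stays above 0.2 out to 20 kb this gives 120,000 SNPs.
#'
#' @param genome_size Genome assembly size in bp.
#' @param decay_distance Distance in bp at which mean r2 drops below the
#'   working threshold.
#' @return Integer marker count.
#' @export
marker_density <- function(genome_size, decay_distance) {
  if (genome_size <= 0 || decay_distance <= 0) {
    abort("genome_size and decay_distance must be > 0")
  }
  floor(genome_size / decay_distance)
}

#' Distance at which an LD-decay curve crosses a threshold
#'
#' Scans the non-empty bins in increasing distance order and returns the
#' median distance of the last bin (starting from the shortest) whose mean
#' r2 is still at or above `threshold`; used to feed [marker_density()].
#' Returns `NA` when even the first bin is below the threshold.
#'
#' @param bins An [ld_decay()] tibble.
#' @param threshold Working r2 level (e.g. 0.2 for genomic selection, 0.3
#'   for association mapping).
#' @return Distance in bp (or `NA`).
#' @export
decay_distance <- function(bins, threshold = 0.2) {
  usable <- bins[!is.na(bins$mean_r2) & bins$n_pairs > 0, ]
  usable <- usable[order(usable$median_distance), ]
  above <- usable$mean_r2 >= threshold
  if (!above[1]) {
    return(NA_real_)
  }
  last <- if (all(above)) nrow(usable) else which(!above)[1] - 1
  usable$median_distance[last]
}
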