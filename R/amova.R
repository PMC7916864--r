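#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Partitions an individual-level squared-distance matrix into among-
#' supergroup, among-group-within-supergroup and within-group components in
#' the classic sums-of-squares framework: sums of squares are computed from
#' the squared distances, mean squares are equated to their expectations
#' with unequal-sample-size coefficients, and significance is assessed by
#' permutation -- whole groups are permuted across supergroups for the top
#' level, and samples are permuted across groups within their supergroup for
#' the middle level, with `p = (n_as_extreme + 1) / (n_perm + 1)`.
#'
#' Negative variance components are reported as computed, and additionally
#' truncated to zero for the percentage-of-variation breakdown (the common
#' AMOVA convention). With a single supergroup the top stratum is omitted
#' and a one-level AMOVA (among groups / within groups) is returned; a
#' supergroup containing a single group leaves the top-level component
#' reported but based on reduced information.
#'
#' @param d2 Symmetric squared-distance matrix with zero diagonal and
#'   sample ids as dimnames (e.g. from [dosage_dist2()]).
#' @param metadata Sample metadata tibble (`sample`, `group`,
#'   `supergroup`) covering every row of `d2`.
#' @param n_perm Number of permutations per tested stratum (default 999).
#' @param seed Integer seed for the permutations.
#' @return An object of class `popgenld_amova`: a list with `table` (tibble
#'   with columns `stratum`, `df`, `SS`, `MS`, `variance`,
#'   `variance_trunc`, `pct`, `p_value`), `n_perm`, `n_samples`.
#' @export
#'
#' @examples
#' sim <- sim_structured(c(A = 10, B = 10, C = 10), fst = 0.1,
#'                       n_loci = 300, supergroup = c("f1", "f1", "f2"),
#'                       seed = 5)
#' fit <- amova(dosage_dist2(sim$gm), sim$metadata, n_perm = 99, seed = 1)
#' tidy(fit)
amova <- function(d2, metadata, n_perm = 999, seed = NULL) {
  check_metadata(metadata)
  ids <- rownames(d2)
  if (is.null(ids) || !setequal(ids, metadata$sample)) {
    abort("dimnames(d2) must match metadata$sample")
  }
  if (max(abs(d2 - t(d2))) > 1e-8 || any(abs(diag(d2)) > 1e-12)) {
    abort("d2 must be symmetric with zero diagonal")
  }
  meta <- metadata[match(ids, metadata$sample), ]
  group <- as.character(meta$group)
  sgroup <- as.character(meta$supergroup)
  obs <- amova_components(d2, group, sgroup)

  with_seed(seed, {
    p_mid <- NA_real_
    p_top <- NA_real_
    if (n_perm > 0 && obs$df["among_groups"] > 0) {
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        pg <- permute_within(group, sgroup)
        perm <- amova_components(d2, pg, sgroup, need = "mid")
        if (perm$sigma["among_groups"] >= obs$sigma["among_groups"] - 1e-15) {
          cnt <- cnt + 1L
        }
      }
      p_mid <- (cnt + 1) / (n_perm + 1)
    }
    if (n_perm > 0 && !is.na(obs$df["among_supergroups"]) &&
        obs$df["among_supergroups"] > 0) {
      g2s <- group_to_supergroup(group, sgroup)
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        perm_map <- setNames(sample(g2s), names(g2s))
        psg <- unname(perm_map[group])
        perm <- amova_components(d2, group, psg, need = "top")
        if (perm$sigma["among_supergroups"] >=
              obs$sigma["among_supergroups"] - 1e-15) {
          cnt <- cnt + 1L
        }
      }
      p_top <- (cnt + 1) / (n_perm + 1)
    }

    strata <- names(obs$sigma)
    tab <- tibble::tibble(
      stratum = strata,
      df = unname(obs$df[strata]),
      SS = unname(obs$ss[strata]),
      MS = unname(obs$ss[strata] / obs$df[strata]),
      variance = unname(obs$sigma[strata]),
      variance_trunc = pmax(unname(obs$sigma[strata]), 0),
      p_value = dplyr::case_when(
        strata == "among_groups" ~ p_mid,
        strata == "among_supergroups" ~ p_top,
        TRUE ~ NA_real_
      )
    )
    tab$pct <- 100 * tab$variance_trunc / sum(tab$variance_trunc)
    tab <- dplyr::relocate(tab, "pct", .after = "variance_trunc")
    structure(
      list(table = tab, n_perm = n_perm, n_samples = length(ids)),
      class = "popgenld_amova"
    )
  })
}

# Variance components from squared distances for a (super)group labelling.
# `need` limits the work during permutations.
amova_components <- function(d2, group, sgroup, need = c("all", "mid", "top")) {
  need <- match.arg(need)
  n <- length(group)
  groups <- unique(group)
  sgroups <- unique(sgroup)
  G <- length(groups)
  S <- length(sgroups)

  half_sum <- function(idx) sum(d2[idx, idx]) / 2
  ss_tot <- half_sum(seq_len(n)) / n
  n_g <- table(group)[groups]
  n_s <- table(sgroup)[sgroups]
  ss_wg <- sum(vapply(groups, function(g) {
    idx <- which(group == g)
    half_sum(idx) / length(idx)
  }, 0))
  ss_ws <- sum(vapply(sgroups, function(s) {
    idx <- which(sgroup == s)
    half_sum(idx) / length(idx)
  }, 0))
  ss_ag <- ss_ws - ss_wg
  ss_as <- ss_tot - ss_ws

  df_c <- n - G
  df_b <- G - S
  df_a <- S - 1

  sig_c <- ss_wg / df_c
  # sum over supergroups of (sum of n_g^2 within) / n_s
  g_of_s <- vapply(groups, function(g) sgroup[match(g, group)], "")
  sum_ng2_ns <- sum(vapply(sgroups, function(s) {
    sum(n_g[g_of_s == s]^2) / n_s[[s]]
  }, 0))

  if (S == 1) {
    n1 <- (n - sum(n_g^2) / n) / max(df_b, 1)
    sig_b <- if (df_b > 0) (ss_ag / df_b - sig_c) / n1 else NA_real_
    sigma <- c(among_groups = sig_b, within_groups = sig_c)
    df <- c(among_groups = df_b, within_groups = df_c)
    ss <- c(among_groups = ss_ag + ss_as, within_groups = ss_wg)
    return(list(sigma = sigma, df = df, ss = ss))
  }

  n1 <- (n - sum_ng2_ns) / max(df_b, 1)
  sig_b <- if (df_b > 0) (ss_ag / df_b - sig_c) / n1 else 0
  sigma <- c(among_groups = sig_b)
  if (need %in% c("all", "top")) {
    n2 <- (sum_ng2_ns - sum(n_g^2) / n) / df_a
    n3 <- (n - sum(n_s^2) / n) / df_a
    sig_a <- (ss_as / df_a - sig_c - n2 * sig_b) / n3
    sigma <- c(among_supergroups = sig_a, sigma)
  } else {
    sigma <- c(among_supergroups = NA_real_, sigma)
  }
  sigma <- c(sigma, within_groups = sig_c)
  list(
    sigma = sigma,
    df = c(among_supergroups = df_a, among_groups = df_b, within_groups = df_c),
    ss = c(among_supergroups = ss_as, among_groups = ss_ag, within_groups = ss_wg)
  )
}

permute_within <- function(group, sgroup) {
  out <- group
  for (s in unique(sgroup)) {
    idx <- which(sgroup == s)
    out[idx] <- group[idx][sample.int(length(idx))]
  }
  out
}

group_to_supergroup <- function(group, sgroup) {
  groups <- unique(group)
  setNames(vapply(groups, function(g) sgroup[match(g, group)], ""), groups)
}

#' @export
#' @method print popgenld_amova
print.popgenld_amova <- function(x, ...) {
  cat("AMOVA (", x$n_samples, " samples, ", x$n_perm, " permutations)\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Tidy an AMOVA fit
#'
#' @param x A `popgenld_amova` object.
#' @param ... Unused.
#' @return `tidy()` returns the stratum table (one row per stratum);
#'   `glance()` returns a one-row summary.
#' @export
tidy.popgenld_amova <- function(x, ...) x$table

#' @rdname tidy.popgenld_amova
#' @export
glance.popgenld_amova <- function(x, ...) {
  tab <- x$table
  tibble::tibble(
    n_samples = x$n_samples,
    n_perm = x$n_perm,
    total_variance = sum(tab$variance_trunc),
    pct_among_groups = tab$pct[tab$stratum == "among_groups"],
    p_among_groups = tab$p_value[tab$stratum == "among_groups"],
    p_among_supergroups = if ("among_supergroups" %in% tab$stratum) {
      tab$p_value[tab$stratum == "among_supergroups"]
    } else {
      NA_real_
    }
  )
}
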