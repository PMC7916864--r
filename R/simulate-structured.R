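#' Simulate structured populations under the Balding-Nichols model
#'
#' Generates unlinked bi-allelic genotypes for `K` ancestral populations plus
#' optionally admixed groups. Per locus, an ancestral allele frequency `p` is
#' drawn uniformly from `maf_range`; population `k`'s frequency is drawn from
#' the Balding-Nichols distribution `Beta(p(1-F_k)/F_k, (1-p)(1-F_k)/F_k)`
#' with `F_k` the population's target Fst. Each individual carries an
#' admixture vector `q` on the K-simplex and its genotype at a locus is
#' `Binomial(2, sum_k q_k p_k)`. Loci where every population-level frequency
#' is fixed are redrawn (up to `max_resample` rounds, then an error).
#'
#' @param n_per_group Named integer vector of diploid sample counts, one per
#'   group; names become group labels (defaults `pop1..popG`).
#' @param fst Numeric vector of target Fst values, one per ancestral
#'   population (recycled to `K`); each in (0, 1).
#' @param K Number of ancestral populations; defaults to the number of
#'   columns of `admixture` when given, otherwise to the larger of
#'   `length(fst)` and the number of groups (so one Fst value shared by G
#'   groups means G independent ancestral populations).
#' @param admixture Optional `G x K` matrix of per-group admixture
#'   proportions (rows sum to 1). Default: group g is drawn purely from
#'   ancestral population `((g-1) mod K) + 1`.
#' @param n_loci Number of unlinked loci.
#' @param maf_range Ancestral-frequency sampler range (drawn as the minor
#'   allele frequency), default `c(0.1, 0.5)` so that little is lost to a
#'   MAF > 0.05 filter.
#' @param supergroup Optional character vector assigning each group to a
#'   supergroup (e.g. farm); default puts all groups in `"farm1"`.
#' @param n_scaffolds Loci are placed round-robin on this many scaffolds,
#'   1 Mb apart, so that they are effectively unlinked for LD analyses.
#' @param seed Integer seed; the generator is fully reproducible.
#' @param max_resample Redraw rounds allowed for fixed loci.
#'
#' @return A list with `gm` (a [geno_matrix()]), `metadata` (tibble), and
#'   `truth` (list with `ancestral_p`, `pop_freq` (loci x K), `admixture`
#'   (samples x K) and `fst`).
#' @export
#'
#' @examples
#' sim <- sim_structured(
#'   n_per_group = c(A = 20, B = 20), fst = 0.1,
#'   n_loci = 500, seed = 42
#' )
#' sim$gm
sim_structured <- function(n_per_group, fst, K = NULL,
                           admixture = NULL, n_loci = 1000,
                           maf_range = c(0.1, 0.5), supergroup = NULL,
                           n_scaffolds = 20, seed = NULL,
                           max_resample = 20) {
  if (any(fst <= 0 | fst >= 1)) abort("target fst must be in (0, 1)")
  K <- K %||% if (!is.null(admixture)) {
    ncol(as.matrix(admixture))
  } else {
    max(length(fst), length(n_per_group))
  }
  fst <- rep_len(fst, K)
  G <- length(n_per_group)
  groups <- names(n_per_group) %||% paste0("pop", seq_len(G))
  if (is.null(names(n_per_group))) names(n_per_group) <- groups
  if (is.null(admixture)) {
    admixture <- matrix(0, G, K)
    admixture[cbind(seq_len(G), ((seq_len(G) - 1) %% K) + 1)] <- 1
  }
  admixture <- as.matrix(admixture)
  if (nrow(admixture) != G || ncol(admixture) != K) {
    abort("admixture must be a groups x K matrix")
  }
  if (any(abs(rowSums(admixture) - 1) > 1e-8) || any(admixture < 0)) {
    abort("admixture rows must be non-negative and sum to 1")
  }
  supergroup <- supergroup %||% rep("farm1", G)

  with_seed(seed, {
    draw_locus_block <- function(m) {
      p <- runif(m, maf_range[1], maf_range[2])
      pk <- vapply(seq_len(K), function(k) {
        f <- fst[k]
        rbeta(m, p * (1 - f) / f, (1 - p) * (1 - f) / f)
      }, numeric(m))
      list(p = p, pk = matrix(pk, nrow = m))
    }
    blk <- draw_locus_block(n_loci)
    for (round in seq_len(max_resample)) {
      fixed <- rowSums(blk$pk > 0 & blk$pk < 1) == 0
      if (!any(fixed)) break
      redraw <- draw_locus_block(sum(fixed))
      blk$p[fixed] <- redraw$p
      blk$pk[fixed, ] <- redraw$pk
    }
    if (any(rowSums(blk$pk > 0 & blk$pk < 1) == 0)) {
      abort("could not avoid fixed loci; widen maf_range or lower fst")
    }

    q <- admixture[rep(seq_len(G), n_per_group), , drop = FALSE]
    n <- nrow(q)
    # expected individual-level allele frequency: loci x samples
    ind_p <- blk$pk %*% t(q)
    dosage <- matrix(
      rbinom(n_loci * n, 2, as.vector(ind_p)),
      nrow = n_loci, ncol = n, byrow = FALSE
    )

    ids <- paste0(rep(groups, n_per_group), "_",
                  unlist(lapply(n_per_group, seq_len)))
    scaf <- paste0("scaf", ((seq_len(n_loci) - 1) %% n_scaffolds) + 1)
    pos <- as.integer(((seq_len(n_loci) - 1) %/% n_scaffolds + 1) * 1e6)
    gm <- geno_matrix(
      t(dosage),
      variants = tibble::tibble(scaffold = scaf, pos = pos, ref = "A", alt = "G"),
      samples = ids
    )
    metadata <- tibble::tibble(
      sample = ids,
      group = rep(groups, n_per_group),
      supergroup = rep(supergroup, n_per_group)
    )
    truth <- list(
      ancestral_p = blk$p[order(scaf, pos)],
      pop_freq = blk$pk[order(scaf, pos), , drop = FALSE],
      admixture = q, fst = fst
    )
    list(gm = gm, metadata = metadata, truth = truth)
  })
}
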