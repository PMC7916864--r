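# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / first principles, never by calling the package
# path they check.

# --- pedigree inbreeding by path counting (Wright's method) -----------------
# F_X = sum over common ancestors A and non-overlapping path pairs of
# (1/2)^(n1+n2+1) * (1 + F_A). Valid for small pedigrees.
path_counting_f <- function(ped, individual) {
  parents <- function(id) {
    r <- ped[ped$individual == id, ]
    if (nrow(r) == 0) {
      return(c(NA, NA))
    }
    c(r$sire, r$dam)
  }
  # all ancestor paths from id up, as vectors id -> ... -> ancestor
  paths_up <- function(id) {
    out <- list(id)
    pr <- parents(id)
    for (p in pr[!is.na(pr)]) {
      out <- c(out, lapply(paths_up(p), function(pp) c(id, pp)))
    }
    out
  }
  pr <- parents(individual)
  if (any(is.na(pr))) {
    return(0)
  }
  ps <- paths_up(pr[1])
  pd <- paths_up(pr[2])
  f <- 0
  for (a in ps) {
    for (b in pd) {
      anc <- a[length(a)]
      if (anc != b[length(b)]) next
      # paths may share only the common ancestor itself
      if (length(intersect(a[-length(a)], b[-length(b)])) > 0) next
      n1 <- length(a) - 1
      n2 <- length(b) - 1
      f <- f + 0.5^(n1 + n2 + 1) * (1 + path_counting_f(ped, anc))
    }
  }
  f
}

# --- Burrows composite D, direct cell-by-cell evaluation --------------------
burrows_direct <- function(tab) {
  n <- sum(tab)
  s <- 0
  sa <- 0
  sb <- 0
  for (i in 0:2) {
    for (j in 0:2) {
      cnt <- tab[i + 1, j + 1]
      s <- s + cnt * i * j
      sa <- sa + cnt * i
      sb <- sb + cnt * j
    }
  }
  pa <- sa / (2 * n)
  pb <- sb / (2 * n)
  (n / (n - 1)) * (s / (2 * n) - 2 * pa * pb)
}

# --- haplotype enumeration for double-het-free tables -----------------------
# Each non-double-het genotype pair resolves into two unambiguous haplotypes;
# returns the plain haplotype-count D = P_AB - pA pB and allele freqs.
hap_enum_d <- function(tab) {
  stopifnot(tab[2, 2] == 0)
  haps <- matrix(0, 0, 2)
  for (i in 0:2) {
    for (j in 0:2) {
      cnt <- tab[i + 1, j + 1]
      if (cnt == 0) next
      h1 <- c(as.integer(i >= 1), as.integer(j >= 1))
      h2 <- c(as.integer(i == 2), as.integer(j == 2))
      for (k in seq_len(cnt)) haps <- rbind(haps, h1, h2)
    }
  }
  p_ab <- mean(haps[, 1] == 1 & haps[, 2] == 1)
  p_a <- mean(haps[, 1])
  p_b <- mean(haps[, 2])
  list(d = p_ab - p_a * p_b, p_a = p_a, p_b = p_b)
}

# all 3x3 count tables with total n (compositions of n into 9 cells)
enumerate_tables <- function(n) {
  out <- list()
  rec <- function(cells, left) {
    if (length(cells) == 8) {
      out[[length(out) + 1]] <<- matrix(c(cells, left), 3, 3)
      return()
    }
    for (v in 0:left) rec(c(cells, v), left - v)
  }
  rec(integer(0), n)
  out
}

# --- naive Nei (1972) distance from two frequency vectors -------------------
nei_direct <- function(pa, pb) {
  ja <- 0
  jb <- 0
  jab <- 0
  L <- length(pa)
  for (l in seq_len(L)) {
    ja <- ja + pa[l]^2 + (1 - pa[l])^2
    jb <- jb + pb[l]^2 + (1 - pb[l])^2
    jab <- jab + pa[l] * pb[l] + (1 - pa[l]) * (1 - pb[l])
  }
  -log((jab / L) / sqrt((ja / L) * (jb / L)))
}
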