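---
title: "Methods: diversity, ROH, differentiation and LD-based Ne in popgenld"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: diversity, ROH, differentiation and LD-based Ne in popgenld}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popgenld)
```

popgenld characterises farmed-animal populations from whole-genome SNP
genotypes: per-group diversity and inbreeding, runs of homozygosity,
population differentiation, and linkage-disequilibrium (LD) decay with
LD-based effective-population-size (Ne) trajectories. This vignette is the
package's own account of the statistical machinery, the choices behind it,
and what the bundled simulators can and cannot tell you about real data.

## Genotype model and site filters

All analyses operate on a `geno_matrix`: samples x variants alternate-allele
dosages (0/1/2, `NA` for a missing call) with a scaffold/position map.
`read_vcf()` keeps only bi-allelic SNP records. `apply_filters()` retains
sites with MAF > 0.05, missing rate < 0.1 and QUAL > 30 by default, all
strict inequalities. MAF is computed across **all** samples jointly: the
intended workflow filters the pooled sample set once and then analyses
subgroups, so per-group MAF in `group_diversity()` is descriptive, not a
filter. Genotype-level qualities (GQ) are not used. Coordinates are 1-based
and all distances are in base pairs.

## Inbreeding coefficients

**F_HOM** (`f_hom()`) is the method-of-moments excess-homozygosity
coefficient $F = (O_{hom} - E_{hom}) / (m - E_{hom})$ with
$E_{hom} = \sum_j \big(1 - 2 p_j (1-p_j)\, \tfrac{2N_j}{2N_j - 1}\big)$,
the small-sample-corrected expected homozygote count. Under Hardy–Weinberg
the estimator is centred at 0; heterozygote excess drives it negative
(bounded near $-1$), complete homozygosity gives exactly 1. Reference
frequencies $p_j$ default to the pooled sample set because the natural
reporting unit is a pooled panel with group breakdowns; a
`freq_scope = "group"` switch recomputes them within each sample's group.

**F_PED** (`f_ped()`) is Wright's coefficient via the recursive tabular
(additive-relationship) method, founders at $F = 0$. The test suite checks
it against an independent path-counting oracle on designed and random
pedigrees.

**F_ROH** (`f_roh()`) is the fraction of the callable genome covered by
runs of homozygosity at least as long as a threshold (500 kb, 1 Mb and 2 Mb
by default; the three results are nested, so F_ROH is non-increasing in the
threshold). The callable length $L$ is a configuration input; the pipeline
defaults to the observed span of the analysed scaffolds.

## ROH detection

`detect_roh()` slides a window of 20 consecutive SNPs one SNP at a time. A
window is homozygous when its heterozygote count does not exceed
`floor(error_rate * window)`; with the default error rate of 0.01 the
budget is **zero**, so a single heterozygote breaks a run. This is a
deliberate, strict reading of the three window parameters: it is
appropriate for high-coverage sequence genotypes, and it makes the
detector's behaviour easy to reason about (every SNP inside a reported
segment is homozygous or missing). Missing calls are non-informative: they
neither count as heterozygous nor break a run, which is safe because the
missing-rate filter bounds missingness below 10%. Segment boundaries are
the outermost SNP positions of the merged homozygous windows — conservative
and simple. One consequence, documented and tested: a segment's ends snap
to the genuinely homozygous background run flanking a true autozygous
tract, so boundary spill of a few inter-SNP gaps is irreducible for any
genotype-only detector.

## Differentiation

`nei_distance()` implements Nei's standard distance $D = -\ln I$ with the
gene identities averaged over loci before the ratio; loci monomorphic in
both groups contribute identity 1, and disjointly fixed panels are flagged
as infinite. `wc_fst()` implements Weir–Cockerham $\theta$ as a **ratio of
sums** of the per-locus variance components $a$, $b$, $c$ (the standard
recommendation; averaging per-locus ratios is noisier and biased), with
pooled-monomorphic loci excluded — they contribute zero to both sums.
$\theta$ may be slightly negative in undifferentiated data; that is a
property of the estimator, not an error.

`amova()` partitions an individual-level squared-distance matrix into
among-supergroup (farm), among-group-within-supergroup (colour-type) and
within-group components, equating mean squares to expectations with
unequal-sample-size coefficients. The distance fed by the pipeline is the
mean squared dosage difference over shared non-missing loci
(`dosage_dist2()`); the distance is configurable because distance-matrix
AMOVA is defined for any squared dissimilarity. Significance is by
permutation: whole groups across supergroups for the top stratum, samples
across groups within their supergroup for the middle stratum, with the
$(x+1)/(n+1)$ correction and 999 permutations by default. Negative variance
components are reported as computed and truncated to zero for the
percentage breakdown (the common AMOVA convention); both values are
emitted.

## Composite LD and Ne

With unphased genotypes, haplotype frequencies are not observable, so
`composite_d()` uses Burrows' composite disequilibrium
$$\hat\Delta = \frac{N}{N-1}\left(\frac{\sum_i X_i Y_i}{2N} - 2\hat p_A \hat p_B\right),$$
where $X_i, Y_i$ are the two dosages. The bracketed sum captures gametic
plus non-gametic (cross-gamete, within-individual) associations; under
random union of gametes the non-gametic part has expectation zero, so
$\hat\Delta$ estimates the gametic $D$ without phase. On
phased-equivalent data (no double heterozygotes) the two associations
coincide SNP by SNP, giving the exact identity
$\hat\Delta = 2\,\tfrac{N}{N-1}\,\hat D_{hap}$ that the test suite checks
exhaustively against a haplotype-enumeration oracle on all small tables.

`pair_r2()` computes $r^2 = \hat\Delta^2 / (p_A p_a p_B p_b)$ over the
samples non-missing at both loci, then applies the haplotype-sample-size
correction $r^2_c = (r^2 - 1/n)/(1 - 1/n)$ with $n$ = 2 x diploid count.
Corrected values are clamped to $[0, 1]$: the correction can produce small
negatives at low true LD, and negative mass would bias the Sved inversion
upward. Group-restricted analyses recompute allele frequencies within the
group and skip pairs monomorphic there.

`ld_decay()` subsamples SNPs (default 100,000, seeded, scaffolds >= 10 Mb
only), forms all same-scaffold pairs up to a maximum distance, and bins
them in half-open distance intervals; the bin summary uses the median of
realized pair distances (midpoint fallback for empty bins). The pipeline
runs three distance sets — <= 100 kb / 10 kb bins, <= 1 Mb / 100 kb bins,
<= 10 Mb / 1 Mb bins.

`ne_from_r2()` inverts Sved's drift expectation
$E[r^2] = 1/(1 + 4 N_e c)$, and `ne_trajectory()` dates each estimate at
$t = 1/(2c)$ generations ago: at the default 1 cM/Mb, $t = 5$ maps to
10 Mb and $t = 200$ to 250 kb. No additional $1/n$ term is added inside
the expectation because the sample-size correction has already been applied
to $r^2$. For each requested $t$ the bin whose median distance is nearest
the target is selected; $c$ is taken from the bin's realized median (the
median recombination distance of the pairs actually used), and points with
no bin within a factor of two of the target are omitted with a warning.
`marker_density()` converts the distance at which mean $r^2$ drops below a
working threshold (0.2 for genomic selection, 0.3 for association mapping)
into a panel size, `floor(genome / distance)`.

## What the simulators emulate

The package is exercised end to end against generators with known truth:

* `sim_structured()` — Balding–Nichols structure: population $k$'s
  frequency is $\mathrm{Beta}(p(1-F_k)/F_k,\,(1-p)(1-F_k)/F_k)$ around an
  ancestral $p$, individuals draw genotypes binomially through their
  admixture vectors. This parameterisation makes the target $F_k$ directly
  comparable to Weir–Cockerham $\theta$. Ancestral MAF is uniform on
  (0.1, 0.5) by default so little is lost to the MAF > 0.05 filter. Loci
  are unlinked (spread 1 Mb apart over many scaffolds).
* `sim_wright_fisher()` — a forward-in-time discrete-generation population
  of $2N_e$ haplotypes with Poisson crossovers and random union of
  gametes. Forward simulation keeps the LD/Ne ground truth transparent:
  all terminal LD is generated by drift at the configured $N_e$ and broken
  by the configured recombination rate.
* `plant_roh()` — forces autozygous tracts, choosing the sample's
  scaffold-wide major allele as the homozygote so allele frequencies are
  minimally disturbed; an error rate can inject in-tract heterozygotes.
* `sim_pedigree()` — full-sib, half-sib and random designs with the
  textbook inbreeding coefficients attached.

These emulate drift, structure, admixture and autozygosity — not mutation,
selection, variable recombination maps, genotyping-error processes or
reference-alignment artefacts. Passing recovery tests therefore shows the
estimators are correct under their own model assumptions; it does not
certify behaviour under, say, assembly errors that manufacture spurious
long-range LD.

## Numerical and design notes

* Filtering is idempotent, and every generator is reproducible from its
  seed; package functions never disturb the caller's RNG state.
* Window arithmetic in `detect_roh()` uses cumulative sums, so detection is
  $O(\text{SNPs})$ per sample and scaffold; scaffolds with fewer SNPs than
  one window yield no segments rather than an error.
* Pairwise r2 is computed with missingness-exact pairwise-complete counts
  in blocks of 200,000 pairs to bound memory.
* Degenerate inputs fail loudly: all variants filtered out, monomorphic
  loci in `composite_d()`, $m = E_{hom}$ in `f_hom()`, pedigree cycles,
  $I = 0$ in Nei's distance, and $r^2 \ge 1$ in the Sved inversion are all
  explicit errors, warnings or flagged values rather than silent `NaN`s.
* Problem sizes in the test and acceptance workloads (e.g. 20,000 unlinked
  loci for Fst recovery, a 10 Mb chromosome with ~2,500 start loci and 200
  generations for Ne recovery, 200 replicates x 199 permutations for the
  AMOVA null) were chosen as the smallest designs at which the targeted
  tolerances are comfortably identifiable.
* The orchestration layer is a pair of R functions (`run_all()`,
  `simulate_and_run()`) rather than a shell executable: the package's users
  drive analyses from R, and the report bundle (TSV tables with a
  version + parameter-hash header) keeps runs byte-reproducible under a
  fixed seed.

## Known limitations

* The composite r2 denominator uses allele-frequency products (the classic
  definition); under strong departures from Hardy–Weinberg the composite
  correlation with genotypic-variance denominators would be better behaved.
* Sved's expectation is an approximation; inverting it propagates its bias,
  most visibly at short distances (old generations) where mutation and
  sampling matter, and estimates inherit the usual upward-Ne bias when the
  clamped-at-zero r2 mass is large.
* AMOVA permutation of whole groups across supergroups has limited
  resolution when there are few groups; the top-stratum p-value is then
  coarse by construction.
* `detect_roh()` with the default zero heterozygote budget will split true
  autozygous tracts at genotyping errors; raise `error_rate` (the budget is
  `floor(error_rate * window)`) if your genotypes are noisier than
  high-coverage sequence data.
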