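#' Full-analysis configuration
#'
#' Bundles the stage configurations used by [run_all()]. The defaults
#' reproduce the standard whole-genome workflow: MAF/missing/QUAL site
#' filters, 20-SNP ROH windows with thresholds 500 kb / 1 Mb / 2 Mb,
#' composite-r2 LD decay in three distance sets (<= 100 kb in 10 kb bins,
#' <= 1 Mb in 100 kb bins, <= 10 Mb in 1 Mb bins), Sved Ne at 200, 150,
#' 100, 50, 10 and 5 generations ago, and marker-density recommendations at
#' r2 thresholds 0.2 and 0.3.
#'
#' @param filter A [filter_spec()], or `NULL` to skip filtering.
#' @param roh A [roh_params()].
#' @param roh_thresholds F_ROH length thresholds in bp.
#' @param callable_length Callable genome length L for F_ROH; `NULL` uses
#'   the total observed span of the analysed scaffolds.
#' @param ld An [ld_config()].
#' @param ld_sets List of `c(max_distance, bin_size)` pairs.
#' @param genome_size Assembly size used for marker-density output.
#' @param amova_perm AMOVA permutation count.
#' @param stages Character vector of stages to run, a subset of
#'   `c("diversity", "roh", "differentiation", "amova", "ld", "ne")`.
#' @param seed Global seed; stage seeds are derived deterministically.
#' @return A list of class `run_config`.
#' @export
run_config <- function(filter = filter_spec(),
                       roh = roh_params(),
                       roh_thresholds = c(5e5, 1e6, 2e6),
                       callable_length = NULL,
                       ld = ld_config(),
                       ld_sets = list(c(1e5, 1e4), c(1e6, 1e5), c(1e7, 1e6)),
                       genome_size = 2.4e9,
                       amova_perm = 999,
                       stages = c("diversity", "roh", "differentiation",
                                  "amova", "ld", "ne"),
                       seed = NULL) {
  structure(
    list(
      filter = filter, roh = roh, roh_thresholds = roh_thresholds,
      callable_length = callable_length, ld = ld, ld_sets = ld_sets,
      genome_size = genome_size, amova_perm = amova_perm,
      stages = stages, seed = seed
    ),
    class = "run_config"
  )
}

#' Run the full population-genomic analysis
#'
#' Orchestrates filtering, per-group diversity, ROH / F_ROH, pairwise
#' Nei / Fst, AMOVA, adjacent-SNP r2, LD decay curves, Ne trajectories and
#' marker-density recommendations, returning all results as a named list of
#' tibbles (a "report bundle"). When `out_dir` is given every table is also
#' written as TSV with a header comment recording the package version and a
#' hash of the run parameters; identical inputs, configuration and seed
#' yield byte-identical files.
#'
#' @param gm A [geno_matrix()] (e.g. from [read_vcf()]).
#' @param metadata Sample metadata tibble.
#' @param config A [run_config()].
#' @param out_dir Optional output directory for TSV tables.
#' @return A named list with elements (depending on enabled stages)
#'   `diversity`, `roh_segments`, `froh`, `roh_group_summary`,
#'   `differentiation`, `amova`, `adjacent_r2`, `ld_decay`,
#'   `ne_trajectory`, `marker_density`, and `manifest`.
#' @export
run_all <- function(gm, metadata, config = run_config(), out_dir = NULL) {
  check_metadata(metadata)
  stages <- config$stages
  bundle <- list()

  if (!is.null(config$filter)) {
    gm <- apply_filters(gm, config$filter)
  }
  groups <- unique(metadata$group)

  run_stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  if ("diversity" %in% stages) {
    bundle$diversity <- run_stage("diversity", group_diversity(gm, metadata))
  }

  if ("roh" %in% stages) {
    bundle_roh <- run_stage("roh", {
      params <- config$roh
      params$min_length <- min(config$roh_thresholds)
      segs <- detect_roh(gm, params = params)
      L <- config$callable_length %||% sum(tapply(
        gm$variants$pos, gm$variants$scaffold, function(p) max(p) - min(p) + 1
      ))
      fr <- f_roh(segs, L, thresholds = config$roh_thresholds,
                  samples = gm$samples) |>
        dplyr::left_join(
          dplyr::select(metadata, "sample", "group"), by = "sample"
        )
      summ <- fr |>
        dplyr::group_by(.data$group, .data$threshold) |>
        dplyr::summarise(
          mean_n_segments = mean(.data$n_segments),
          sd_n_segments = sd(.data$n_segments),
          mean_f_roh = mean(.data$f_roh),
          sd_f_roh = sd(.data$f_roh),
          .groups = "drop"
        )
      list(segs = segs, fr = fr, summ = summ)
    })
    bundle$roh_segments <- bundle_roh$segs
    bundle$froh <- bundle_roh$fr
    bundle$roh_group_summary <- bundle_roh$summ
  }

  if ("differentiation" %in% stages) {
    bundle$differentiation <- run_stage(
      "differentiation", pair_divergence(gm, metadata)
    )
  }

  if ("amova" %in% stages) {
    bundle$amova <- run_stage("amova", tidy(amova(
      dosage_dist2(gm), metadata,
      n_perm = config$amova_perm, seed = derive_seed(config$seed, 1)
    )))
  }

  if ("ld" %in% stages) {
    ld_res <- run_stage("ld", {
      cfg <- config$ld
      cfg$seed <- cfg$seed %||% derive_seed(config$seed, 2)
      adj <- dplyr::bind_rows(c(
        purrr::map(groups, ~ adjacent_r2(gm, metadata, group = .x)),
        list(adjacent_r2(gm))
      ))
      bins <- dplyr::bind_rows(purrr::map(config$ld_sets, function(set) {
        dplyr::bind_rows(c(
          purrr::map(
            groups,
            ~ ld_decay(gm, set[1], set[2], metadata, group = .x, config = cfg)
          ),
          list(ld_decay(gm, set[1], set[2], config = cfg))
        )) |>
          dplyr::mutate(max_distance = set[1], bin_size = set[2])
      }))
      list(adj = adj, bins = bins, cfg = cfg)
    })
    bundle$adjacent_r2 <- ld_res$adj
    bundle$ld_decay <- ld_res$bins

    if ("ne" %in% stages) {
      ne_res <- run_stage("ne", {
        traj <- dplyr::bind_rows(purrr::map(
          unique(ld_res$bins$group),
          function(g) {
            b <- ld_res$bins[ld_res$bins$group == g, ]
            suppressWarnings(ne_trajectory(b, ld_res$cfg)) |>
              dplyr::mutate(group = g)
          }
        ))
        fine <- ld_res$bins[
          ld_res$bins$group == "all" &
            ld_res$bins$bin_size == min(vapply(config$ld_sets, `[`, 0, 2)),
        ]
        dens <- purrr::map(c(0.2, 0.3), function(th) {
          dd <- decay_distance(fine, th)
          tibble::tibble(
            r2_threshold = th,
            decay_distance = dd,
            n_snps = if (is.na(dd)) NA_real_ else marker_density(config$genome_size, dd)
          )
        }) |>
          dplyr::bind_rows()
        list(traj = traj, dens = dens)
      })
      bundle$ne_trajectory <- ne_res$traj
      bundle$marker_density <- ne_res$dens
    }
  }

  bundle$manifest <- run_manifest(config)
  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir, config)
  }
  bundle
}

run_manifest <- function(config) {
  flat <- unlist(config, use.names = TRUE)
  tibble::tibble(
    parameter = c("package_version", "parameter_hash", names(flat)),
    value = c(
      as.character(utils::packageVersion("popgenld")),
      rlang::hash(config),
      vapply(flat, function(x) paste(format(x), collapse = ","), "")
    )
  )
}

write_bundle <- function(bundle, out_dir, config) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  header <- c(
    paste0("# popgenld ", utils::packageVersion("popgenld")),
    paste0("# params ", rlang::hash(config))
  )
  for (nm in names(bundle)) {
    path <- file.path(out_dir, paste0(nm, ".tsv"))
    writeLines(header, path)
    suppressWarnings(readr::write_tsv(bundle[[nm]], path, append = TRUE,
                                      col_names = TRUE))
  }
  invisible(out_dir)
}

#' Simulate a preset dataset, analyse it, and compare with truth
#'
#' Generates one of three synthetic study designs, pushes it through
#' [run_all()], and appends a truth-versus-estimate comparison table:
#'
#' * `"structured-3pop"`: three Balding-Nichols populations on two farms;
#'   comparison of target vs realized pairwise Fst.
#' * `"constant-ne"`: constant-size Wright-Fisher chromosome; comparison of
#'   true vs estimated Ne per reported generation.
#' * `"planted-roh"`: Hardy-Weinberg background with planted autozygous
#'   tracts; comparison of planted vs detected genome fraction (F_ROH) per
#'   sample.
#'
#' @param preset One of `"structured-3pop"`, `"constant-ne"`,
#'   `"planted-roh"`.
#' @param seed Integer seed driving both simulation and analysis.
#' @param out_dir Optional output directory (TSVs, as in [run_all()]).
#' @return The [run_all()] bundle with an extra `truth_comparison` tibble.
#' @export
simulate_and_run <- function(preset = c("structured-3pop", "constant-ne",
                                        "planted-roh"),
                             seed = 1, out_dir = NULL) {
  preset <- match.arg(preset)
  sim_seed <- derive_seed(seed, 10)

  if (preset == "structured-3pop") {
    fst <- c(0.05, 0.05, 0.10)
    sim <- sim_structured(
      n_per_group = c(demi = 25, pastel = 25, black = 25),
      fst = fst, n_loci = 3000,
      supergroup = c("farmA", "farmA", "farmB"), seed = sim_seed
    )
    config <- run_config(
      filter = filter_spec(min_qual = NULL),
      stages = c("diversity", "differentiation", "amova"),
      amova_perm = 199, seed = seed
    )
    bundle <- run_all(sim$gm, sim$metadata, config, out_dir = NULL)
    cmp <- bundle$differentiation |>
      dplyr::mutate(
        target_fst = purrr::map2_dbl(.data$group_a, .data$group_b, function(a, b) {
          lv <- unique(sim$metadata$group)
          mean(fst[c(match(a, lv), match(b, lv))])
        })
      ) |>
      dplyr::select("group_a", "group_b", "target_fst", realized_fst = "fst")
  } else if (preset == "constant-ne") {
    true_ne <- 100
    sim <- sim_wright_fisher(
      ne = true_ne, n_generations = 150, chrom_length = 1e7,
      recomb_rate = 1e-8, sample_size = 50, n_loci = 1500, seed = sim_seed
    )
    meta <- tibble::tibble(
      sample = sim$gm$samples, group = "sim", supergroup = "sim"
    )
    config <- run_config(
      filter = filter_spec(min_qual = NULL),
      ld = ld_config(n_snps = Inf, min_scaffold_length = 0),
      stages = c("diversity", "ld", "ne"), seed = seed
    )
    bundle <- run_all(sim$gm, meta, config, out_dir = NULL)
    cmp <- bundle$ne_trajectory |>
      dplyr::filter(.data$group == "all") |>
      dplyr::mutate(true_ne = true_ne) |>
      dplyr::select("generations_ago", "true_ne", estimated_ne = "ne")
  } else {
    gm <- sim_hw_genotypes(
      n_samples = 12, n_snps = 3000, spacing = 1e4, seed = sim_seed
    )
    span <- max(gm$variants$pos) - min(gm$variants$pos) + 1
    tracts <- with_seed(derive_seed(seed, 11), {
      dplyr::bind_rows(purrr::map(gm$samples[1:8], function(id) {
        n_tr <- sample(1:2, 1)
        starts <- sort(sample.int(span - 4e6, n_tr))
        while (n_tr == 2 && diff(starts) < 4e6) {
          starts <- sort(sample.int(span - 4e6, n_tr))
        }
        tibble::tibble(
          sample = id, scaffold = "scaf1",
          start = starts,
          end = starts + sample(seq(5e5, 3e6, by = 5e5), n_tr, replace = TRUE)
        )
      }))
    })
    gm <- plant_roh(gm, tracts)
    meta <- tibble::tibble(
      sample = gm$samples, group = "sim", supergroup = "sim"
    )
    config <- run_config(
      filter = filter_spec(min_qual = NULL),
      callable_length = span,
      stages = c("diversity", "roh"), seed = seed
    )
    bundle <- run_all(gm, meta, config, out_dir = NULL)
    planted <- tracts |>
      dplyr::group_by(.data$sample) |>
      dplyr::summarise(
        planted_fraction = sum(.data$end - .data$start + 1) / span,
        .groups = "drop"
      )
    cmp <- bundle$froh |>
      dplyr::filter(.data$threshold == 5e5) |>
      dplyr::left_join(planted, by = "sample") |>
      dplyr::mutate(planted_fraction = dplyr::coalesce(.data$planted_fraction, 0)) |>
      dplyr::select("sample", "planted_fraction", detected_f_roh = "f_roh")
  }

  bundle$truth_comparison <- cmp
  if (!is.null(out_dir)) {
    write_bundle(bundle, out_dir, list(preset = preset, seed = seed))
  }
  bundle
}
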