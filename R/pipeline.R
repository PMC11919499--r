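#' Pipeline configuration
#'
#' Builds (or reads from JSON) the configuration driving the staged pipeline:
#' variant design, ribosome-density simulation with flux-matched selection,
#' synthetic-dataset generation, per-cell fitting, and the normalization /
#' statistics stage. Every stage writes its outputs under `outdir` together
#' with a provenance record (package version, seed, config hash).
#'
#' @param orf_fasta Path to the ORF FASTA (default: bundled eGFP CDS).
#' @param rate_table Path to a codon rate TSV, or `NULL` for the built-in
#'   usage-derived table.
#' @param guides_fasta Path to the siRNA guide FASTA (default: bundled
#'   synthetic guides).
#' @param outdir Output directory.
#' @param window_len Slow-window length (codons).
#' @param k_select Number of flux-matched variants to carry forward.
#' @param sim Named list overriding [sim_params()] fields.
#' @param synth Named list overriding [cell_sim_config()] fields.
#' @param km,beta Fixed kinetic constants for fitting.
#' @param seed Global seed; stage seeds are derived from it.
#' @param n_sim_variants `"all"` or an integer cap on how many variants are
#'   simulated in the simulate stage (subsampled evenly along the ORF).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(orf_fasta = system.file("extdata", "egfp_cds.fasta",
                                                    package = "slowcodon"),
                            rate_table = NULL,
                            guides_fasta = system.file("extdata",
                                                       "sirna_guides_synthetic.fasta",
                                                       package = "slowcodon"),
                            outdir = "slowcodon_out",
                            window_len = 10L, k_select = 5L,
                            sim = list(), synth = list(),
                            km = 1.2, beta = 0.03, seed = 1L,
                            n_sim_variants = "all") {
  structure(list(orf_fasta = orf_fasta, rate_table = rate_table,
                 guides_fasta = guides_fasta, outdir = outdir,
                 window_len = as.integer(window_len),
                 k_select = as.integer(k_select),
                 sim = sim, synth = synth, km = km, beta = beta,
                 seed = as.integer(seed), n_sim_variants = n_sim_variants),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path JSON file with `pipeline_config` fields.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

config_rates <- function(config) {
  if (is.null(config$rate_table)) default_elongation_rates()
  else read_rate_table(config$rate_table)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, null = "null")
  unname(tools::md5sum(tmp))
}

write_provenance <- function(config, stage, outputs) {
  rec <- list(stage = stage,
              package = "slowcodon",
              version = as.character(utils::packageVersion("slowcodon")),
              seed = config$seed,
              config_hash = config_hash(config),
              outputs = outputs,
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  path <- file.path(config$outdir, paste0(stage, ".provenance.json"))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

ensure_outdir <- function(config) {
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
}

#' Pipeline stage: slow-window variants and siRNA site reports
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the variants tibble and site report.
#' @export
pipeline_variants <- function(config) {
  ensure_outdir(config)
  orf <- read_orf(config$orf_fasta)
  rates <- config_rates(config)
  variants <- slow_window_variants(orf, rates, config$window_len)
  fa <- file.path(config$outdir, "variants.fasta")
  write_variants_fasta(variants, fa)

  guides <- read_guides(config$guides_fasta)
  sites <- dplyr::bind_rows(purrr::map2(
    guides$guide, guides$sirna_id,
    function(g, id) dplyr::bind_rows(
      map_sirna_sites(orf, g, id),
      dplyr::filter(scan_seed_matches(orf, g, id), .data$kind == "seed")
    )
  ))
  rep_path <- file.path(config$outdir, "sirna_sites.tsv")
  write_site_report(sites, rep_path)
  safety <- check_variant_seed_safety(variants, guides)
  safety_path <- file.path(config$outdir, "seed_safety.tsv")
  utils::write.table(
    dplyr::select(safety, -dplyr::all_of(c("gained", "lost"))),
    safety_path, sep = "\t", quote = FALSE, row.names = FALSE)

  write_provenance(config, "variants", c(fa, rep_path, safety_path))
  invisible(list(orf = orf, variants = variants, sites = sites, safety = safety))
}

stage_sim_params <- function(config) {
  do.call(sim_params, utils::modifyList(list(rng_seed = config$seed), config$sim))
}

#' Pipeline stage: density profiles and flux-matched selection
#'
#' Simulates the unmutated ORF and the variant set (all of them, or an even
#' subsample when `config$n_sim_variants` is an integer), writes per-codon
#' profiles and a flux summary, and selects the `k_select` variants whose
#' flux is closest to the unmutated reference.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly: list with `reference`, `profiles`, `selection`.
#' @export
pipeline_simulate <- function(config) {
  ensure_outdir(config)
  orf <- read_orf(config$orf_fasta)
  rates <- config_rates(config)
  variants <- slow_window_variants(orf, rates, config$window_len)
  if (!identical(config$n_sim_variants, "all")) {
    n <- min(as.integer(config$n_sim_variants), nrow(variants))
    idx <- unique(round(seq(1, nrow(variants), length.out = n)))
    variants <- variants[idx, ]
  }
  base <- stage_sim_params(config)
  reference <- simulate_density(orf, rates, base)
  profiles <- purrr::map(seq_len(nrow(variants)), function(i) {
    vorf <- orf_from_sequence(variants$sequence[i], id = variants$variant_id[i])
    p <- base
    p$rng_seed <- config$seed + i
    simulate_density(vorf, rates, p)
  })
  selection <- select_flux_matched(profiles, reference,
                                   min(config$k_select, length(profiles)))

  prof_path <- file.path(config$outdir, "density_profiles.tsv")
  all_prof <- dplyr::bind_rows(lapply(c(list(reference), profiles), as.data.frame))
  utils::write.table(all_prof, prof_path, sep = "\t", quote = FALSE, row.names = FALSE)
  flux_path <- file.path(config$outdir, "flux_summary.json")
  jsonlite::write_json(
    list(reference_flux = flux(reference),
         params = unclass(base),
         selection = selection),
    flux_path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  write_provenance(config, "simulate", c(prof_path, flux_path))
  invisible(list(reference = reference, profiles = profiles, selection = selection))
}

#' Pipeline stage: synthetic dataset
#'
#' @param config A [pipeline_config()].
#' @param conditions Condition table; defaults to unmutated eGFP under the
#'   four siRNA conditions with a strong knockdown planted for the targeting
#'   siRNAs.
#' @return Invisibly, the `synthetic_dataset`.
#' @export
pipeline_synth <- function(config, conditions = NULL) {
  ensure_outdir(config)
  if (is.null(conditions)) {
    conditions <- condition_table("eGFP") |>
      dplyr::mutate(delta_mult = ifelse(.data$sirna %in% c("siRNA1", "siRNA2"),
                                        10, 1))
  }
  cfg <- do.call(cell_sim_config,
                 utils::modifyList(list(rng_seed = config$seed, km = config$km,
                                        beta = config$beta), config$synth))
  ds <- simulate_dataset(cfg, conditions)
  traj_path <- file.path(config$outdir, "trajectories.csv")
  truth_path <- file.path(config$outdir, "truth.csv")
  write_trajectories(ds$trajectories, traj_path)
  utils::write.csv(ds$truth, truth_path, row.names = FALSE)
  write_provenance(config, "synth", c(traj_path, truth_path))
  invisible(ds)
}

#' Pipeline stage: per-cell kinetic fits
#'
#' @param config A [pipeline_config()].
#' @param trajectories Trajectory tibble; defaults to the synth stage output
#'   on disk.
#' @return Invisibly, the fit table.
#' @export
pipeline_fit <- function(config, trajectories = NULL) {
  ensure_outdir(config)
  if (is.null(trajectories)) {
    traj_path <- file.path(config$outdir, "trajectories.csv")
    if (!file.exists(traj_path)) {
      stop("no trajectories found at ", traj_path, "; run pipeline_synth first",
           call. = FALSE)
    }
    trajectories <- read_trajectories(traj_path)
  }
  if (nrow(trajectories) == 0) stop("empty trajectory table", call. = FALSE)
  fits <- fit_cells(trajectories, km = config$km, beta = config$beta,
                    seed = config$seed)
  fit_path <- file.path(config$outdir, "fits.csv")
  utils::write.csv(fits, fit_path, row.names = FALSE)
  write_provenance(config, "fit", fit_path)
  invisible(fits)
}

#' Pipeline stage: normalization ladder and group statistics
#'
#' @param config A [pipeline_config()].
#' @param fits Fit table; defaults to the fit stage output on disk.
#' @param sictrl Label of the control-siRNA condition.
#' @return Invisibly: list with per-cell `cells` table, condition summaries
#'   and Mann-Whitney test report.
#' @export
pipeline_stats <- function(config, fits = NULL, sictrl = "siCtrl") {
  ensure_outdir(config)
  if (is.null(fits)) {
    fit_path <- file.path(config$outdir, "fits.csv")
    if (!file.exists(fit_path)) {
      stop("no fit table at ", fit_path, "; run pipeline_fit first", call. = FALSE)
    }
    fits <- tibble::as_tibble(utils::read.csv(fit_path, stringsAsFactors = FALSE))
  }
  cells <- normalize_per_cell(fits, quiet = TRUE)
  cells <- fold_change(cells)
  if (sictrl %in% cells$sirna && any(cells$sirna != sictrl)) {
    keep <- cells$sirna != "none"
    normed <- rnai_relative_fc(cells[keep, ], sictrl = sictrl)
    cells <- dplyr::left_join(
      cells,
      dplyr::select(normed, "cell_id", "sirna", "norm_fc_tau"),
      by = c("cell_id", "sirna"))
  }
  summaries <- summarize_conditions(cells, "fc_tau")

  # Mann-Whitney: each non-reference group against the reference construct
  # within the same siRNA condition
  ref <- "eGFP"
  tests <- cells |>
    dplyr::group_by(.data$sirna) |>
    dplyr::group_modify(function(d, g) {
      others <- setdiff(unique(d$construct), ref)
      if (!length(others) || !any(d$construct == ref)) return(tibble::tibble())
      dplyr::bind_rows(lapply(others, function(ct) {
        res <- mannwhitney_u(d$fc_tau[d$construct == ct],
                             d$fc_tau[d$construct == ref])
        res$construct <- ct
        res
      }))
    }) |>
    dplyr::ungroup()
  if (nrow(tests)) tests$stars <- significance_stars(tests$p)

  cells_path <- file.path(config$outdir, "cells_normalized.csv")
  utils::write.csv(cells, cells_path, row.names = FALSE)
  sum_path <- file.path(config$outdir, "condition_summaries.csv")
  utils::write.csv(dplyr::select(summaries, -dplyr::any_of("experiment_medians")),
                   sum_path, row.names = FALSE)
  test_path <- file.path(config$outdir, "tests.json")
  jsonlite::write_json(tests, test_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  write_provenance(config, "stats", c(cells_path, sum_path, test_path))
  invisible(list(cells = cells, summaries = summaries, tests = tests))
}

#' Run the full pipeline
#'
#' Executes variants, simulate, synth, fit and stats in order and writes a
#' manifest linking every artifact with the seed and config hash. Stages
#' whose provenance record already exists under `outdir` are skipped unless
#' `force = TRUE`, so an interrupted run resumes from the last completed
#' stage.
#'
#' @param config A [pipeline_config()].
#' @param force Re-run stages even if their outputs exist.
#' @return Invisibly, the manifest list.
#' @export
pipeline_run_all <- function(config, force = FALSE) {
  ensure_outdir(config)
  stages <- c("variants", "simulate", "synth", "fit", "stats")
  done <- function(stage) {
    file.exists(file.path(config$outdir, paste0(stage, ".provenance.json")))
  }
  runners <- list(variants = pipeline_variants, simulate = pipeline_simulate,
                  synth = pipeline_synth, fit = pipeline_fit,
                  stats = pipeline_stats)
  for (stage in stages) {
    if (!force && done(stage)) {
      message("stage '", stage, "' already complete; skipping")
      next
    }
    runners[[stage]](config)
  }
  manifest <- list(
    seed = config$seed,
    config_hash = config_hash(config),
    stages = lapply(stats::setNames(stages, stages), function(s) {
      jsonlite::read_json(file.path(config$outdir, paste0(s, ".provenance.json")))
    })
  )
  man_path <- file.path(config$outdir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
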