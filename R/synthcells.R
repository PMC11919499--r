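#' Configuration for the synthetic single-cell generator
#'
#' Emulates a two-channel live-cell imaging experiment on single-cell
#' arrays: per cell, a shared lipoplex count drives correlated initial
#' expression in the eGFP and CayRFP channels, while mRNA degradation rates
#' are drawn independently per channel (so cross-channel delta correlation is
#' ~0, matching the control analysis of the real data). Defaults: 10-min
#' sampling over 30 h, multiplicative lognormal measurement noise plus an
#' additive Gaussian background, 5% non-expressing cells, lognormal
#' cell-to-cell variation of rates with CV 0.4 (a placeholder magnitude for
#' recovery tests, not a claim about any dataset).
#'
#' @param n_cells Cells per condition.
#' @param duration_h Total imaging time (h).
#' @param dt_h Sampling interval (h); default 1/6 (10 min).
#' @param lipoplex_mean Mean lipoplex particles per cell (Poisson, zero
#'   redraws counted).
#' @param mrna_per_lipoplex Mean mRNA molecules released per lipoplex.
#' @param base_delta Baseline mRNA degradation rate (1/h) for both channels.
#' @param base_ktl Baseline translation rate (fluorescence a.u. per mRNA per
#'   h; absolute scale is arbitrary).
#' @param cv_ktl,cv_delta Lognormal coefficients of variation of per-cell
#'   translation and degradation rates.
#' @param noise_cv Multiplicative measurement noise CV.
#' @param baseline_sd Additive background noise SD (a.u.).
#' @param frac_nonexpressing Fraction of cells emitted as near-baseline
#'   trajectories.
#' @param t0_range Per-cell expression onset window (h), shared between
#'   channels.
#' @param km,beta Fixed maturation and protein degradation rates (1/h).
#' @param rng_seed Integer seed; the full dataset is deterministic given it.
#' @return List of class `cell_sim_config`.
#' @export
cell_sim_config <- function(n_cells = 200L, duration_h = 30, dt_h = 1 / 6,
                            lipoplex_mean = 3, mrna_per_lipoplex = 50,
                            base_delta = 0.15, base_ktl = 1,
                            cv_ktl = 0.4, cv_delta = 0.4,
                            noise_cv = 0.05, baseline_sd = 5,
                            frac_nonexpressing = 0.05,
                            t0_range = c(0.5, 2.5),
                            km = 1.2, beta = 0.03, rng_seed = 1L) {
  stopifnot(n_cells >= 1, dt_h > 0, duration_h > 0,
            cv_ktl >= 0, cv_delta >= 0, noise_cv >= 0, baseline_sd >= 0,
            frac_nonexpressing >= 0, frac_nonexpressing < 1,
            base_delta > 0, base_ktl > 0)
  structure(as.list(environment()), class = "cell_sim_config")
}

#' Default condition table
#'
#' One row per experimental condition: a construct label, an siRNA label and
#' per-channel multipliers on the mRNA degradation rate. Effects of
#' slow-codon windows and of targeting siRNAs are encoded as multipliers on
#' the eGFP-channel delta; the CayRFP reference channel is untouched
#' (`delta_mult_rfp = 1`) unless a condition says otherwise. `ktl_mult`
#' scales the eGFP-channel expression rate.
#'
#' @param constructs Character vector of construct labels (first one is the
#'   conventional unmutated reference).
#' @param sirnas Character vector of siRNA condition labels.
#' @return Tibble `construct`, `sirna`, `delta_mult`, `delta_mult_rfp`,
#'   `ktl_mult` with all multipliers 1 (edit to plant effects).
#' @export
condition_table <- function(constructs = "eGFP",
                            sirnas = c("none", "siCtrl", "siRNA1", "siRNA2")) {
  tidyr::expand_grid(construct = constructs, sirna = sirnas) |>
    dplyr::mutate(delta_mult = 1, delta_mult_rfp = 1, ktl_mult = 1)
}

lognormal_mult <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Draw paired kinetic parameters for cells of one condition
#'
#' Per cell: one shared lipoplex count N ~ Poisson(`lipoplex_mean`)
#' (zero draws are redrawn and counted), then per channel
#' m0 ~ Poisson(N x `mrna_per_lipoplex`) conditioned >= 1. The shared N makes
#' m0 x k_tl positively correlated across channels; degradation rates are
#' drawn independently per channel (lognormal around the condition's
#' multiplier times `base_delta`), so their cross-channel correlation is ~0.
#'
#' @param config A [cell_sim_config()].
#' @param condition One row of a [condition_table()].
#' @param n_cells Number of cells (defaults to `config$n_cells`).
#' @return Tibble with 2 rows per cell (channels `eGFP`, `CayRFP`):
#'   `cell_id`, `channel`, `m0`, `ktl`, `m0ktl`, `delta`, `tau`, `t0`,
#'   `non_expressing`, plus the condition labels. Attribute `n_zero_redraws`
#'   counts redrawn zero-lipoplex cells.
#' @export
sample_cell_params <- function(config, condition = condition_table()[1, ],
                               n_cells = config$n_cells) {
  stopifnot(inherits(config, "cell_sim_config"))
  n <- n_cells
  # shared lipoplex count, zero-truncated with redraw count
  N <- stats::rpois(n, config$lipoplex_mean)
  n_zero <- 0L
  while (any(N == 0L)) {
    idx <- which(N == 0L)
    n_zero <- n_zero + length(idx)
    N[idx] <- stats::rpois(length(idx), config$lipoplex_mean)
  }
  draw_m0 <- function() {
    m <- stats::rpois(n, N * config$mrna_per_lipoplex)
    pmax(m, 1L)
  }
  dmult <- condition$delta_mult %||% 1
  dmult_rfp <- condition$delta_mult_rfp %||% 1
  kmult <- condition$ktl_mult %||% 1
  t0 <- stats::runif(n, config$t0_range[1], config$t0_range[2])
  nonexp <- stats::runif(n) < config$frac_nonexpressing

  ch <- function(channel, delta_mult, ktl_mult) {
    tibble::tibble(
      cell_id = sprintf("cell%04d", seq_len(n)),
      channel = channel,
      m0 = draw_m0(),
      ktl = config$base_ktl * ktl_mult * lognormal_mult(n, config$cv_ktl),
      delta = config$base_delta * delta_mult * lognormal_mult(n, config$cv_delta),
      t0 = t0,
      non_expressing = nonexp
    )
  }
  out <- dplyr::bind_rows(
    ch("eGFP", dmult, kmult),
    ch("CayRFP", dmult_rfp, 1)
  ) |>
    dplyr::mutate(
      m0ktl = ifelse(.data$non_expressing, 0, .data$m0 * .data$ktl),
      tau = 1 / .data$delta,
      construct = condition$construct %||% "eGFP",
      sirna = condition$sirna %||% "none"
    ) |>
    dplyr::arrange(.data$cell_id, dplyr::desc(.data$channel))
  attr(out, "n_zero_redraws") <- n_zero
  out
}

#' Simulate a full synthetic dataset
#'
#' Draws ground-truth kinetic parameters per cell and channel for every
#' condition row, evaluates the closed-form model on the regular sampling
#' grid and corrupts it with multiplicative lognormal noise and an additive
#' Gaussian background. Deterministic given `config$rng_seed`.
#'
#' @param config A [cell_sim_config()].
#' @param conditions A [condition_table()] (one row per condition).
#' @return List of class `synthetic_dataset` with `trajectories` (tibble:
#'   `cell_id`, `channel`, `construct`, `sirna`, `experiment_id`, `time_h`,
#'   `fluorescence`) and `truth` (one row per cell x channel with the
#'   generating parameters).
#' @examples
#' cfg <- cell_sim_config(n_cells = 4, rng_seed = 7)
#' ds <- simulate_dataset(cfg, condition_table("eGFP", "none"))
#' dplyr::count(ds$trajectories, channel)
#' @export
simulate_dataset <- function(config, conditions = condition_table()) {
  stopifnot(inherits(config, "cell_sim_config"))
  times <- seq(0, config$duration_h, by = config$dt_h)
  with_seed(config$rng_seed, {
    pieces <- purrr::map(seq_len(nrow(conditions)), function(i) {
      cond <- conditions[i, ]
      truth <- sample_cell_params(config, cond)
      truth$cell_id <- paste0("c", i, "_", truth$cell_id)
      traj <- truth |>
        dplyr::rowwise() |>
        dplyr::reframe(
          cell_id = .data$cell_id, channel = .data$channel,
          construct = .data$construct, sirna = .data$sirna,
          time_h = times,
          mu = model_fluorescence(times, .data$delta, .data$m0ktl, .data$t0,
                                  config$km, config$beta)
        )
      noise <- lognormal_mult(nrow(traj), config$noise_cv)
      traj$fluorescence <- traj$mu * noise +
        stats::rnorm(nrow(traj), 0, config$baseline_sd)
      traj$mu <- NULL
      list(truth = truth, traj = traj)
    })
    structure(list(
      trajectories = dplyr::bind_rows(purrr::map(pieces, "traj")),
      truth = dplyr::bind_rows(purrr::map(pieces, "truth")),
      config = config, conditions = conditions
    ), class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", dplyr::n_distinct(x$truth$cell_id), " cells x 2 channels, ",
      nrow(x$conditions), " condition(s), ",
      length(unique(x$trajectories$time_h)), " time points\n", sep = "")
  invisible(x)
}

#' Write / read trajectory tables in the package CSV dialect
#'
#' Columns: `cell_id`, `channel`, `construct`, `sirna`, `time_h`,
#' `fluorescence` (extra columns are preserved).
#'
#' @param trajectories Trajectory tibble.
#' @param path CSV path.
#' @return `path` (writer) or tibble (reader).
#' @export
write_trajectories <- function(trajectories, path) {
  utils::write.csv(trajectories, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
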