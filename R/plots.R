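#' Plot ribosome density profiles
#'
#' Overlays one or more density profiles along the ORF; slow-codon window
#' spans can be marked.
#'
#' @param profiles A `density_profile` or a list of them.
#' @param mode `"rho"` (A-site occupancy) or `"coverage"`.
#' @param windows Optional tibble with `orf_id`, `window_start`, `window_len`
#'   to shade the mutated windows.
#' @return A ggplot object.
#' @export
plot_density_profiles <- function(profiles, mode = c("rho", "coverage"),
                                  windows = NULL) {
  mode <- match.arg(mode)
  if (inherits(profiles, "density_profile")) profiles <- list(profiles)
  df <- dplyr::bind_rows(lapply(profiles, as.data.frame))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$codon, y = .data[[mode]],
                                        colour = .data$orf_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "codon position", colour = NULL,
                  y = if (mode == "rho") "A-site occupancy" else "footprint coverage") +
    ggplot2::theme_minimal()
  if (!is.null(windows)) {
    p <- p + ggplot2::geom_rect(
      data = windows,
      ggplot2::aes(xmin = .data$window_start,
                   xmax = .data$window_start + .data$window_len - 1,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, alpha = 0.08
    )
  }
  p
}

#' @export
autoplot.density_profile <- function(object, ...) plot_density_profiles(object, ...)

#' Plot single-cell trajectories with optional fit overlays
#'
#' @param trajectories Tibble (`cell_id`, `channel`, `time_h`,
#'   `fluorescence`).
#' @param fits Optional fit table from [fit_cells()]; fitted curves are
#'   overlaid.
#' @param max_cells Cap on the number of cells drawn.
#' @param km,beta Fixed rates used when drawing fitted curves.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, fits = NULL, max_cells = 20L,
                              km = 1.2, beta = 0.03) {
  keep <- utils::head(unique(trajectories$cell_id), max_cells)
  df <- dplyr::filter(trajectories, .data$cell_id %in% keep)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time_h, y = .data$fluorescence,
                                        group = .data$cell_id)) +
    ggplot2::geom_line(alpha = 0.4, colour = "darkgreen") +
    ggplot2::facet_wrap(~channel, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "fluorescence (a.u.)") +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    grid <- seq(min(df$time_h), max(df$time_h), length.out = 150)
    fl <- fits |>
      dplyr::filter(.data$cell_id %in% keep, .data$converged) |>
      dplyr::rowwise() |>
      dplyr::reframe(cell_id = .data$cell_id, channel = .data$channel,
                     time_h = grid,
                     fluorescence = model_fluorescence(grid, .data$delta_hat,
                                                       .data$m0ktl_hat,
                                                       .data$t0_hat, km, beta))
    p <- p + ggplot2::geom_line(data = fl, colour = "grey30", linewidth = 0.3)
  }
  p
}

#' Plot a density-stability correlation profile
#'
#' @param profile A `correlation_profile`.
#' @param sites Optional tibble of siRNA sites (`start_nt`) marked as
#'   vertical lines at their codon positions.
#' @return A ggplot object.
#' @export
plot_correlation_profile <- function(profile, sites = NULL) {
  p <- ggplot2::ggplot(dplyr::filter(profile, .data$defined),
                       ggplot2::aes(x = .data$codon, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::ylim(-1, 1) +
    ggplot2::labs(x = "codon position", y = "Pearson r (density vs stability)") +
    ggplot2::theme_minimal()
  if (!is.null(sites) && nrow(sites)) {
    p <- p + ggplot2::geom_vline(xintercept = ceiling(sites$start_nt / 3),
                                 colour = "orange", linetype = 3)
  }
  p
}

#' @export
autoplot.correlation_profile <- function(object, ...) plot_correlation_profile(object, ...)
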