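#' Per-cell two-channel normalization
#'
#' For every cell with converged fits in both channels, computes the
#' normalized stability tau_n = tau_eGFP / tau_CayRFP and the normalized
#' expression rate k_n = (m0 x k_tl)_eGFP / (m0 x k_tl)_CayRFP. Cells with a
#' failed, non-expressing or non-finite fit in either channel, or a zero or
#' infinite reference stability, are dropped; the count is reported via
#' attribute `n_dropped` and a message.
#'
#' @param fits Fit table from [fit_cells()]: one row per cell x channel with
#'   `cell_id`, `channel` (values `"eGFP"` and `"CayRFP"`), `tau_hat`,
#'   `m0ktl_hat`, `converged`, `non_expressing`, plus condition columns
#'   (e.g. `construct`, `sirna`, `cell_line`, `experiment_id`) that are
#'   carried through.
#' @param quiet Suppress the dropped-cell message.
#' @return Tibble, one row per retained cell: condition columns, `tau_n`,
#'   `k_n`, and the per-channel values (`tau_egfp`, `tau_rfp`, `m0ktl_egfp`,
#'   `m0ktl_rfp`).
#' @export
normalize_per_cell <- function(fits, quiet = FALSE) {
  needed <- c("cell_id", "channel", "tau_hat", "m0ktl_hat", "converged",
              "non_expressing")
  stopifnot(all(needed %in% names(fits)))
  cond_cols <- setdiff(names(fits), c(needed, "delta_hat", "t0_hat",
                                      "residual_ss", "n_points",
                                      "se_delta", "se_m0ktl", "se_t0"))
  cond_cols <- setdiff(cond_cols, "cell_id")

  ok <- fits |>
    dplyr::filter(.data$converged, !.data$non_expressing,
                  is.finite(.data$tau_hat), .data$tau_hat > 0,
                  is.finite(.data$m0ktl_hat), .data$m0ktl_hat > 0)
  wide <- ok |>
    dplyr::select(dplyr::all_of(c("cell_id", cond_cols, "channel",
                                  "tau_hat", "m0ktl_hat"))) |>
    tidyr::pivot_wider(names_from = "channel",
                       values_from = c("tau_hat", "m0ktl_hat")) |>
    dplyr::filter(!is.na(.data$tau_hat_eGFP), !is.na(.data$tau_hat_CayRFP))

  n_cells <- dplyr::n_distinct(fits$cell_id)
  n_dropped <- n_cells - nrow(wide)
  if (!quiet && n_dropped > 0) {
    message(n_dropped, " of ", n_cells,
            " cells dropped (failed/non-expressing/degenerate fits)")
  }
  out <- wide |>
    dplyr::transmute(
      dplyr::across(dplyr::all_of(c("cell_id", cond_cols))),
      tau_egfp = .data$tau_hat_eGFP,
      tau_rfp = .data$tau_hat_CayRFP,
      m0ktl_egfp = .data$m0ktl_hat_eGFP,
      m0ktl_rfp = .data$m0ktl_hat_CayRFP,
      tau_n = .data$tau_hat_eGFP / .data$tau_hat_CayRFP,
      k_n = .data$m0ktl_hat_eGFP / .data$m0ktl_hat_CayRFP
    )
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Fold change of normalized stability against the unmutated reference
#'
#' Within each experimental condition (every combination of the `condition`
#' columns, e.g. siRNA x cell line), divides each cell's tau_n by the median
#' tau_n of the reference construct in that same condition. The reference
#' construct's median fold change is 1 by construction. The expression-rate
#' fold change `fc_k` is computed the same way.
#'
#' @param cells Output of [normalize_per_cell()] with a `construct` column.
#' @param reference_construct Construct label of the unmutated reference.
#' @param condition Columns defining "same experimental condition".
#' @return `cells` with `fc_tau` and `fc_k` added.
#' @export
fold_change <- function(cells, reference_construct = "eGFP",
                        condition = intersect(c("sirna", "cell_line"), names(cells))) {
  stopifnot("construct" %in% names(cells))
  grouped <- if (length(condition)) dplyr::group_by(cells, dplyr::across(dplyr::all_of(condition))) else cells
  out <- grouped |>
    dplyr::mutate(
      .ref_tau = stats::median(.data$tau_n[.data$construct == reference_construct]),
      .ref_k = stats::median(.data$k_n[.data$construct == reference_construct]),
      fc_tau = .data$tau_n / .data$.ref_tau,
      fc_k = .data$k_n / .data$.ref_k
    ) |>
    dplyr::ungroup()
  if (any(!is.finite(out$.ref_tau))) {
    stop("reference construct '", reference_construct,
         "' missing in some condition", call. = FALSE)
  }
  dplyr::select(out, -dplyr::all_of(c(".ref_tau", ".ref_k")))
}

#' RNAi-relative fold change (normalization to siCtrl)
#'
#' Isolates the RNAi effect: for every cell measured under a targeting siRNA,
#' divides its stability fold change by the median fold change of the same
#' construct under the non-targeting control siRNA.
#'
#' @param cells Output of [fold_change()] with `sirna` and `fc_tau` columns.
#' @param sictrl Label of the non-targeting control condition.
#' @param by Columns identifying "same construct" (a `cell_line` column is
#'   included automatically when present).
#' @return `cells` with `norm_fc_tau` added (defined for every row, including
#'   siCtrl rows, whose per-construct median is 1 by construction).
#' @export
rnai_relative_fc <- function(cells, sictrl = "siCtrl",
                             by = intersect(c("construct", "cell_line"), names(cells))) {
  stopifnot(all(c("sirna", "fc_tau") %in% names(cells)))
  out <- cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::mutate(
      .ref = stats::median(.data$fc_tau[.data$sirna == sictrl]),
      norm_fc_tau = .data$fc_tau / .data$.ref
    ) |>
    dplyr::ungroup()
  if (any(!is.finite(out$.ref))) {
    bad <- unique(out$construct[!is.finite(out$.ref)])
    stop("no '", sictrl, "' cells for construct(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  dplyr::select(out, -".ref")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum test. Uses the exact null distribution when the
#' combined sample size is <= 16 and there are no ties; otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param exact_max Combined-size threshold for the exact branch.
#' @return Tibble with `U` (statistic of group `a`), `p`, and `method`.
#' @examples
#' mannwhitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mannwhitney_u <- function(a, b, exact_max = 16L) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) == 0L || length(b) == 0L) stop("empty group", call. = FALSE)
  na <- length(a); nb <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  if (!ties && (na + nb) <= exact_max) {
    # exact null distribution of U
    lo <- min(U, na * nb - U)
    p <- min(2 * stats::pwilcox(lo, na, nb), 1)
    method <- "exact"
  } else {
    mu <- na * nb / 2
    tie_tab <- table(r)
    n <- na + nb
    sigma2 <- na * nb / 12 * ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- min(2 * stats::pnorm(-abs(z)), 1)
    }
    method <- "normal_approx"
  }
  tibble::tibble(U = U, p = p, method = method,
                 n_a = na, n_b = nb)
}

#' Significance stars
#'
#' Maps a p-value to the star labels used throughout the analysis:
#' `****` for p < 1e-4, `***` for p < 1e-3, `**` for p < 1e-2, `*` for
#' p < 5e-2 and `ns` otherwise; boundary values fall in the less significant
#' class.
#'
#' @param p P-value(s) in \[0, 1\].
#' @return Character vector of labels.
#' @export
significance_stars <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p must be in [0, 1]", call. = FALSE)
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 1e-4 ~ "****",
    p < 1e-3 ~ "***",
    p < 1e-2 ~ "**",
    p < 5e-2 ~ "*",
    TRUE ~ "ns"
  )
}

#' Per-codon correlation between ribosome density and stability
#'
#' For each codon position, the Pearson correlation across constructs between
#' the simulated steady-state ribosome density at that position and a
#' per-construct stability measure (typically the construct median of
#' `fc_tau` or `norm_fc_tau`). Positions where the density does not vary
#' across constructs are flagged undefined.
#'
#' @param construct_stats Tibble with `orf_id` and `stability` (one row per
#'   construct; >= 3 constructs).
#' @param profiles List of `density_profile` objects on the same codon grid,
#'   whose `orf_id`s cover `construct_stats$orf_id`.
#' @param mode Density column to use: `"rho"` or `"coverage"`.
#' @param p_values Add per-position two-sided correlation-test p-values.
#' @return Tibble of class `correlation_profile`: `codon`, `r`, `defined`,
#'   `n_constructs` (and `p` if requested).
#' @export
correlation_profile <- function(construct_stats, profiles,
                                mode = c("rho", "coverage"),
                                p_values = FALSE) {
  mode <- match.arg(mode)
  stopifnot(all(c("orf_id", "stability") %in% names(construct_stats)))
  if (nrow(construct_stats) < 3) stop("need >= 3 constructs", call. = FALSE)
  ids <- vapply(profiles, function(p) p$orf_id[1], character(1))
  missing <- setdiff(construct_stats$orf_id, ids)
  if (length(missing)) {
    stop("no density profile for: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  lens <- vapply(profiles, nrow, integer(1))
  if (length(unique(lens)) != 1L) stop("profiles on mismatched codon grids", call. = FALSE)
  L <- lens[1]
  dens <- vapply(construct_stats$orf_id,
                 function(id) profiles[[which(ids == id)[1]]][[mode]],
                 numeric(L))
  # dens: L x n_constructs
  s <- construct_stats$stability
  n <- length(s)
  r <- rep(NA_real_, L)
  for (i in seq_len(L)) {
    x <- dens[i, ]
    if (stats::sd(x) > 0 && stats::sd(s) > 0) r[i] <- stats::cor(x, s)
  }
  out <- tibble::tibble(codon = seq_len(L), r = r,
                        defined = !is.na(r), n_constructs = n)
  if (p_values) {
    out$p <- vapply(seq_len(L), function(i) {
      if (is.na(r[i]) || n < 3 || abs(r[i]) >= 1) return(NA_real_)
      tt <- r[i] * sqrt((n - 2) / (1 - r[i]^2))
      2 * stats::pt(-abs(tt), df = n - 2)
    }, numeric(1))
  }
  class(out) <- c("correlation_profile", class(out))
  out
}

#' Condition summaries: median, MAD and per-experiment medians
#'
#' The dispersion measure is the unscaled median absolute deviation
#' (no 1.4826 consistency factor) unless `scaled_mad = TRUE`.
#'
#' @param cells Tibble of per-cell records.
#' @param value Name of the value column to summarize (string).
#' @param grouping Character vector of condition columns.
#' @param experiment Column identifying replicate experiments (optional; must
#'   be present in `cells` to get per-experiment medians).
#' @param scaled_mad Use the 1.4826-scaled MAD instead.
#' @return Tibble: grouping columns, `n_cells`, `median`, `mad`, and a
#'   list-column `experiment_medians` when `experiment` is available.
#' @export
summarize_conditions <- function(cells, value = "fc_tau",
                                 grouping = intersect(c("construct", "sirna", "cell_line"),
                                                      names(cells)),
                                 experiment = "experiment_id",
                                 scaled_mad = FALSE) {
  konst <- if (scaled_mad) 1.4826 else 1
  has_exp <- experiment %in% names(cells)
  cells |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grouping))) |>
    dplyr::summarise(
      n_cells = dplyr::n(),
      median = stats::median(.data[[value]]),
      mad = stats::mad(.data[[value]], constant = konst),
      experiment_medians = if (has_exp) {
        m <- tapply(.data[[value]], .data[[experiment]], stats::median)
        list(stats::setNames(as.numeric(m), names(m)))
      } else {
        list(NULL)
      },
      .groups = "drop"
    )
}

#' Bootstrap confidence interval for a group median
#'
#' Percentile bootstrap over cells.
#'
#' @param x Numeric vector.
#' @param n_boot Number of bootstrap resamples.
#' @param conf Confidence level.
#' @param seed RNG seed.
#' @return Named numeric: `median`, `lower`, `upper`.
#' @export
median_boot_ci <- function(x, n_boot = 2000L, conf = 0.95, seed = 1L) {
  x <- x[is.finite(x)]
  meds <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) stats::median(sample(x, replace = TRUE)), numeric(1))
  })
  q <- stats::quantile(meds, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  c(median = stats::median(x), lower = q[1], upper = q[2])
}
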