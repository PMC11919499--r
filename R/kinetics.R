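#' Closed-form fluorescence of the three-stage expression model
#'
#' The model is the linear cascade
#' mRNA --k_tl--> nascent protein --k_m--> mature (fluorescent) protein,
#' with first-order mRNA degradation delta and protein degradation beta acting
#' on both protein species, started from (m0, 0, 0) at onset time t0:
#' \deqn{m' = -\delta m, \quad
#'       g^{*'} = k_{tl} m - (\beta + k_m) g^*, \quad
#'       g' = k_m g^* - \beta g.}
#' The mature-protein solution is a sum of three exponentials with rates
#' delta, beta + k_m and beta; it is evaluated through divided differences of
#' the exponential so nearly degenerate rate pairs (relative difference below
#' ~1e-8) go through the analytic limit instead of a catastrophic
#' cancellation. Only the product m0 x k_tl is identifiable from a
#' fluorescence trajectory, so it enters as one argument.
#'
#' @param times Sampling times (h). Values before `t0` give 0.
#' @param delta mRNA degradation rate (1/h); stability is tau = 1/delta.
#' @param m0ktl Initial expression rate m0 x k_tl (molecules/h, arbitrary
#'   fluorescence scale absorbed).
#' @param t0 Expression onset time (h).
#' @param km Maturation rate (1/h).
#' @param beta Protein degradation rate (1/h).
#' @param scale Fluorescence units per mature protein.
#' @return Numeric vector of fluorescence values at `times`.
#' @examples
#' t <- seq(0, 30, by = 1/6)
#' y <- model_fluorescence(t, delta = 0.2, m0ktl = 100, t0 = 1)
#' @export
model_fluorescence <- function(times, delta, m0ktl, t0 = 0,
                               km = 1.2, beta = 0.03, scale = 1) {
  if (any(c(delta, km, beta) < 0)) stop("rates must be >= 0", call. = FALSE)
  s <- pmax(times - t0, 0)
  y <- scale * km * m0ktl * exp_divdiff3(delta, beta + km, beta, s)
  y[times <= t0] <- 0
  y
}

# second divided difference of x -> exp(-x s) at nodes x <= y, computed
# cancellation-free through expm1; limit -s exp(-x s) at coincident nodes
exp_divdiff2 <- function(x, y, s) {
  d <- y - x
  if (d == 0) return(-s * exp(-x * s))
  exp(-x * s) * expm1(-d * s) / d
}

# third divided difference of x -> exp(-x s) at nodes (a, b, c);
# symmetric in the nodes and numerically stable for arbitrarily close nodes:
# nested stable first differences, with the analytic triple-node limit
# f''(m)/2 = s^2 exp(-m s)/2 when the full node spread is negligible
exp_divdiff3 <- function(a, b, c, s) {
  r <- sort(c(a, b, c))
  spread <- r[3] - r[1]
  if (spread <= 1e-9 * max(r[3], 1)) {
    m <- (r[1] + r[3]) / 2
    return(s^2 * exp(-m * s) / 2)
  }
  (exp_divdiff2(r[1], r[2], s) - exp_divdiff2(r[2], r[3], s)) / (r[1] - r[3])
}

#' Fit a single-cell fluorescence trajectory
#'
#' Non-linear least squares fit of [model_fluorescence()] to one trajectory
#' with the maturation rate `km` and protein degradation rate `beta` held
#' fixed (they are measured independently in cycloheximide experiments and
#' shared across cells). Free parameters: `delta`, the product `m0ktl`, and
#' the onset time `t0` (bounded). Initialization: `t0` from the first time
#' the signal exceeds 5% of its maximum, `delta` from the late-phase
#' log-linear slope when the trajectory decays (else 0.1/h), `m0ktl` from the
#' peak height; plus jittered restarts, best residual wins (deterministic
#' given `seed`). Trajectories with no signal above the noise floor are
#' flagged non-expressing and not fitted.
#'
#' @param traj Data frame with columns `time_h` and `fluorescence` (>= 10
#'   points), or a numeric vector of values with `times` supplied.
#' @param km,beta Fixed maturation and protein degradation rates (1/h).
#' @param times Sampling times if `traj` is a bare numeric vector.
#' @param t0_bounds Lower/upper bounds on the onset time (h).
#' @param n_starts Number of jittered restarts on top of the base start.
#' @param seed Seed for the restart jitter.
#' @return Object of class `slowcodon_fit` with elements `delta_hat`,
#'   `m0ktl_hat`, `t0_hat`, `tau_hat`, `residual_ss`, `converged`,
#'   `non_expressing`, `se` (named numeric), `n_points`, `fixed`.
#'   [tidy()] and [glance()] methods are provided.
#' @export
fit_trajectory <- function(traj, km = 1.2, beta = 0.03, times = NULL,
                           t0_bounds = c(0, 5), n_starts = 5L, seed = 1L) {
  if (is.numeric(traj) && !is.null(times)) {
    traj <- tibble::tibble(time_h = times, fluorescence = traj)
  }
  stopifnot(all(c("time_h", "fluorescence") %in% names(traj)))
  t <- traj$time_h
  y <- traj$fluorescence
  if (length(t) < 10L) stop("need at least 10 time points", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(t))) stop("non-finite values in trajectory", call. = FALSE)
  if (is.unsorted(t, strictly = TRUE)) stop("times must be strictly increasing", call. = FALSE)
  if (km <= 0 || beta <= 0) stop("fixed km and beta must be > 0", call. = FALSE)

  # noise floor from successive differences (robust to the smooth trend)
  noise <- stats::sd(diff(y)) / sqrt(2)
  amp <- max(y) - stats::quantile(y, 0.1, names = FALSE)
  if (!is.finite(amp) || amp <= 5 * noise || max(y) <= 0) {
    return(new_fit(NA, NA, NA, NA_real_, FALSE, TRUE,
                   c(delta = NA_real_, m0ktl = NA_real_, t0 = NA_real_),
                   length(y), km, beta))
  }

  start <- init_guess(t, y, km, beta, t0_bounds)
  starts <- list(start)
  jit <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      c(log_delta = start[["log_delta"]] + stats::rnorm(1, 0, 0.7),
        log_A = start[["log_A"]] + stats::rnorm(1, 0, 0.5),
        t0 = min(max(start[["t0"]] + stats::runif(1, -0.5, 1), t0_bounds[1]), t0_bounds[2]))
    })
  })
  starts <- c(starts, jit)

  obj <- function(par) {
    mu <- model_fluorescence(t, exp(par[1]), exp(par[2]), par[3], km, beta)
    sum((y - mu)^2)
  }
  lower <- c(-12, -20, t0_bounds[1])
  upper <- c(6, 40, min(t0_bounds[2], max(t)))
  best <- NULL
  for (p0 in starts) {
    fit <- try(stats::nlminb(unname(p0), obj, lower = lower, upper = upper,
                             control = list(iter.max = 500, eval.max = 1000)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best)) {
    return(new_fit(NA, NA, NA, NA_real_, FALSE, FALSE,
                   c(delta = NA_real_, m0ktl = NA_real_, t0 = NA_real_),
                   length(y), km, beta))
  }
  converged <- best$convergence == 0
  par <- best$par
  delta_hat <- exp(par[1]); A_hat <- exp(par[2]); t0_hat <- par[3]
  se <- fit_se(t, y, delta_hat, A_hat, t0_hat, km, beta, best$objective)
  new_fit(delta_hat, A_hat, t0_hat, best$objective, converged, FALSE, se,
          length(y), km, beta)
}

new_fit <- function(delta, A, t0, rss, converged, non_expressing, se,
                    n, km, beta) {
  structure(list(
    delta_hat = delta, m0ktl_hat = A, t0_hat = t0,
    tau_hat = if (is.na(delta) || delta == 0) Inf else 1 / delta,
    residual_ss = rss, converged = converged, non_expressing = non_expressing,
    se = se, n_points = n, fixed = c(km = km, beta = beta)
  ), class = "slowcodon_fit")
}

init_guess <- function(t, y, km, beta, t0_bounds) {
  ymax <- max(y)
  ipk <- which.max(y)
  above <- which(y > 0.05 * ymax)
  t0 <- if (length(above)) t[above[1]] else t[1]
  t0 <- min(max(t0, t0_bounds[1]), t0_bounds[2])
  # late-phase log-linear slope if the trajectory decays after the peak
  delta0 <- 0.1
  if (ipk < length(t) - 5 && y[length(y)] < 0.8 * ymax) {
    tail_i <- seq.int(max(ipk + 1L, length(t) - floor(length(t) / 3)), length(t))
    yy <- y[tail_i]
    ok <- yy > 0
    if (sum(ok) >= 5) {
      sl <- stats::coef(stats::lm(log(yy[ok]) ~ t[tail_i][ok]))[2]
      if (is.finite(sl) && sl < 0) delta0 <- max(min(-sl, 5), 1e-3)
    }
  }
  # scale m0ktl so that the model peak matches the observed peak
  unit <- model_fluorescence(t, delta0, 1, t0, km, beta)
  A0 <- ymax / max(max(unit), 1e-12)
  c(log_delta = log(delta0), log_A = log(max(A0, 1e-12)), t0 = t0)
}

# Gauss-Newton standard errors: sigma^2 (J'J)^-1 with a numerical Jacobian
fit_se <- function(t, y, delta, A, t0, km, beta, rss) {
  par <- c(delta = delta, m0ktl = A, t0 = t0)
  f <- function(p) model_fluorescence(t, p[1], p[2], p[3], km, beta)
  J <- matrix(NA_real_, length(t), 3)
  for (j in 1:3) {
    h <- max(abs(par[j]) * 1e-6, 1e-9)
    pp <- par; pp[j] <- pp[j] + h
    pm <- par; pm[j] <- pm[j] - h
    J[, j] <- (f(pp) - f(pm)) / (2 * h)
  }
  dof <- max(length(t) - 3, 1)
  s2 <- rss / dof
  se <- rep(NA_real_, 3)
  V <- try(solve(crossprod(J)), silent = TRUE)
  if (!inherits(V, "try-error")) {
    d <- diag(V)
    se <- ifelse(d > 0, sqrt(s2 * d), NA_real_)
  }
  stats::setNames(se, c("delta", "m0ktl", "t0"))
}

#' mRNA stability from a fit
#'
#' Stability tau is the inverse of the fitted mRNA degradation rate. A zero
#' rate yields the infinite-stability sentinel `Inf`, which downstream ratio
#' operations exclude (with a count).
#'
#' @param fit A `slowcodon_fit`, or a numeric vector of delta values.
#' @return tau in hours.
#' @export
stability <- function(fit) {
  delta <- if (inherits(fit, "slowcodon_fit")) fit$delta_hat else fit
  ifelse(is.na(delta), NA_real_, ifelse(delta == 0, Inf, 1 / delta))
}

#' @export
print.slowcodon_fit <- function(x, ...) {
  if (x$non_expressing) {
    cat("<slowcodon_fit> non-expressing trajectory (not fitted)\n")
  } else {
    cat(sprintf(
      "<slowcodon_fit> delta = %.4g /h (tau = %.3g h), m0*ktl = %.4g, t0 = %.3g h, RSS = %.4g%s\n",
      x$delta_hat, x$tau_hat, x$m0ktl_hat, x$t0_hat, x$residual_ss,
      if (!x$converged) " [NOT CONVERGED]" else ""))
  }
  invisible(x)
}

#' Tidy a trajectory fit
#' @param x A `slowcodon_fit`.
#' @param ... Unused.
#' @return One row per free parameter: `term`, `estimate`, `std.error`.
#' @importFrom generics tidy
#' @export
tidy.slowcodon_fit <- function(x, ...) {
  tibble::tibble(
    term = c("delta", "m0ktl", "t0"),
    estimate = c(x$delta_hat, x$m0ktl_hat, x$t0_hat),
    std.error = unname(x$se)
  )
}

#' One-line fit summary
#' @param x A `slowcodon_fit`.
#' @param ... Unused.
#' @importFrom generics glance
#' @export
glance.slowcodon_fit <- function(x, ...) {
  tibble::tibble(
    delta_hat = x$delta_hat, m0ktl_hat = x$m0ktl_hat, t0_hat = x$t0_hat,
    tau_hat = x$tau_hat, residual_ss = x$residual_ss,
    converged = x$converged, non_expressing = x$non_expressing,
    n_points = x$n_points
  )
}

#' Fit every cell x channel trajectory in a long table
#'
#' @param trajectories Tibble with `cell_id`, `channel`, `time_h`,
#'   `fluorescence` (and optionally condition columns, carried through).
#' @inheritParams fit_trajectory
#' @return Tibble, one row per cell x channel, with fit fields (`delta_hat`,
#'   `m0ktl_hat`, `t0_hat`, `tau_hat`, `residual_ss`, `converged`,
#'   `non_expressing`, standard errors) and any condition columns.
#' @export
fit_cells <- function(trajectories, km = 1.2, beta = 0.03,
                      t0_bounds = c(0, 5), n_starts = 5L, seed = 1L) {
  meta_cols <- setdiff(names(trajectories),
                       c("time_h", "fluorescence"))
  trajectories |>
    dplyr::group_by(dplyr::across(dplyr::all_of(meta_cols))) |>
    dplyr::group_modify(function(d, g) {
      f <- fit_trajectory(d, km = km, beta = beta, t0_bounds = t0_bounds,
                          n_starts = n_starts, seed = seed)
      gl <- glance(f)
      gl$se_delta <- f$se[["delta"]]
      gl$se_m0ktl <- f$se[["m0ktl"]]
      gl$se_t0 <- f$se[["t0"]]
      gl
    }) |>
    dplyr::ungroup()
}
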