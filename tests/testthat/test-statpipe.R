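# minimal fit-table builder: one row per cell x channel
fake_fits <- function(n, tau_g, tau_r, construct = "eGFP", sirna = "none",
                      k_g = 100, k_r = 100, prefix = "c") {
  ids <- sprintf("%s%03d", prefix, seq_len(n))
  dplyr::bind_rows(
    tibble::tibble(cell_id = ids, channel = "eGFP", construct = construct,
                   sirna = sirna, tau_hat = tau_g, m0ktl_hat = k_g,
                   converged = TRUE, non_expressing = FALSE),
    tibble::tibble(cell_id = ids, channel = "CayRFP", construct = construct,
                   sirna = sirna, tau_hat = tau_r, m0ktl_hat = k_r,
                   converged = TRUE, non_expressing = FALSE)
  )
}

test_that("normalize_per_cell forms channel ratios and drops failed cells", {
  f <- fake_fits(4, tau_g = 5, tau_r = 10)
  cells <- normalize_per_cell(f, quiet = TRUE)
  expect_equal(cells$tau_n, rep(0.5, 4))
  expect_equal(cells$k_n, rep(1, 4))

  # identical channels -> tau_n = 1
  f1 <- fake_fits(3, tau_g = 7, tau_r = 7)
  expect_equal(normalize_per_cell(f1, quiet = TRUE)$tau_n, rep(1, 3))

  # a cell failing one channel is dropped and counted
  f$converged[1] <- FALSE
  expect_message(out <- normalize_per_cell(f), "1 of 4 cells dropped")
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_dropped"), 1L)

  # infinite reference stability excluded
  f2 <- fake_fits(3, tau_g = 5, tau_r = 10)
  f2$tau_hat[f2$channel == "CayRFP" & f2$cell_id == "c001"] <- Inf
  expect_equal(nrow(normalize_per_cell(f2, quiet = TRUE)), 2)
})

test_that("planted one-channel destabilization gives median tau_n ~ 0.5", {
  cfg <- cell_sim_config(n_cells = 150, frac_nonexpressing = 0, rng_seed = 14,
                         noise_cv = 0, baseline_sd = 0)
  cond <- dplyr::mutate(condition_table("eGFP", "none"), delta_mult = 2)
  ds <- simulate_dataset(cfg, cond)
  # use ground truth as 'fits' to isolate the normalization arithmetic
  fits <- ds$truth |>
    dplyr::mutate(tau_hat = .data$tau, m0ktl_hat = pmax(.data$m0ktl, 1e-9),
                  converged = TRUE, non_expressing = .data$non_expressing) |>
    dplyr::select(dplyr::all_of(c("cell_id", "channel", "construct", "sirna",
                                  "tau_hat", "m0ktl_hat", "converged",
                                  "non_expressing")))
  cells <- normalize_per_cell(fits, quiet = TRUE)
  expect_equal(median(cells$tau_n), 0.5, tolerance = 0.12)
})

test_that("fold_change self-normalizes the reference construct", {
  ref <- fake_fits(5, tau_g = c(4, 5, 6, 5, 5), tau_r = 5)
  var <- fake_fits(5, tau_g = 0.66 * 5, tau_r = 5, construct = "win064",
                   prefix = "v")
  cells <- normalize_per_cell(dplyr::bind_rows(ref, var), quiet = TRUE)
  fc <- fold_change(cells)
  expect_equal(median(fc$fc_tau[fc$construct == "eGFP"]), 1)
  expect_equal(unique(fc$fc_tau[fc$construct == "win064"]), 0.66)
  expect_error(fold_change(dplyr::filter(cells, construct != "eGFP")),
               "reference construct")
})

test_that("rnai_relative_fc isolates the RNAi effect", {
  mk <- function(construct, sirna, tau_g, prefix) {
    fake_fits(6, tau_g = tau_g, tau_r = 10, construct = construct,
              sirna = sirna, prefix = prefix)
  }
  fits <- dplyr::bind_rows(
    mk("eGFP",   "siCtrl", 10,  "a"),   # fc reference
    mk("eGFP",   "siRNA1", 1,   "b"),   # knockdown x10
    mk("win064", "siCtrl", 6.6, "d"),   # destabilized construct
    mk("win064", "siRNA1", 1.32, "e")   # protected: only x5 knockdown
  )
  cells <- fold_change(normalize_per_cell(fits, quiet = TRUE))
  out <- rnai_relative_fc(cells)
  med <- out |>
    dplyr::group_by(.data$construct, .data$sirna) |>
    dplyr::summarise(m = median(.data$norm_fc_tau), .groups = "drop")
  expect_equal(med$m[med$construct == "eGFP" & med$sirna == "siCtrl"], 1)
  expect_equal(med$m[med$construct == "win064" & med$sirna == "siCtrl"], 1)
  expect_equal(med$m[med$construct == "win064" & med$sirna == "siRNA1"], 2)
  expect_error(rnai_relative_fc(dplyr::filter(cells, sirna != "siCtrl")),
               "siCtrl")
})

test_that("scale invariance: rescaling fluorescence leaves the ladder unchanged", {
  t <- seq(0, 30, by = 1 / 6)
  set.seed(77)
  mk_traj <- function(scale) {
    purrr::map_dfr(1:3, function(i) {
      dplyr::bind_rows(
        tibble::tibble(cell_id = paste0("c", i), channel = "eGFP", time_h = t,
                       fluorescence = scale * model_fluorescence(t, 0.2 + 0.05 * i, 120, 1)),
        tibble::tibble(cell_id = paste0("c", i), channel = "CayRFP", time_h = t,
                       fluorescence = scale * model_fluorescence(t, 0.15, 100, 1)))
    })
  }
  f1 <- fit_cells(mk_traj(1))
  f2 <- fit_cells(mk_traj(37.5))
  c1 <- normalize_per_cell(dplyr::mutate(f1, construct = "eGFP", sirna = "none"),
                           quiet = TRUE)
  c2 <- normalize_per_cell(dplyr::mutate(f2, construct = "eGFP", sirna = "none"),
                           quiet = TRUE)
  expect_equal(c1$tau_n, c2$tau_n, tolerance = 1e-6)
  expect_equal(c1$k_n, c2$k_n, tolerance = 1e-6)
  expect_equal(fold_change(c1)$fc_tau, fold_change(c2)$fc_tau, tolerance = 1e-6)
})

test_that("Mann-Whitney U: exact branch matches spec example and enumeration", {
  res <- mannwhitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)
  expect_equal(res$method, "exact")

  # identical groups -> p = 1
  same <- mannwhitney_u(1:5 + 0.5, 1:5 + 0.5)
  expect_equal(same$p, 1)

  # all tie-free splits with n_a, n_b <= 6 match exhaustive enumeration
  set.seed(9)
  for (na in 2:6) {
    for (nb in 2:6) {
      x <- sample(100, na + nb)  # distinct -> tie-free
      a <- x[seq_len(na)]; b <- x[-seq_len(na)]
      got <- mannwhitney_u(a, b)
      ref <- mw_enum(a, b)
      expect_equal(got$U, ref$U)
      expect_equal(got$p, ref$p, tolerance = 1e-12)
    }
  }

  # normal approximation close to exact at n = 8 + 8
  set.seed(10)
  x <- sample(1000, 16)
  a <- x[1:8]; b <- x[9:16]
  approx <- mannwhitney_u(a, b, exact_max = 0)
  exact <- mw_enum(a, b)
  expect_lt(abs(approx$p - exact$p), 0.01)

  expect_error(mannwhitney_u(numeric(0), 1:3), "empty")
})

test_that("Mann-Whitney agrees with wilcox.test as an independent cross-check", {
  set.seed(3)
  a <- rnorm(7); b <- rnorm(9) + 0.5
  got <- mannwhitney_u(a, b)
  ref <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE, correct = TRUE))
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p, ref$p.value, tolerance = 1e-10)
})

test_that("significance stars follow the printed mapping with boundary rule", {
  expect_equal(significance_stars(c(0.3, 5e-5, 5e-4, 5e-3, 0.03)),
               c("ns", "****", "***", "**", "*"))
  expect_equal(significance_stars(0.05), "ns")    # boundary -> less significant
  expect_equal(significance_stars(1e-2), "*")
  expect_equal(significance_stars(1e-3), "**")
  expect_equal(significance_stars(1e-4), "***")
  expect_error(significance_stars(1.2), "in \\[0, 1\\]")
})

test_that("correlation_profile: exact match, undefined positions, sign recovery", {
  mk_prof <- function(id, rho) {
    new_density_profile(id, rho, rep(0, length(rho)), rho, rep(0, length(rho)),
                        1, 0, sim_params())
  }
  rho <- rbind(c(0.1, 0.2, 0.5, 0.5), c(0.3, 0.2, 0.4, 0.5), c(0.5, 0.2, 0.3, 0.5))
  profs <- list(mk_prof("a", rho[1, ]), mk_prof("b", rho[2, ]), mk_prof("c", rho[3, ]))

  # stability equal to density at position 1 -> r = 1 there
  cs <- tibble::tibble(orf_id = c("a", "b", "c"), stability = rho[, 1])
  cp <- correlation_profile(cs, profs, p_values = TRUE)
  expect_equal(cp$r[1], 1)
  expect_false(cp$defined[2])  # no density variance at position 2
  expect_false(cp$defined[4])
  expect_equal(cp$r[3], stats::cor(rho[, 3], rho[, 1]))

  # constant stability -> undefined everywhere
  cs0 <- tibble::tibble(orf_id = c("a", "b", "c"), stability = rep(2, 3))
  expect_true(all(!correlation_profile(cs0, profs)$defined |
                  is.na(correlation_profile(cs0, profs)$r)))

  # affine rescaling of stability leaves r unchanged
  cs2 <- dplyr::mutate(cs, stability = 3 * .data$stability + 7)
  expect_equal(correlation_profile(cs2, profs)$r, cp$r)

  expect_error(correlation_profile(cs[1:2, ], profs), ">= 3 constructs")
})

test_that("summarize_conditions: median, unscaled MAD, per-experiment medians", {
  cells <- tibble::tibble(
    construct = "eGFP", sirna = "none",
    experiment_id = rep(c("e1", "e2", "e3"), each = 5),
    fc_tau = c(1, 2, 3, 4, 5, 2, 3, 4, 5, 6, 0, 1, 2, 3, 4))
  s <- summarize_conditions(cells, "fc_tau")
  expect_equal(s$median, 3)
  expect_equal(s$mad, 1)  # unscaled MAD of 0:6-ish set around median
  em <- s$experiment_medians[[1]]
  expect_equal(unname(em[c("e1", "e2", "e3")]), c(3, 4, 2))

  one <- summarize_conditions(cells[1, ], "fc_tau")
  expect_equal(one$mad, 0)
})
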