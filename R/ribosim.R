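#' Simulation parameters for ribosome traffic
#'
#' Bundles the rates and bookkeeping controls of the exclusion-process
#' simulation. Defaults are physiological orders of magnitude: initiation
#' 0.1/s, termination 2/s, premature drop-off 2e-4/s, mean elongation rate
#' 5 codons/s, ribosome footprint 10 codons (~30 nt). The relative rate table
#' (mean 1.0) is multiplied by `omega_mean` inside the simulator to obtain
#' physical elongation rates.
#'
#' @param alpha_on Initiation rate (1/s), > 0 unless deliberately 0.
#' @param alpha_off Termination rate (1/s).
#' @param gamma Premature drop-off rate per ribosome (1/s).
#' @param footprint Ribosome size in codons (>= 1).
#' @param omega_mean Mean elongation rate (codons/s) applied to the relative
#'   rate table.
#' @param burn_in Time discarded before averaging (s); `NULL` means 10x the
#'   expected free-ribosome traversal time of the ORF.
#' @param sample_time Averaging window (s); `NULL` means 100x the traversal
#'   time.
#' @param n_batches Number of batches for batch-means standard errors.
#' @param rng_seed Integer seed; identical seeds give identical event
#'   sequences.
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(alpha_on = 0.1, alpha_off = 2, gamma = 2e-4,
                       footprint = 10L, omega_mean = 5, burn_in = NULL,
                       sample_time = NULL, n_batches = 20L, rng_seed = 1L) {
  stopifnot(alpha_on >= 0, alpha_off > 0, gamma >= 0, footprint >= 1,
            omega_mean > 0, n_batches >= 2)
  if (!is.null(sample_time) && sample_time <= 0) stop("sample_time must be > 0", call. = FALSE)
  structure(list(alpha_on = alpha_on, alpha_off = alpha_off, gamma = gamma,
                 footprint = as.integer(footprint), omega_mean = omega_mean,
                 burn_in = burn_in, sample_time = sample_time,
                 n_batches = as.integer(n_batches),
                 rng_seed = as.integer(rng_seed)),
            class = "sim_params")
}

orf_omega <- function(orf, rates, omega_mean) {
  lut <- rate_lookup(validate_rate_table(rates))
  unname(lut[orf$codons]) * omega_mean
}

#' Simulate steady-state ribosome density along an ORF
#'
#' Continuous-time Markov (Gillespie direct method) simulation of ribosome
#' traffic: initiation at codon 1 when the first `footprint` codons are
#' clear, codon-specific hops, premature drop-off, termination at the last
#' codon, hard steric exclusion between footprints. After `burn_in`, A-site
#' occupancy and footprint coverage are time-averaged over `sample_time`,
#' with batch-means Monte-Carlo standard errors, and the flux is the rate of
#' completed terminations.
#'
#' @param orf An `orf` object.
#' @param rates Relative elongation-rate table.
#' @param params A [sim_params()] object.
#' @return A tibble of class `density_profile`: one row per codon with
#'   `orf_id`, `codon`, `rho` (A-site occupancy), `stderr`, `coverage`
#'   (probability the codon is covered by any part of a footprint) and
#'   `coverage_se`. Attributes: `flux`, `flux_se`, `params`, `n_events`.
#' @examples
#' orf <- orf_from_sequence(strrep("GCCAAA", 6), "toy")
#' p <- sim_params(footprint = 2, sample_time = 200, rng_seed = 7)
#' prof <- simulate_density(orf, params = p)
#' flux(prof)
#' @export
simulate_density <- function(orf, rates = default_elongation_rates(),
                             params = sim_params()) {
  stopifnot(inherits(orf, "orf"), inherits(params, "sim_params"))
  if (orf$length < params$footprint) {
    stop("ORF shorter than the ribosome footprint", call. = FALSE)
  }
  omega <- orf_omega(orf, rates, params$omega_mean)
  traversal <- sum(1 / omega)
  burn_in <- params$burn_in %||% (10 * traversal)
  sample_time <- params$sample_time %||% (100 * traversal)
  if (sample_time <= 0) stop("sample_time must be > 0", call. = FALSE)

  res <- with_seed(params$rng_seed, {
    gillespie_tasep(omega, params$alpha_on, params$alpha_off, params$gamma,
                    params$footprint, burn_in, sample_time,
                    params$n_batches, FALSE)
  })
  new_density_profile(orf$id, res$rho, res$rho_se, res$coverage,
                      res$coverage_se, res$flux, res$flux_se, params,
                      n_events = res$n_events)
}

new_density_profile <- function(orf_id, rho, stderr, coverage, coverage_se,
                                flux, flux_se, params, n_events = NA_real_) {
  out <- tibble::tibble(
    orf_id = orf_id, codon = seq_along(rho),
    rho = as.numeric(rho), stderr = as.numeric(stderr),
    coverage = as.numeric(coverage), coverage_se = as.numeric(coverage_se)
  )
  attr(out, "flux") <- flux
  attr(out, "flux_se") <- flux_se
  attr(out, "params") <- params
  attr(out, "n_events") <- n_events
  class(out) <- c("density_profile", class(out))
  out
}

#' Flux of a density profile
#' @param profile A `density_profile`.
#' @return Completed terminations per unit time (attribute `flux`).
#' @export
flux <- function(profile) attr(profile, "flux")

#' Occupancy at a codon or nucleotide position
#'
#' Nucleotide positions map to the codon containing them (`ceiling(nt / 3)`).
#'
#' @param profile A `density_profile`.
#' @param codon Codon index (1-based), or
#' @param nt nucleotide position (1-based); exactly one of the two.
#' @param mode `"rho"` (A-site occupancy) or `"coverage"`.
#' @return Occupancy value.
#' @export
density_at <- function(profile, codon = NULL, nt = NULL, mode = c("rho", "coverage")) {
  mode <- match.arg(mode)
  if (is.null(codon) == is.null(nt)) {
    stop("give exactly one of 'codon' or 'nt'", call. = FALSE)
  }
  if (!is.null(nt)) codon <- ceiling(nt / 3)
  if (any(codon < 1 | codon > nrow(profile))) {
    stop("position out of range", call. = FALSE)
  }
  profile[[mode]][codon]
}

#' Exact stationary density for small instances
#'
#' Builds the full configuration space of the same Markov process (every set
#' of A-site positions with pairwise spacing >= footprint), assembles the
#' generator matrix, solves for the stationary distribution and returns exact
#' per-codon occupancy and flux. Serves as an independent oracle for
#' [simulate_density()]; feasible only for small lattices (the configuration
#' count is capped).
#'
#' @inheritParams simulate_density
#' @param max_states Cap on the number of configurations (default 1e5).
#' @return A `density_profile` with zero standard errors and exact `flux`.
#' @export
exact_density_small <- function(orf, rates = default_elongation_rates(),
                                params = sim_params(), max_states = 1e5) {
  stopifnot(inherits(orf, "orf"), inherits(params, "sim_params"))
  L <- orf$length
  f <- params$footprint
  if (L < f) stop("ORF shorter than the ribosome footprint", call. = FALSE)
  omega <- orf_omega(orf, rates, params$omega_mean)

  states <- enumerate_configs(L, f, max_states)
  n <- length(states)
  key <- function(s) if (length(s) == 0L) "empty" else paste(s, collapse = ",")
  index <- stats::setNames(seq_len(n), vapply(states, key, character(1)))

  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  add <- function(from, to, rate) {
    ii[[length(ii) + 1L]] <<- from; jj[[length(jj) + 1L]] <<- to
    xx[[length(xx) + 1L]] <<- rate
  }
  for (s_idx in seq_len(n)) {
    s <- states[[s_idx]]
    # initiation
    if (params$alpha_on > 0 && (length(s) == 0L || s[1] > f)) {
      add(s_idx, index[[key(c(1L, s))]], params$alpha_on)
    }
    if (length(s) > 0L) {
      for (k in seq_along(s)) {
        p <- s[k]
        if (p == L) {
          t <- s[-k]
          add(s_idx, index[[key(t)]], params$alpha_off)
        } else if (k == length(s) || s[k + 1L] >= p + 1L + f) {
          t <- s; t[k] <- p + 1L
          add(s_idx, index[[key(t)]], omega[p + 1L])
        }
        if (params$gamma > 0) {
          t <- s[-k]
          add(s_idx, index[[key(t)]], params$gamma)
        }
      }
    }
  }

  Q <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  Matrix::diag(Q) <- Matrix::diag(Q) - Matrix::rowSums(Q)
  # stationary distribution: pi Q = 0, sum(pi) = 1
  A <- Matrix::t(Q)
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  pi <- as.numeric(Matrix::solve(A, b))
  pi <- pmax(pi, 0); pi <- pi / sum(pi)

  rho <- numeric(L); cov <- numeric(L)
  for (s_idx in seq_len(n)) {
    s <- states[[s_idx]]
    if (length(s) == 0L) next
    rho[s] <- rho[s] + pi[s_idx]
    covered <- unique(unlist(lapply(s, function(p) p:min(p + f - 1L, L))))
    cov[covered] <- cov[covered] + pi[s_idx]
  }
  at_L <- vapply(states, function(s) length(s) > 0L && s[length(s)] == L, logical(1))
  J <- params$alpha_off * sum(pi[at_L])

  new_density_profile(orf$id, rho, rep(0, L), cov, rep(0, L), J, 0, params)
}

# all A-site configurations on a lattice of length L with spacing >= f,
# as sorted integer vectors (including the empty configuration)
enumerate_configs <- function(L, f, max_states) {
  acc <- list(integer(0))
  grow <- function(prefix, next_min) {
    for (p in seq.int(next_min, L)) {
      cfg <- c(prefix, p)
      acc[[length(acc) + 1L]] <<- cfg
      if (length(acc) > max_states) {
        stop("configuration space exceeds max_states = ", max_states, call. = FALSE)
      }
      if (p + f <= L) grow(cfg, p + f)
    }
  }
  grow(integer(0), 1L)
  acc
}

#' Select flux-matched variants
#'
#' Ranks variant density profiles by relative flux deviation from a reference
#' profile and returns the `k` closest. Ties are broken by ascending window
#' position (parsed from ids of the form `*_win<start>`, else by id).
#'
#' @param profiles List of `density_profile` objects (identical parameters).
#' @param reference Reference `density_profile` (e.g. the unmutated ORF).
#' @param k Number of variants to select.
#' @return Tibble `orf_id`, `flux`, `flux_deviation` (|J - J_ref| / J_ref),
#'   `selected` rows only, ordered by deviation.
#' @export
select_flux_matched <- function(profiles, reference, k = 5L) {
  J_ref <- flux(reference)
  if (!is.finite(J_ref) || J_ref <= 0) stop("reference flux must be > 0", call. = FALSE)
  if (k > length(profiles)) stop("k exceeds the number of profiles", call. = FALSE)
  ids <- vapply(profiles, function(p) p$orf_id[1], character(1))
  Js <- vapply(profiles, flux, numeric(1))
  win <- suppressWarnings(as.integer(sub(".*_win0*([0-9]+)$", "\\1", ids)))
  win[is.na(win)] <- .Machine$integer.max
  dev <- abs(Js - J_ref) / J_ref
  ord <- order(dev, win, ids)
  tibble::tibble(orf_id = ids[ord], flux = Js[ord], flux_deviation = dev[ord])[seq_len(k), ]
}

#' Write / read a density profile as TSV
#' @param profile A `density_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  out <- tibble::as_tibble(df)
  class(out) <- c("density_profile", class(out))
  out
}

# evaluate expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
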