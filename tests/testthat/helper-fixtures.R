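# shared fixtures built in code

egfp_orf <- function() {
  read_orf(system.file("extdata", "egfp_cds.fasta", package = "slowcodon"))
}

synthetic_guides <- function() {
  read_guides(system.file("extdata", "sirna_guides_synthetic.fasta",
                          package = "slowcodon"))
}

# tiny rate table where every codon family has a known slowest member:
# rate = RSCU-free toy, deterministic from codon string
toy_rates <- function() {
  r <- default_elongation_rates()
  r
}

# uniform-rate table (all 61 codons rate 1)
uniform_rates <- function() {
  r <- default_elongation_rates()
  r$rate <- 1
  r
}

random_orf <- function(L, id = "rand") {
  codons <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                           c("TAA", "TAG", "TGA")), L, replace = TRUE)
  orf_from_sequence(paste(codons, collapse = ""), id = id)
}

# percentile bootstrap of a statistic of several independent cell groups,
# resampling every group (so reference-median denominators contribute their
# sampling noise to the interval, as they must for ratio-of-medians ladders)
group_boot_ci <- function(groups, stat, n_boot = 1000L, conf = 0.95, seed = 1L) {
  draws <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      stat(lapply(groups, function(g) sample(g, replace = TRUE)))
    }, numeric(1))
  })
  q <- stats::quantile(draws, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  c(estimate = stat(groups), lower = q[1], upper = q[2])
}

reverse_complement_str <- function(x) {
  as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(gsub("U", "T", toupper(x)))))
}

# exhaustive two-sided Mann-Whitney p-value by enumerating all labelings
mw_enum <- function(a, b) {
  na <- length(a); nb <- length(b)
  vals <- c(a, b)
  u_of <- function(idx) {
    r <- rank(vals)
    sum(r[idx]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  combos <- utils::combn(na + nb, na)
  us <- apply(combos, 2, u_of)
  lo <- min(u_obs, na * nb - u_obs)
  p <- min(2 * mean(us <= lo), 1)
  list(U = u_obs, p = p)
}

# exact propagator integration of the three-stage linear ODE system
# x' = A x on the grid of elapsed times: x(s + dt) = expm(A dt) x(s).
# Independent of the closed form; exact to machine precision.
ode_oracle <- function(times, delta, m0ktl, t0, km, beta) {
  A <- matrix(c(-delta,  0,            0,
                m0ktl,   -(beta + km), 0,
                0,       km,           -beta), 3, 3, byrow = TRUE)
  s <- pmax(times - t0, 0)
  grid <- sort(unique(c(0, s)))
  dts <- diff(grid)
  vals <- numeric(length(grid))
  x <- c(1, 0, 0)
  cache <- list()
  for (k in seq_along(dts)) {
    keyv <- sprintf("%.12g", dts[k])
    E <- cache[[keyv]]
    if (is.null(E)) {
      E <- as.matrix(Matrix::expm(Matrix::Matrix(A * dts[k])))
      cache[[keyv]] <- E
    }
    x <- as.numeric(E %*% x)
    vals[k + 1] <- x[3]
  }
  vals[match(s, grid)]
}
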