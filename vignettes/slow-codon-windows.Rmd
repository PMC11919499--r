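---
title: "Slow-codon windows, ribosome traffic and mRNA stability: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slow-codon windows, ribosome traffic and mRNA stability: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slowcodon)
```

## What this package models

Synonymous codons are decoded at different speeds. Replacing a contiguous
stretch of codons by their slowest synonyms ("slow-codon window") locally
slows ribosomes, reshapes the steady-state ribosome density along the open
reading frame, and — through coupling between translation and decay pathways
such as quality control and RNA interference — changes the lifetime of the
mRNA. `slowcodon` implements the computational chain needed to study this
quantitatively:

1. **Variant design** (`slow_window_variants()`): every placement of a
   `window_len`-codon window along the ORF, each codon inside replaced by its
   slowest synonym. A 239-codon eGFP ORF with a 10-codon window yields
   239 − 10 + 1 = 230 variants, all translating to the identical protein.
2. **Ribosome traffic simulation** (`simulate_density()`): a totally
   asymmetric exclusion process with extended particles — initiation at
   codon 1, codon-specific elongation rates, premature drop-off, termination —
   simulated with the Gillespie direct method, yielding per-codon occupancy,
   flux, and Monte-Carlo standard errors.
3. **Kinetic fitting** (`fit_trajectory()`, `fit_cells()`): per-cell
   non-linear least squares of two-channel fluorescence trajectories to a
   three-stage translation/maturation/degradation model, with maturation and
   protein-degradation rates held fixed.
4. **Synthetic data** (`simulate_dataset()`): a generator emulating
   two-channel single-cell array experiments, so the full downstream pipeline
   is testable without microscopy data.
5. **Statistics** (`normalize_per_cell()`, `fold_change()`,
   `rnai_relative_fc()`, `mannwhitney_u()`, `correlation_profile()`): the
   normalization ladder, rank tests and per-codon density–stability
   correlation profiles.

## The ribosome traffic model

A ribosome is an extended particle occupying `footprint` codons (default 10,
about 30 nt), tracked by its A-site at the 5′ edge of the occupied stretch.
The continuous-time Markov dynamics are:

- initiation at codon 1 with rate $\alpha_{on}$, allowed only when codons
  $1..f$ are clear;
- elongation from codon $i$ to $i+1$ with rate $\omega_{i+1}$ (the rate of
  the codon being decoded next), allowed only when the ribosome ahead has its
  A-site at $\ge i + 1 + f$;
- premature drop-off anywhere with rate $\gamma$;
- termination from the last codon with rate $\alpha_{off}$.

Defaults ($\alpha_{on} = 0.1\,/s$, $\alpha_{off} = 2\,/s$,
$\gamma = 2\times10^{-4}\,/s$, mean elongation $5$ codons/s) are
physiological orders of magnitude; under them translation is
initiation-limited, and a slow window raises occupancy locally by roughly the
ratio of mean to window elongation rate while reducing flux only when the
window's carrying capacity drops below the initiation rate. Both the A-site
occupancy (`rho`) and the footprint-coverage probability (`coverage`) are
reported, since published density profiles do not always state which
convention they use.

**Elongation-rate table.** Measured per-codon elongation rates for human
cells are not available to this package, so the shipped default
(`default_elongation_rates()`) is an explicit stand-in: each codon's rate is
its relative synonymous codon usage computed from a standard human
codon-usage table, rescaled to mean 1.0 and multiplied by `omega_mean` inside
the simulator. This preserves the ordinal optimal/non-optimal structure that
window design and the qualitative density predictions rely on; any user table
(TSV with `codon`, `rate`) can be substituted via `read_rate_table()`.

**Verification.** `exact_density_small()` builds the full configuration space
of the same process (all A-site placements with pairwise spacing $\ge f$),
solves the stationary distribution of the generator matrix exactly, and
serves as an independent oracle: the test suite checks Gillespie densities
against it to within three Monte-Carlo standard errors on random small
instances, plus analytic limits (empty lattice, two-state chain, flux =
$\alpha_{off} \cdot \rho_L$).

**Numerical choices.** Fixed burn-in (default 10× the free-ribosome traversal
time) rather than automatic convergence detection; batch-means standard
errors (default 20 batches); R's RNG drives the C++ core so a seed fixes the
entire event sequence bit-for-bit. Flux-matched selection
(`select_flux_matched()`) ranks variants by $|J - J_{ref}|/J_{ref}$ with ties
broken by window position. Because the defaults are initiation-limited, the
variants closest in flux to the unmutated reference are those whose windows
barely throttle throughput; their downstream density deficit is
correspondingly small (fractions of a percent), so the packaged checks of the
"raised at the window, reduced downstream" pattern use long sampling windows
for the final comparisons.

## The three-stage expression model

For one cell and one channel, with mRNA amount $m$, immature protein $g^*$
and mature (fluorescent) protein $g$:

$$ m' = -\delta m, \qquad
   g^{*\prime} = k_{tl} m - (\beta + k_m) g^*, \qquad
   g' = k_m g^* - \beta g, $$

started from $(m_0, 0, 0)$ at a per-cell onset time $t_0$. The fluorescence
is proportional to $g$, a sum of three exponentials with rates $\delta$,
$\beta + k_m$, $\beta$. mRNA stability is $\tau = 1/\delta$.

The closed form is evaluated as a third divided difference of
$x \mapsto e^{-xs}$, computed through `expm1`-based nested first differences,
which is stable for arbitrarily close rate pairs — naive evaluation loses up
to half the significant digits when $\delta \approx \beta + k_m$ and $s$ is
small. The test suite compares it against exact matrix-exponential
propagation of the linear system at 1000 random parameter draws (relative
tolerance $10^{-6}$), including deliberately near-degenerate draws.

**Fitting.** Only the product $m_0 k_{tl}$ is identifiable from a
trajectory, so the fitter exposes it as one parameter. $k_m$ and $\beta$ are
fixed inputs (they are measured independently in translation-arrest
experiments; defaults $k_m = 1.2\,/h$, $\beta = 0.03\,/h$ are
order-of-magnitude eGFP values and configurable — downstream conclusions are
ratio-based and insensitive to these shared constants). Free parameters
$(\delta, m_0 k_{tl}, t_0)$ are optimized on a log scale for the rates with
`nlminb`; the onset time is bounded to $[0, 5]$ h. Initialization: $t_0$
from the first crossing of 5% of the trajectory maximum, $\delta$ from the
late-phase log-linear slope when the trajectory decays (0.1/h otherwise),
$m_0 k_{tl}$ from the peak height, followed by five jittered restarts
(deterministic given the seed), best residual sum of squares wins. Least
squares is unweighted. Trajectories whose amplitude does not exceed five
times the difference-based noise floor are flagged non-expressing and not
fitted; an exactly zero fitted $\delta$ maps to the infinite-stability
sentinel and is excluded (and counted) downstream. The printed model
equations omit an onset time; it is included here because expression start
varies from cell to cell after transfection, and trajectories begin near
zero.

## The synthetic-data generator

`simulate_dataset()` emulates what a two-channel single-cell array experiment
measures: per cell, a shared lipoplex count $N \sim$ Poisson (zero draws
redrawn and counted) sets the delivered mRNA dose of both channels
($m_0 \sim$ Poisson$(N \times$ mRNA/lipoplex$)$), which induces the
positive cross-channel correlation of initial expression rates seen in
co-delivery experiments, while degradation rates are drawn independently per
channel (lognormal), giving near-zero cross-channel $\delta$ correlation.
Condition effects (slow-codon windows, targeting siRNA) enter as
multipliers on the eGFP-channel $\delta$; the reference channel is
untouched. Trajectories are the closed-form model times lognormal
multiplicative noise (CV default 5%) plus additive Gaussian background, on a
10-min grid over 30 h; a configurable fraction (default 5%) of cells is
emitted near-baseline to exercise the non-expressing path.

What the generator does **not** emulate: image-level effects (segmentation
errors, background drift, photobleaching), cell division and death,
cell-cycle-coupled expression, and any mechanistic coupling between ribosome
density and degradation — condition effects are planted as multipliers, not
derived from the traffic model. A green end-to-end test therefore
establishes that the estimation and normalization machinery recovers planted
effects of realistic magnitude from data with realistic sampling and noise;
it says nothing about whether the biological coupling itself holds.
Cell-to-cell CVs (default 0.4 lognormal) are placeholders of plausible
magnitude for recovery tests, not measurements.

## The normalization ladder and statistics

Per cell: $\tau_n = \tau_{eGFP}/\tau_{CayRFP}$ and
$k_n = (m_0k_{tl})_{eGFP}/(m_0k_{tl})_{CayRFP}$ cancel dose and cell-state
variation. Per condition: $FC_\tau$ divides by the median $\tau_n$ of the
unmutated construct in the same condition (so the reference's median fold
change is exactly 1). Per construct: the RNAi-relative fold change divides
$FC_\tau$ under a targeting siRNA by the construct's median $FC_\tau$ under
the non-targeting control. Cells failing either channel's fit are dropped
with a logged count; ratios with zero or infinite denominators are excluded
and counted.

Group comparisons use the Mann–Whitney U test: the exact null distribution
when the combined sample is $\le 16$ and tie-free, otherwise the normal
approximation with tie and continuity corrections; p-values are reported raw
(no multiple-testing correction — the star mapping is the conventional one
with boundaries assigned to the less significant class). Dispersion is the
unscaled median absolute deviation (no 1.4826 factor), matching "median
absolute deviation" as commonly printed; a flag restores the scaled version.

`correlation_profile()` correlates, per codon, simulated density with a
per-construct stability measure **across constructs** (default: the
construct median of the fold change). Correlating per-construct medians
rather than single cells is a deliberate choice: the density profile is a
construct-level prediction, and per-cell correlation would inflate the
sample size with within-construct noise that carries no density information.
Positions where density does not vary across constructs are flagged
undefined rather than given an arbitrary value.

## Seeds, determinism and degenerate inputs

Every stochastic component (simulator, generator, fit restarts, bootstrap)
consumes R's RNG under a locally scoped seed, so identical configurations
reproduce bit-identical outputs without disturbing the caller's RNG state.
Degenerate inputs are handled explicitly: ORFs with internal stops or
non-triplet length are rejected with positions reported; stop codons are
excluded from rate tables and window replacement; `alpha_on = 0` yields the
empty-lattice profile; `window_len` equal to the ORF length yields exactly
one variant; boundary p-values fall in the less significant star class.

## Design choices where the problem was open

- **Window indexing**: 1-based codon positions with closed intervals; the
  first mutated codon defines the window position, and the terminal stop is
  trimmed before any position arithmetic (so a 720-nt CDS is a 239-codon
  ORF and the last 10-codon window starts at codon 230).
- **Seed definition**: guide positions 2–8 (7-mer), perfect complementarity,
  no G:U wobble — the standard minimal seed; configurable.
- **Tie-breaking** in slowest-synonym selection: lexicographically smallest
  codon among minima, for determinism.
- **siRNA guides**: the bundled guides are *synthetic* stand-ins constructed
  as reverse complements of the bundled eGFP ORF at nt 122–140 and 433–451,
  reproducing the canonical binding positions; they are labelled synthetic
  in the file name and are not published reagent sequences.
- **Configs**: JSON rather than YAML (no YAML parser among the package's
  dependencies); structure and semantics are unchanged.

## Known limitations

- The elongation-rate table is usage-derived, not measured; absolute
  simulated fluxes and densities are therefore relative quantities.
- The traffic model is single-mRNA: no ribosome recycling, tRNA-pool
  competition, or mRNA circularization.
- The fitter assumes a single expression onset and no photobleaching or
  calibration to absolute protein numbers.
- Under the initiation-limited defaults, downstream density reductions for
  nearly flux-matched variants are sub-percent effects; resolving them
  requires long sampling windows (the packaged tests do this) and they
  should not be over-interpreted at default precision.

## A compact run

```{r example, eval = FALSE}
egfp <- read_orf(system.file("extdata", "egfp_cds.fasta", package = "slowcodon"))
variants <- slow_window_variants(egfp)
ref <- simulate_density(egfp, params = sim_params(sample_time = 4000, rng_seed = 1))

cfg <- cell_sim_config(n_cells = 60, rng_seed = 1)
conds <- condition_table("eGFP", c("siCtrl", "siRNA1")) |>
  dplyr::mutate(delta_mult = ifelse(sirna == "siRNA1", 10, 1))
ds <- simulate_dataset(cfg, conds)
fits <- fit_cells(ds$trajectories)
cells <- fold_change(normalize_per_cell(fits))
summarize_conditions(cells, "fc_tau")
```
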