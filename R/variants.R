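#' Slowest synonymous codon
#'
#' Returns, for each input codon, the synonymous codon with the smallest
#' elongation rate in `rates`. If the input codon is already the slowest, or
#' its amino acid has a single codon (Met, Trp), the input is returned
#' unchanged. Ties are broken by taking the lexicographically smallest codon
#' among the minima, so the substitution is deterministic.
#'
#' @param codon Character vector of sense codons (DNA, uppercase or not).
#' @param rates Rate table (see [default_elongation_rates()]).
#' @return Character vector of codons, same length as `codon`.
#' @export
slowest_synonym <- function(codon, rates = default_elongation_rates()) {
  rates <- validate_rate_table(rates)
  codon <- vapply(codon, normalize_dna, character(1), USE.NAMES = FALSE)
  if (any(codon %in% STOP_CODONS)) stop("stop codon has no synonym", call. = FALSE)
  if (!all(codon %in% SENSE_CODONS)) {
    stop("not a sense codon: ", codon[!codon %in% SENSE_CODONS][1], call. = FALSE)
  }
  slow <- slowest_by_aa(rates)
  unname(slow[GENETIC_CODE_TABLE[codon]])
}

# amino acid -> its slowest codon (lexicographic tie-break)
slowest_by_aa <- function(rates) {
  ord <- order(rates$amino_acid, rates$rate, rates$codon)
  r <- rates[ord, ]
  first <- !duplicated(r$amino_acid)
  stats::setNames(r$codon[first], r$amino_acid[first])
}

#' Generate all slow-codon-window variants of an ORF
#'
#' Slides a window of `window_len` adjacent codons along the ORF and, at each
#' start position, replaces every codon inside the window by its slowest
#' synonym ([slowest_synonym()]). Codons outside the window are untouched, so
#' every variant translates to the parent protein. An ORF of L codons yields
#' exactly L - window_len + 1 variants.
#'
#' @param orf An `orf` object.
#' @param rates Elongation-rate table.
#' @param window_len Window length in codons (default 10).
#' @return A tibble with one row per variant: `variant_id`, `window_start`
#'   (1-based codon index of the first replaced codon), `window_len`,
#'   `n_changed` (codons actually substituted), `sequence` (full nucleotide
#'   string) and `codons` (list-column). The parent `orf` is attached as
#'   attribute `"parent"`.
#' @examples
#' fa <- system.file("extdata", "egfp_cds.fasta", package = "slowcodon")
#' v <- slow_window_variants(read_orf(fa))
#' nrow(v)  # 230 for the 239-codon eGFP ORF
#' @export
slow_window_variants <- function(orf, rates = default_elongation_rates(),
                                 window_len = 10L) {
  stopifnot(inherits(orf, "orf"))
  window_len <- as.integer(window_len)
  if (window_len < 1L) stop("window_len must be >= 1", call. = FALSE)
  if (window_len > orf$length) {
    stop("window_len (", window_len, ") exceeds ORF length (", orf$length, ")",
         call. = FALSE)
  }
  rates <- validate_rate_table(rates)
  slow <- slowest_by_aa(rates)
  slow_codons <- unname(slow[GENETIC_CODE_TABLE[orf$codons]])

  starts <- seq_len(orf$length - window_len + 1L)
  width <- max(3L, nchar(as.character(max(starts))))
  out <- purrr::map(starts, function(s) {
    idx <- s:(s + window_len - 1L)
    codons <- orf$codons
    codons[idx] <- slow_codons[idx]
    tibble::tibble(
      variant_id = sprintf("%s_win%0*d", orf$id, width, s),
      window_start = s,
      window_len = window_len,
      n_changed = sum(codons != orf$codons),
      sequence = paste(codons, collapse = ""),
      codons = list(codons)
    )
  })
  res <- dplyr::bind_rows(out)
  attr(res, "parent") <- orf
  res
}

#' Write variants (and their parent) to FASTA
#'
#' @param variants Tibble from [slow_window_variants()].
#' @param path Output FASTA path.
#' @param include_parent Prepend the parent ORF record.
#' @return `path`, invisibly.
#' @export
write_variants_fasta <- function(variants, path, include_parent = TRUE) {
  seqs <- variants$sequence
  ids <- variants$variant_id
  parent <- attr(variants, "parent")
  if (include_parent && !is.null(parent)) {
    seqs <- c(orf_sequence(parent), seqs)
    ids <- c(parent$id, ids)
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}
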