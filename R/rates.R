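#' Codon-specific elongation rates
#'
#' The simulator and variant designer need a relative translation speed for
#' each of the 61 sense codons. The default table shipped with the package is
#' a stand-in derived from human codon-usage frequencies: each codon's rate is
#' its relative synonymous codon usage (RSCU, usage divided by the mean usage
#' of its synonym family), rescaled so the mean rate over all sense codons is
#' 1.0. This preserves the ordinal optimal-versus-non-optimal structure that
#' slow-window design needs; it is not a measured elongation-rate set, and any
#' user table can be supplied instead via [read_rate_table()].
#'
#' @return A tibble with columns `codon` (61 sense codons), `rate`
#'   (dimensionless, mean 1.0) and `amino_acid`.
#' @examples
#' rates <- default_elongation_rates()
#' dplyr::slice_min(rates, rate, n = 3)
#' @export
default_elongation_rates <- function() {
  usage <- HUMAN_CODON_USAGE
  aa <- GENETIC_CODE_TABLE[names(usage)]
  fam_mean <- tapply(usage, aa, mean)
  rscu <- usage / fam_mean[aa]
  rate <- rscu / mean(rscu)
  tibble::tibble(
    codon = names(usage),
    rate = as.numeric(rate),
    amino_acid = unname(aa)
  )
}

#' Read a codon elongation-rate table from TSV
#'
#' @param path TSV file with header columns `codon` and `rate`.
#' @return Tibble with `codon`, `rate`, `amino_acid`, validated to cover all
#'   61 sense codons with strictly positive rates.
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) stop("rate table not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("codon", "rate") %in% names(df))) {
    stop("rate table must have 'codon' and 'rate' columns", call. = FALSE)
  }
  df$codon <- normalize_dna(df$codon)
  validate_rate_table(tibble::tibble(
    codon = df$codon, rate = as.numeric(df$rate),
    amino_acid = unname(GENETIC_CODE_TABLE[df$codon])
  ))
}

#' Write a rate table to TSV
#' @param rates Rate tibble (`codon`, `rate`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(rates, path) {
  utils::write.table(rates[, c("codon", "rate")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_rate_table <- function(rates) {
  if (any(rates$codon %in% STOP_CODONS)) {
    stop("rate table must not contain stop codons", call. = FALSE)
  }
  missing <- setdiff(SENSE_CODONS, rates$codon)
  if (length(missing) > 0L) {
    stop("rate table missing codons: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rates$codon)) stop("duplicate codons in rate table", call. = FALSE)
  if (any(!is.finite(rates$rate)) || any(rates$rate <= 0)) {
    stop("all rates must be finite and > 0", call. = FALSE)
  }
  rates
}

rate_lookup <- function(rates) {
  stats::setNames(rates$rate, rates$codon)
}

# Human codon usage, frequencies per thousand codons (GenBank-derived
# summary values, standard reference table). Used only to rank synonymous
# codons by usage; absolute values are immaterial downstream.
HUMAN_CODON_USAGE <- c(
  TTT = 17.6, TTC = 20.3, TTA = 7.7,  TTG = 12.9,
  CTT = 13.2, CTC = 19.6, CTA = 7.2,  CTG = 39.6,
  ATT = 16.0, ATC = 20.8, ATA = 7.5,  ATG = 22.0,
  GTT = 11.0, GTC = 14.5, GTA = 7.1,  GTG = 28.1,
  TCT = 15.2, TCC = 17.7, TCA = 12.2, TCG = 4.4,
  CCT = 17.5, CCC = 19.8, CCA = 16.9, CCG = 6.9,
  ACT = 13.1, ACC = 18.9, ACA = 15.1, ACG = 6.1,
  GCT = 18.4, GCC = 27.7, GCA = 15.8, GCG = 7.4,
  TAT = 12.2, TAC = 15.3,
  CAT = 10.9, CAC = 15.1,
  CAA = 12.3, CAG = 34.2,
  AAT = 17.0, AAC = 19.1,
  AAA = 24.4, AAG = 31.9,
  GAT = 21.8, GAC = 25.1,
  GAA = 29.0, GAG = 39.6,
  TGT = 10.6, TGC = 12.6, TGG = 13.2,
  CGT = 4.5,  CGC = 10.4, CGA = 6.2,  CGG = 11.4,
  AGT = 12.1, AGC = 19.5,
  AGA = 12.2, AGG = 12.0,
  GGT = 10.8, GGC = 22.2, GGA = 16.5, GGG = 16.5
)
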