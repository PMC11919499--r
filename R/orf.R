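#' Read an open reading frame from a FASTA file
#'
#' Reads a coding sequence, normalizes it to uppercase DNA (U becomes T),
#' trims a terminal stop codon if present, and splits it into codons.
#' Sequences with an internal stop codon or a length not divisible by three
#' are rejected.
#'
#' @param path Path to a FASTA file.
#' @param record_id Optional record name to select; defaults to the first
#'   record.
#' @param id Optional label for the returned ORF; defaults to the FASTA
#'   record name.
#' @return An object of class `orf`: a list with `id`, `codons` (character
#'   vector of triplets), `length` (codon count) and `stop_trimmed`.
#' @examples
#' fa <- system.file("extdata", "egfp_cds.fasta", package = "slowcodon")
#' egfp <- read_orf(fa)
#' egfp$length
#' @export
read_orf <- function(path, record_id = NULL, id = NULL) {
  if (!file.exists(path)) {
    stop("FASTA file not found: ", path, call. = FALSE)
  }
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0L) stop("no records in ", path, call. = FALSE)
  if (!is.null(record_id)) {
    hit <- which(names(recs) == record_id | startsWith(names(recs), paste0(record_id, " ")))
    if (length(hit) == 0L) stop("record '", record_id, "' not found in ", path, call. = FALSE)
    recs <- recs[hit[1]]
  } else {
    recs <- recs[1]
  }
  orf_from_sequence(as.character(recs[[1]]),
                    id = id %||% sub("\\s.*$", "", names(recs)[1]))
}

#' Build an ORF object from a nucleotide string
#'
#' @param sequence Nucleotide sequence (DNA or RNA alphabet, any case).
#' @param id Label for the ORF.
#' @return An `orf` object (see [read_orf()]).
#' @export
orf_from_sequence <- function(sequence, id = "orf") {
  seq <- normalize_dna(sequence)
  if (nchar(seq) %% 3L != 0L) {
    stop("sequence length ", nchar(seq), " is not divisible by 3", call. = FALSE)
  }
  codons <- substring(seq, seq(1L, nchar(seq), 3L), seq(3L, nchar(seq), 3L))
  stop_trimmed <- FALSE
  if (length(codons) > 0L && codons[length(codons)] %in% STOP_CODONS) {
    codons <- codons[-length(codons)]
    stop_trimmed <- TRUE
  }
  internal <- which(codons %in% STOP_CODONS)
  if (length(internal) > 0L) {
    stop("internal stop at codon ", internal[1], call. = FALSE)
  }
  bad <- grepl("[^ACGT]", codons)
  if (any(bad)) {
    stop("non-ACGT characters in codon ", which(bad)[1], call. = FALSE)
  }
  structure(
    list(id = id, codons = codons, length = length(codons),
         stop_trimmed = stop_trimmed),
    class = "orf"
  )
}

#' @export
print.orf <- function(x, ...) {
  cat("<orf> ", x$id, ": ", x$length, " codons",
      if (x$stop_trimmed) " (terminal stop trimmed)", "\n", sep = "")
  invisible(x)
}

#' Nucleotide sequence of an ORF
#' @param orf An `orf` object.
#' @return Single uppercase DNA string (stop codon not included).
#' @export
orf_sequence <- function(orf) paste(orf$codons, collapse = "")

#' Translate an ORF under the standard genetic code
#' @param orf An `orf` object or a character vector of codons.
#' @return Amino-acid string.
#' @export
translate_orf <- function(orf) {
  codons <- if (inherits(orf, "orf")) orf$codons else orf
  aa <- GENETIC_CODE_TABLE[codons]
  if (anyNA(aa)) stop("unknown codon: ", codons[which(is.na(aa))[1]], call. = FALSE)
  paste(aa, collapse = "")
}

# uppercase, RNA -> DNA
normalize_dna <- function(x) {
  x <- toupper(gsub("[\\s]", "", x, perl = TRUE))
  gsub("U", "T", x, fixed = TRUE)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(normalize_dna(x))))
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

GENETIC_CODE_TABLE <- {
  gc <- Biostrings::GENETIC_CODE
  gc[!names(gc) %in% c("TAA", "TAG", "TGA")]
}

SENSE_CODONS <- names(GENETIC_CODE_TABLE)

`%||%` <- function(a, b) if (is.null(a)) b else a
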