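#' Map full siRNA target sites on an ORF
#'
#' Finds every position where the ORF (sense strand) contains the exact
#' reverse complement of the siRNA guide strand, i.e. a perfectly
#' complementary binding site. Positions are 1-based nucleotide coordinates
#' of the 5'-most matched target nucleotide.
#'
#' @param orf An `orf` object.
#' @param guide Guide-strand sequence (RNA or DNA alphabet; 19-23 nt typical).
#' @param sirna_id Label used in the returned table.
#' @return Tibble with columns `sirna_id`, `start_nt`, `match_len`, `kind`
#'   (`"full"`); zero rows if the guide has no site.
#' @examples
#' fa <- system.file("extdata", "egfp_cds.fasta", package = "slowcodon")
#' gfa <- system.file("extdata", "sirna_guides_synthetic.fasta", package = "slowcodon")
#' guides <- read_guides(gfa)
#' map_sirna_sites(read_orf(fa), guides$guide[1], guides$sirna_id[1])
#' @export
map_sirna_sites <- function(orf, guide, sirna_id = "siRNA") {
  stopifnot(inherits(orf, "orf"))
  guide <- normalize_dna(guide)
  if (nchar(guide) < 10L) stop("guide shorter than 10 nt", call. = FALSE)
  site <- reverse_complement(guide)
  starts <- find_all(orf_sequence(orf), site)
  tibble::tibble(
    sirna_id = rep(sirna_id, length(starts)),
    start_nt = starts,
    match_len = rep(nchar(site), length(starts)),
    kind = rep("full", length(starts))
  )
}

#' Scan an ORF for siRNA seed matches
#'
#' Maps every occurrence of the reverse complement of the guide's seed
#' (guide positions `seed[1]`..`seed[2]`, default 2-8, perfect
#' complementarity, no G:U wobble) on the ORF. Seed hits that sit at the
#' seed-aligned offset inside a full binding site are flagged `"full"`;
#' the rest are `"seed"`.
#'
#' @inheritParams map_sirna_sites
#' @param seed Integer pair: first and last guide position of the seed.
#' @return Tibble `sirna_id`, `start_nt` (5'-most matched ORF nucleotide of
#'   the seed region), `match_len`, `kind` (`"seed"` or `"full"`).
#' @export
scan_seed_matches <- function(orf, guide, sirna_id = "siRNA", seed = c(2L, 8L)) {
  stopifnot(inherits(orf, "orf"))
  guide <- normalize_dna(guide)
  if (nchar(guide) < 10L) stop("guide shorter than 10 nt", call. = FALSE)
  if (seed[2] > nchar(guide)) stop("seed extends past guide end", call. = FALSE)
  seed_seq <- substr(guide, seed[1], seed[2])
  target <- reverse_complement(seed_seq)
  starts <- find_all(orf_sequence(orf), target)
  # guide position k pairs with ORF position s + len(guide) - k for a full
  # site starting at s, so the seed region of a full site at s starts at
  # s + len(guide) - seed[2]
  full <- map_sirna_sites(orf, guide, sirna_id)
  full_seed_starts <- full$start_nt + nchar(guide) - seed[2]
  tibble::tibble(
    sirna_id = rep(sirna_id, length(starts)),
    start_nt = starts,
    match_len = rep(nchar(target), length(starts)),
    kind = c("seed", "full")[as.integer(starts %in% full_seed_starts) + 1L]
  )
}

#' Compare seed/full siRNA sites of a variant against its parent
#'
#' For each variant and guide, lists seed and full sites gained or lost by
#' the synonymous substitutions and reports whether any full binding site was
#' gained (constructs should never gain one).
#'
#' @param variants Tibble from [slow_window_variants()] (or any tibble with
#'   `variant_id` and `sequence`); the parent is taken from its `"parent"`
#'   attribute unless given explicitly.
#' @param guides Tibble with `sirna_id` and `guide` columns (see
#'   [read_guides()]).
#' @param parent Parent `orf` (optional if attached to `variants`).
#' @param seed Seed definition passed to [scan_seed_matches()].
#' @return Tibble: one row per variant x guide with counts of gained/lost
#'   seed and full sites, `no_full_site_gained`, and list-columns `gained`
#'   and `lost` holding the site tables.
#' @export
check_variant_seed_safety <- function(variants, guides,
                                      parent = attr(variants, "parent"),
                                      seed = c(2L, 8L)) {
  if (is.null(parent)) stop("parent ORF not supplied", call. = FALSE)
  stopifnot(inherits(parent, "orf"))

  site_table <- function(orf) {
    dplyr::bind_rows(purrr::map2(
      guides$guide, guides$sirna_id,
      function(g, id) dplyr::bind_rows(
        map_sirna_sites(orf, g, id),
        dplyr::filter(scan_seed_matches(orf, g, id, seed), .data$kind == "seed")
      )
    ))
  }
  parent_sites <- site_table(parent)

  rows <- purrr::pmap(list(variants$variant_id, variants$sequence), function(vid, sq) {
    vorf <- orf_from_sequence(sq, id = vid)
    vsites <- site_table(vorf)
    key <- function(d) paste(d$sirna_id, d$kind, d$start_nt)
    gained <- vsites[!key(vsites) %in% key(parent_sites), , drop = FALSE]
    lost <- parent_sites[!key(parent_sites) %in% key(vsites), , drop = FALSE]
    tibble::tibble(
      variant_id = vid,
      n_seed_gained = sum(gained$kind == "seed"),
      n_seed_lost = sum(lost$kind == "seed"),
      n_full_gained = sum(gained$kind == "full"),
      n_full_lost = sum(lost$kind == "full"),
      no_full_site_gained = sum(gained$kind == "full") == 0L,
      gained = list(gained),
      lost = list(lost)
    )
  })
  dplyr::bind_rows(rows)
}

#' Read siRNA guide strands from FASTA
#'
#' @param path FASTA file of guide-strand sequences (RNA or DNA letters).
#' @return Tibble with `sirna_id` and `guide` (normalized to DNA uppercase).
#' @export
read_guides <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  tibble::tibble(
    sirna_id = sub("\\s.*$", "", names(recs)),
    guide = vapply(as.character(recs), normalize_dna, character(1), USE.NAMES = FALSE)
  )
}

#' Write a site report to TSV
#' @param sites Tibble of sites (`sirna_id`, `start_nt`, `match_len`, `kind`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_site_report <- function(sites, path) {
  utils::write.table(sites[, c("sirna_id", "start_nt", "match_len", "kind")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# all 1-based start positions of pattern in subject (overlapping allowed)
find_all <- function(subject, pattern) {
  n <- nchar(subject)
  k <- nchar(pattern)
  if (k > n) return(integer(0))
  cand <- seq_len(n - k + 1L)
  cand[substring(subject, cand, cand + k - 1L) == pattern]
}
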