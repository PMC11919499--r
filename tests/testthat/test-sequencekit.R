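test_that("read_orf parses, normalizes and validates reading frames", {
  tmp <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">tiny", "ATGAAA"), tmp)
  o <- read_orf(tmp)
  expect_equal(o$codons, c("ATG", "AAA"))
  expect_equal(o$length, 2L)

  # lowercase / RNA input is normalized
  o2 <- orf_from_sequence("augaaa", id = "rna")
  expect_equal(o2$codons, c("ATG", "AAA"))

  # terminal stop trimmed and recorded
  o3 <- orf_from_sequence("ATGAAATAA")
  expect_true(o3$stop_trimmed)
  expect_equal(o3$length, 2L)

  # canonical eGFP fixture: 720 nt incl. stop -> 239 codons
  egfp <- egfp_orf()
  expect_equal(egfp$length, 239L)
  expect_true(egfp$stop_trimmed)

  expect_error(orf_from_sequence("ATGTAAAAA"), "internal stop at codon 2")
  expect_error(orf_from_sequence("ATGAA"), "not divisible by 3")
  expect_error(read_orf(file.path(tempdir(), "nope.fasta")), "not found")
  expect_error(orf_from_sequence("ATGANA"), "non-ACGT")
})

test_that("slowest_synonym picks the minimal-rate codon deterministically", {
  rates <- default_elongation_rates()
  # single-codon families return the input
  expect_equal(slowest_synonym("ATG", rates), "ATG")
  expect_equal(slowest_synonym("TGG", rates), "TGG")

  # forced minimal-rate rule on a custom table
  custom <- rates
  custom$rate[custom$codon == "AAA"] <- 0.5
  custom$rate[custom$codon == "AAG"] <- 1.0
  expect_equal(slowest_synonym("AAG", custom), "AAA")

  # brute-force min over the 6 Leu codons of the shipped table
  leu <- rates[rates$amino_acid == "L", ]
  expect_equal(slowest_synonym("CTG", rates),
               min(leu$codon[leu$rate == min(leu$rate)]))

  # lexicographic tie-break
  tied <- rates
  tied$rate[tied$amino_acid == "K"] <- 1  # AAA, AAG tie
  expect_equal(slowest_synonym("AAG", tied), "AAA")

  expect_error(slowest_synonym("TAA", rates), "stop codon")
})

test_that("slow_window_variants enumerates one synonymous variant per start", {
  egfp <- egfp_orf()
  v <- slow_window_variants(egfp)
  expect_equal(nrow(v), 230L)
  expect_equal(v$window_start, 1:230)

  # translation invariance over all variants, changes confined to the window
  parent_aa <- translate_orf(egfp)
  for (i in seq_len(nrow(v))) {
    codons <- v$codons[[i]]
    expect_identical(translate_orf(codons), parent_aa)
    changed <- which(codons != egfp$codons)
    expect_lte(length(changed), v$window_len[i])
    expect_true(all(changed >= v$window_start[i] &
                    changed <= v$window_start[i] + v$window_len[i] - 1))
  }

  # degenerate window sizes
  o12 <- random_orf(12)
  expect_equal(nrow(slow_window_variants(o12, window_len = 10)), 3L)
  expect_equal(slow_window_variants(o12, window_len = 10)$window_start, 1:3)
  expect_equal(nrow(slow_window_variants(o12, window_len = 12)), 1L)
  expect_error(slow_window_variants(o12, window_len = 13), "exceeds")
})

test_that("variant FASTA round-trips through read_orf", {
  egfp <- egfp_orf()
  v <- slow_window_variants(egfp)[1:3, ]
  attr(v, "parent") <- egfp
  tmp <- withr::local_tempfile(fileext = ".fasta")
  write_variants_fasta(v, tmp)
  back <- read_orf(tmp, record_id = v$variant_id[2])
  expect_equal(orf_sequence(back), v$sequence[2])
})

test_that("map_sirna_sites finds exact reverse-complement sites", {
  toy <- orf_from_sequence("ATGAAACCCGGG", "toy")
  guide <- reverse_complement_str("AAACCC")
  hit <- map_sirna_sites(toy, paste0(guide, "AAAA"), "g")  # pad to >= 10 nt
  # padded guide has no site; use a planted 10-nt guide instead
  expect_equal(nrow(hit), 0L)
  guide10 <- reverse_complement_str("AAACCCGGG")  # 9 nt -> too short
  expect_error(map_sirna_sites(toy, guide10, "g"), "shorter than 10")
  guide_ok <- reverse_complement_str("ATGAAACCCG")
  expect_equal(map_sirna_sites(toy, guide_ok, "g")$start_nt, 1L)

  # round trip on random ORFs: planting the complement always yields p
  set.seed(11)
  for (rep in 1:5) {
    orf <- random_orf(60)
    p <- sample(30, 1)
    site <- substr(orf_sequence(orf), p, p + 18)
    g <- reverse_complement_str(site)
    hits <- map_sirna_sites(orf, g, "g")
    expect_true(p %in% hits$start_nt)
  }

  # the shipped synthetic guides hit the fixture ORF at nt 122 and 433
  egfp <- egfp_orf()
  g <- synthetic_guides()
  expect_equal(map_sirna_sites(egfp, g$guide[1], g$sirna_id[1])$start_nt, 122L)
  expect_equal(map_sirna_sites(egfp, g$guide[2], g$sirna_id[2])$start_nt, 433L)

  # RNA-alphabet guides are accepted
  rna_guide <- gsub("T", "U", g$guide[1])
  expect_equal(map_sirna_sites(egfp, rna_guide)$start_nt, 122L)
})

test_that("scan_seed_matches maps 7-mer seed complements and flags full sites", {
  # toy ORF with the seed complement planted twice
  guide <- "TTACGCATGACGTAGCATG"        # seed = guide[2..8] = TACGCAT
  seed_rc <- reverse_complement_str(substr(guide, 2, 8))  # ATGCGTA
  orf <- orf_from_sequence(paste0("ATG", seed_rc, "GCAGCAGCAGCAGC", seed_rc, "GC"),
                           "toy")
  hits <- scan_seed_matches(orf, guide, "g")
  expect_equal(hits$start_nt, c(4L, 25L))
  expect_true(all(hits$kind == "seed"))

  # absent seed -> empty
  none <- scan_seed_matches(orf_from_sequence(strrep("GCA", 20), "gc"), guide)
  expect_equal(nrow(none), 0L)

  # full sites appear among seed hits at the seed-aligned offset
  egfp <- egfp_orf()
  g <- synthetic_guides()
  for (i in 1:2) {
    full <- map_sirna_sites(egfp, g$guide[i], g$sirna_id[i])
    seeds <- scan_seed_matches(egfp, g$guide[i], g$sirna_id[i])
    offset <- full$start_nt + nchar(g$guide[i]) - 8L
    expect_true(all(offset %in% seeds$start_nt[seeds$kind == "full"]))
  }
})

test_that("check_variant_seed_safety reports gained and lost sites", {
  egfp <- egfp_orf()
  guides <- synthetic_guides()

  # a variant identical to the parent: nothing gained or lost
  v_id <- tibble::tibble(variant_id = "same", sequence = orf_sequence(egfp))
  rep0 <- check_variant_seed_safety(v_id, guides, parent = egfp)
  expect_equal(rep0$n_seed_gained + rep0$n_seed_lost +
               rep0$n_full_gained + rep0$n_full_lost, 0L)
  expect_true(rep0$no_full_site_gained)

  # destroying the full site at nt 122 (codon 41) is reported as lost
  v <- slow_window_variants(egfp)
  v41 <- v[v$window_start == 41, ]
  expect_false(identical(v41$codons[[1]][41:50], egfp$codons[41:50]))
  rep1 <- check_variant_seed_safety(v41, guides, parent = egfp)
  expect_gte(sum(rep1$n_full_lost), 1L)

  # planting a full site via the window -> no_full_site_gained FALSE
  base <- orf_from_sequence(strrep("CTGGAA", 15), "toy")   # optimal Leu/Glu
  slow_codons <- c(slowest_synonym("CTG"), slowest_synonym("GAA"))
  planted_guide <- reverse_complement_str(paste(rep(slow_codons, 5)[1:5], collapse = ""))
  vt <- slow_window_variants(base, window_len = 10)[1, ]
  repl <- check_variant_seed_safety(vt, tibble::tibble(sirna_id = "pg", guide = planted_guide),
                                    parent = base)
  expect_false(repl$no_full_site_gained)
})
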