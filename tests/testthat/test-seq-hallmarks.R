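test_that("longest-ORF search handles the simple cases", {
  orf <- find_longest_orf("ATGAAATAA")
  expect_equal(orf$orf_start, 1)
  expect_equal(orf$orf_end, 9)
  expect_equal(orf$protein, "MK")
  expect_equal(orf$length_aa, 2)

  # two planted ORFs, the 7-codon one wins
  s <- paste0("CC", "ATGAAAAAATAA", "C", "ATGAAAAAAAAAAAAAAATAG")
  orf <- find_longest_orf(s)
  expect_equal(orf$length_aa, 6)

  expect_equal(nrow(find_longest_orf("CCCCCCCCC")), 0)
  expect_error(find_longest_orf("ATG"), "shorter")
})

test_that("longest-ORF search agrees with the exhaustive-scan oracle", {
  set.seed(31)
  for (i in 1:500) {
    s <- random_dna(300)
    mine <- find_longest_orf(s)
    oracle <- oracle_longest_orf(s)
    if (is.null(oracle)) {
      expect_equal(nrow(mine), 0)
    } else {
      expect_equal(mine$orf_start, unname(oracle["start"]))
      expect_equal(mine$orf_end, unname(oracle["end"]))
      # translated length times three plus the stop spans the ORF
      expect_equal(mine$length_aa * 3 + 3, mine$orf_end - mine$orf_start + 1)
    }
  }
})

test_that("molecular weight follows the average-mass table", {
  expect_error(protein_mw(""), "empty")
  expect_error(protein_mw("GXG"), "invalid residue")
  expect_equal(protein_mw("GG") * 1000, 132.12, tolerance = 1e-4)
  # permutation invariance
  expect_equal(protein_mw("MKTAYIAK"), protein_mw("KAIYATKM"))
})

test_that("isoelectric point matches an independent bisection oracle", {
  # oracle: direct midpoint of the two relevant pKa values for glycylglycine
  # (no ionizable side chains): pI = (pKa_Nterm + pKa_Cterm)/2
  expect_equal(protein_pi("GG"), (7.50 + 3.55) / 2, tolerance = 1e-3)
  expect_gt(protein_pi(strrep("K", 10)), protein_pi(strrep("D", 10)))
  # composition-only: permutation invariant up to the N-terminal residue
  expect_equal(protein_pi("KDYHKC"), protein_pi("KCHYDK"), tolerance = 1e-3)
  # uniroot on the same charge model as an independent numeric check
  counts <- table(factor(strsplit("MKDDEHRYC", "")[[1]]))
  charge <- function(ph) {
    pos <- sum(c(counts[["H"]] / (1 + 10^(ph - 5.98)),
                 counts[["K"]] / (1 + 10^(ph - 10)),
                 counts[["R"]] / (1 + 10^(ph - 12)))[c(TRUE, TRUE, TRUE)],
               1 / (1 + 10^(ph - 7.00))) # Met N-terminus
    neg <- sum(2 / (1 + 10^(4.05 - ph)), # D x2
               1 / (1 + 10^(4.45 - ph)), # E
               1 / (1 + 10^(9.00 - ph)), # C
               1 / (1 + 10^(10.0 - ph)), # Y
               1 / (1 + 10^(3.55 - ph))) # C-terminus
    pos - neg
  }
  oracle <- stats::uniroot(charge, c(0, 14), tol = 1e-8)$root
  expect_equal(protein_pi("MKDDEHRYC"), oracle, tolerance = 1e-3)
})

test_that("motif scanning reports all (overlapping) hits, 1-based", {
  expect_equal(scan_motif("NPAXXXNPA", "NPA"), c(1, 7))
  expect_equal(scan_motif("AAAA", "NPA"), integer(0))
  expect_equal(scan_motif("AAAA", "AA"), c(1, 2, 3))
  expect_error(scan_motif("AAAA", ""), "non-empty")
})

test_that("C-terminal motif extraction", {
  expect_equal(cterm_motif("SYDF"), "SYDF")
  expect_equal(cterm_motif("AAASYDF"), "SYDF")
  expect_error(cterm_motif("SY"), "shorter")
})

test_that("hydropathy profile equals the sliding-window oracle", {
  prof <- hydropathy_profile(strrep("A", 19), window = 19)
  expect_equal(nrow(prof$profile), 1)
  expect_equal(prof$profile$hydropathy, 1.8)
  expect_equal(prof$profile$center, 10)

  # alternating R/A: mean (-4.5 + 1.8)/2 = -1.35, never above 1.6
  alt <- paste(rep(c("R", "A"), 30), collapse = "")
  expect_equal(nrow(hydropathy_profile(alt)$segments), 0)

  # 25 I flanked by 20 D each side: one segment over the I-run centers
  s <- paste0(strrep("D", 20), strrep("I", 25), strrep("D", 20))
  res <- hydropathy_profile(s)
  expect_equal(nrow(res$segments), 1)
  # independent windowed-mean oracle
  vals <- c(I = 4.5, D = -3.5)[strsplit(s, "")[[1]]]
  win_mean <- vapply(10:(65 - 9), function(ct) mean(vals[(ct - 9):(ct + 9)]),
                     numeric(1))
  above <- (10:56)[win_mean > 1.6]
  expect_equal(res$segments$start, min(above))
  expect_equal(res$segments$end, max(above))

  expect_error(hydropathy_profile("AAAA", window = 2), "odd")
  expect_error(hydropathy_profile("AAA", window = 19), "longer")
})

test_that("segment merging bridges short sub-threshold gaps", {
  # window 3: two Asp residues between Ile runs give exactly 2 sub-threshold
  # centers, bridged when merge_gap >= 2
  s <- paste0(strrep("I", 10), "DD", strrep("I", 10))
  merged <- hydropathy_profile(s, window = 3, merge_gap = 3)
  split <- hydropathy_profile(s, window = 3, merge_gap = 0)
  expect_equal(nrow(merged$segments), 1)
  expect_gt(nrow(split$segments), 1)
})

test_that("global alignment identity matches examples and the DP oracle", {
  expect_equal(global_align("ACDE", "ACDE")$identity, 100)
  expect_equal(global_align("ACDE", "ACDD")$identity, 75)
  expect_equal(global_align("MKT", "MT")$identity,
               oracle_align_identities("MKT", "MT")[1], tolerance = 1e-9)
  # symmetry of identity
  set.seed(7)
  for (i in 1:5) {
    a <- paste(sample(c("A", "C", "D", "K", "M", "T"), 8, TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "D", "K", "M", "T"), 6, TRUE), collapse = "")
    expect_equal(global_align(a, b)$identity, global_align(b, a)$identity)
  }
  expect_error(global_align("", "A"), "empty")
})

test_that("brute-force alignment oracle validates tiny alignments", {
  for (pair in list(c("ACDE", "ACD"), c("MK", "MKT"), c("AC", "CA"))) {
    ids <- oracle_align_identities(pair[1], pair[2])
    got <- global_align(pair[1], pair[2])$identity
    expect_true(any(abs(ids - got) < 1e-9),
                label = paste("identity", got, "among optimal alignments of",
                              pair[1], pair[2]))
  }
})

test_that("selectivity-filter mapping follows the alignment", {
  m <- map_selectivity_filter("MKFV", "MKFV", template_positions = c(2, 4))
  expect_equal(m$query_pos, c(2, 4))
  expect_equal(m$query_residue, c("K", "V"))

  # one extra N-terminal residue on the template shifts everything by -1
  q <- "KFVDERHAY"
  t2 <- paste0("M", q)
  m <- map_selectivity_filter(q, t2, template_positions = c(3, 8))
  expect_equal(m$query_pos, c(2, 7))

  # deletion in the query yields an explicit gap, not an error
  m <- map_selectivity_filter("MKAAAAERH", "MKWDYAAAAERH",
                              template_positions = c(4))
  expect_equal(m$query_residue[1], "-")
  expect_true(is.na(m$query_pos[1]))

  expect_error(map_selectivity_filter("MK", "MK", template_positions = 5),
               "outside")
})

test_that("in-silico PCR honors degeneracy on the primer side only", {
  hits <- in_silico_pcr("AAACATCAGTTTGGGCCCAAA", "CAYCARTTTG", "TTTGGGCCCA")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$length_bp,
               oracle_pcr_lengths("AAACATCAGTTTGGGCCCAAA",
                                  "CAYCARTTTG", "TTTGGGCCCA"))
  # Y matches C/T but not A; template N matches nothing
  expect_equal(nrow(in_silico_pcr(paste0("G", "CATCATCATG", strrep("A", 20),
                                         "CCCCCCCCCC"),
                                  "CAYCAYCAYG", "GGGGGGGGGG")), 1)
  expect_equal(nrow(in_silico_pcr(paste0("G", "CAACATCATG", strrep("A", 20),
                                         "CCCCCCCCCC"),
                                  "CAYCAYCAYG", "GGGGGGGGGG")), 0)
  expect_equal(nrow(in_silico_pcr(paste0("G", "CANCATCATG", strrep("A", 20),
                                         "CCCCCCCCCC"),
                                  "CAYCAYCAYG", "GGGGGGGGGG")), 0)
  expect_error(in_silico_pcr("ACGT", "CAY", "GGG"), "at least 10")
})

test_that("in-silico PCR agrees with the degeneracy-expansion oracle", {
  set.seed(91)
  for (i in 1:25) {
    template <- random_dna(200)
    f_start <- sample(1:60, 1)
    p_len <- sample(c(250, 431, 120, 90), 1)
    p_len <- min(p_len, 200 - f_start + 1)
    r_end <- f_start + p_len - 1
    fwd <- substr(template, f_start, f_start + 11)
    rev_site <- substr(template, r_end - 11, r_end)
    rev <- revcomp_chr(rev_site)
    # degenerate-ize two fwd positions with codes containing the true base
    fc <- strsplit(fwd, "")[[1]]
    fc[3] <- c(A = "R", C = "Y", G = "R", T = "Y")[fc[3]]
    fc[7] <- c(A = "W", C = "S", G = "S", T = "W")[fc[7]]
    fwd <- paste(fc, collapse = "")
    got <- in_silico_pcr(template, fwd, rev)
    expect_equal(got$length_bp, oracle_pcr_lengths(template, fwd, rev))
    expect_true(p_len %in% got$length_bp)
  }
})

test_that("variant length difference is symmetric and absolute", {
  expect_equal(variant_length_diff("AAAA", "AAAA"), 0)
  expect_equal(variant_length_diff(strrep("A", 10), strrep("C", 17)), 7)
  expect_equal(variant_length_diff(strrep("C", 17), strrep("A", 10)), 7)
})

test_that("FASTA round-trips through 60-column records", {
  seqs <- c(v1 = random_dna(150), v2 = random_dna(101))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(back, seqs)
  expect_true(any(nchar(readLines(f)) <= 61))
})
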