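test_that("find_anchor reports both strands with 0-based positions", {
  # ACGT is its own reverse complement: one site, both strands
  hits <- find_anchor("AAACGTAA", "ACGT")
  expect_equal(hits$position, c(2L, 2L))
  expect_setequal(hits$strand, c("+", "-"))
  expect_equal(nrow(find_anchor("AAACGTAA", "GGGG")), 0L)
  expect_error(find_anchor("AAACGTAA", ""), class = "fibh_config_error")
  # mismatch tolerance
  hits <- find_anchor("AAACGTAA", "ACCT", max_mismatch = 1)
  expect_true(2L %in% hits$position[hits$strand == "+"])
})

test_that("qc_flags detect homopolymer runs and foreign symbols", {
  expect_equal(qc_flags(strrep("ACGT", 100)), character(0))
  expect_equal(qc_flags(paste0("ACGT", strrep("N", 12), "ACGT")), "POLY_N")
  expect_equal(qc_flags(paste0("ACGT", strrep("G", 25), "ACGT")), "POLY_G")
  expect_equal(qc_flags(paste0("ACGT", strrep("N", 9), "ACGT")), character(0))
  expect_true("NON_ACGTN" %in% qc_flags("ACGTRACGT"))
})

test_that("extraction round-trips the generator truth on both strands", {
  co <- small_cohort()
  ex <- extract_cohort(co$sequences, flank_len = co$spec$flank_len)
  expect_equal(length(ex$loci), nrow(co$truth))
  strands_seen <- character(0)
  for (id in names(ex$loci)) {
    l <- ex$loci[[id]]
    tr <- co$truth[co$truth$strain_id == id, ]
    expect_identical(l$gene_seq, co$genes[[id]])
    expect_equal(l$gene_start, tr$start)
    expect_equal(l$gene_end, tr$end)
    expect_equal(l$strand, tr$strand)
    expect_equal(nchar(l$upstream_seq), co$spec$flank_len)
    expect_equal(nchar(l$downstream_seq), co$spec$flank_len)
    strands_seen <- c(strands_seen, l$strand)
  }
  expect_setequal(unique(strands_seen), c("+", "-")) # both orientations exercised
})

test_that("strand invariance: reverse-complementing the chromosome mirrors coordinates", {
  co <- small_cohort()
  id <- co$truth$strain_id[1]
  chrom <- co$sequences[[co$truth$chrom[1]]]
  l1 <- extract_locus(chrom, flank_len = 1000)
  l2 <- extract_locus(dna_revcomp(chrom), flank_len = 1000)
  expect_identical(l1$gene_seq, l2$gene_seq)
  expect_false(l1$strand == l2$strand)
  n <- nchar(chrom)
  expect_equal(l2$gene_start, n - l1$gene_end)
  expect_equal(l2$gene_end, n - l1$gene_start)
})

test_that("missing and ambiguous anchors raise structured errors", {
  refs <- fibh_refs()
  bg <- strrep("ACGTTGCAACGGATTA", 200)
  expect_error(extract_locus(bg), class = "fibh_not_found")
  gene <- paste0(refs$start_barcode, strrep("GGTTCA", 300), refs$end_barcode)
  two_copies <- paste0(bg, gene, bg, gene, bg)
  expect_error(extract_locus(two_copies), class = "fibh_ambiguous")
  # anchors on opposite strands only -> ambiguous, not guessed
  opp <- paste0(bg, gene, bg, dna_revcomp(gene), bg)
  expect_error(extract_locus(opp), class = "fibh_ambiguous")
})

test_that("flanks are clamped at chromosome edges with truncation flags", {
  refs <- fibh_refs()
  gene <- paste0(refs$start_barcode, strrep("GGTTCA", 300), refs$end_barcode)
  chrom <- paste0(strrep("ATTGCCAT", 250), gene, strrep("ATTGCCAT", 250)) # 2 kb each side
  l <- extract_locus(chrom, flank_len = 5000)
  expect_equal(nchar(l$upstream_seq), 2000L)
  expect_equal(nchar(l$downstream_seq), 2000L)
  expect_true(all(c("FLANK_TRUNCATED_UP", "FLANK_TRUNCATED_DOWN") %in% l$qc_flags))
  expect_true("LENGTH_OUT_OF_RANGE" %in% l$qc_flags) # 1.8 kb toy gene
})

test_that("polyN strains are counted and excluded exactly", {
  spec <- synth_cohort_spec(n_wild = 0, n_local = 4, n_improved = 0,
                            background_len = 45000, seed = 55,
                            polyn_strains = c("L2", "L4"))
  co <- make_cohort(spec)
  ex <- extract_cohort(co$sequences, flank_len = spec$flank_len)
  flagged <- names(ex$loci)[vapply(ex$loci, function(l)
    "POLY_N" %in% l$qc_flags, TRUE)]
  expect_setequal(flagged, c("L2", "L4"))
  expect_equal(length(ex$loci) - length(flagged), 2L)
})
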