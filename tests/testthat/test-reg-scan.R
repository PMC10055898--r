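test_that("the 3' UTR is the first 85 bp of the downstream flank", {
  refs <- fibh_refs()
  utr <- extract_utr3(refs$downstream)
  expect_equal(nchar(utr), 85L)
  expect_identical(utr, substr(refs$downstream, 1, 85))
  exact <- random_dna(85)
  expect_identical(extract_utr3(exact), exact)
  expect_error(extract_utr3(random_dna(84)), class = "fibh_truncated")
})

test_that("element scanning matches IUPAC patterns on both strands", {
  locus <- structure(list(
    strain_id = "s1", chrom_id = "c1", gene_start = 0L, gene_end = 10L,
    strand = "+", gene_seq = strrep("ACGT", 100),
    upstream_seq = paste0(strrep("TTTT", 20), "CAGCTG", strrep("TTTT", 20)),
    downstream_seq = strrep("TTAA", 40), qc_flags = character(0)
  ), class = "fibh_locus")
  defs <- data.frame(name = "E-box", pattern = "CANNTG", region = "UPSTREAM",
                     stringsAsFactors = FALSE)
  hits <- scan_elements(locus, defs)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$position, 80L)
  expect_equal(hits$match, "CAGCTG")
  # non-palindromic pattern found on the minus strand
  locus$upstream_seq <- paste0(strrep("CCCC", 10), dna_revcomp("TATAAAT"),
                               strrep("CCCC", 10))
  defs2 <- data.frame(name = "TATA-box", pattern = "TATAWAW", region = "UPSTREAM",
                      stringsAsFactors = FALSE)
  hits2 <- scan_elements(locus, defs2)
  expect_true(any(hits2$strand == "-"))
  expect_error(scan_elements(locus, defs[0, ]), class = "fibh_config_error")
})

test_that("planted intron FMBP sites are present in every cohort strain", {
  co <- small_cohort()
  ex <- extract_cohort(co$sequences, flank_len = co$spec$flank_len)
  defs <- default_elements()
  hits <- do.call(rbind, lapply(names(ex$loci), function(id)
    scan_elements(ex$loci[[id]], defs, annotate_gene(ex$loci[[id]]$gene_seq))))
  pres <- element_presence(hits, names(ex$loci), defs)
  expect_true(all(pres[, "FMBP-site"]))
  expect_true(all(pres[, "E-box"]))
  expect_true(all(pres[, "TATA-box"]))
  # hit count invariant under strain order
  hits_rev <- do.call(rbind, lapply(rev(names(ex$loci)), function(id)
    scan_elements(ex$loci[[id]], defs, annotate_gene(ex$loci[[id]]$gene_seq))))
  expect_equal(nrow(hits_rev), nrow(hits))
})

test_that("an element knocked out by mutation shows up as absent", {
  refs <- fibh_refs()
  locus <- structure(list(
    strain_id = "mut", chrom_id = "c", gene_start = 0L, gene_end = 10L,
    strand = "+", gene_seq = strrep("ACGT", 50),
    upstream_seq = strrep("ATTT", 50),  # no E-box, no TATA
    downstream_seq = strrep("ATTT", 50), qc_flags = character(0)
  ), class = "fibh_locus")
  defs <- default_elements()
  defs <- defs[defs$region != "INTRON", ]
  hits <- scan_elements(locus, defs)
  pres <- element_presence(hits, "mut", defs)
  expect_false(any(pres))
})

test_that("conservation reports count variant columns and class exclusivity", {
  same <- stats::setNames(rep(strrep("ACGTTGCA", 20), 4), paste0("s", 1:4))
  rep0 <- conservation_report(same)
  expect_equal(rep0$identity_percent, 100)
  expect_equal(rep0$n_variant_columns, 0L)
  # one substitution in one strain -> exactly one variant column
  mut <- same
  m <- strsplit(mut[[2]], "")[[1]]
  m[37] <- "C"
  mut[2] <- paste(m, collapse = "")
  rep1 <- conservation_report(mut)
  expect_equal(rep1$n_variant_columns, 1L)
  expect_equal(rep1$variant_columns, 36L)
  expect_error(conservation_report(same[1]), class = "fibh_config_error")
})

test_that("SNPs shared across classes are not called class-exclusive", {
  base <- strrep("ACGTTGCA", 30)
  snp_at <- function(s, i) {
    m <- strsplit(s, "")[[1]]; m[i] <- "T"; paste(m, collapse = "")
  }
  # the variant is carried by one wild and one local strain: crosses classes
  seqs <- c(W1 = snp_at(base, 50), W2 = base, L1 = snp_at(base, 50), L2 = base)
  classes <- c(W1 = "wild", W2 = "wild", L1 = "local", L2 = "local")
  rep_mixed <- conservation_report(seqs, classes)
  expect_false(rep_mixed$any_class_exclusive)
  # control: variant carried by exactly the wild strains is class-exclusive
  seqs2 <- c(W1 = snp_at(base, 50), W2 = snp_at(base, 50), L1 = base, L2 = base)
  rep_excl <- conservation_report(seqs2, classes)
  expect_true(rep_excl$any_class_exclusive)
})
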