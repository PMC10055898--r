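test_that("make_repeat_core fills the target, stays in frame and is seeded", {
  u <- "GGTGCTGGAGCTGGTTCA"
  rc <- make_repeat_core(18, unit_alphabet = c(u1 = u), seed = 1)
  expect_equal(as.character(rc), u)
  expect_error(make_repeat_core(100, unit_alphabet = character(0)),
               class = "fibh_config_error")
  a <- make_repeat_core(5000, seed = 42)
  b <- make_repeat_core(5000, seed = 42)
  expect_identical(as.character(a), as.character(b))
  expect_false(identical(as.character(a),
                         as.character(make_repeat_core(5000, seed = 43))))
  # length within one unit of the target
  expect_lt(abs(nchar(a) - 5000), max(nchar(fibh_refs()$units)) + 1)
  # in frame, no stop codon, GAGAGS-family peptides
  pep <- translate_cds(as.character(a))
  expect_equal(pep$diagnostics, character(0))
  expect_false(grepl("*", pep$peptide, fixed = TRUE))
  expect_true(grepl("GAGAGS", pep$peptide))
})

test_that("repeat cores are GC-rich and linkers carry exactly one NdeI site each", {
  for (seed in 1:5) {
    rc <- make_repeat_core(12000, seed = seed)
    expect_gte(gc_content(as.character(rc)), 0.55)
    expect_lte(gc_content(as.character(rc)), 0.62)
    expect_equal(length(scan_ndei(as.character(rc))), attr(rc, "n_linkers"))
  }
  # one linker per ~1.5 kb
  rc <- make_repeat_core(15000, seed = 9)
  expect_gt(attr(rc, "n_linkers"), 5)
  expect_lt(attr(rc, "n_linkers"), 15)
})

test_that("the reference gene reconstructs the canonical component lengths", {
  g <- make_fibh_locus(reference = TRUE)
  expect_equal(nchar(g$gene_seq), 16788L)
  expect_equal(g$exon1[2] - g$exon1[1], 67L)
  expect_equal(g$intron[2] - g$intron[1], 971L)
  expect_equal(g$exon2[2] - g$exon2[1], 15750L)
})

test_that("gene drawing respects class labels, boundaries nest, CDS is clean", {
  spec <- synth_cohort_spec(seed = 2)
  expect_error(make_fibh_locus(spec, "feral", seed = 1),
               class = "fibh_config_error")
  g <- make_fibh_locus(spec, "local", seed = 10)
  # tiling: exon1 + intron + exon2 and tnr5 + rc + tnr3
  expect_equal(g$exon1[2], g$intron[1])
  expect_equal(g$intron[2], g$exon2[1])
  expect_equal(g$exon2[2], nchar(g$gene_seq))
  expect_equal(g$tnr5[2], g$rc[1])
  expect_equal(g$rc[2], g$tnr3[1])
  expect_equal(g$tnr3[2], g$exon2[2])
  tnr5 <- substr(g$gene_seq, g$tnr5[1] + 1, g$tnr5[2])
  rc <- substr(g$gene_seq, g$rc[1] + 1, g$rc[2])
  tnr3 <- substr(g$gene_seq, g$tnr3[1] + 1, g$tnr3[2])
  exon2 <- substr(g$gene_seq, g$exon2[1] + 1, g$exon2[2])
  expect_identical(paste0(tnr5, rc, tnr3), exon2)
  refs <- fibh_refs()
  cds <- paste0(substr(g$gene_seq, refs$cds_offset + 1, 67), exon2)
  tr <- translate_cds(cds)
  expect_equal(tr$diagnostics, character(0))
})

test_that("class mean length is recovered within 3 SE over repeated draws", {
  spec <- synth_cohort_spec(seed = 3)
  lens <- vapply(1:100, function(i)
    nchar(make_fibh_locus(spec, "improved", seed = 20000 + i)$gene_seq), 1)
  se <- spec$length_sd_by_class[["improved"]] / sqrt(length(lens))
  expect_lt(abs(mean(lens) - 15795), 3 * se)
})

test_that("group variants insert/delete canonical blocks at unit boundaries", {
  g <- make_fibh_locus(synth_cohort_spec(seed = 4), "improved", seed = 50)
  v1 <- apply_group_variant(g, 1, seed = 1)
  expect_equal(v1$variant$seq, "GGTGCT")
  v2 <- apply_group_variant(g, 2, seed = 2)
  expect_equal(v2$variant$length, 18L)
  expect_equal(translate_cds(v2$variant$seq)$peptide, "GAGAGS")
  v3 <- apply_group_variant(g, 3, seed = 3)
  expect_equal(v3$variant$length, 18L)
  expect_equal(translate_cds(v3$variant$seq)$peptide, "GAGAGS")
  expect_equal(sum(strsplit(v2$variant$seq, "")[[1]] !=
                   strsplit(v3$variant$seq, "")[[1]]), 1L) # differ by one base
  v4 <- apply_group_variant(g, 4, seed = 4)
  expect_true(startsWith(v4$variant$seq, "GGTGCT"))
  expect_true(endsWith(v4$variant$seq, "TCA"))
  expect_gte(v4$variant$length, 54L)
  expect_lte(v4$variant$length, 4302L)
  expect_equal(v4$variant$length %% 3L, 0L)
  expect_error(apply_group_variant(g, 5, seed = 1), class = "fibh_config_error")
  # gene stays consistent after the edit
  gl <- v4$locus
  expect_equal(gl$tnr3[2], nchar(gl$gene_seq))
  expect_equal(nchar(gl$gene_seq), nchar(g$gene_seq) + v4$variant$length)
})

test_that("embedding places the locus verbatim (+) or reverse-complemented (-)", {
  locus <- strrep("ACGTTGCA", 50)
  emb <- embed_in_chromosome(locus, 2000, "+", seed = 5)
  expect_identical(substr(emb$chrom_seq, emb$locus_start + 1, emb$locus_end), locus)
  embm <- embed_in_chromosome(locus, 2000, "-", seed = 6)
  expect_identical(substr(embm$chrom_seq, embm$locus_start + 1, embm$locus_end),
                   dna_revcomp(locus))
  expect_error(embed_in_chromosome(locus, 100, "+", seed = 1),
               class = "fibh_config_error")
})

test_that("make_cohort conserves counts, is byte-deterministic and honours shared alleles", {
  spec <- synth_cohort_spec(n_wild = 2, n_local = 3, n_improved = 3,
                            background_len = 45000, seed = 77,
                            share_alleles = list(c("P1", "P3")))
  co1 <- make_cohort(spec)
  expect_equal(length(co1$sequences), 8L)
  expect_equal(nrow(co1$truth), 8L)
  expect_equal(unname(table(co1$truth$class)[c("improved", "local", "wild")]),
               c(3L, 3L, 2L), ignore_attr = TRUE)
  co2 <- make_cohort(spec)
  expect_identical(co1$sequences, co2$sequences)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$genes[["P1"]], co1$genes[["P3"]])
  expect_false(identical(co1$genes[["P1"]], co1$genes[["P2"]]))
})
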