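test_that("pairwise identity matches hand-checkable cases", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 75)
  expect_error(pairwise_identity("", "ACGT"), class = "fibh_config_error")
})

test_that("identity agrees with the brute-force DP oracle on random pairs", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    a <- random_dna(n)
    # mix of related and unrelated pairs
    b <- if (i %% 2 == 0) {
      m <- strsplit(a, "")[[1]]
      k <- sample(1:8, 1)
      pos <- sample(length(m), k)
      m[pos] <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
      paste(m, collapse = "")
    } else {
      random_dna(sample(20:200, 1))
    }
    expect_lt(abs(pairwise_identity(a, b) - oracle_identity(a, b)), 0.1,
              label = sprintf("pair %d", i))
  }
})

test_that("group identity handles trivial and divergence-ordered cohorts", {
  expect_equal(group_identity(c(a = "ACGTAC", b = "ACGTAC"))$identity_percent, 100)
  expect_equal(group_identity(c(a = "AC", b = "AG"))$identity_percent, 50)
  expect_error(group_identity(c(a = "ACGT")), class = "fibh_config_error")
  # n identical copies stay at 100 for any n >= 2
  for (n in c(3, 6)) {
    seqs <- stats::setNames(rep(strrep("GGTTCA", 30), n), paste0("s", 1:n))
    expect_equal(group_identity(seqs)$identity_percent, 100)
  }
  # identity decreases monotonically with injected divergence
  set.seed(21)
  backbone <- random_dna(600, gc = 0.6)
  diverge <- function(k) {
    m <- strsplit(backbone, "")[[1]]
    pos <- sample(length(m), k)
    m[pos] <- chartr("ACGT", "GTAC", m[pos])
    paste(m, collapse = "")
  }
  idents <- vapply(c(5, 30, 90), function(k)
    group_identity(c(a = backbone, b = diverge(k)))$identity_percent, 1)
  expect_true(all(diff(idents) < 0))
})

test_that("differential_sequence recovers single unit indels leftmost-canonically", {
  x <- strrep("GGAGCTTCAGCA", 20)
  y <- strrep("TCAGGAGGTACT", 20)
  a <- paste0(x, "GGTGCT", y)
  b <- paste0(x, y)
  d <- differential_sequence(b, a)
  expect_equal(nrow(d), 1L)
  expect_equal(d$kind, "insertion")
  expect_equal(d$seq, "GGTGCT")
  expect_equal(d$group, "1")
  expect_false(d$pair_complex)
  # polarity flip: same block, opposite kind
  d2 <- differential_sequence(a, b)
  expect_equal(d2$kind, "deletion")
  expect_identical(d2$seq, d$seq)
  expect_identical(d2$position, d$position)
  # equal inputs
  expect_equal(nrow(differential_sequence(a, a)), 0L)
})

test_that("injected group variants are recovered and classified exactly", {
  g <- make_fibh_locus(synth_cohort_spec(seed = 31), "improved", seed = 70)
  rc0 <- substr(g$gene_seq, g$rc[1] + 1, g$rc[2])
  expected_label <- c("1" = "1", "2" = "2/3", "3" = "2/3", "4" = "4")
  for (grp in c("1", "2", "3", "4")) {
    for (kind in c("insertion", "deletion")) {
      out <- apply_group_variant(g, grp, seed = 500 + as.integer(grp) * 7 +
                                   (kind == "deletion"), kind = kind)
      rc1 <- substr(out$locus$gene_seq, out$locus$rc[1] + 1, out$locus$rc[2])
      d <- differential_sequence(rc0, rc1)
      expect_equal(nrow(d), 1L, info = paste(grp, kind))
      expect_equal(d$kind, kind, info = paste(grp, kind))
      expect_equal(d$length, out$variant$length, info = paste(grp, kind))
      if (grp == "4") {
        # multi-unit blocks inside tandem runs are recovered up to rotation
        expect_true(grepl(d$seq, strrep(out$variant$seq, 2), fixed = TRUE),
                    info = paste(grp, kind))
      } else {
        expect_identical(d$seq, out$variant$seq, info = paste(grp, kind))
      }
      expect_equal(d$group, unname(expected_label[grp]), info = paste(grp, kind))
    }
  }
})

test_that("unit insertions at random split points are recovered up to the canonical shift", {
  set.seed(41)
  units <- fibh_refs()$units
  base <- as.character(make_repeat_core(2000, seed = 8))
  for (i in 1:12) {
    u <- sample(units, 1)
    at <- sample(0:nchar(base), 1)
    with_u <- paste0(substr(base, 1, at), u,
                     substr(base, at + 1, nchar(base)))
    d <- differential_sequence(base, with_u)
    expect_equal(nrow(d), 1L)
    expect_equal(d$length, unname(nchar(u)))
    # recovered block is a rotation of the inserted unit
    expect_true(grepl(d$seq, strrep(u, 2), fixed = TRUE))
  }
})

test_that("two separated insertions are reported as a complex pair", {
  x <- strrep("GGAGCTTCAGCA", 15)
  y <- strrep("TCAGGAGGTACT", 15)
  z <- strrep("GCTACTGGATCA", 15)
  a <- paste0(x, y, z)
  b <- paste0(x, "GGTGCT", y, "GGTGCTGGAGCTGGTTCA", z)
  d <- differential_sequence(a, b)
  expect_gte(nrow(d), 2L)
  expect_true(all(d$pair_complex))
  expect_setequal(d$seq, c("GGTGCT", "GGTGCTGGAGCTGGTTCA"))
})

test_that("classification is total, deterministic and matches the group envelopes", {
  expect_equal(classify_differential("GGTGCT"), "1")
  expect_equal(classify_differential("GGTGCTGGAGCTGGTTCA"), "2/3")
  block54 <- strrep("GGTGCTGGTGCTGGTTCA", 3)
  expect_equal(classify_differential(block54), "4")
  expect_equal(classify_differential(strrep("GGTGCTGGTGCTGGTTCA", 239)), "4")
  # boundary violations fall to OTHER
  expect_equal(classify_differential("GGTGCA"), "OTHER")
  expect_equal(classify_differential(strrep("A", 18)), "OTHER")
  expect_equal(classify_differential(paste0("GGTGCT", strrep("GCA", 15), "TAA")), "OTHER")
  expect_equal(classify_differential(strrep("GGTGCTGGTGCTGGTTCA", 240)), "OTHER") # > 4302
  set.seed(51)
  for (i in 1:20) {
    s <- random_dna(sample(c(6, 18, 54, 100), 1))
    expect_identical(classify_differential(s), classify_differential(s))
    expect_true(classify_differential(s) %in% c("1", "2/3", "4", "OTHER"))
  }
})

test_that("hexamer spectrum counts in-frame units and ranks GGTGCT", {
  hs <- hexamer_spectrum("GGTGCTGGTGCT")
  expect_equal(unname(hs$counts["GGTGCT"]), 2L)
  expect_equal(hs$ggtgct_rank, 1L)
  # trailing fragment shorter than 6 bp is ignored
  hs2 <- hexamer_spectrum("GGTGCTGGTGCTAAA")
  expect_equal(sum(hs2$counts), 2L)
  # generator cores have GGTGCT as the modal boundary hexamer
  rc <- as.character(make_repeat_core(6000, seed = 14))
  expect_equal(hexamer_spectrum(rc)$ggtgct_rank, 1L)
  expect_error(hexamer_spectrum("ACG"), class = "fibh_config_error")
})
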