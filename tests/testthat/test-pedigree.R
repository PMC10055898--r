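test_that("family partition groups identical alleles and isolates singletons", {
  part <- family_partition(c(s1 = "AC", s2 = "AC", s3 = "AG"))
  expect_equal(length(part$families), 1L)
  expect_equal(part$families[[1]]$member_ids, c("s1", "s2"))
  expect_equal(part$families[[1]]$family_id, "I")
  expect_equal(part$singletons, "s3")
  # all-distinct cohort: zero families, n singletons
  wild <- stats::setNames(c("AAC", "AAG", "AAT"), c("W1", "W2", "W3"))
  part2 <- family_partition(wild)
  expect_equal(length(part2$families), 0L)
  expect_equal(length(part2$singletons), 3L)
})

test_that("families are a partition, ordered by size then length, order-invariant", {
  alleles <- c(a1 = "AAAA", a2 = "AAAA", a3 = "AAAA",
               b1 = "CCCCCC", b2 = "CCCCCC",
               c1 = "GGGGGGGG", c2 = "GGGGGGGG",
               d1 = "TTT")
  part <- family_partition(alleles)
  members <- unlist(lapply(part$families, `[[`, "member_ids"))
  expect_equal(sort(c(members, part$singletons)), sort(names(alleles)))
  expect_equal(anyDuplicated(members), 0L)
  sizes <- vapply(part$families, function(f) length(f$member_ids), 1L)
  expect_equal(sizes, sort(sizes, decreasing = TRUE))
  # equal sizes tie-broken by allele length (descending)
  expect_equal(part$families[[2]]$allele_length, 8L)
  expect_equal(part$families[[3]]$allele_length, 6L)
  # permuting input changes nothing
  part_perm <- family_partition(alleles[sample(length(alleles))])
  expect_equal(lapply(part_perm$families, `[[`, "member_ids"),
               lapply(part$families, `[[`, "member_ids"))
  expect_equal(part_perm$singletons, part$singletons)
})

test_that("upgma reproduces closed-form and degenerate cases", {
  d <- matrix(c(0, 0.4, 0.4, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tr <- upgma(d)
  expect_s3_class(tr, "phylo")
  expect_equal(sort(tr$tip.label), c("a", "b"))
  expect_equal(unname(tr$edge.length), c(0.2, 0.2))
  # all-zero distances: star-like, all heights zero
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  trz <- upgma(z)
  expect_true(all(trz$edge.length == 0))
  # invalid input
  bad <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_error(upgma(bad), class = "fibh_config_error")
  expect_error(upgma(matrix(0, 1, 1)), class = "fibh_config_error")
})

test_that("upgma agrees with the hclust average-linkage reference on random matrices", {
  set.seed(61)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    # random symmetric matrix with distinct entries (no ties)
    v <- sample(seq(0.05, 1, by = 0.008), n * (n - 1) / 2)
    d <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
    d[lower.tri(d)] <- v
    d <- d + t(d)
    tr <- upgma(d)
    coph_mine <- ape::cophenetic.phylo(tr)[rownames(d), colnames(d)]
    coph_ref <- oracle_upgma_cophenetic(d)[rownames(d), colnames(d)]
    expect_equal(coph_mine, coph_ref, tolerance = 1e-7)
  }
})

test_that("upgma reconstructs the generating topology from ultrametric input", {
  set.seed(71)
  for (i in 1:6) {
    n <- sample(4:8, 1)
    hm <- random_ultrametric(n)
    tr <- upgma(hm)
    coph <- ape::cophenetic.phylo(tr)[rownames(hm), colnames(hm)]
    expect_equal(coph, hm, tolerance = 1e-9)
  }
})

test_that("upgma output is invariant to taxon input order", {
  set.seed(81)
  n <- 6
  v <- sample(seq(0.05, 1, by = 0.01), n * (n - 1) / 2)
  d <- matrix(0, n, n, dimnames = list(paste0("t", 1:n), paste0("t", 1:n)))
  d[lower.tri(d)] <- v
  d <- d + t(d)
  perm <- sample(n)
  t1 <- upgma(d)
  t2 <- upgma(d[perm, perm])
  expect_equal(ape::cophenetic.phylo(t1)[rownames(d), rownames(d)],
               ape::cophenetic.phylo(t2)[rownames(d), rownames(d)],
               tolerance = 1e-12)
})

test_that("modal-allele summary computes carrier percentages", {
  strains <- c(stats::setNames(rep(strrep("A", 100), 3), c("p1", "p2", "p3")),
               c(q1 = strrep("C", 90)))
  part <- family_partition(strains)
  s <- opti_allele_summary(part, total_known = 4)
  expect_equal(s$carriers, 3L)
  expect_equal(s$percent, 75)
  expect_equal(s$allele_length, 100L)
  # boundary cases
  expect_equal(opti_allele_summary(list(families = list()), 10)$percent, 0)
  one <- family_partition(c(a = "AA", b = "AA"))
  expect_equal(opti_allele_summary(one, 2)$percent, 100)
  expect_error(opti_allele_summary(one, 1), class = "fibh_config_error")
})

test_that("newick export round-trips through ape", {
  d <- matrix(c(0, .2, .6, .2, 0, .6, .6, .6, 0), 3, 3,
              dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  tr <- upgma(d)
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  expect_equal(sort(back$tip.label), c("x", "y", "z"))
  expect_equal(sum(back$edge.length), sum(tr$edge.length), tolerance = 1e-9)
})
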