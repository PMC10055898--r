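# Shared fixtures and independent oracles for the test suite.

fixture_env <- new.env(parent = emptyenv())

# small cohort reused across test files (built once)
small_cohort <- function() {
  if (is.null(fixture_env$cohort)) {
    spec <- synth_cohort_spec(n_wild = 2L, n_local = 3L, n_improved = 3L,
                              background_len = 45000L, seed = 101L)
    fixture_env$cohort <- make_cohort(spec)
  }
  fixture_env$cohort
}

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# ---- brute-force affine-gap global alignment oracle (R, small inputs) ------
# Independent of the package's C++ path: full score matrices, traceback in R.
oracle_identity <- function(a, b, match = 5, mismatch = -4,
                            gap_open = -10, gap_ext = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e15
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1) # gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1) # gap in a (consume b)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- gap_open + gap_ext * (i - 2)
  for (j in 2:(m + 1)) Y[1, j] <- gap_open + gap_ext * (j - 2)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + gap_open, Y[i - 1, j] + gap_open,
                     X[i - 1, j] + gap_ext)
      Y[i, j] <- max(M[i, j - 1] + gap_open, X[i, j - 1] + gap_open,
                     Y[i, j - 1] + gap_ext)
    }
  }
  # traceback (prefer M, then X, then Y on ties)
  i <- n + 1; j <- m + 1
  vals <- c(M[i, j], X[i, j], Y[i, j])
  state <- which.max(vals)
  matches <- 0; cols <- 0
  eps <- 1e-9
  while (i > 1 || j > 1) {
    if (i == 1) { j <- j - 1; cols <- cols + 1; next }
    if (j == 1) { i <- i - 1; cols <- cols + 1; next }
    if (state == 1) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      if (A[i - 1] == B[j - 1]) matches <- matches + 1
      cols <- cols + 1
      target <- M[i, j] - s
      i <- i - 1; j <- j - 1
      state <- which(abs(c(M[i, j], X[i, j], Y[i, j]) - target) < eps)[1]
    } else if (state == 2) {
      cols <- cols + 1
      target <- X[i, j]
      i <- i - 1
      cands <- c(M[i, j] + gap_open, X[i, j] + gap_ext, Y[i, j] + gap_open)
      state <- c(1L, 2L, 3L)[which(abs(cands - target) < eps)[1]]
    } else {
      cols <- cols + 1
      target <- Y[i, j]
      j <- j - 1
      cands <- c(M[i, j] + gap_open, X[i, j] + gap_open, Y[i, j] + gap_ext)
      state <- c(1L, 2L, 3L)[which(abs(cands - target) < eps)[1]]
    }
  }
  100 * matches / cols
}

# oracle score only (no traceback ambiguity): the optimal global score
oracle_score <- function(a, b, match = 5, mismatch = -4,
                         gap_open = -10, gap_ext = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e15
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- gap_open + gap_ext * (i - 2)
  for (j in 2:(m + 1)) Y[1, j] <- gap_open + gap_ext * (j - 2)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + gap_open, Y[i - 1, j] + gap_open,
                     X[i - 1, j] + gap_ext)
      Y[i, j] <- max(M[i, j - 1] + gap_open, X[i, j - 1] + gap_open,
                     Y[i, j - 1] + gap_ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# reference UPGMA via stats::hclust average linkage (cophenetic comparison)
oracle_upgma_cophenetic <- function(d) {
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  as.matrix(stats::cophenetic(hc))
}

# random ultrametric distance matrix from a random rooted tree
random_ultrametric <- function(n) {
  heights <- sort(runif(n - 1, 0.1, 1))
  # sequential random joins with increasing heights
  groups <- as.list(paste0("t", seq_len(n)))
  hmat <- matrix(0, n, n, dimnames = list(paste0("t", seq_len(n)),
                                          paste0("t", seq_len(n))))
  for (h in heights) {
    i <- sample(length(groups), 1)
    cand <- setdiff(seq_along(groups), i)
    j <- if (length(cand) == 1) cand else sample(cand, 1)
    for (x in groups[[i]]) for (y in groups[[j]]) {
      hmat[x, y] <- hmat[y, x] <- 2 * h
    }
    groups[[i]] <- c(groups[[i]], groups[[j]])
    groups <- groups[-j]
  }
  hmat
}
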