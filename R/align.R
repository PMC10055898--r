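# Pairwise alignment and percent identity.
#
# Global affine-gap alignment runs in C++ (linear memory for statistics, one
# byte per cell for traceback). Long repeat cores are handled by the anchored
# scheme: common prefix/suffix trimming, then chaining of rare shared k-mers
# (longest increasing subsequence), with dynamic programming only on the
# segments between chained anchors.

ALIGN_DEFAULTS <- list(match = 5, mismatch = -4, gap_open = -10, gap_ext = -1)

align_stats <- function(a, b, params = ALIGN_DEFAULTS) {
  .align_stats_cpp(a, b, params$match, params$mismatch,
                   params$gap_open, params$gap_ext)
}

align_traceback <- function(a, b, params = ALIGN_DEFAULTS,
                            free_a_ends = FALSE, free_b_ends = FALSE,
                            max_cells = 8e8) {
  .align_tb_cpp(a, b, params$match, params$mismatch,
                params$gap_open, params$gap_ext,
                free_a_ends, free_b_ends, max_cells)
}

kmer_positions <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(list())
  pos <- seq_len(n - k + 1L)
  split(pos, substring(x, pos, pos + k - 1L))
}

# Chain shared rare k-mers between a and b into co-linear exact anchors.
# Returns a data.frame (a_start, b_start, len), 1-based, strictly increasing
# and non-overlapping in both sequences; zero rows when nothing chains.
chain_anchors <- function(a, b, k = 24L, max_occ = 12L, max_pairs = 200000L) {
  ta <- kmer_positions(a, k)
  tb <- kmer_positions(b, k)
  shared <- intersect(names(ta), names(tb))
  if (length(shared) == 0L) return(NULL)
  occ <- lengths(ta)[shared] * lengths(tb)[shared]
  shared <- shared[lengths(ta)[shared] <= max_occ & lengths(tb)[shared] <= max_occ]
  if (length(shared) == 0L) return(NULL)
  pa <- integer(0); pb <- integer(0)
  total <- 0L
  for (km in shared) {
    xs <- ta[[km]]; ys <- tb[[km]]
    np <- length(xs) * length(ys)
    if (total + np > max_pairs) break
    total <- total + np
    pa <- c(pa, rep(xs, each = length(ys)))
    pb <- c(pb, rep(ys, times = length(xs)))
  }
  if (length(pa) == 0L) return(NULL)
  ord <- order(pa, pb)
  pa <- pa[ord]; pb <- pb[ord]
  # longest strictly-increasing subsequence in pb (pa already sorted; ties in
  # pa must not both be kept, strict inequality handles that)
  n <- length(pb)
  tails <- integer(0)       # pb value ending the best chain of each length
  tails_idx <- integer(0)
  parent <- integer(n)
  lisln <- integer(n)
  for (i in seq_len(n)) {
    pos <- findInterval(pb[i] - 1L, tails) # chains we can extend
    if (pos < length(tails)) {
      tails[pos + 1L] <- pb[i]
      tails_idx[pos + 1L] <- i
    } else {
      tails <- c(tails, pb[i])
      tails_idx <- c(tails_idx, i)
    }
    lisln[i] <- pos + 1L
    parent[i] <- if (pos > 0L) tails_idx[pos] else 0L
  }
  # reconstruct
  best_len <- length(tails)
  idx <- tails_idx[best_len]
  chain <- integer(best_len)
  for (j in rev(seq_len(best_len))) {
    chain[j] <- idx
    idx <- parent[idx]
  }
  ca <- pa[chain]; cb <- pb[chain]
  # enforce strict co-linearity in a as well
  keep <- c(TRUE, diff(ca) > 0L)
  ca <- ca[keep]; cb <- cb[keep]
  # merge diagonal-contiguous anchors, trim overlaps between neighbours
  seg_a <- integer(0); seg_b <- integer(0); seg_l <- integer(0)
  cur_a <- ca[1L]; cur_b <- cb[1L]; cur_l <- k
  if (length(ca) > 1L) {
    for (i in 2L:length(ca)) {
      if (ca[i] - cb[i] == cur_a - cur_b && ca[i] <= cur_a + cur_l) {
        cur_l <- ca[i] + k - cur_a
      } else {
        seg_a <- c(seg_a, cur_a); seg_b <- c(seg_b, cur_b); seg_l <- c(seg_l, cur_l)
        cur_a <- ca[i]; cur_b <- cb[i]; cur_l <- k
      }
    }
  }
  seg_a <- c(seg_a, cur_a); seg_b <- c(seg_b, cur_b); seg_l <- c(seg_l, cur_l)
  # trim anchor overlaps (in either sequence) against the previous segment
  if (length(seg_a) > 1L) {
    for (i in 2L:length(seg_a)) {
      prev_end_a <- seg_a[i - 1L] + seg_l[i - 1L]
      prev_end_b <- seg_b[i - 1L] + seg_l[i - 1L]
      cut <- max(prev_end_a - seg_a[i], prev_end_b - seg_b[i], 0L)
      seg_a[i] <- seg_a[i] + cut
      seg_b[i] <- seg_b[i] + cut
      seg_l[i] <- seg_l[i] - cut
    }
    ok <- seg_l > 0L
    seg_a <- seg_a[ok]; seg_b <- seg_b[ok]; seg_l <- seg_l[ok]
  }
  if (length(seg_a) == 0L) return(NULL)
  data.frame(a_start = seg_a, b_start = seg_b, len = seg_l)
}

# single most central shared anchor (0-based positions), or NULL
find_shared_anchor <- function(a, b, k = 24L) {
  anc <- chain_anchors(a, b, k, max_occ = 16L)
  if (is.null(anc)) return(NULL)
  centre <- abs((anc$a_start + anc$len / 2) / nchar(a) - 0.5)
  i <- which.min(centre)
  c(anc$a_start[i] - 1L, anc$b_start[i] - 1L)
}

# stats (matches, columns) for one inter-anchor segment
segment_stats <- function(a, b, params, cap_cells, k, depth) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L && nb == 0L) return(c(0, 0))
  if (na == 0L || nb == 0L) return(c(0, max(na, nb)))
  if (as.double(na) * nb <= cap_cells || depth >= 12L) {
    st <- align_stats(a, b, params)
    return(c(st$matches, st$columns))
  }
  anchored_stats(a, b, params, cap_cells, k = max(12L, k %/% 2L), depth = depth + 1L)
}

# anchored (matches, columns) via one chaining pass + per-segment DP
anchored_stats <- function(a, b, params = ALIGN_DEFAULTS, cap_cells = 2.5e7,
                           k = 24L, depth = 0L) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L || nb == 0L) return(c(0, max(na, nb)))
  lcp <- lcp_len(a, b)
  lcs <- min(lcs_len(a, b), min(na, nb) - lcp)
  ma <- substr(a, lcp + 1L, na - lcs)
  mb <- substr(b, lcp + 1L, nb - lcs)
  base <- c(lcp + lcs, lcp + lcs)
  if (nchar(ma) == 0L || nchar(mb) == 0L) {
    return(base + c(0, max(nchar(ma), nchar(mb))))
  }
  if (as.double(nchar(ma)) * nchar(mb) <= cap_cells) {
    st <- align_stats(ma, mb, params)
    return(base + c(st$matches, st$columns))
  }
  anc <- chain_anchors(ma, mb, k)
  if (is.null(anc)) {
    if (depth >= 12L) {
      # no shared structure at all: score as full-length mismatch/gap block
      return(base + c(0, max(nchar(ma), nchar(mb))))
    }
    ha <- nchar(ma) %/% 2L; hb <- nchar(mb) %/% 2L
    left <- segment_stats(substr(ma, 1L, ha), substr(mb, 1L, hb),
                          params, cap_cells, k, depth + 1L)
    right <- segment_stats(substr(ma, ha + 1L, nchar(ma)),
                           substr(mb, hb + 1L, nchar(mb)),
                           params, cap_cells, k, depth + 1L)
    return(base + left + right)
  }
  tot <- c(sum(anc$len), sum(anc$len)) # anchors are exact matches
  prev_a <- 1L; prev_b <- 1L
  for (i in seq_len(nrow(anc))) {
    ga <- substr(ma, prev_a, anc$a_start[i] - 1L)
    gb <- substr(mb, prev_b, anc$b_start[i] - 1L)
    tot <- tot + segment_stats(ga, gb, params, cap_cells, k, depth + 1L)
    prev_a <- anc$a_start[i] + anc$len[i]
    prev_b <- anc$b_start[i] + anc$len[i]
  }
  tot <- tot + segment_stats(substr(ma, prev_a, nchar(ma)),
                             substr(mb, prev_b, nchar(mb)),
                             params, cap_cells, k, depth + 1L)
  base + tot
}

#' Percent identity of two sequences under global alignment
#'
#' Global affine-gap alignment; identity is the fraction of alignment columns
#' with identical symbols, in percent. Pairs whose dynamic-programming matrix
#' would exceed `cap_cells` cells are aligned with the anchored scheme
#' (common-prefix/suffix trimming plus rare shared-k-mer chaining, DP between
#' anchors), which is exact on the segments it solves directly.
#'
#' @param a,b DNA strings.
#' @param cap_cells largest DP matrix solved directly.
#' @return identity percentage in \[0, 100\].
#' @export
pairwise_identity <- function(a, b, cap_cells = 2.5e7) {
  if (!is.character(a) || !is.character(b) || nchar(a) == 0L || nchar(b) == 0L) {
    stop_fibh("fibh_config_error", "pairwise_identity requires non-empty sequences")
  }
  if (a == b) return(100)
  st <- anchored_stats(a, b, ALIGN_DEFAULTS, cap_cells)
  100 * st[1] / st[2]
}

#' Pairwise identity matrix
#'
#' @param seqs named character vector of sequences.
#' @param cap_cells passed to [pairwise_identity()].
#' @return symmetric matrix of identity percentages (100 on the diagonal).
#' @export
identity_matrix <- function(seqs, cap_cells = 2.5e7) {
  n <- length(seqs)
  ids <- names(seqs) %||% as.character(seq_len(n))
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      v <- pairwise_identity(seqs[[i]], seqs[[j]], cap_cells)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  m
}

# ---- anchored traceback (gapped strings), used by the progressive MSA -----

tb_segment <- function(a, b, params, cap_cells, k, depth) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L && nb == 0L) return(list(a = "", b = ""))
  if (na == 0L) return(list(a = strrep("-", nb), b = b))
  if (nb == 0L) return(list(a = a, b = strrep("-", na)))
  if (as.double(na + 1) * (nb + 1) <= cap_cells || depth >= 12L) {
    tb <- align_traceback(a, b, params, max_cells = cap_cells * 4)
    return(list(a = tb$aligned_a, b = tb$aligned_b))
  }
  anchored_traceback(a, b, params, cap_cells, k = max(12L, k %/% 2L),
                     depth = depth + 1L)
}

anchored_traceback <- function(a, b, params = ALIGN_DEFAULTS, cap_cells = 6.4e7,
                               k = 24L, depth = 0L) {
  na <- nchar(a); nb <- nchar(b)
  lcp <- lcp_len(a, b)
  lcs <- min(lcs_len(a, b), min(na, nb) - lcp)
  ma <- substr(a, lcp + 1L, na - lcs)
  mb <- substr(b, lcp + 1L, nb - lcs)
  pre <- substr(a, 1L, lcp)
  suf <- substr(a, na - lcs + 1L, na)
  mid <- if (nchar(ma) == 0L && nchar(mb) == 0L) {
    list(a = "", b = "")
  } else if (nchar(ma) == 0L) {
    list(a = strrep("-", nchar(mb)), b = mb)
  } else if (nchar(mb) == 0L) {
    list(a = ma, b = strrep("-", nchar(ma)))
  } else if (as.double(nchar(ma) + 1) * (nchar(mb) + 1) <= cap_cells) {
    tb <- align_traceback(ma, mb, params, max_cells = cap_cells * 4)
    list(a = tb$aligned_a, b = tb$aligned_b)
  } else {
    anc <- chain_anchors(ma, mb, k)
    if (is.null(anc)) {
      if (depth >= 12L) {
        list(a = paste0(ma, strrep("-", nchar(mb))),
             b = paste0(strrep("-", nchar(ma)), mb))
      } else {
        ha <- nchar(ma) %/% 2L; hb <- nchar(mb) %/% 2L
        left <- tb_segment(substr(ma, 1L, ha), substr(mb, 1L, hb),
                           params, cap_cells, k, depth + 1L)
        right <- tb_segment(substr(ma, ha + 1L, nchar(ma)),
                            substr(mb, hb + 1L, nchar(mb)),
                            params, cap_cells, k, depth + 1L)
        list(a = paste0(left$a, right$a), b = paste0(left$b, right$b))
      }
    } else {
      pa <- character(0); pb <- character(0)
      prev_a <- 1L; prev_b <- 1L
      for (i in seq_len(nrow(anc))) {
        seg <- tb_segment(substr(ma, prev_a, anc$a_start[i] - 1L),
                          substr(mb, prev_b, anc$b_start[i] - 1L),
                          params, cap_cells, k, depth + 1L)
        anchor_str <- substr(ma, anc$a_start[i], anc$a_start[i] + anc$len[i] - 1L)
        pa <- c(pa, seg$a, anchor_str)
        pb <- c(pb, seg$b, anchor_str)
        prev_a <- anc$a_start[i] + anc$len[i]
        prev_b <- anc$b_start[i] + anc$len[i]
      }
      seg <- tb_segment(substr(ma, prev_a, nchar(ma)),
                        substr(mb, prev_b, nchar(mb)),
                        params, cap_cells, k, depth + 1L)
      list(a = paste0(paste(pa, collapse = ""), seg$a),
           b = paste0(paste(pb, collapse = ""), seg$b))
    }
  }
  list(aligned_a = paste0(pre, mid$a, suf),
       aligned_b = paste0(pre, mid$b, suf))
}
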