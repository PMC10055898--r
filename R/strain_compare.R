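# Differential sequences between repetitive cores, and their classification
# around the GGTGCT core unit.
#
# Two cores that differ by a single whole-repeat event reduce, after
# common-prefix/suffix trimming, to one inserted or deleted block. Indels
# inside tandem runs are placed leftmost (as in VCF left-alignment). Pairs
# that do not reduce to a single block are split recursively at shared
# k-mer anchors and reported as complex (two or more differential sequences).

diff_block_row <- function(kind, position, seq, pair_complex = FALSE) {
  pep <- NA_character_
  if (nchar(seq) %% 3L == 0L && nchar(seq) >= 3L) {
    pep <- translate_cds(seq)$peptide
  }
  data.frame(
    kind = kind, position = position, length = nchar(seq), seq = seq,
    peptide = pep, group = classify_differential(seq),
    pair_complex = pair_complex, stringsAsFactors = FALSE
  )
}

diff_rec <- function(a, b, offset_a, offset_b, depth = 0L) {
  if (a == b) return(NULL)
  na <- nchar(a); nb <- nchar(b)
  lcp <- lcp_len(a, b)
  lcs <- min(lcs_len(a, b), min(na, nb) - lcp)
  ma <- substr(a, lcp + 1L, na - lcs)
  mb <- substr(b, lcp + 1L, nb - lcs)
  if (nchar(ma) == 0L || nchar(mb) == 0L) {
    # single block. Placement within a tandem run is ambiguous; canonical
    # choice is the leftmost placement whose block is unit-anchored (starts
    # GGTGCT and ends TCA, like the repeat units the groups are defined on),
    # then the leftmost starting GGTGCT, then the leftmost overall.
    if (nchar(ma) == 0L) { # insertion a -> b
      long <- b; n_short <- na; off <- offset_b
      kind <- "insertion"
    } else {
      long <- a; n_short <- nb; off <- offset_a
      kind <- "deletion"
    }
    L <- abs(na - nb)
    lcs_max <- lcs_len(a, b)
    p_left <- max(0L, n_short - lcs_max)
    p_right <- min(lcp_len(a, b), n_short)
    pos <- p_left
    best_rank <- 3L
    for (p in p_left:p_right) {
      anchored <- substr(long, p + 1L, p + 6L) == "GGTGCT"
      ends_tca <- substr(long, p + L - 2L, p + L) == "TCA"
      rank <- if (anchored && ends_tca) 0L else if (anchored) 1L else 2L
      if (rank < best_rank) { best_rank <- rank; pos <- p }
      if (best_rank == 0L) break
    }
    block <- substr(long, pos + 1L, pos + L)
    return(diff_block_row(kind, off + pos, block))
  }
  # complex: split at a shared anchor
  if (depth < 30L) {
    anc <- find_shared_anchor(ma, mb, 18L)
    if (is.null(anc)) anc <- find_shared_anchor(ma, mb, 9L)
    if (!is.null(anc) && (anc[1] > 0L || anc[2] > 0L) &&
        (anc[1] < nchar(ma) || anc[2] < nchar(mb))) {
      left <- diff_rec(substr(ma, 1L, anc[1]), substr(mb, 1L, anc[2]),
                       offset_a + lcp, offset_b + lcp, depth + 1L)
      right <- diff_rec(substr(ma, anc[1] + 1L, nchar(ma)),
                        substr(mb, anc[2] + 1L, nchar(mb)),
                        offset_a + lcp + anc[1], offset_b + lcp + anc[2],
                        depth + 1L)
      return(rbind(left, right))
    }
  }
  # irreducible middle: report as one deletion plus one insertion
  rbind(
    diff_block_row("deletion", offset_a + lcp, ma),
    diff_block_row("insertion", offset_b + lcp, mb)
  )
}

#' Differential sequences between two repetitive cores
#'
#' @param rc_a,rc_b gene-oriented core sequences (polarity a -> b: an
#'   "insertion" block is present in `rc_b` only).
#' @return data.frame with one row per differential block: `kind`
#'   (insertion/deletion), leftmost-canonical `position` (0-based offset in
#'   the sequence carrying the block), `length`, `seq`, `peptide` (if in
#'   frame), `group` (1, 2/3, 4 or OTHER) and `pair_complex` (TRUE on every
#'   row when the pair needs two or more blocks). Equal inputs give zero rows.
#' @export
differential_sequence <- function(rc_a, rc_b) {
  stopifnot(is.character(rc_a), is.character(rc_b))
  out <- diff_rec(rc_a, rc_b, 0L, 0L)
  if (is.null(out)) {
    return(data.frame(kind = character(0), position = integer(0),
                      length = integer(0), seq = character(0),
                      peptide = character(0), group = character(0),
                      pair_complex = logical(0), stringsAsFactors = FALSE))
  }
  out$pair_complex <- nrow(out) > 1L
  rownames(out) <- NULL
  out
}

#' Classify a differential block into the four canonical groups
#'
#' Group 1: exactly the hexanucleotide GGTGCT. Group 2/3: an 18-bp in-frame
#' block encoding the hexapeptide GAGAGS (the two published variants differ
#' by one base and are not distinguishable without their printed sequences,
#' so both carry the joint label "2/3"). Group 4: a 54-4302 bp in-frame
#' block starting GGTGCT, ending TCA, with a stop-free translation.
#' Anything else is OTHER.
#'
#' @param seq the block sequence (or a one-row data.frame with a `seq`
#'   column, as returned by [differential_sequence()]).
#' @return one of "1", "2/3", "4", "OTHER".
#' @export
classify_differential <- function(seq) {
  if (is.data.frame(seq)) seq <- seq$seq
  stopifnot(is.character(seq), length(seq) == 1L)
  if (seq == "GGTGCT") return("1")
  n <- nchar(seq)
  if (n %% 3L == 0L && n >= 3L) {
    pep <- translate_cds(seq)$peptide
    if (n == 18L && pep == "GAGAGS") return("2/3")
    if (n >= 54L && n <= 4302L && startsWith(seq, "GGTGCT") &&
        endsWith(seq, "TCA") && !grepl("*", pep, fixed = TRUE)) {
      return("4")
    }
  }
  "OTHER"
}

#' In-frame hexamer spectrum of a repetitive core
#'
#' Counts the hexanucleotides found at in-frame 6-bp steps through the core
#' (a trailing fragment shorter than 6 bp is ignored) and reports the rank of
#' the GGTGCT core unit.
#'
#' @param rc core DNA string of length >= 6.
#' @return list with `counts` (named integer vector, decreasing) and
#'   `ggtgct_rank` (NA if absent).
#' @export
hexamer_spectrum <- function(rc) {
  if (nchar(rc) < 6L) {
    stop_fibh("fibh_config_error", "hexamer_spectrum requires >= 6 bp")
  }
  starts <- seq.int(1L, nchar(rc) - 5L, by = 6L)
  hex <- substring(rc, starts, starts + 5L)
  tab <- sort(table(hex), decreasing = TRUE)
  counts <- stats::setNames(as.integer(tab), names(tab))
  rank <- match("GGTGCT", names(counts))
  list(counts = counts, ggtgct_rank = rank)
}
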