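# Progressive multiple alignment with an average-linkage (UPGMA) guide tree.
#
# Profiles are merged by aligning their column consensus strings with the
# affine-gap aligner and propagating the new gap columns into each profile.
# This consensus-progressive scheme is deliberately simple and deterministic;
# it is accurate for the highly similar region cohorts it is applied to
# (terminal non-repetitive blocks, introns, flanks) and adequate as a
# cohort-level summary for diverged repeat cores.

msa_consensus <- function(mat) {
  if (nrow(mat) == 1L) return(mat[1L, ])
  symbols <- sort(setdiff(unique(as.vector(mat)), "-"))
  counts <- vapply(symbols, function(s) colSums(mat == s),
                   numeric(ncol(mat)))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  # per column: most frequent non-gap symbol, alphabetical on ties
  symbols[max.col(counts, ties.method = "first")]
}

aln_conserved_columns <- function(mat) {
  ref <- matrix(mat[1L, ], nrow(mat), ncol(mat), byrow = TRUE)
  colSums(mat == ref) == nrow(mat) & mat[1L, ] != "-"
}

expand_profile <- function(mat, gapped_cons) {
  keep <- seq_chars(gapped_cons) != "-"
  out <- matrix("-", nrow = nrow(mat), ncol = length(keep),
                dimnames = list(rownames(mat), NULL))
  out[, keep] <- mat
  out
}

#' Progressive multiple sequence alignment
#'
#' @param seqs named character vector (>= 1 sequence).
#' @param max_cells largest consensus-pair DP matrix allowed.
#' @return character matrix, one row per input sequence (original names,
#'   input order), gaps as "-".
#' @export
msa_align <- function(seqs, max_cells = 8e8) {
  n <- length(seqs)
  ids <- names(seqs) %||% as.character(seq_len(n))
  names(seqs) <- ids
  if (n == 1L) {
    return(matrix(seq_chars(seqs[[1L]]), nrow = 1L, dimnames = list(ids, NULL)))
  }
  if (length(unique(seqs)) == 1L) {
    m <- do.call(rbind, lapply(seqs, seq_chars))
    rownames(m) <- ids
    return(m)
  }
  d <- stats::as.dist(1 - identity_matrix(seqs) / 100)
  hc <- stats::hclust(d, method = "average")
  profiles <- lapply(seq_len(n), function(i)
    matrix(seq_chars(seqs[[i]]), nrow = 1L, dimnames = list(ids[i], NULL)))
  merged <- vector("list", n - 1L)
  for (s in seq_len(n - 1L)) {
    pick <- function(k) if (k < 0L) profiles[[-k]] else merged[[k]]
    A <- pick(hc$merge[s, 1L])
    B <- pick(hc$merge[s, 2L])
    ca <- paste(msa_consensus(A), collapse = "")
    cb <- paste(msa_consensus(B), collapse = "")
    tb <- anchored_traceback(ca, cb, cap_cells = min(max_cells, 6.4e7))
    A2 <- expand_profile(A, tb$aligned_a)
    B2 <- expand_profile(B, tb$aligned_b)
    merged[[s]] <- rbind(A2, B2)
  }
  out <- merged[[n - 1L]]
  out[ids, , drop = FALSE]
}

#' Group identity of a sequence cohort
#'
#' Aligns all sequences (progressive alignment, average-linkage guide tree)
#' and reports the percentage of alignment columns in which every sequence
#' carries the same non-gap symbol.
#'
#' @param seqs named character vector of >= 2 sequences.
#' @param scope optional label for the region (e.g. "TNR5", "RC").
#' @param cohort optional cohort label.
#' @param max_cells passed to [msa_align()].
#' @return list of class `identity_report`: `scope`, `cohort`,
#'   `identity_percent`, `n_sequences`, `alignment_length`.
#' @export
group_identity <- function(seqs, scope = NA_character_, cohort = NA_character_,
                           max_cells = 8e8) {
  if (length(seqs) < 2L) {
    stop_fibh("fibh_config_error", "group_identity requires >= 2 sequences")
  }
  aln <- msa_align(seqs, max_cells = max_cells)
  ncols <- ncol(aln)
  conserved <- sum(aln_conserved_columns(aln))
  structure(list(
    scope = scope, cohort = cohort,
    identity_percent = 100 * conserved / ncols,
    n_sequences = nrow(aln),
    alignment_length = ncols
  ), class = "identity_report")
}

#' @export
print.identity_report <- function(x, ...) {
  cat(sprintf("<identity_report> %s%s: %.2f%% over %d columns (n = %d)\n",
              if (is.na(x$scope)) "" else x$scope,
              if (is.na(x$cohort)) "" else paste0(" [", x$cohort, "]"),
              x$identity_percent, x$alignment_length, x$n_sequences))
  invisible(x)
}
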