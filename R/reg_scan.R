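# Cis-regulatory element scanning over upstream, intron and downstream
# regions, 3' UTR extraction and cross-strain conservation reports.

#' Default cis-regulatory element definitions
#'
#' The shipped patterns are deliberately generic placeholders (the canonical
#' E-box class and the TATA consensus, plus the synthetic FMBP-site motif the
#' cohort generator plants in every intron); real binding-site definitions
#' are expected to be supplied by the user.
#'
#' @return data.frame with columns `name`, `pattern` (IUPAC), `region`
#'   (UPSTREAM, INTRON or DOWNSTREAM).
#' @export
default_elements <- function() {
  refs <- fibh_refs()
  data.frame(
    name = c("E-box", "TATA-box", "FMBP-site", "E-box-downstream"),
    pattern = c("CANNTG", "TATAWAW", refs$fmbp_site, "CANNTG"),
    region = c("UPSTREAM", "UPSTREAM", "INTRON", "DOWNSTREAM"),
    stringsAsFactors = FALSE
  )
}

#' Extract the 3' UTR from a downstream flank
#'
#' The 3' UTR is defined as the first 85 bp of the downstream 5 kb sequence,
#' in gene orientation.
#'
#' @param downstream_seq downstream flank (gene orientation).
#' @return 85-bp DNA string.
#' @export
extract_utr3 <- function(downstream_seq) {
  n <- nchar(downstream_seq)
  if (n < 85L) {
    stop_fibh("fibh_truncated",
              sprintf("downstream flank is %d bp; 85 bp needed for the 3' UTR", n),
              available = n, required = 85L)
  }
  substr(downstream_seq, 1L, 85L)
}

region_sequence <- function(locus, region, anatomy = NULL) {
  switch(region,
    UPSTREAM = locus$upstream_seq,
    DOWNSTREAM = locus$downstream_seq,
    INTRON = {
      if (is.null(anatomy)) {
        stop_fibh("fibh_config_error",
                  "an annotation is required to scan the INTRON region")
      }
      slice_gene(locus$gene_seq, anatomy$intron)
    },
    stop_fibh("fibh_config_error", sprintf("unknown region: %s", region))
  )
}

#' Scan a locus for cis-regulatory elements
#'
#' IUPAC matches on both strands of each region; positions are region-local,
#' 0-based, on the forward (gene-orientation) strand.
#'
#' @param locus a `fibh_locus`.
#' @param defs element definitions (see [default_elements()]).
#' @param anatomy optional `gene_anatomy` (required for INTRON regions).
#' @return data.frame: `strain_id`, `element`, `region`, `position`,
#'   `strand`, `match`.
#' @export
scan_elements <- function(locus, defs = default_elements(), anatomy = NULL) {
  if (nrow(defs) == 0L) {
    stop_fibh("fibh_config_error", "element definitions must be non-empty")
  }
  rows <- list()
  for (i in seq_len(nrow(defs))) {
    region <- defs$region[i]
    seq <- region_sequence(locus, region, anatomy)
    pat <- defs$pattern[i]
    fwd <- scan_iupac(seq, pat)
    rcp <- dna_revcomp(pat)
    rev <- if (rcp == pat) fwd[0, , drop = FALSE] else scan_iupac(seq, rcp)
    rows[[i]] <- rbind(
      if (nrow(fwd)) data.frame(strain_id = locus$strain_id, element = defs$name[i],
                                region = region, position = fwd$position,
                                strand = "+", match = fwd$match,
                                stringsAsFactors = FALSE),
      if (nrow(rev)) data.frame(strain_id = locus$strain_id, element = defs$name[i],
                                region = region, position = rev$position,
                                strand = "-", match = rev$match,
                                stringsAsFactors = FALSE)
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(strain_id = character(0), element = character(0),
                      region = character(0), position = integer(0),
                      strand = character(0), match = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Element presence/absence matrix for a cohort
#'
#' @param hits row-bound results of [scan_elements()] over a cohort.
#' @param strain_ids all strains (so absent rows appear as FALSE).
#' @param defs the element definitions used.
#' @return logical matrix, strains x elements.
#' @export
element_presence <- function(hits, strain_ids, defs = default_elements()) {
  m <- matrix(FALSE, length(strain_ids), nrow(defs),
              dimnames = list(strain_ids, defs$name))
  if (nrow(hits)) {
    for (r in seq_len(nrow(hits))) {
      m[hits$strain_id[r], hits$element[r]] <- TRUE
    }
  }
  m
}

#' Cross-strain conservation report for one region
#'
#' Aligns the region across strains, flags variant columns (columns without
#' a single shared non-gap symbol), reports the overall column identity, and
#' tests whether any variant column is class-exclusive, i.e. its minority
#' symbols are carried by exactly the members of one class.
#'
#' @param region_seqs named character vector (strain id -> region sequence),
#'   >= 2 strains.
#' @param classes optional named character vector of class labels.
#' @param max_cells passed to the aligner.
#' @return list: `identity_percent`, `alignment_length`, `n_variant_columns`,
#'   `variant_columns` (0-based), `any_class_exclusive`,
#'   `class_exclusive_columns`.
#' @export
conservation_report <- function(region_seqs, classes = NULL, max_cells = 8e8) {
  if (length(region_seqs) < 2L) {
    stop_fibh("fibh_config_error", "conservation_report requires >= 2 strains")
  }
  aln <- msa_align(region_seqs, max_cells = max_cells)
  conserved <- aln_conserved_columns(aln)
  variant_cols <- which(!conserved)
  excl <- integer(0)
  if (!is.null(classes) && length(variant_cols)) {
    cls <- classes[rownames(aln)]
    for (vc in variant_cols) {
      col <- aln[, vc]
      tab <- sort(table(col), decreasing = TRUE)
      minority <- rownames(aln)[col != names(tab)[1L]]
      for (cl in unique(cls)) {
        members <- rownames(aln)[cls == cl]
        if (length(minority) && setequal(minority, members)) {
          excl <- c(excl, vc)
          break
        }
      }
    }
  }
  list(
    identity_percent = 100 * sum(conserved) / ncol(aln),
    alignment_length = ncol(aln),
    n_variant_columns = length(variant_cols),
    variant_columns = variant_cols - 1L,
    any_class_exclusive = length(excl) > 0L,
    class_exclusive_columns = excl - 1L
  )
}
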