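# Decomposition of an extracted FibH gene into exon I, intron and exon II,
# and of exon II into 5' TNR, repetitive core and 3' TNR, with GC content,
# degenerate-motif coverage, NdeI amorphous-region sites and translation
# diagnostics.

#' Annotate a gene-oriented FibH sequence
#'
#' Boundary strategy: exon I is anchored at the gene start (its reference
#' length is fixed); the intron is the gap between the end of exon I and the
#' located start of the 5' TNR reference; the 5'/3' TNRs are delimited by
#' free-end-gap alignment of the reference blocks against the ends of exon
#' II; the repetitive core is the remainder. Splice-site consistency (GT...AG)
#' is reported, not enforced. An anchor alignment below `identity_floor`
#' raises the TNR_MISMATCH diagnostic and keeps best-effort intervals.
#'
#' @param gene_seq gene-oriented DNA string.
#' @param ref_exon1,ref_tnr5,ref_tnr3 reference anchor blocks (defaults from
#'   [fibh_refs()]).
#' @param cds_offset 0-based offset of the ATG within exon I.
#' @param motif IUPAC repeat motif scanned over the core (default: the 49-bp
#'   degenerate FibH repeat motif).
#' @param identity_floor minimum anchor identity before TNR_MISMATCH.
#' @param intron_search_bp how far beyond exon I to search for the 5' TNR.
#' @return object of class `gene_anatomy`: gene-local 0-based half-open
#'   intervals (`exon1`, `intron`, `exon2`, `tnr5`, `rc`, `tnr3`),
#'   `gc_fraction`, `amorphous_sites` (gene-local NdeI positions),
#'   `motif_matches` (data.frame, positions local to the core),
#'   `motif_coverage`, `translation`, `diagnostics`, `splice_ok`.
#' @export
annotate_gene <- function(gene_seq,
                          ref_exon1 = NULL, ref_tnr5 = NULL, ref_tnr3 = NULL,
                          cds_offset = NULL, motif = NULL,
                          identity_floor = 0.9, intron_search_bp = 1400L) {
  refs <- fibh_refs()
  ref_exon1 <- ref_exon1 %||% refs$exon1
  ref_tnr5 <- ref_tnr5 %||% refs$tnr5
  ref_tnr3 <- ref_tnr3 %||% refs$tnr3
  cds_offset <- cds_offset %||% refs$cds_offset
  motif <- motif %||% refs$motif49
  gl <- nchar(gene_seq)
  diagnostics <- character(0)

  e1 <- nchar(ref_exon1)
  if (gl < e1 + nchar(ref_tnr5) + nchar(ref_tnr3) + 100L) {
    stop_fibh("fibh_config_error", "gene sequence implausibly short")
  }

  # 5' TNR start: scan a window after exon I with the reference prefix
  probe_len <- min(30L, nchar(ref_tnr5))
  probe <- substr(ref_tnr5, 1L, probe_len)
  win_end <- min(gl, e1 + intron_search_bp)
  window <- substr(gene_seq, e1 + 1L, win_end)
  hits <- scan_iupac(window, probe, min_identity = identity_floor)
  if (nrow(hits) == 0L) {
    hits <- scan_iupac(window, probe, min_identity = 0.7)
    diagnostics <- c(diagnostics, "TNR_MISMATCH")
  }
  if (nrow(hits) == 0L) {
    # best effort: assume the canonical 971-bp intron
    t5_start <- e1 + 971L
  } else {
    best <- hits[which.max(hits$n_matching), , drop = FALSE]
    leftmost <- hits[hits$n_matching == best$n_matching[1L], , drop = FALSE]
    t5_start <- e1 + leftmost$position[1L]
  }

  exon1 <- c(0L, e1)
  intron <- c(e1, t5_start)
  exon2 <- c(t5_start, gl)
  intron_seq <- substr(gene_seq, intron[1] + 1L, intron[2])
  splice_ok <- startsWith(intron_seq, "GT") && endsWith(intron_seq, "AG")

  # 5' TNR end: free right end in the subject window
  w5 <- substr(gene_seq, t5_start + 1L, min(gl, t5_start + nchar(ref_tnr5) + 60L))
  a5 <- align_traceback(ref_tnr5, w5, free_a_ends = TRUE)
  t5_id <- a5$matches / max(nchar(ref_tnr5), 1L)
  t5_end <- t5_start + a5$b_end
  if (t5_id < identity_floor) diagnostics <- c(diagnostics, "TNR_MISMATCH")

  # 3' TNR start: align the reference against the end of the gene with a
  # free left end (reversed trick: align reversed strings with free right end)
  w3_start <- max(t5_end, gl - nchar(ref_tnr3) - 60L)
  w3 <- substr(gene_seq, w3_start + 1L, gl)
  rev_str <- function(x) paste(rev(seq_chars(x)), collapse = "")
  a3 <- align_traceback(rev_str(ref_tnr3), rev_str(w3), free_a_ends = TRUE)
  t3_id <- a3$matches / max(nchar(ref_tnr3), 1L)
  t3_start <- gl - a3$b_end
  if (t3_id < identity_floor) diagnostics <- c(diagnostics, "TNR_MISMATCH")

  if (t3_start < t5_end) t3_start <- t5_end # degenerate: no core
  tnr5 <- c(t5_start, t5_end)
  rc <- c(t5_end, t3_start)
  tnr3 <- c(t3_start, gl)
  rc_seq <- substr(gene_seq, rc[1] + 1L, rc[2])

  motif_matches <- if (nchar(rc_seq) >= nchar(motif)) {
    scan_iupac(rc_seq, motif)
  } else {
    data.frame(position = integer(0), match = character(0),
               n_matching = integer(0), stringsAsFactors = FALSE)
  }
  motif_cov <- 0
  if (nrow(motif_matches) > 0L) {
    covered <- logical(nchar(rc_seq))
    L <- nchar(motif)
    for (p in motif_matches$position) covered[(p + 1L):(p + L)] <- TRUE
    motif_cov <- mean(covered)
  }

  cds <- paste0(substr(gene_seq, cds_offset + 1L, e1),
                substr(gene_seq, exon2[1] + 1L, exon2[2]))
  tr <- translate_cds(cds)
  diagnostics <- unique(c(diagnostics, tr$diagnostics))

  structure(list(
    exon1 = exon1, intron = intron, exon2 = exon2,
    tnr5 = tnr5, rc = rc, tnr3 = tnr3,
    gc_fraction = gc_content(gene_seq),
    amorphous_sites = scan_ndei(gene_seq),
    motif_matches = motif_matches,
    motif_coverage = motif_cov,
    translation = tr$peptide,
    diagnostics = diagnostics,
    splice_ok = splice_ok
  ), class = "gene_anatomy")
}

#' @export
print.gene_anatomy <- function(x, ...) {
  cat(sprintf(paste0("<gene_anatomy> exon1 [%d,%d) intron [%d,%d) exon2 [%d,%d)\n",
                     "  tnr5 [%d,%d) rc [%d,%d) tnr3 [%d,%d)\n",
                     "  gc %.4f, %d NdeI sites, motif coverage %.2f%s\n"),
              x$exon1[1], x$exon1[2], x$intron[1], x$intron[2],
              x$exon2[1], x$exon2[2], x$tnr5[1], x$tnr5[2],
              x$rc[1], x$rc[2], x$tnr3[1], x$tnr3[2],
              x$gc_fraction, length(x$amorphous_sites), x$motif_coverage,
              if (length(x$diagnostics)) paste0(", diagnostics: ", paste(x$diagnostics, collapse = ",")) else ""))
  invisible(x)
}

anatomy_intervals <- function(x) {
  data.frame(
    feature = c("exon1", "intron", "exon2", "tnr5", "rc", "tnr3"),
    start = c(x$exon1[1], x$intron[1], x$exon2[1], x$tnr5[1], x$rc[1], x$tnr3[1]),
    end = c(x$exon1[2], x$intron[2], x$exon2[2], x$tnr5[2], x$rc[2], x$tnr3[2]),
    stringsAsFactors = FALSE
  )
}

slice_gene <- function(gene_seq, iv) substr(gene_seq, iv[1] + 1L, iv[2])
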