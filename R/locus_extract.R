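# Barcode-anchored extraction of the complete FibH locus from assembled
# chromosomes, on either strand, with QC flags.

#' Barcode pair for locus extraction
#'
#' @param start_barcode,end_barcode 20-bp DNA strings: the terminal sequences
#'   of the reference gene (start = first 20 bp, end = last 20 bp in gene
#'   orientation).
#' @param max_mismatch allowed substitutions per anchor (default 0: the
#'   inputs are assemblies, not reads).
#' @return object of class `barcode_pair`.
#' @export
barcode_pair <- function(start_barcode, end_barcode, max_mismatch = 0L) {
  for (b in c(start_barcode, end_barcode)) {
    if (nchar(b) != 20L || grepl("[^ACGT]", b)) {
      stop_fibh("fibh_config_error",
                "barcodes must be 20 bp over the ACGT alphabet")
    }
  }
  structure(list(start_barcode = start_barcode, end_barcode = end_barcode,
                 max_mismatch = as.integer(max_mismatch)),
            class = "barcode_pair")
}

#' Default barcode pair of the synthetic reference gene
#' @return a [barcode_pair()].
#' @export
default_barcodes <- function() {
  refs <- fibh_refs()
  barcode_pair(refs$start_barcode, refs$end_barcode)
}

#' Find anchor occurrences on both strands
#'
#' @param chrom chromosome DNA string.
#' @param barcode anchor sequence.
#' @param max_mismatch allowed substitutions.
#' @return data.frame with 0-based forward-strand `position` (start of the
#'   occurrence) and `strand` ("+" or "-"), sorted by position.
#' @export
find_anchor <- function(chrom, barcode, max_mismatch = 0L) {
  if (nchar(barcode) == 0L) {
    stop_fibh("fibh_config_error", "barcode must be non-empty")
  }
  subject <- Biostrings::DNAString(chrom)
  fwd <- Biostrings::matchPattern(barcode, subject, max.mismatch = max_mismatch)
  rev <- Biostrings::matchPattern(dna_revcomp(barcode), subject,
                                  max.mismatch = max_mismatch)
  out <- data.frame(
    position = c(BiocGenerics::start(fwd), BiocGenerics::start(rev)) - 1L,
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Homopolymer and alphabet QC flags for an extracted gene
#'
#' @param gene_seq gene DNA string.
#' @param max_n_run N-run length at or above which POLY_N is flagged.
#' @param max_g_run G-run length at or above which POLY_G is flagged (20
#'   exceeds the longest legitimate G-run in the coding repeat units).
#' @return character vector of flags (possibly empty): POLY_N, POLY_G,
#'   NON_ACGTN.
#' @export
qc_flags <- function(gene_seq, max_n_run = 10L, max_g_run = 20L) {
  flags <- character(0)
  if (grepl(sprintf("N{%d,}", max_n_run), gene_seq)) flags <- c(flags, "POLY_N")
  if (grepl(sprintf("G{%d,}", max_g_run), gene_seq)) flags <- c(flags, "POLY_G")
  if (grepl("[^ACGTN]", gene_seq)) flags <- c(flags, "NON_ACGTN")
  flags
}

#' Extract the complete FibH locus from one chromosome
#'
#' Locates the start and end barcodes on both strands, requires exactly one
#' consistent pair on one strand, and returns the gene-oriented gene sequence
#' together with its flanks. Gene length outside the plausible 13-25 kb band
#' is flagged (LENGTH_OUT_OF_RANGE), not rejected.
#'
#' @param chrom chromosome DNA string.
#' @param barcodes a [barcode_pair()].
#' @param flank_len requested flank length (default 5000 bp); truncated
#'   flanks carry FLANK_TRUNCATED_UP / FLANK_TRUNCATED_DOWN flags.
#' @param strain_id,chrom_id identifiers carried through to the result.
#' @param length_band plausibility band for the gene length in bp.
#' @return object of class `fibh_locus`: strain/chrom ids, 0-based half-open
#'   forward-strand `gene_start`/`gene_end`, `strand`, gene-oriented
#'   `gene_seq`, `upstream_seq`, `downstream_seq` and `qc_flags`.
#' @export
extract_locus <- function(chrom, barcodes = default_barcodes(), flank_len = 5000L,
                          strain_id = NA_character_, chrom_id = NA_character_,
                          length_band = c(13000L, 25000L)) {
  bl_s <- nchar(barcodes$start_barcode)
  bl_e <- nchar(barcodes$end_barcode)
  s_hits <- find_anchor(chrom, barcodes$start_barcode, barcodes$max_mismatch)
  e_hits <- find_anchor(chrom, barcodes$end_barcode, barcodes$max_mismatch)

  cand <- list()
  # forward: gene = [start-anchor begin, end-anchor end)
  for (s in s_hits$position[s_hits$strand == "+"]) {
    for (e in e_hits$position[e_hits$strand == "+"]) {
      if (e + bl_e > s + bl_s) {
        cand[[length(cand) + 1L]] <- list(start = s, end = e + bl_e, strand = "+")
      }
    }
  }
  # reverse: start barcode matches near the forward-strand end of the gene
  for (s in s_hits$position[s_hits$strand == "-"]) {
    for (e in e_hits$position[e_hits$strand == "-"]) {
      if (s + bl_s > e) {
        cand[[length(cand) + 1L]] <- list(start = e, end = s + bl_s, strand = "-")
      }
    }
  }
  if (length(cand) == 0L) {
    stop_fibh("fibh_not_found", "no consistent barcode anchor pair found",
              start_hits = s_hits, end_hits = e_hits)
  }
  if (length(cand) > 1L) {
    desc <- vapply(cand, function(x)
      sprintf("[%d, %d) strand %s", x$start, x$end, x$strand), "")
    stop_fibh("fibh_ambiguous",
              sprintf("multiple candidate anchor pairs: %s",
                      paste(desc, collapse = "; ")),
              candidates = cand)
  }
  hit <- cand[[1L]]
  n <- nchar(chrom)
  gene_fwd <- substr(chrom, hit$start + 1L, hit$end)
  flags <- character(0)

  if (hit$strand == "+") {
    gene_seq <- gene_fwd
    up_start <- max(0L, hit$start - flank_len)
    upstream <- substr(chrom, up_start + 1L, hit$start)
    down_end <- min(n, hit$end + flank_len)
    downstream <- substr(chrom, hit$end + 1L, down_end)
  } else {
    gene_seq <- dna_revcomp(gene_fwd)
    down_start <- max(0L, hit$start - flank_len)
    downstream <- dna_revcomp(substr(chrom, down_start + 1L, hit$start))
    up_end <- min(n, hit$end + flank_len)
    upstream <- dna_revcomp(substr(chrom, hit$end + 1L, up_end))
  }
  if (nchar(upstream) < flank_len) flags <- c(flags, "FLANK_TRUNCATED_UP")
  if (nchar(downstream) < flank_len) flags <- c(flags, "FLANK_TRUNCATED_DOWN")
  gl <- nchar(gene_seq)
  if (gl < length_band[1] || gl > length_band[2]) {
    flags <- c(flags, "LENGTH_OUT_OF_RANGE")
  }
  flags <- c(flags, qc_flags(gene_seq))

  structure(list(
    strain_id = strain_id, chrom_id = chrom_id,
    gene_start = hit$start, gene_end = hit$end, strand = hit$strand,
    gene_seq = gene_seq, upstream_seq = upstream, downstream_seq = downstream,
    qc_flags = flags
  ), class = "fibh_locus")
}

#' @export
print.fibh_locus <- function(x, ...) {
  cat(sprintf("<fibh_locus> %s on %s [%d, %d) strand %s, gene %d bp%s\n",
              x$strain_id, x$chrom_id, x$gene_start, x$gene_end, x$strand,
              nchar(x$gene_seq),
              if (length(x$qc_flags)) paste0(", flags: ", paste(x$qc_flags, collapse = ",")) else ""))
  invisible(x)
}

#' Extract loci for a whole cohort
#'
#' Applies [extract_locus()] to every chromosome; extraction failures are
#' recorded per strain instead of aborting the cohort.
#'
#' @param sequences named character vector of chromosomes (names are strain
#'   or chromosome ids).
#' @param barcodes a [barcode_pair()].
#' @param flank_len flank length in bp.
#' @param strain_ids optional ids (defaults to sequence names).
#' @return list with `loci` (named list of `fibh_locus`) and `report`
#'   (data.frame: strain, chrom, start, end, strand, length, flags, status).
#' @export
extract_cohort <- function(sequences, barcodes = default_barcodes(),
                           flank_len = 5000L, strain_ids = NULL) {
  ids <- strain_ids %||% sub("^chr_", "", names(sequences))
  loci <- list()
  rows <- list()
  for (i in seq_along(sequences)) {
    id <- ids[i]
    res <- tryCatch(
      extract_locus(sequences[[i]], barcodes, flank_len,
                    strain_id = id, chrom_id = names(sequences)[i]),
      fibhome_error = function(e) e
    )
    if (inherits(res, "fibh_locus")) {
      loci[[id]] <- res
      rows[[i]] <- data.frame(
        strain_id = id, chrom = res$chrom_id, start = res$gene_start,
        end = res$gene_end, strand = res$strand, length = nchar(res$gene_seq),
        flags = paste(res$qc_flags, collapse = ","), status = "ok",
        stringsAsFactors = FALSE
      )
    } else {
      rows[[i]] <- data.frame(
        strain_id = id, chrom = names(sequences)[i], start = NA_integer_,
        end = NA_integer_, strand = NA_character_, length = NA_integer_,
        flags = "", status = class(res)[1], stringsAsFactors = FALSE
      )
    }
  }
  list(loci = loci, report = do.call(rbind, rows))
}
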