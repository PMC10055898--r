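# Fixed reference sequences for the synthetic FibH locus.
#
# All references are synthesised deterministically from a private
# Park-Miller stream, so the package ships no sequence data files. They are
# *synthetic* stand-ins with the documented structural properties of the real
# gene (lengths, frame, splice dinucleotides, terminal barcodes), not the
# B. mori sequences.

# codons with no stop, used for the coding reference parts (GC-leaning)
CODING_CODONS <- c(
  "GCT", "GCA", "GCC", "GGA", "GGC", "TCT", "TCC", "AGC", "ACC", "ACA",
  "GTC", "GTT", "CCA", "CCT", "CAA", "CAG", "GAA", "GAT", "TAC", "TGC",
  "ATC", "ATT", "CTC", "CTT", "AAC", "AAG"
)

# substrings that must not occur in any reference outside their defined place
REF_FORBIDDEN <- c("CATATG", "GGTGCT")

# default repeat-unit alphabet: hexanucleotide-seeded blocks, each starting
# GGTGCT, ending TCA, in frame, encoding GAGAGS-family peptides. u3 is the
# consensus instantiation of the 49-bp degenerate motif's core.
FIBH_UNITS <- c(
  u1 = "GGTGCTGGAGCTGGTTCA",
  u2 = "GGTGCTGGAGCTGGATCA",
  u3 = "GGTGCTGGTGCTGGTTCA",
  u4 = "GGTGCTAGCGGAGCTGGAGCTGGAAGTGCTGGAAGTTCA"
)

# amorphous linker: 33 bp, in frame, stop-free, exactly one NdeI site
FIBH_LINKER <- "GGAGCTTCACATATGGGAGCTGGTACTGGTTCA"

# the published 49-symbol degenerate repeat motif
FIBH_MOTIF49 <- "AGGWRSYGGWGCTGGYTCAGGWGCTGGTGCTGGTKCAGGWGCTGGTGCT"

ref_env <- new.env(parent = emptyenv())

purge_forbidden <- function(seq, patterns = REF_FORBIDDEN, frame_safe = FALSE) {
  # deterministically break forbidden substrings; when frame_safe, swap with a
  # same-frame purine/pyrimidine switch that cannot create a stop codon
  repeat {
    hit <- FALSE
    for (p in patterns) {
      pos <- regexpr(p, seq, fixed = TRUE)
      if (pos > 0L) {
        hit <- TRUE
        at <- as.integer(pos) + 2L # third base of the offending hexamer
        old <- substr(seq, at, at)
        new <- c(A = "C", C = "A", G = "C", T = "C")[[old]]
        substr(seq, at, at) <- new
      }
    }
    if (!hit) return(seq)
  }
}

coding_ref <- function(rng, n_codons) {
  idx <- 1L + floor(rng(n_codons) * length(CODING_CODONS))
  seq <- paste(CODING_CODONS[idx], collapse = "")
  purge_forbidden(seq)
}

#' Reference anchors and defaults for the synthetic FibH locus
#'
#' Returns the fixed synthetic reference components used by the cohort
#' generator and, as defaults, by the annotation functions: exon I (67 bp,
#' with the ORF starting at the internal ATG), the 5' and 3' terminal
#' non-repetitive blocks of exon II, the canonical intron backbone (986 bp,
#' GT...AG), 5 kb upstream/downstream flank backbones with planted regulatory
#' elements, the 85-bp 3' UTR, the terminal 20-bp barcodes, the repeat-unit
#' alphabet and the 49-bp degenerate repeat motif.
#'
#' @return a named list of reference sequences and constants.
#' @export
fibh_refs <- function() {
  if (!is.null(ref_env$refs)) return(ref_env$refs)
  rng <- lcg_new(20230244)

  utr5 <- purge_forbidden(lcg_dna(rng, 25L, gc = 0.45))
  exon1 <- paste0(utr5, "ATG", coding_ref(rng, 13L))            # 67 bp, ORF at 25
  tnr5 <- coding_ref(rng, 66L)                                  # 198 bp
  tnr3 <- paste0(coding_ref(rng, 20L), "TAA")                   # 63 bp incl. stop

  fmbp_site <- "GTCAATTGGT"                                     # placeholder motif
  intron_mid <- purge_forbidden(lcg_dna(rng, 982L - 150L - nchar(fmbp_site), gc = 0.4))
  intron_pre <- purge_forbidden(lcg_dna(rng, 150L, gc = 0.4))
  intron <- paste0("GT", intron_pre, fmbp_site, intron_mid, "AG") # 986 bp
  stopifnot(nchar(intron) == 986L)

  tata <- "TATAAAT"
  ebox <- "CAGCTG"
  up_a <- purge_forbidden(lcg_dna(rng, 4800L - nchar(ebox), gc = 0.38))
  up_b <- purge_forbidden(lcg_dna(rng, 5000L - 4800L - nchar(tata) - 28L, gc = 0.38))
  up_tail <- purge_forbidden(lcg_dna(rng, 28L, gc = 0.38))
  upstream <- paste0(up_a, ebox, up_b, tata, up_tail)           # 5000 bp
  stopifnot(nchar(upstream) == 5000L)

  utr3 <- purge_forbidden(lcg_dna(rng, 85L, gc = 0.42))
  down_a <- purge_forbidden(lcg_dna(rng, 40L, gc = 0.38))
  down_b <- purge_forbidden(lcg_dna(rng, 5000L - 85L - 40L - nchar(ebox), gc = 0.38))
  downstream <- paste0(utr3, down_a, ebox, down_b)              # 5000 bp
  stopifnot(nchar(downstream) == 5000L)

  refs <- list(
    exon1 = exon1,
    cds_offset = 25L,
    tnr5 = tnr5,
    tnr3 = tnr3,
    intron = intron,
    upstream = upstream,
    downstream = downstream,
    utr3 = utr3,
    fmbp_site = fmbp_site,
    fmbp_offset_intron = 152L,   # 0-based offset of the planted site in the intron
    ebox = ebox,
    tata = tata,
    start_barcode = substr(exon1, 1L, 20L),
    end_barcode = substr(tnr3, nchar(tnr3) - 19L, nchar(tnr3)),
    units = FIBH_UNITS,
    linker = FIBH_LINKER,
    motif49 = FIBH_MOTIF49
  )
  ref_env$refs <- refs
  refs
}
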