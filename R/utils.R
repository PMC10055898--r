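#' @useDynLib fibhome, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rgeom rbinom setNames
#' @importFrom utils write.table read.delim
NULL

# ---- structured conditions -------------------------------------------------

stop_fibh <- function(class, message, ...) {
  data <- list(...)
  cond <- structure(
    class = c(class, "fibhome_error", "error", "condition"),
    c(list(message = message, call = sys.call(-1)), data)
  )
  stop(cond)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- deterministic local PRNG (reference sequences) ------------------------

# Park-Miller minimal standard generator; used only to synthesise the fixed
# reference sequences so they are reproducible without touching R's RNG state.
lcg_new <- function(seed) {
  state <- as.double(seed %% 2147483647L)
  if (state == 0) state <- 1
  function(n = 1L) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      state <<- (16807 * state) %% 2147483647
      out[i] <- state / 2147483647
    }
    out
  }
}

lcg_dna <- function(rng, n, gc = 0.5) {
  u <- rng(n)
  at <- c("A", "T")
  gcb <- c("G", "C")
  pick <- u < gc
  out <- character(n)
  u2 <- rng(n)
  out[pick] <- gcb[1 + (u2[pick] < 0.5)]
  out[!pick] <- at[1 + (u2[!pick] < 0.5)]
  paste(out, collapse = "")
}

# Stable per-strain seed derived from the strain id and a master seed.
# The extra mixing rounds matter: ids differing in one character would
# otherwise give near-consecutive seeds, whose first Mersenne-Twister draws
# are correlated.
strain_seed <- function(strain_id, master_seed) {
  codes <- utf8ToInt(strain_id)
  h <- 7
  for (k in codes) h <- (h * 131 + k) %% 2147483563
  h <- (h + as.double(master_seed) * 9973) %% 2147483563
  h <- bitwXor(as.integer(h), bitwShiftR(as.integer(h), 13))
  h <- (as.double(h) * 48271) %% 2147483647
  h <- bitwXor(as.integer(h), bitwShiftR(as.integer(h), 17))
  h <- (as.double(h) * 69621) %% 2147483647
  as.integer(h)
}

# ---- basic sequence helpers ------------------------------------------------

#' Reverse complement of a DNA string
#'
#' @param x character vector of DNA sequences (ACGTN and IUPAC codes allowed).
#' @return character vector of reverse complements.
#' @export
dna_revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# ---- GC content ------------------------------------------------------------

#' GC fraction of a sequence
#'
#' Counts G and C over the A/C/G/T positions only; ambiguity codes such as N
#' are excluded from both numerator and denominator.
#'
#' @param seq a single DNA string.
#' @return fraction in \[0, 1\].
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  ch <- seq_chars(toupper(seq))
  countable <- ch %in% c("A", "C", "G", "T")
  n <- sum(countable)
  if (n == 0L) {
    stop_fibh("fibh_undefined", "gc_content undefined: no countable A/C/G/T bases")
  }
  sum(ch %in% c("G", "C")) / n
}

# ---- translation -----------------------------------------------------------

#' Translate a coding sequence with diagnostics
#'
#' Standard genetic code. The trailing incomplete codon (if any) is dropped and
#' flagged as a frameshift; a stop codon before the final codon is flagged as a
#' premature stop; codons containing non-ACGT symbols translate to X and are
#' flagged.
#'
#' @param cds a single DNA string (the concatenated coding exons).
#' @return list with `peptide` (character, `*` marks stops) and `diagnostics`
#'   (character vector, subset of FRAMESHIFT, PREMATURE_STOP, AMBIGUOUS_CODON).
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L, nchar(cds) >= 3L)
  cds <- toupper(cds)
  diagnostics <- character(0)
  usable <- (nchar(cds) %/% 3L) * 3L
  if (usable != nchar(cds)) diagnostics <- c(diagnostics, "FRAMESHIFT")
  dna <- Biostrings::DNAString(substr(cds, 1L, usable))
  pep <- as.character(Biostrings::translate(dna, if.fuzzy.codon = "X"))
  if (grepl("X", pep, fixed = TRUE)) diagnostics <- c(diagnostics, "AMBIGUOUS_CODON")
  internal <- substr(pep, 1L, nchar(pep) - 1L)
  if (grepl("*", internal, fixed = TRUE)) diagnostics <- c(diagnostics, "PREMATURE_STOP")
  list(peptide = pep, diagnostics = diagnostics)
}

# ---- IUPAC scanning --------------------------------------------------------

IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  M = 3L, R = 5L, W = 9L, S = 6L, Y = 10L, K = 12L,
  V = 7L, H = 11L, D = 13L, B = 14L, N = 15L
)

iupac_bits <- function(x, what = "pattern") {
  ch <- seq_chars(toupper(x))
  bad <- !(ch %in% names(IUPAC_BITS))
  if (any(bad)) {
    stop_fibh("fibh_config_error",
              sprintf("invalid IUPAC symbol(s) in %s: %s", what,
                      paste(unique(ch[bad]), collapse = ", ")))
  }
  unname(IUPAC_BITS[ch])
}

#' Scan a sequence with an IUPAC degenerate motif
#'
#' Reports every window (overlaps allowed) where at least `min_identity` of
#' the positions satisfy their IUPAC class. Satisfaction is containment of the
#' subject symbol's base set in the pattern symbol's base set, so an N in the
#' subject is only satisfied by an N in the pattern, while pattern N matches
#' any subject symbol.
#'
#' @param seq subject DNA string (may contain ambiguity codes).
#' @param pattern IUPAC pattern string.
#' @param min_identity minimum fraction of satisfied positions, default 1
#'   (exact degenerate match).
#' @return data.frame with 0-based `position`, `match` (the matched substring)
#'   and `n_matching` (positions satisfying their class).
#' @export
scan_iupac <- function(seq, pattern, min_identity = 1.0) {
  stopifnot(length(seq) == 1L, length(pattern) == 1L,
            min_identity > 0, min_identity <= 1)
  p <- iupac_bits(pattern, "pattern")
  s <- iupac_bits(seq, "subject")
  L <- length(p)
  n <- length(s)
  empty <- data.frame(position = integer(0), match = character(0),
                      n_matching = integer(0), stringsAsFactors = FALSE)
  if (n < L) return(empty)
  nw <- n - L + 1L
  counts <- integer(nw)
  for (j in seq_len(L)) {
    sj <- s[j:(n - L + j)]
    counts <- counts + as.integer(bitwAnd(sj, p[j]) == sj)
  }
  need <- ceiling(min_identity * L - 1e-9)
  pos <- which(counts >= need)
  if (length(pos) == 0L) return(empty)
  data.frame(position = pos - 1L,
             match = substring(seq, pos, pos + L - 1L),
             n_matching = counts[pos],
             stringsAsFactors = FALSE)
}

#' NdeI restriction site positions
#'
#' Finds all 0-based start positions of the NdeI recognition site CATATG.
#' Consecutive sites delimit the amorphous regions of the repetitive core.
#'
#' @param seq a DNA string.
#' @return integer vector of 0-based positions (possibly empty).
#' @export
scan_ndei <- function(seq) {
  stopifnot(length(seq) == 1L)
  hits <- gregexpr("CATATG", toupper(seq), fixed = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits) - 1L
}

# ---- misc ------------------------------------------------------------------

lcp_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- seq_chars(substr(a, 1L, n))
  cb <- seq_chars(substr(b, 1L, n))
  neq <- which(ca != cb)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

lcs_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  if (n == 0L) return(0L)
  ca <- rev(seq_chars(substr(a, nchar(a) - n + 1L, nchar(a))))
  cb <- rev(seq_chars(substr(b, nchar(b) - n + 1L, nchar(b))))
  neq <- which(ca != cb)
  if (length(neq) == 0L) n else neq[1L] - 1L
}

roman_numeral <- function(i) as.character(utils::as.roman(i))
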