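# Synthetic silkworm FibH cohort generator.
#
# Generates chromosomes carrying ground-truthed FibH loci with the structure
# the downstream analysis assumes: exon I (67 bp) + one short intron + exon II
# (5' TNR + GC-rich repetitive core of GGTGCT-seeded units + 3' TNR), 5 kb
# flanks with planted regulatory elements, class-specific total-length
# distributions, whole-unit block indels, rare SNPs in TNR/intron/flanks, and
# embedding on either strand of a random chromosome background.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  invisible(runif(8L)) # warm the stream: early draws of nearby seeds correlate
  force(code)
}

#' Specification for a synthetic FibH cohort
#'
#' Defaults are the cohort-level statistics reported for the silkworm
#' pan-genome: class mean gene lengths 19,698 / 16,427 / 15,795 bp for wild,
#' local and improved strains, an intron drawn mostly from \{971, 986\} bp,
#' and a GC-rich repetitive core built from GGTGCT-seeded units.
#'
#' @param n_wild,n_local,n_improved strain counts per class.
#' @param length_mean_by_class named numeric, mean total gene length (bp).
#' @param length_sd_by_class named numeric, SD of total gene length (bp).
#' @param unit_alphabet repeat units; each must start GGTGCT, end TCA, have
#'   length a multiple of 3 and translate in frame without stop codons.
#' @param canonical_run_prob probability that the next sampled stretch is a
#'   run of the canonical unit u3 (the degenerate-motif consensus).
#' @param canonical_run_mean mean geometric run length for canonical runs.
#' @param snp_rate substitution rate per bp in TNR/intron/flanks.
#' @param block_indel_lambda named numeric, Poisson mean count of Group 1-4
#'   block events applied per strain (names "1","2","3","4").
#' @param linker_period approximate spacing (bp) of amorphous linkers in the
#'   repetitive core; each linker carries exactly one NdeI site.
#' @param background_len chromosome background length (bp).
#' @param flank_len flank length (bp); must be at least 85 so the downstream
#'   flank contains the full 3' UTR.
#' @param share_alleles optional list of character vectors of strain ids; all
#'   strains in a vector receive a byte-identical gene and flanks (the first
#'   member is the founder).
#' @param polyn_strains character vector of strain ids whose repetitive core
#'   receives an injected N-run (QC fixture).
#' @param tnr5_ref,tnr3_ref,exon1_ref reference blocks; defaults from
#'   [fibh_refs()].
#' @param seed master seed; per-strain seeds are derived by stable hashing of
#'   the strain id.
#' @return an object of class `synth_cohort_spec`.
#' @export
synth_cohort_spec <- function(n_wild = 5L, n_local = 10L, n_improved = 10L,
                              length_mean_by_class = c(wild = 19698, local = 16427, improved = 15795),
                              length_sd_by_class = c(wild = 1500, local = 800, improved = 600),
                              unit_alphabet = FIBH_UNITS,
                              canonical_run_prob = 0.62,
                              canonical_run_mean = 10,
                              snp_rate = 5e-4,
                              block_indel_lambda = c("1" = 0.5, "2" = 0.4, "3" = 0.4, "4" = 0.3),
                              linker_period = 1500L,
                              background_len = 60000L,
                              flank_len = 5000L,
                              share_alleles = NULL,
                              polyn_strains = character(0),
                              tnr5_ref = NULL, tnr3_ref = NULL, exon1_ref = NULL,
                              seed = 1L) {
  refs <- fibh_refs()
  spec <- list(
    n_wild = as.integer(n_wild), n_local = as.integer(n_local),
    n_improved = as.integer(n_improved),
    length_mean_by_class = length_mean_by_class,
    length_sd_by_class = length_sd_by_class,
    unit_alphabet = unit_alphabet,
    canonical_run_prob = canonical_run_prob,
    canonical_run_mean = canonical_run_mean,
    snp_rate = snp_rate,
    block_indel_lambda = block_indel_lambda,
    linker_period = as.integer(linker_period),
    background_len = as.integer(background_len),
    flank_len = as.integer(flank_len),
    share_alleles = share_alleles,
    polyn_strains = polyn_strains,
    tnr5_ref = tnr5_ref %||% refs$tnr5,
    tnr3_ref = tnr3_ref %||% refs$tnr3,
    exon1_ref = exon1_ref %||% refs$exon1,
    seed = as.integer(seed)
  )
  validate_cohort_spec(spec)
  structure(spec, class = "synth_cohort_spec")
}

validate_cohort_spec <- function(spec) {
  lens <- c(spec$length_mean_by_class, spec$length_sd_by_class,
            spec$background_len, spec$flank_len, spec$linker_period)
  if (any(lens <= 0)) {
    stop_fibh("fibh_config_error", "all lengths and SDs must be > 0")
  }
  if (spec$flank_len < 85L) {
    stop_fibh("fibh_config_error",
              "flank_len must be >= 85 bp (must contain the 3' UTR)")
  }
  if (length(spec$unit_alphabet) == 0L) {
    stop_fibh("fibh_config_error", "unit_alphabet must not be empty")
  }
  for (u in spec$unit_alphabet) {
    if (nchar(u) %% 3L != 0L || !startsWith(u, "GGTGCT") || !endsWith(u, "TCA")) {
      stop_fibh("fibh_config_error",
                sprintf("unit %s must start GGTGCT, end TCA, length multiple of 3", u))
    }
    pep <- translate_cds(u)
    if (grepl("*", pep$peptide, fixed = TRUE)) {
      stop_fibh("fibh_config_error", sprintf("unit %s contains a stop codon", u))
    }
  }
  invisible(spec)
}

#' Build a repetitive core from the unit alphabet
#'
#' Concatenates repeat units (runs of the canonical unit interleaved with the
#' other alphabet members) until the total length is within one unit of
#' `target_len`, punctuating the core with an in-frame 33-bp amorphous linker
#' (exactly one NdeI site each) approximately every `linker_period` bp.
#'
#' @param target_len target core length in bp.
#' @param unit_alphabet repeat units (see [synth_cohort_spec()]).
#' @param seed integer seed.
#' @param canonical_run_prob,canonical_run_mean run-sampling parameters.
#' @param linker_period linker spacing in bp.
#' @return a DNA string with attributes `boundaries` (0-based block start
#'   offsets), `blocks` (the block strings) and `n_linkers`.
#' @export
make_repeat_core <- function(target_len, unit_alphabet = FIBH_UNITS, seed = 1L,
                             canonical_run_prob = 0.62, canonical_run_mean = 10,
                             linker_period = 1500L) {
  if (length(unit_alphabet) == 0L) {
    stop_fibh("fibh_config_error", "unit_alphabet must not be empty")
  }
  if (target_len < min(nchar(unit_alphabet))) {
    stop_fibh("fibh_config_error",
              "target_len shorter than the shortest alphabet unit")
  }
  canon <- unit_alphabet[which.min(!grepl("^GGTGCTGGTGCT", unit_alphabet))]
  others <- setdiff(unit_alphabet, canon)
  if (length(others) == 0L) others <- canon
  with_seed(seed, {
    blocks <- character(0)
    len <- 0L
    since_linker <- 0L
    queue <- character(0)
    while (len < target_len) {
      if (length(queue) == 0L) {
        if (runif(1) < canonical_run_prob) {
          k <- 1L + rgeom(1L, 1 / canonical_run_mean)
          queue <- rep(canon, k)
        } else {
          queue <- sample(others, 1L)
        }
      }
      u <- queue[1L]; queue <- queue[-1L]
      blocks <- c(blocks, u)
      len <- len + nchar(u)
      since_linker <- since_linker + nchar(u)
      if (since_linker >= linker_period && len < target_len) {
        blocks <- c(blocks, FIBH_LINKER)
        len <- len + nchar(FIBH_LINKER)
        since_linker <- 0L
      }
    }
    seq <- paste(blocks, collapse = "")
    ends <- cumsum(nchar(blocks))
    structure(seq,
              boundaries = c(0L, ends[-length(ends)]),
              blocks = blocks,
              n_linkers = sum(blocks == FIBH_LINKER))
  })
}

intron_length_draw <- function() {
  u <- runif(1)
  if (u < 0.55) return(971L)
  if (u < 0.95) return(986L)
  others <- c(958:970, 972:985, 987L, 988L, 1007L)
  others[1L + floor(runif(1) * length(others))]
}

# derive a per-strain intron of the requested length from the 986-bp backbone
intron_of_length <- function(len) {
  backbone <- fibh_refs()$intron
  bl <- nchar(backbone)           # 986
  cut <- 700L                     # fixed internal edit point (after FMBP site)
  if (len == bl) return(backbone)
  if (len < bl) {
    k <- bl - len
    return(paste0(substr(backbone, 1L, cut), substr(backbone, cut + k + 1L, bl)))
  }
  k <- len - bl
  filler <- paste(rep("TGCTA", ceiling(k / 5)), collapse = "")
  paste0(substr(backbone, 1L, cut), substr(filler, 1L, k),
         substr(backbone, cut + 1L, bl))
}

#' Generate one synthetic FibH gene
#'
#' Draws the total gene length from the class distribution, an intron length
#' from the documented mixture (971 bp with probability 0.55, 986 bp with
#' 0.40, other observed lengths otherwise), and assembles
#' exon I + intron + (5' TNR + repetitive core + 3' TNR).
#'
#' @param spec a [synth_cohort_spec()].
#' @param class one of "wild", "local", "improved".
#' @param seed integer seed.
#' @param reference if TRUE, build the fixed reference gene instead of a
#'   random draw: intron 971 bp and exon II exactly 15,750 bp, giving the
#'   canonical total length of 16,788 bp.
#' @return an object of class `fibh_gene`: list with `gene_seq`, `class`,
#'   gene-local 0-based half-open boundary intervals (`exon1`, `intron`,
#'   `exon2`, `tnr5`, `rc`, `tnr3`), `rc_boundaries` (block starts within the
#'   core), `n_linkers` and `intron_len`.
#' @export
make_fibh_locus <- function(spec = synth_cohort_spec(), class = "improved",
                            seed = 1L, reference = FALSE) {
  if (!class %in% c("wild", "local", "improved")) {
    stop_fibh("fibh_config_error", sprintf("unknown class label: %s", class))
  }
  refs <- fibh_refs()
  fixed_len <- nchar(spec$exon1_ref) + nchar(spec$tnr5_ref) + nchar(spec$tnr3_ref)
  if (reference) {
    intron_len <- 971L
    rc_target <- 15750L - nchar(spec$tnr5_ref) - nchar(spec$tnr3_ref)
  } else {
    drawn <- with_seed(seed, {
      total <- rnorm(1, spec$length_mean_by_class[[class]],
                     spec$length_sd_by_class[[class]])
      list(total = round(total), intron_len = intron_length_draw())
    })
    intron_len <- drawn$intron_len
    rc_target <- drawn$total - fixed_len - intron_len
    min_rc <- 30L * max(nchar(spec$unit_alphabet))
    if (rc_target < min_rc) rc_target <- min_rc
    # keep the core in frame: block lengths are multiples of 3 anyway
  }
  if (reference) {
    # deterministic core of exactly rc_target bp: canonical units with
    # evenly spaced amorphous linkers (844 * 18 + 9 * 33 = 15,489 for the
    # default references)
    n_linkers <- max(0L, round(rc_target / spec$linker_period) - 1L)
    n_units <- (rc_target - n_linkers * nchar(FIBH_LINKER)) / 18L
    stopifnot(n_units == round(n_units))
    canon <- spec$unit_alphabet[[which(grepl("^GGTGCTGGTGCT", spec$unit_alphabet))[1L]]]
    blocks <- rep(canon, n_units)
    if (n_linkers > 0L) {
      step <- n_units %/% (n_linkers + 1L)
      at <- step * seq_len(n_linkers) + seq_len(n_linkers) - 1L
      for (p in at) blocks <- append(blocks, FIBH_LINKER, after = p)
    }
    seqs <- paste(blocks, collapse = "")
    ends <- cumsum(nchar(blocks))
    rc <- structure(seqs, boundaries = c(0L, ends[-length(ends)]),
                    blocks = blocks, n_linkers = n_linkers)
  } else {
    rc <- make_repeat_core(rc_target, spec$unit_alphabet, seed = seed + 7L,
                           canonical_run_prob = spec$canonical_run_prob,
                           canonical_run_mean = spec$canonical_run_mean,
                           linker_period = spec$linker_period)
  }
  intron <- intron_of_length(intron_len)
  e1 <- nchar(spec$exon1_ref)
  t5 <- nchar(spec$tnr5_ref)
  t3 <- nchar(spec$tnr3_ref)
  rcl <- nchar(rc)
  gene <- paste0(spec$exon1_ref, intron, spec$tnr5_ref, as.character(rc), spec$tnr3_ref)
  gl <- nchar(gene)
  e2s <- e1 + intron_len
  structure(list(
    gene_seq = gene,
    class = class,
    exon1 = c(0L, e1),
    intron = c(e1, e2s),
    exon2 = c(e2s, gl),
    tnr5 = c(e2s, e2s + t5),
    rc = c(e2s + t5, e2s + t5 + rcl),
    tnr3 = c(e2s + t5 + rcl, gl),
    rc_boundaries = attr(rc, "boundaries"),
    rc_blocks = attr(rc, "blocks"),
    n_linkers = attr(rc, "n_linkers"),
    intron_len = intron_len
  ), class = "fibh_gene")
}

group_block <- function(group, unit_alphabet = FIBH_UNITS) {
  switch(as.character(group),
    "1" = "GGTGCT",
    "2" = unname(unit_alphabet[["u1"]] %||% unit_alphabet[[1L]]),
    "3" = unname(unit_alphabet[["u2"]] %||% unit_alphabet[[min(2L, length(unit_alphabet))]]),
    "4" = NULL,
    stop_fibh("fibh_config_error", sprintf("group must be 1, 2, 3 or 4, got %s", group))
  )
}

#' Apply one Group 1-4 block variant to a gene's repetitive core
#'
#' Inserts (or deletes) one block at a repeat-unit boundary: Group 1 the
#' hexanucleotide GGTGCT; Groups 2 and 3 an 18-bp in-frame block encoding
#' GAGAGS (two blocks differing by one base); Group 4 an in-frame block of
#' 54-4302 bp built from whole units, starting GGTGCT and ending TCA.
#'
#' @param locus a `fibh_gene` from [make_fibh_locus()].
#' @param group 1, 2, 3 or 4.
#' @param seed integer seed (chooses the boundary and, for Group 4, the size).
#' @param kind "insertion" or "deletion".
#' @return list with `locus` (the modified `fibh_gene`) and `variant` (a
#'   one-row data.frame: type, kind, position within the core, length, seq).
#' @export
apply_group_variant <- function(locus, group, seed = 1L, kind = c("insertion", "deletion")) {
  kind <- match.arg(kind)
  stopifnot(inherits(locus, "fibh_gene"))
  if (!as.character(group) %in% c("1", "2", "3", "4")) {
    stop_fibh("fibh_config_error", sprintf("group must be 1, 2, 3 or 4, got %s", group))
  }
  rc_seq <- substr(locus$gene_seq, locus$rc[1] + 1L, locus$rc[2])
  blocks <- locus$rc_blocks
  if (is.null(blocks)) {
    stop_fibh("fibh_config_error", "locus carries no repeat-block bookkeeping")
  }
  bnd <- cumsum(c(0L, nchar(blocks)))[seq_along(blocks)]
  unit_idx <- which(blocks != FIBH_LINKER & nchar(blocks) == 18L)

  res <- with_seed(seed, {
    if (kind == "insertion") {
      block <- group_block(group)
      if (is.null(block)) { # group 4: whole 18-bp units, 54..4302 bp
        k <- sample(3:239, 1L)
        units18 <- FIBH_UNITS[nchar(FIBH_UNITS) == 18L]
        block <- paste(sample(units18, k, replace = TRUE), collapse = "")
      }
      i <- sample(seq_along(blocks), 1L) # insert before block i
      at <- bnd[i]
      new_blocks <- append(blocks, block, after = i - 1L)
      list(new_blocks = new_blocks, at = at, seq = block, len = nchar(block))
    } else {
      if (length(unit_idx) == 0L) {
        stop_fibh("fibh_rc_too_short", "no whole repeat unit left to delete")
      }
      if (as.character(group) == "1") {
        i <- sample(unit_idx, 1L)
        at <- bnd[i]; len <- 6L
        seqdel <- substr(blocks[i], 1L, 6L)
        new_blocks <- blocks
        new_blocks[i] <- substr(blocks[i], 7L, nchar(blocks[i]))
      } else if (as.character(group) %in% c("2", "3")) {
        i <- sample(unit_idx, 1L)
        at <- bnd[i]; len <- 18L
        seqdel <- blocks[i]
        new_blocks <- blocks[-i]
      } else {
        runs <- split(unit_idx, cumsum(c(1L, diff(unit_idx) != 1L)))
        runs <- runs[vapply(runs, length, 1L) >= 3L]
        if (length(runs) == 0L) {
          stop_fibh("fibh_rc_too_short", "core too short for a Group 4 deletion")
        }
        r <- runs[[sample(length(runs), 1L)]]
        k <- min(length(r), 3L + floor(runif(1) * 5))
        drop_idx <- r[seq_len(k)]
        at <- bnd[drop_idx[1L]]; len <- 18L * k
        seqdel <- paste(blocks[drop_idx], collapse = "")
        new_blocks <- blocks[-drop_idx]
      }
      if (len >= nchar(rc_seq)) {
        stop_fibh("fibh_rc_too_short", "deletion longer than the repetitive core")
      }
      list(new_blocks = new_blocks, at = at, seq = seqdel, len = len)
    }
  })

  new_locus <- rebuild_gene(locus, res$new_blocks)
  variant <- data.frame(
    type = paste0("group", group),
    kind = kind,
    rc_position = res$at,
    length = res$len,
    seq = res$seq,
    stringsAsFactors = FALSE
  )
  list(locus = new_locus, variant = variant)
}

# rebuild a fibh_gene after its core's block list changed
rebuild_gene <- function(locus, new_blocks) {
  new_rc <- paste(new_blocks, collapse = "")
  exon1 <- substr(locus$gene_seq, locus$exon1[1] + 1L, locus$exon1[2])
  intron <- substr(locus$gene_seq, locus$intron[1] + 1L, locus$intron[2])
  tnr5 <- substr(locus$gene_seq, locus$tnr5[1] + 1L, locus$tnr5[2])
  tnr3 <- substr(locus$gene_seq, locus$tnr3[1] + 1L, locus$tnr3[2])
  gene <- paste0(exon1, intron, tnr5, new_rc, tnr3)
  e1 <- nchar(exon1); il <- nchar(intron)
  t5 <- nchar(tnr5); t3 <- nchar(tnr3); rcl <- nchar(new_rc)
  e2s <- e1 + il
  gl <- nchar(gene)
  out <- locus
  out$gene_seq <- gene
  out$exon2 <- c(e2s, gl)
  out$tnr5 <- c(e2s, e2s + t5)
  out$rc <- c(e2s + t5, e2s + t5 + rcl)
  out$tnr3 <- c(e2s + t5 + rcl, gl)
  ends <- cumsum(nchar(new_blocks))
  out$rc_boundaries <- c(0L, ends[-length(ends)])
  out$rc_blocks <- new_blocks
  out$n_linkers <- sum(new_blocks == FIBH_LINKER)
  out
}

apply_snps <- function(seq, rate, protect = NULL) {
  # protect: list of c(start, end) 0-based half-open intervals left untouched
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(list(seq = seq, positions = integer(0)))
  pos <- sort(sample.int(n, k))
  if (!is.null(protect)) {
    keep <- rep(TRUE, length(pos))
    for (iv in protect) keep <- keep & !(pos > iv[1] & pos <= iv[2])
    pos <- pos[keep]
  }
  if (length(pos) == 0L) return(list(seq = seq, positions = integer(0)))
  ch <- seq_chars(seq)
  subs <- c(A = "G", C = "T", G = "A", T = "C", N = "N")
  ch[pos] <- unname(subs[ch[pos]])
  list(seq = paste(ch, collapse = ""), positions = pos - 1L)
}

#' Embed a flanked locus in a random chromosome background
#'
#' @param gene_with_flanks DNA string (upstream + gene + downstream).
#' @param background_len chromosome length in bp; must exceed the locus.
#' @param strand "+" or "-"; on "-" the embedded sequence is the reverse
#'   complement and truth coordinates refer to the forward strand.
#' @param seed integer seed.
#' @return list with `chrom_seq` and 0-based half-open `locus_start`,
#'   `locus_end` on the forward strand.
#' @export
embed_in_chromosome <- function(gene_with_flanks, background_len, strand = "+", seed = 1L) {
  n <- nchar(gene_with_flanks)
  if (background_len <= n) {
    stop_fibh("fibh_config_error", "background shorter than the locus")
  }
  stopifnot(strand %in% c("+", "-"))
  with_seed(seed, {
    bg <- paste(sample(c("A", "C", "G", "T"), background_len - n, replace = TRUE,
                       prob = c(0.31, 0.19, 0.19, 0.31)), collapse = "")
    offset <- sample.int(background_len - n, 1L) - 1L # 0-based
    insert <- if (strand == "+") gene_with_flanks else dna_revcomp(gene_with_flanks)
    chrom <- paste0(substr(bg, 1L, offset), insert,
                    substr(bg, offset + 1L, nchar(bg)))
    list(chrom_seq = chrom, locus_start = offset, locus_end = offset + n)
  })
}

#' Generate a full synthetic cohort
#'
#' One chromosome per strain, with a ground-truth table and variant list.
#' Deterministic under the spec seed: per-strain seeds are derived by stable
#' hashing of the strain id.
#'
#' @param spec a [synth_cohort_spec()].
#' @return list with `sequences` (named character vector of chromosomes),
#'   `truth` (data.frame of coordinates and boundaries), `variants`
#'   (data.frame of applied block events and SNP counts), `genes` (named
#'   character vector of the true gene strings) and `spec`.
#' @export
make_cohort <- function(spec = synth_cohort_spec()) {
  refs <- fibh_refs()
  classes <- c(rep("wild", spec$n_wild), rep("local", spec$n_local),
               rep("improved", spec$n_improved))
  prefix <- c(wild = "W", local = "L", improved = "P")
  ids <- unlist(lapply(c("wild", "local", "improved"), function(cl) {
    n <- sum(classes == cl)
    if (n == 0L) return(character(0))
    paste0(prefix[[cl]], seq_len(n))
  }))
  classes <- classes[order(match(classes, c("wild", "local", "improved")))]

  founders <- list() # shared-allele cache: leader id -> built locus bundle
  share_of <- list()
  if (!is.null(spec$share_alleles)) {
    for (grp in spec$share_alleles) for (m in grp) share_of[[m]] <- grp[[1L]]
  }

  seqs <- character(0)
  truth <- NULL
  variants <- NULL
  genes <- character(0)

  build_gene_bundle <- function(id, cl) {
    sd0 <- strain_seed(id, spec$seed)
    locus <- make_fibh_locus(spec, cl, seed = sd0)
    vrec <- NULL
    # Poisson block events per group
    ev <- with_seed(sd0 + 11L, {
      lam <- spec$block_indel_lambda
      counts <- vapply(names(lam), function(g) stats::rpois(1L, lam[[g]]), 1L)
      kinds <- lapply(counts, function(k) {
        if (k == 0L) character(0) else sample(c("insertion", "deletion"), k, replace = TRUE, prob = c(0.6, 0.4))
      })
      list(counts = counts, kinds = kinds)
    })
    i <- 0L
    for (g in names(ev$counts)) {
      for (k in seq_len(ev$counts[[g]])) {
        i <- i + 1L
        out <- tryCatch(
          apply_group_variant(locus, g, seed = sd0 + 100L + i, kind = ev$kinds[[g]][k]),
          fibh_rc_too_short = function(e) NULL
        )
        if (!is.null(out)) {
          locus <- out$locus
          vr <- out$variant
          vr$strain_id <- id
          vrec <- rbind(vrec, vr)
        }
      }
    }
    # SNPs in intron and TNRs (splice sites, end barcode protected)
    snp <- with_seed(sd0 + 23L, {
      il <- locus$intron
      t5 <- locus$tnr5
      t3 <- locus$tnr3
      protect <- list(
        c(il[1], il[1] + 2L), c(il[2] - 2L, il[2]),                     # GT..AG
        c(il[1] + refs$fmbp_offset_intron, il[1] + refs$fmbp_offset_intron + nchar(refs$fmbp_site)),
        c(t3[2] - 20L, t3[2])                                           # end barcode
      )
      region <- list(c(il[1], t5[2]), t3)   # intron + 5'TNR, 3'TNR
      ch <- seq_chars(locus$gene_seq)
      pos_all <- integer(0)
      for (iv in region) {
        sub <- substr(locus$gene_seq, iv[1] + 1L, iv[2])
        r <- apply_snps(sub, spec$snp_rate,
                        protect = lapply(protect, function(p) p - iv[1]))
        if (length(r$positions)) {
          ch[iv[1] + r$positions + 1L] <- seq_chars(r$seq)[r$positions + 1L]
          pos_all <- c(pos_all, iv[1] + r$positions)
        }
      }
      list(seq = paste(ch, collapse = ""), positions = pos_all)
    })
    locus$gene_seq <- snp$seq
    if (length(snp$positions)) {
      vrec <- rbind(vrec, data.frame(
        type = "snp", kind = "substitution", rc_position = NA_integer_,
        length = 1L, seq = "", strain_id = id,
        stringsAsFactors = FALSE
      )[rep(1L, length(snp$positions)), , drop = FALSE])
    }
    # flanks: reference backbones with SNPs (elements and 3' UTR protected)
    fl <- with_seed(sd0 + 31L, {
      up <- substr(refs$upstream, 5001L - spec$flank_len, 5000L)
      dn <- substr(refs$downstream, 1L, spec$flank_len)
      upp <- apply_snps(up, spec$snp_rate,
                        protect = list(c(nchar(up) - 210L, nchar(up))))
      dnp <- apply_snps(dn, spec$snp_rate, protect = list(c(0L, 140L)))
      list(up = upp$seq, dn = dnp$seq)
    })
    list(locus = locus, up = fl$up, dn = fl$dn, variants = vrec)
  }

  for (i in seq_along(ids)) {
    id <- ids[i]
    cl <- classes[i]
    leader <- share_of[[id]]
    if (!is.null(leader)) {
      if (is.null(founders[[leader]])) founders[[leader]] <- build_gene_bundle(leader, cl)
      bundle <- founders[[leader]]
    } else {
      bundle <- build_gene_bundle(id, cl)
    }
    locus <- bundle$locus
    gene <- locus$gene_seq
    qc_polyn <- id %in% spec$polyn_strains
    if (qc_polyn) {
      # replace 12 bp inside the core with Ns (assembly-gap fixture)
      at <- locus$rc[1] + 301L
      gene <- paste0(substr(gene, 1L, at), strrep("N", 12L),
                     substr(gene, at + 13L, nchar(gene)))
    }
    full <- paste0(bundle$up, gene, bundle$dn)
    sd0 <- strain_seed(id, spec$seed)
    strand <- if (with_seed(sd0 + 41L, runif(1)) < 0.5) "+" else "-"
    emb <- embed_in_chromosome(full, spec$background_len, strand, seed = sd0 + 43L)
    chrom_id <- paste0("chr_", id)
    up_len <- nchar(bundle$up)
    dn_len <- nchar(bundle$dn)
    if (strand == "+") {
      gstart <- emb$locus_start + up_len
    } else {
      gstart <- emb$locus_start + dn_len
    }
    gend <- gstart + nchar(gene)
    seqs[chrom_id] <- emb$chrom_seq
    genes[id] <- gene
    truth <- rbind(truth, data.frame(
      strain_id = id, class = cl, chrom = chrom_id,
      start = gstart, end = gend, strand = strand,
      gene_length = nchar(gene),
      exon1_start = locus$exon1[1], exon1_end = locus$exon1[2],
      intron_start = locus$intron[1], intron_end = locus$intron[2],
      exon2_start = locus$exon2[1], exon2_end = locus$exon2[2],
      tnr5_start = locus$tnr5[1], tnr5_end = locus$tnr5[2],
      rc_start = locus$rc[1], rc_end = locus$rc[2],
      tnr3_start = locus$tnr3[1], tnr3_end = locus$tnr3[2],
      n_linkers = if (!is.null(locus$n_linkers)) locus$n_linkers else length(scan_ndei(substr(gene, locus$rc[1] + 1L, locus$rc[2]))),
      intron_len = locus$intron_len,
      qc_polyn = qc_polyn,
      stringsAsFactors = FALSE
    ))
    if (!is.null(bundle$variants) && is.null(share_of[[id]])) {
      variants <- rbind(variants, bundle$variants)
    }
  }
  rownames(truth) <- NULL
  list(sequences = seqs, truth = truth, variants = variants,
       genes = genes, spec = spec)
}
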