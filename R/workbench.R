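# Shared I/O and the end-to-end pipeline driver:
# simulate -> extract -> anatomy -> compare -> pedigree -> regscan.

#' Read a (possibly gzipped) FASTA file
#' @param path input file.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write sequences to FASTA (fixed 60-column wrap for reproducible bytes)
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, filepath = path, width = 60L)
  invisible(path)
}

#' Write a data.frame as TSV
#' @param df data.frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

families_table <- function(part, classes = NULL) {
  rows <- lapply(part$families, function(f) {
    data.frame(family = f$family_id, member = f$member_ids,
               class = if (is.null(classes)) NA_character_ else unname(classes[f$member_ids]),
               allele_length = f$allele_length, stringsAsFactors = FALSE)
  })
  if (length(part$singletons)) {
    rows[[length(rows) + 1L]] <- data.frame(
      family = "singleton", member = part$singletons,
      class = if (is.null(classes)) NA_character_ else unname(classes[part$singletons]),
      allele_length = NA_integer_,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(family = character(0), member = character(0),
                                      class = character(0), allele_length = integer(0))
  out
}

#' Run the full FibH analysis pipeline on a synthetic cohort
#'
#' Chains simulate, extract, anatomy, compare, pedigree and regscan, writing
#' all stage outputs and a JSON manifest into `out_dir`. Re-running with the
#' same configuration and seed reproduces byte-identical text outputs.
#'
#' @param spec a [synth_cohort_spec()] (its seed drives all randomness).
#' @param out_dir output directory (created if missing).
#' @param barcodes a [barcode_pair()].
#' @param elements element definitions for the regscan stage.
#' @param tree_max_n cap on the number of strains entering the UPGMA tree
#'   (largest strains by family size first); NULL for no cap.
#' @return (invisibly) a list with every stage's in-memory results.
#' @export
run_pipeline <- function(spec = synth_cohort_spec(), out_dir,
                         barcodes = default_barcodes(),
                         elements = default_elements(),
                         tree_max_n = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = spec$seed, stages = list())
  t0 <- Sys.time()

  # -- stage 1: simulate ----------------------------------------------------
  cohort <- make_cohort(spec)
  write_fasta(cohort$sequences, file.path(out_dir, "chromosomes.fa"))
  write_tsv(cohort$truth, file.path(out_dir, "truth.tsv"))
  manifest$stages$simulate <- list(n_strains = nrow(cohort$truth))

  # -- stage 2: extract -----------------------------------------------------
  ex <- extract_cohort(cohort$sequences, barcodes, spec$flank_len)
  write_tsv(ex$report, file.path(out_dir, "extraction_report.tsv"))
  gene_records <- unlist(lapply(ex$loci, function(l) {
    stats::setNames(list(l$gene_seq, l$upstream_seq, l$downstream_seq),
                    paste0(l$strain_id, c("_gene", "_upstream", "_downstream")))
  }), recursive = FALSE)
  write_fasta(unlist(gene_records), file.path(out_dir, "loci.fa"))
  flagged <- vapply(ex$loci, function(l)
    any(l$qc_flags %in% c("POLY_N", "POLY_G", "NON_ACGTN")), TRUE)
  keep <- names(ex$loci)[!flagged]
  manifest$stages$extract <- list(
    n_input = length(cohort$sequences),
    n_extracted = length(ex$loci),
    n_qc_excluded = sum(flagged),
    n_passed = length(keep))

  classes <- stats::setNames(cohort$truth$class, cohort$truth$strain_id)

  # -- stage 3: anatomy -----------------------------------------------------
  anatomies <- lapply(ex$loci[keep], function(l) annotate_gene(l$gene_seq))
  anat_rows <- lapply(keep, function(id) {
    a <- anatomies[[id]]
    data.frame(
      strain_id = id, class = unname(classes[id]),
      gene_length = nchar(ex$loci[[id]]$gene_seq),
      exon1_len = a$exon1[2] - a$exon1[1],
      intron_len = a$intron[2] - a$intron[1],
      exon2_len = a$exon2[2] - a$exon2[1],
      tnr5_len = a$tnr5[2] - a$tnr5[1],
      rc_len = a$rc[2] - a$rc[1],
      tnr3_len = a$tnr3[2] - a$tnr3[1],
      gc = a$gc_fraction,
      n_ndei = length(a$amorphous_sites),
      motif_coverage = a$motif_coverage,
      diagnostics = paste(a$diagnostics, collapse = ","),
      stringsAsFactors = FALSE)
  })
  anatomy_df <- do.call(rbind, anat_rows)
  write_tsv(anatomy_df, file.path(out_dir, "anatomy.tsv"))
  peptides <- vapply(anatomies, function(a) a$translation, "")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(peptides),
                              filepath = file.path(out_dir, "peptides.fa"),
                              width = 60L)
  manifest$stages$anatomy <- list(n_annotated = length(anatomies))

  # -- stage 4: compare -----------------------------------------------------
  region_seq <- function(id, what) {
    a <- anatomies[[id]]
    slice_gene(ex$loci[[id]]$gene_seq, a[[what]])
  }
  idr <- list()
  for (scope in c("tnr5", "tnr3", "intron")) {
    seqs <- stats::setNames(vapply(keep, region_seq, "", what = scope), keep)
    idr[[toupper(scope)]] <- group_identity(seqs, scope = toupper(scope), cohort = "all")
  }
  for (cl in unique(unname(classes[keep]))) {
    members <- keep[classes[keep] == cl]
    if (length(members) >= 2L) {
      seqs <- stats::setNames(vapply(members, region_seq, "", what = "rc"), members)
      idr[[paste0("RC_", cl)]] <- group_identity(seqs, scope = "RC", cohort = cl)
    }
  }
  idr_df <- do.call(rbind, lapply(idr, function(r) data.frame(
    scope = r$scope, cohort = r$cohort, identity_percent = r$identity_percent,
    n_sequences = r$n_sequences, alignment_length = r$alignment_length,
    stringsAsFactors = FALSE)))
  write_tsv(idr_df, file.path(out_dir, "identity_report.tsv"))

  # differential sequences between length-adjacent cores within a class
  diff_rows <- list()
  for (cl in unique(unname(classes[keep]))) {
    members <- keep[classes[keep] == cl]
    if (length(members) < 2L) next
    rcs <- stats::setNames(vapply(members, region_seq, "", what = "rc"), members)
    members <- members[order(nchar(rcs), members)]
    for (i in seq_len(length(members) - 1L)) {
      a <- members[i]; b <- members[i + 1L]
      blocks <- differential_sequence(rcs[[a]], rcs[[b]])
      if (nrow(blocks)) {
        blocks$strain_a <- a; blocks$strain_b <- b
        diff_rows[[length(diff_rows) + 1L]] <- blocks
      }
    }
  }
  diff_df <- if (length(diff_rows)) do.call(rbind, diff_rows) else
    data.frame(kind = character(0), position = integer(0), length = integer(0),
               seq = character(0), peptide = character(0), group = character(0),
               pair_complex = logical(0), strain_a = character(0),
               strain_b = character(0), stringsAsFactors = FALSE)
  # long Group 4 blocks are truncated for the report (full length retained)
  diff_df$seq <- ifelse(nchar(diff_df$seq) > 60L,
                        paste0(substr(diff_df$seq, 1L, 57L), "..."), diff_df$seq)
  write_tsv(diff_df, file.path(out_dir, "differential_sequences.tsv"))
  manifest$stages$compare <- list(
    n_identity_reports = length(idr), n_diff_blocks = nrow(diff_df))

  # -- stage 5: pedigree ----------------------------------------------------
  genes <- stats::setNames(vapply(ex$loci[keep], function(l) l$gene_seq, ""), keep)
  part <- family_partition(genes, classes)
  write_tsv(families_table(part, classes), file.path(out_dir, "families.tsv"))
  tree_ids <- keep
  if (!is.null(tree_max_n) && length(tree_ids) > tree_max_n) {
    ord <- order(!(tree_ids %in% unlist(lapply(part$families, `[[`, "member_ids"))),
                 tree_ids)
    tree_ids <- tree_ids[ord][seq_len(tree_max_n)]
  }
  tree <- NULL
  if (length(tree_ids) >= 2L) {
    dm <- gene_distance_matrix(genes[tree_ids])
    tree <- upgma(dm)
    write_newick(tree, file.path(out_dir, "pedigree.nwk"))
  }
  summ <- opti_allele_summary(part, total_known = length(keep))
  jsonlite::write_json(summ, file.path(out_dir, "pedigree_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$pedigree <- list(
    n_families = length(part$families), n_singletons = length(part$singletons),
    n_in_tree = length(tree_ids))

  # -- stage 6: regscan -----------------------------------------------------
  hits <- do.call(rbind, lapply(keep, function(id)
    scan_elements(ex$loci[[id]], elements, anatomies[[id]])))
  write_tsv(hits, file.path(out_dir, "element_hits.tsv"))
  pres <- element_presence(hits, keep, elements)
  write_tsv(data.frame(strain_id = rownames(pres), pres, check.names = FALSE),
            file.path(out_dir, "element_presence.tsv"))
  cons <- list()
  for (region in c("UPSTREAM", "INTRON", "DOWNSTREAM")) {
    seqs <- stats::setNames(vapply(keep, function(id)
      region_sequence(ex$loci[[id]], region, anatomies[[id]]), ""), keep)
    cons[[region]] <- conservation_report(seqs, classes)
  }
  utr3 <- vapply(keep, function(id) extract_utr3(ex$loci[[id]]$downstream_seq), "")
  cons$UTR3_distinct <- length(unique(utr3))
  jsonlite::write_json(cons, file.path(out_dir, "conservation.json"),
                       auto_unbox = TRUE, digits = NA)
  manifest$stages$regscan <- list(
    n_hits = nrow(hits),
    n_regions = 3L)

  manifest$elapsed_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  manifest$package_version <- as.character(utils::packageVersion("fibhome"))
  manifest_out <- manifest
  manifest_out$elapsed_sec <- NULL # keep manifests byte-identical across runs
  jsonlite::write_json(manifest_out, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, extraction = ex, anatomies = anatomies,
                 identity_reports = idr, diffs = diff_df, families = part,
                 tree = tree, opti = summ, element_hits = hits,
                 conservation = cons, manifest = manifest_out,
                 out_dir = out_dir))
}
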