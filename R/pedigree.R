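# Pedigree families from identical FibH alleles and UPGMA clustering.

#' Partition strains into identical-allele families
#'
#' Strains with byte-identical gene sequences form a family; strains whose
#' allele is unique remain singletons ("could not be clustered"). Families
#' are named with Roman numerals by decreasing size, then decreasing allele
#' length; members are sorted lexicographically.
#'
#' @param strains named character vector: strain id -> gene sequence.
#'   QC-flagged strains must already have been excluded.
#' @param classes optional named character vector: strain id -> class label,
#'   used for the per-family class composition.
#' @return list with `families` (list of `family` objects: `family_id`,
#'   `member_ids`, `allele_length`, `representative_seq`,
#'   `class_composition`) and `singletons` (character vector).
#' @export
family_partition <- function(strains, classes = NULL) {
  stopifnot(is.character(strains), !is.null(names(strains)))
  groups <- split(names(strains), unname(strains))
  sizes <- lengths(groups)
  fam_groups <- groups[sizes >= 2L]
  singles <- sort(unlist(groups[sizes == 1L], use.names = FALSE))
  if (length(fam_groups) > 0L) {
    lens <- nchar(names(fam_groups))
    ord <- order(-lengths(fam_groups), -lens)
    fam_groups <- fam_groups[ord]
  }
  families <- lapply(seq_along(fam_groups), function(i) {
    members <- sort(fam_groups[[i]])
    allele <- names(fam_groups)[i]
    comp <- NULL
    if (!is.null(classes)) {
      comp <- table(factor(classes[members],
                           levels = c("wild", "local", "improved")))
    }
    structure(list(
      family_id = roman_numeral(i),
      member_ids = members,
      allele_length = nchar(allele),
      representative_seq = allele,
      class_composition = comp
    ), class = "fibh_family")
  })
  list(families = families, singletons = singles)
}

#' @export
print.fibh_family <- function(x, ...) {
  cat(sprintf("<family %s> %d members, allele %d bp: %s\n",
              x$family_id, length(x$member_ids), x$allele_length,
              paste(x$member_ids, collapse = ", ")))
  invisible(x)
}

#' Distance matrix from gene sequences
#'
#' Distance is 1 - identity/100 under global alignment.
#'
#' @param seqs named character vector of gene sequences.
#' @return symmetric numeric matrix with zero diagonal.
#' @export
gene_distance_matrix <- function(seqs) {
  1 - identity_matrix(seqs) / 100
}

#' UPGMA clustering
#'
#' Average-linkage agglomeration with cluster-size weighting; node height is
#' half the merge distance, so the tree is rooted and ultrametric. Ties are
#' broken deterministically by merging the lexicographically smallest label
#' pair first (a cluster is labelled by its smallest member).
#'
#' @param dist symmetric distance matrix (or `dist` object) with zero
#'   diagonal; entries must be finite and non-negative.
#' @return an `ape` "phylo" tree with branch lengths.
#' @export
upgma <- function(dist) {
  if (inherits(dist, "dist")) dist <- as.matrix(dist)
  n <- nrow(dist)
  if (is.null(rownames(dist))) {
    rownames(dist) <- colnames(dist) <- paste0("t", seq_len(n))
  }
  if (n < 2L) stop_fibh("fibh_config_error", "upgma requires >= 2 taxa")
  if (any(!is.finite(dist)) || any(dist < 0)) {
    stop_fibh("fibh_config_error", "distances must be finite and non-negative")
  }
  if (any(abs(dist - t(dist)) > 1e-12)) {
    stop_fibh("fibh_config_error", "distance matrix must be symmetric")
  }
  ids <- rownames(dist)
  active <- seq_len(n)
  size <- rep(1L, n)
  height <- rep(0, n)
  newick <- ids           # growing subtree strings
  label <- ids            # tie-break label: smallest member id
  d <- dist
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    best <- NULL
    best_d <- Inf
    for (ii in seq_len(k - 1L)) {
      for (jj in (ii + 1L):k) {
        i <- active[ii]; j <- active[jj]
        dij <- d[i, j]
        lab <- sort(c(label[i], label[j]))
        if (dij < best_d - 1e-15) {
          best_d <- dij; best <- c(i, j); best_lab <- lab
        } else if (abs(dij - best_d) <= 1e-15) {
          if (lab[1] < best_lab[1] ||
              (lab[1] == best_lab[1] && lab[2] < best_lab[2])) {
            best <- c(i, j); best_lab <- lab
          }
        }
      }
    }
    i <- best[1]; j <- best[2]
    h <- best_d / 2
    bi <- h - height[i]
    bj <- h - height[j]
    new_idx <- length(size) + 1L
    size[new_idx] <- size[i] + size[j]
    height[new_idx] <- h
    newick[new_idx] <- sprintf("(%s:%.17g,%s:%.17g)",
                               newick[i], bi, newick[j], bj)
    label[new_idx] <- min(label[i], label[j])
    # average-linkage update over all remaining clusters
    d <- rbind(cbind(d, 0), 0)
    for (m in setdiff(active, c(i, j))) {
      d[new_idx, m] <- d[m, new_idx] <-
        (size[i] * d[i, m] + size[j] * d[j, m]) / (size[i] + size[j])
    }
    active <- c(setdiff(active, c(i, j)), new_idx)
  }
  tree <- ape::read.tree(text = paste0(newick[length(newick)], ";"))
  tree
}

#' Write a tree in Newick format
#'
#' @param tree an `ape` "phylo" object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Modal-allele (Opti-FibH style) summary
#'
#' Identifies the modal allele (largest family), its length and carrier
#' count, and the carrier percentage of all known genes.
#'
#' @param families result of [family_partition()] (or its `families` field).
#' @param total_known total number of known gene sequences the percentage
#'   refers to (may include strains from outside the current cohort).
#' @param extra_carriers carriers of the modal allele known from outside the
#'   current cohort.
#' @return list: `allele_length`, `carriers`, `total_known`, `percent`
#'   (2 decimals).
#' @export
opti_allele_summary <- function(families, total_known, extra_carriers = 0L) {
  if (!is.null(families$families)) families <- families$families
  carriers <- if (length(families) == 0L) 0L else length(families[[1L]]$member_ids)
  carriers <- carriers + as.integer(extra_carriers)
  if (total_known < carriers) {
    stop_fibh("fibh_config_error", "total_known smaller than carrier count")
  }
  list(
    allele_length = if (length(families)) families[[1L]]$allele_length else NA_integer_,
    carriers = carriers,
    total_known = as.integer(total_known),
    percent = round(100 * carriers / total_known, 2L)
  )
}
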