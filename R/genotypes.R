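#' Impute strain mitochondrial genotypes from founder haplotypes
#'
#' Mitochondria are maternally inherited without recombination, so every CC
#' strain carries the complete mitochondrial genome of one founder. A strain's
#' genotype at every marker is therefore read directly off the founder allele
#' table through its recorded maternal haplotype; no probabilistic imputation
#' is involved. Strains sharing a haplotype get identical rows, so the matrix
#' has at most as many distinct rows as there are founders.
#'
#' Dosage coding: per marker, the major allele (most frequent among the
#' founders, ties broken alphabetically) is coded 0; for biallelic markers the
#' minor allele is coded 1. Markers with more than two founder alleles get
#' codes 1, 2, ... in decreasing allele frequency (ties alphabetical); the
#' association engine treats those via a joint F-test on the allele factor.
#'
#' @param strain_table data.frame with columns `strain_id`, `haplotype`.
#' @param marker_table data.frame with columns `marker_id`, `position_bp`, and
#'   one `allele_<founder>` column per founder.
#' @param founders founder labels; defaults to the `allele_*` columns present.
#' @param mt_genome_length maximum valid 1-based marker coordinate.
#' @return an object of class `genotype_matrix`: strain ids, marker ids and
#'   positions, an allele character matrix, a numeric dosage matrix, and the
#'   per-marker allele-to-code map.
#' @export
impute_genotypes <- function(strain_table, marker_table, founders = NULL,
                             mt_genome_length = 16299) {
  acols <- grep("^allele_", names(marker_table), value = TRUE)
  if (is.null(founders)) founders <- sub("^allele_", "", acols)
  missing_cols <- setdiff(paste0("allele_", founders), names(marker_table))
  if (length(missing_cols)) {
    stop("marker table lacks allele columns for founder(s): ",
         paste(sub("^allele_", "", missing_cols), collapse = ", "), call. = FALSE)
  }
  bad_hap <- setdiff(unique(strain_table$haplotype), founders)
  if (length(bad_hap)) {
    stop("unknown haplotype label(s): ", paste(bad_hap, collapse = ", "),
         call. = FALSE)
  }
  if (any(marker_table$position_bp < 1 | marker_table$position_bp > mt_genome_length)) {
    stop("marker position outside [1, ", mt_genome_length, "]", call. = FALSE)
  }
  n_m <- nrow(marker_table)
  fa <- as.matrix(marker_table[, paste0("allele_", founders), drop = FALSE])
  rownames(fa) <- marker_table$marker_id
  colnames(fa) <- founders
  for (i in seq_len(n_m)) {
    na_f <- founders[is.na(fa[i, ]) | fa[i, ] == ""]
    if (length(na_f)) {
      stop(sprintf("marker %s: missing founder allele for %s",
                   marker_table$marker_id[i], paste(na_f, collapse = ", ")),
           call. = FALSE)
    }
  }
  allele_map <- vector("list", n_m)
  names(allele_map) <- marker_table$marker_id
  code <- matrix(0L, length(founders), n_m,
                 dimnames = list(founders, marker_table$marker_id))
  for (i in seq_len(n_m)) {
    tab <- table(fa[i, ])
    ord <- names(tab)[order(-tab, names(tab))]  # frequency desc, ties alphabetical
    allele_map[[i]] <- stats::setNames(seq_along(ord) - 1L, ord)
    code[, i] <- allele_map[[i]][fa[i, ]]
  }
  alleles <- t(fa)[strain_table$haplotype, , drop = FALSE]
  dosage <- code[strain_table$haplotype, , drop = FALSE]
  rownames(alleles) <- rownames(dosage) <- strain_table$strain_id
  structure(list(strain_ids = strain_table$strain_id,
                 marker_ids = marker_table$marker_id,
                 position_bp = stats::setNames(marker_table$position_bp,
                                               marker_table$marker_id),
                 haplotypes = stats::setNames(strain_table$haplotype,
                                              strain_table$strain_id),
                 alleles = alleles, dosage = dosage, allele_map = allele_map),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d strains x %d markers (%d distinct rows)\n",
              length(x$strain_ids), length(x$marker_ids),
              nrow(unique(x$dosage))))
  invisible(x)
}

#' Group markers by strain-distribution pattern
#'
#' Markers whose dosage columns induce the same partition of strains (up to
#' allele relabeling, i.e. including complementary biallelic columns) are
#' statistically identical in any association scan. This reports those groups,
#' each with a representative marker (lowest genome position) and, for
#' biallelic markers, whether a member's coding is the complement of its
#' representative's.
#'
#' @param g a `genotype_matrix`.
#' @return data.frame with columns `marker_id`, `group`, `representative`,
#'   `complement` (logical).
#' @export
distinct_patterns <- function(g) {
  if (length(g$marker_ids) == 0) stop("empty genotype matrix", call. = FALSE)
  # canonical key: first-occurrence relabeling of the allele column, which is
  # invariant to which allele is called major/minor
  keys <- apply(g$dosage, 2, function(col) {
    paste(match(col, unique(col)), collapse = ",")
  })
  grp <- match(keys, unique(keys))
  out <- data.frame(marker_id = g$marker_ids, group = grp,
                    stringsAsFactors = FALSE)
  rep_of <- vapply(split(seq_along(grp), grp), function(ix) {
    ix[which.min(g$position_bp[ix])]
  }, integer(1))
  out$representative <- g$marker_ids[rep_of[as.character(grp)]]
  out$complement <- vapply(seq_along(grp), function(i) {
    r <- match(out$representative[i], g$marker_ids)
    !identical(unname(g$dosage[, i]), unname(g$dosage[, r]))
  }, logical(1))
  out
}

#' Read a strain table from CSV
#' @param path CSV with columns `strain_id`, `haplotype`.
#' @export
read_strain_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Read a marker table from CSV
#' @param path CSV with columns `marker_id`, `position_bp`, `allele_<founder>`.
#' @export
read_marker_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write genotype allele and dosage matrices as TSV
#' @param g a `genotype_matrix`.
#' @param allele_path,dosage_path output paths (either may be NULL to skip).
#' @export
write_genotypes <- function(g, allele_path = NULL, dosage_path = NULL) {
  if (!is.null(allele_path)) {
    utils::write.table(g$alleles, allele_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  if (!is.null(dosage_path)) {
    utils::write.table(g$dosage, dosage_path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(g)
}
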