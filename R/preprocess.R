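#' Z-transform a vector
#'
#' Centers and scales the non-missing entries to mean 0 and sample standard
#' deviation 1 (denominator n-1); missing entries are preserved in place.
#'
#' @param x numeric vector, NAs allowed.
#' @param name label used in error messages (e.g. the trait name).
#' @return numeric vector of the same length.
#' @export
z_transform <- function(x, name = deparse(substitute(x))) {
  obs <- x[!is.na(x)]
  if (length(obs) < 2) {
    stop(sprintf("cannot z-transform '%s': fewer than 2 observed values", name),
         call. = FALSE)
  }
  s <- stats::sd(obs)
  if (!is.finite(s) || s == 0) {
    stop(sprintf("cannot z-transform '%s': zero variance", name), call. = FALSE)
  }
  (x - mean(obs)) / s
}

#' Remove categorical covariate effects by ordinary least squares
#'
#' Fits `y ~ covariates` (all covariates treated as factors, with intercept)
#' and returns the residuals. Rows with missing `y` are skipped in the fit and
#' returned as NA. The design must be full rank after reference-level drops;
#' aliased columns are reported by name.
#'
#' @param y numeric response.
#' @param covariates data.frame of factors aligned with `y`.
#' @return numeric residual vector, same length as `y`.
#' @export
residualize <- function(y, covariates) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != length(y)) {
    stop("y and covariates have different lengths", call. = FALSE)
  }
  X <- covariate_design(covariates)
  obs <- !is.na(y)
  qr_x <- qr(X[obs, , drop = FALSE])
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate design; aliased: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  out <- rep(NA_real_, length(y))
  out[obs] <- qr.resid(qr_x, y[obs])
  out
}

covariate_design <- function(covariates) {
  if (ncol(covariates) == 0) {
    return(matrix(1, nrow(covariates), 1, dimnames = list(NULL, "(Intercept)")))
  }
  covariates[] <- lapply(covariates, function(v) {
    if (is.numeric(v)) v else factor(v)
  })
  stats::model.matrix(~ ., data = covariates)
}

# Residualize every column of a (units x features) matrix on the same design.
residualize_matrix <- function(Y, covariates) {
  X <- covariate_design(as.data.frame(covariates))
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate design; aliased: ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
  qr.resid(qr_x, Y)
}

#' Collapse unit-level values to strain means
#'
#' Takes an animal- or sample-level matrix and averages rows within strain for
#' one treatment arm. Means are unweighted over the strain's units; per
#' feature, missing values are dropped from the mean and an all-missing cell
#' stays NA. Strains with no units in the arm are dropped and reported via the
#' `"dropped"` attribute.
#'
#' @param values numeric matrix, units x features, rownames = unit ids.
#' @param sample_table data.frame with `sample_id`, `strain_id`, `treatment`.
#' @param arm treatment arm to collapse.
#' @return strain x feature matrix with strain ids as rownames.
#' @export
collapse_to_strain <- function(values, sample_table, arm) {
  st <- sample_table[sample_table$treatment == arm, , drop = FALSE]
  if (nrow(st) == 0) stop("no samples in arm '", arm, "'", call. = FALSE)
  st <- st[st$sample_id %in% rownames(values), , drop = FALSE]
  if (nrow(st) == 0) stop("no rows of 'values' belong to arm '", arm, "'",
                          call. = FALSE)
  v <- values[st$sample_id, , drop = FALSE]
  strains <- sort(unique(st$strain_id))
  out <- matrix(NA_real_, length(strains), ncol(v),
                dimnames = list(strains, colnames(v)))
  grp <- match(st$strain_id, strains)
  for (j in seq_len(ncol(v))) {
    ok <- !is.na(v[, j])
    if (any(ok)) {
      s <- rowsum(v[ok, j], grp[ok])
      n <- rowsum(rep(1, sum(ok)), grp[ok])
      out[as.integer(rownames(s)), j] <- s / n
    }
  }
  all_strains <- unique(sample_table$strain_id)
  attr(out, "dropped") <- setdiff(all_strains, strains)
  out
}

#' Filter lowly expressed genes
#'
#' A gene is retained when it has at least `min_count` counts in at least
#' `min_fraction` of the samples (both bounds inclusive).
#'
#' @param counts integer matrix, genes x samples.
#' @param min_count minimum count per sample (default 10).
#' @param min_fraction minimum fraction of samples meeting it (default 0.5).
#' @return character vector of retained gene ids.
#' @export
filter_genes <- function(counts, min_count = 10, min_fraction = 0.5) {
  if (is.null(dim(counts)) || nrow(counts) == 0 || ncol(counts) == 0) {
    stop("empty count matrix", call. = FALSE)
  }
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  frac <- rowMeans(counts >= min_count)
  rownames(counts)[frac >= min_fraction]
}

#' Log2 counts-per-million normalization
#'
#' Returns `log2(1e6 * count / library_size + 1)` per cell, where the library
#' size is the per-sample column sum over the genes present in the matrix
#' (i.e. after filtering).
#'
#' @param counts integer matrix, genes x samples.
#' @return numeric matrix of the same shape.
#' @export
normalize_counts <- function(counts) {
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "), call. = FALSE)
  }
  log2(sweep(counts, 2, lib / 1e6, "/") + 1)
}

#' Strain-level trait matrix for one arm
#'
#' The trait-GWAS preprocessing path: within the arm, each trait is
#' z-transformed across animals, residualized on the nuisance covariates
#' (sex and experimenter by default), and collapsed to unweighted strain
#' means. Missing trait values are dropped per trait, not per animal.
#'
#' @param trait_table data.frame with `sample_id` plus one column per trait.
#' @param sample_table sample metadata (see [collapse_to_strain()]).
#' @param arm treatment arm.
#' @param covariates covariate column names in `sample_table`.
#' @param traits trait columns to process (default: all non-id columns).
#' @return strain x trait matrix.
#' @export
prepare_trait_matrix <- function(trait_table, sample_table, arm,
                                 covariates = c("sex", "experimenter"),
                                 traits = NULL) {
  if (is.null(traits)) traits <- setdiff(names(trait_table), "sample_id")
  st <- sample_table[sample_table$treatment == arm, , drop = FALSE]
  if (nrow(st) == 0) stop("no samples in arm '", arm, "'", call. = FALSE)
  tt <- trait_table[match(st$sample_id, trait_table$sample_id), , drop = FALSE]
  resid <- matrix(NA_real_, nrow(st), length(traits),
                  dimnames = list(st$sample_id, traits))
  cov_df <- st[, covariates, drop = FALSE]
  for (tr in traits) {
    z <- z_transform(tt[[tr]], name = tr)
    resid[, tr] <- residualize(z, cov_df)
  }
  collapse_to_strain(resid, sample_table, arm)
}

#' Strain-level expression matrix for one arm
#'
#' The trans-eQTL preprocessing path: genes are filtered on the full count
#' matrix (all samples), log2-CPM normalized, then within the arm residualized
#' on the expression nuisance covariates (sex and library plate by default)
#' and collapsed to unweighted strain means.
#'
#' @param counts integer matrix, genes x samples.
#' @param sample_table sample metadata.
#' @param arm treatment arm.
#' @param covariates covariate column names in `sample_table`.
#' @param min_count,min_fraction filtering rule (see [filter_genes()]).
#' @return strain x gene matrix; retained gene ids in attribute `"genes"`.
#' @export
prepare_expression_matrix <- function(counts, sample_table, arm,
                                      covariates = c("sex", "plate"),
                                      min_count = 10, min_fraction = 0.5) {
  keep <- filter_genes(counts, min_count, min_fraction)
  if (length(keep) == 0) stop("no genes pass the expression filter", call. = FALSE)
  norm <- normalize_counts(counts[keep, , drop = FALSE])
  st <- sample_table[sample_table$treatment == arm, , drop = FALSE]
  if (nrow(st) == 0) stop("no samples in arm '", arm, "'", call. = FALSE)
  Y <- t(norm[, st$sample_id, drop = FALSE])  # samples x genes
  Yr <- residualize_matrix(Y, st[, covariates, drop = FALSE])
  rownames(Yr) <- st$sample_id
  out <- collapse_to_strain(Yr, sample_table, arm)
  attr(out, "genes") <- keep
  out
}
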