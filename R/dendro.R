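#' Pairwise p-distance between aligned sequences
#'
#' Proportion of mismatching sites between each pair of equal-length aligned
#' sequences. Alignment columns where either sequence carries a gap character
#' (`-` or `.`) are excluded from both the numerator and the denominator of
#' that pair.
#'
#' @param seqs named character vector of aligned sequences (or list of
#'   per-site character vectors), length >= 2.
#' @return symmetric numeric matrix of p-distances with sequence names.
#' @export
sequence_distance <- function(seqs) {
  if (is.list(seqs)) seqs <- vapply(seqs, paste, character(1), collapse = "")
  if (length(seqs) < 2) stop("need at least 2 sequences", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1) {
    stop("sequences must be equal length (aligned)", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  gap <- mat == "-" | mat == "."
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- !gap[i, ] & !gap[j, ]
      if (!any(ok)) {
        stop(sprintf("no comparable sites between '%s' and '%s'",
                     rownames(mat)[i], rownames(mat)[j]), call. = FALSE)
      }
      D[i, j] <- D[j, i] <- sum(mat[i, ok] != mat[j, ok]) / sum(ok)
    }
  }
  D
}

#' Agglomerative hierarchical clustering
#'
#' Standard agglomerative clustering of items in rows, via [stats::hclust()].
#' Items are re-ordered by label before clustering so that distance ties are
#' broken deterministically regardless of input order. Trait matrices should
#' be z-scored upstream (as [compare_trait_sequence_trees()] does).
#'
#' @param x items x features numeric matrix, or a distance matrix / `dist`
#'   when `distance = "precomputed"`.
#' @param distance `"euclidean"` or `"precomputed"`.
#' @param linkage `"average"` (UPGMA), `"complete"`, or `"ward"` (ward.D2).
#' @return an `hclust` object.
#' @export
hcluster <- function(x, distance = c("euclidean", "precomputed"),
                     linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (distance == "precomputed") {
    d <- stats::as.dist(as.matrix(x))
  } else {
    if (anyNA(x)) stop("missing values in the matrix; impute before clustering",
                       call. = FALSE)
    x <- x[order(rownames(x)), , drop = FALSE]
    d <- stats::dist(x, method = "euclidean")
  }
  if (anyNA(d)) stop("missing values in the distance matrix", call. = FALSE)
  m <- as.matrix(d)
  ord <- order(rownames(m))
  d <- stats::as.dist(m[ord, ord])
  method <- c(average = "average", complete = "complete", ward = "ward.D2")[linkage]
  stats::hclust(d, method = method)
}

#' Cophenetic distance matrix of a dendrogram
#'
#' Entry (i, j) is the merge height at which leaves i and j first join;
#' the diagonal is 0.
#'
#' @param h an `hclust` object.
#' @return symmetric numeric matrix with leaf labels.
#' @export
cophenetic_matrix <- function(h) {
  m <- as.matrix(stats::cophenetic(h))
  diag(m) <- 0
  m
}

#' Cophenetic correlation between two dendrograms
#'
#' Pearson correlation between the lower-triangle cophenetic distances of two
#' trees over the same leaf set (pairs ordered identically). +1 indicates
#' perfectly preserved pairwise structure, 0 none, -1 inversion. Height
#' rescaling of either tree leaves the value unchanged.
#'
#' @param d1,d2 `hclust` objects on identical label sets (>= 3 leaves).
#' @return correlation in [-1, 1], or NA with a warning when either tree's
#'   cophenetic distances have zero variance.
#' @export
cpcc <- function(d1, d2) {
  if (!setequal(d1$labels, d2$labels)) {
    stop("dendrograms have different leaf label sets", call. = FALSE)
  }
  if (length(d1$labels) < 3) stop("need at least 3 leaves", call. = FALSE)
  labs <- sort(d1$labels)
  m1 <- cophenetic_matrix(d1)[labs, labs]
  m2 <- cophenetic_matrix(d2)[labs, labs]
  v1 <- m1[lower.tri(m1)]
  v2 <- m2[lower.tri(m2)]
  if (stats::sd(v1) == 0 || stats::sd(v2) == 0) {
    warning("zero variance in cophenetic distances; CPCC undefined")
    return(NA_real_)
  }
  stats::cor(v1, v2)
}

#' Classical tree-vs-data cophenetic correlation
#'
#' Correlation between a dendrogram's cophenetic distances and the original
#' data distances it was built from.
#'
#' @param h an `hclust` object.
#' @param d the `dist` (or distance matrix) the tree was built from.
#' @return Pearson correlation.
#' @export
cpcc_tree_data <- function(h, d) {
  m <- as.matrix(d)
  labs <- sort(h$labels)
  cm <- cophenetic_matrix(h)[labs, labs]
  dm <- m[labs, labs]
  stats::cor(cm[lower.tri(cm)], dm[lower.tri(dm)])
}

#' Entanglement between two leaf orders
#'
#' With u_i the rank of label i in `order1` and v_i its rank in `order2`, the
#' entanglement is `sum(|u - v|^L)` normalized by its worst case, the identity
#' order against its full reversal. 0 means identical orders; 1 means fully
#' reversed.
#'
#' @param order1,order2 character vectors: the same label set in two orders.
#' @param L exponent (default 1.5).
#' @return entanglement in [0, 1].
#' @export
entanglement <- function(order1, order2, L = 1.5) {
  if (!setequal(order1, order2) || length(order1) != length(order2)) {
    stop("orders must be permutations of the same label set", call. = FALSE)
  }
  n <- length(order1)
  u <- seq_len(n)
  v <- match(order1, order2)
  denom <- sum(abs(seq_len(n) - (n + 1 - seq_len(n)))^L)
  if (denom == 0) return(0)
  sum(abs(u - v)^L) / denom
}

# Leaf order of an hclust tree under a per-internal-node flip state.
# flips: logical vector, one per merge row; TRUE swaps that node's children.
leaf_order_flips <- function(h, flips) {
  n1 <- nrow(h$merge)
  orders <- vector("list", n1)
  for (k in seq_len(n1)) {
    ch <- lapply(h$merge[k, ], function(c) {
      if (c < 0) -c else orders[[c]]
    })
    if (flips[k]) ch <- rev(ch)
    orders[[k]] <- c(ch[[1]], ch[[2]])
  }
  h$labels[orders[[n1]]]
}

all_flip_orders <- function(h) {
  n1 <- nrow(h$merge)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n1))
  t(apply(combos, 1, function(f) leaf_order_flips(h, as.logical(f))))
}

#' Untangle two dendrograms
#'
#' Searches over internal-node rotations (child flips) of both trees for leaf
#' orders minimizing the entanglement. The search is a deterministic greedy
#' alternating sweep: nodes of tree 1 then tree 2 are visited in order and a
#' flip is kept only when it strictly lowers the entanglement; sweeps repeat
#' until one passes with no change. For trees with at most `exhaustive_max`
#' leaves an exhaustive search over all rotation combinations is also run and
#' reported alongside (the greedy value can never be below it).
#'
#' @param d1,d2 `hclust` objects on the same label set.
#' @param L entanglement exponent.
#' @param exhaustive_max run the exhaustive search when both trees have at
#'   most this many leaves (default 8; set to 0 to disable).
#' @return list: `order1`, `order2`, `entanglement` (greedy optimum),
#'   `entanglement_exhaustive` (NA when not run), `cpcc`.
#' @export
untangle <- function(d1, d2, L = 1.5, exhaustive_max = 8) {
  if (!setequal(d1$labels, d2$labels)) {
    stop("dendrograms have different leaf label sets", call. = FALSE)
  }
  f1 <- rep(FALSE, nrow(d1$merge))
  f2 <- rep(FALSE, nrow(d2$merge))
  o1 <- leaf_order_flips(d1, f1)
  o2 <- leaf_order_flips(d2, f2)
  e <- entanglement(o1, o2, L)
  repeat {
    changed <- FALSE
    for (k in seq_along(f1)) {
      f1[k] <- !f1[k]
      cand <- leaf_order_flips(d1, f1)
      ec <- entanglement(cand, o2, L)
      if (ec < e) { e <- ec; o1 <- cand; changed <- TRUE } else f1[k] <- !f1[k]
    }
    for (k in seq_along(f2)) {
      f2[k] <- !f2[k]
      cand <- leaf_order_flips(d2, f2)
      ec <- entanglement(o1, cand, L)
      if (ec < e) { e <- ec; o2 <- cand; changed <- TRUE } else f2[k] <- !f2[k]
    }
    if (!changed) break
  }
  e_ex <- NA_real_
  n <- length(d1$labels)
  if (exhaustive_max > 0 && n <= exhaustive_max) {
    ord1 <- all_flip_orders(d1)
    ord2 <- all_flip_orders(d2)
    labs <- sort(d1$labels)
    U <- t(apply(ord1, 1, function(o) match(labs, o)))
    V <- t(apply(ord2, 1, function(o) match(labs, o)))
    denom <- sum(abs(seq_len(n) - (n + 1 - seq_len(n)))^L)
    e_ex <- Inf
    for (i in seq_len(nrow(U))) {
      vals <- rowSums(abs(matrix(U[i, ], nrow(V), n, byrow = TRUE) - V)^L) / denom
      m <- min(vals)
      if (m < e_ex) e_ex <- m
    }
  }
  list(order1 = o1, order2 = o2, entanglement = e,
       entanglement_exhaustive = e_ex, cpcc = cpcc(d1, d2))
}

#' Compare a trait dendrogram with a sequence dendrogram
#'
#' Builds the two dendrograms compared in a tanglegram: haplotype-level traits
#' (columns z-scored, euclidean distance) and founder mitochondrial sequences
#' (precomputed p-distances), both under the chosen linkage. The trees are
#' untangled and the entanglement score and tree-vs-tree cophenetic
#' correlation are reported. Low entanglement with high CPCC indicates that
#' haplotypes with similar mitochondrial sequences also have similar traits.
#'
#' @param trait_matrix haplotype x trait numeric matrix.
#' @param distances founder distance matrix (or `dist`) with matching labels.
#' @param L entanglement exponent.
#' @param linkage linkage for both trees.
#' @param exhaustive_max passed to [untangle()].
#' @return list: `entanglement`, `cpcc`, `order_traits`, `order_sequences`,
#'   `tree_traits`, `tree_sequences`.
#' @export
compare_trait_sequence_trees <- function(trait_matrix, distances, L = 1.5,
                                         linkage = "average",
                                         exhaustive_max = 0) {
  dm <- as.matrix(distances)
  shared <- intersect(rownames(trait_matrix), rownames(dm))
  if (length(shared) < 3) stop("fewer than 3 shared labels", call. = FALSE)
  tm <- trait_matrix[shared, , drop = FALSE]
  keep <- apply(tm, 2, function(v) stats::sd(v, na.rm = TRUE) > 0)
  if (!all(keep)) {
    warning("dropping constant trait column(s): ",
            paste(colnames(tm)[!keep], collapse = ", "))
    tm <- tm[, keep, drop = FALSE]
  }
  tm <- apply(tm, 2, z_transform, name = "trait column")
  rownames(tm) <- shared
  t_tree <- hcluster(tm, distance = "euclidean", linkage = linkage)
  s_tree <- hcluster(dm[shared, shared], distance = "precomputed",
                     linkage = linkage)
  ut <- untangle(t_tree, s_tree, L = L, exhaustive_max = exhaustive_max)
  list(entanglement = ut$entanglement, cpcc = ut$cpcc,
       order_traits = ut$order1, order_sequences = ut$order2,
       tree_traits = t_tree, tree_sequences = s_tree)
}

#' Write a dendrogram as Newick
#'
#' Serializes an `hclust` tree with branch lengths derived from the merge
#' heights, via `ape`.
#'
#' @param h an `hclust` object.
#' @param path output path.
#' @export
write_newick <- function(h, path) {
  ape::write.tree(ape::as.phylo(h), path)
  invisible(path)
}
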