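# Between-sample community comparison: Sorensen index on shared clusters,
# neighbor-joining phylogeny over cluster representatives, weighted UniFrac
# distances, and principal coordinates analysis.

#' Sorensen similarity index between two samples
#'
#' `Cs = 2j / (a + b) * 100`, where `j` is the number of clusters shared by
#' the two samples and `a`, `b` the numbers of clusters present in each.
#' Returns 0 when supports are disjoint but non-empty, and `NA` when both
#' samples are empty.
#'
#' @param x A `cluster_set` or cluster x sample abundance matrix.
#' @param sample_a,sample_b Sample names.
#' @return Percent similarity in `[0, 100]` or `NA`.
#' @export
sorensen <- function(x, sample_a, sample_b) {
  oc <- overlap_count(x, sample_a, sample_b)
  if (oc[["a"]] + oc[["b"]] == 0) return(NA_real_)
  200 * oc[["j"]] / (oc[["a"]] + oc[["b"]])
}

#' Pairwise Sorensen matrix over all samples
#'
#' @param x A `cluster_set` or cluster x sample abundance matrix.
#' @return Symmetric percent-similarity matrix (diagonal 100).
#' @export
sorensen_matrix <- function(x) {
  abund <- if (inherits(x, "cluster_set")) x$abundance else x
  s <- colnames(abund)
  m <- matrix(100, length(s), length(s), dimnames = list(s, s))
  for (i in seq_along(s)) {
    for (j in seq_along(s)) {
      if (j >= i) next
      m[i, j] <- m[j, i] <- sorensen(abund, s[i], s[j])
    }
  }
  m
}

#' Neighbor-joining tree over cluster representatives
#'
#' Distances default to the p-distance `1 - identity/100` between the
#' representative peptides (no substitution-model correction). Negative
#' branch-length estimates - an artefact of the NJ least-squares step on
#' non-additive matrices - are clamped to zero, with the negative length
#' transferred to a sibling branch so root-to-tip path lengths are
#' preserved.
#'
#' @param x Named character vector of >= 3 peptides, or a square distance
#'   matrix / `dist` object.
#' @return An unrooted [ape::phylo] tree with tip labels from `names(x)`.
#' @export
nj_tree <- function(x) {
  if (is.character(x)) {
    if (length(x) < 3) stop("need at least 3 taxa")
    d <- (100 - identity_matrix(x)) / 100
  } else if (inherits(x, "dist")) {
    d <- as.matrix(x)
  } else {
    d <- as.matrix(x)
  }
  if (nrow(d) < 3) stop("need at least 3 taxa")
  if (any(!is.finite(d))) stop("distances must be finite")
  tree <- ape::nj(stats::as.dist(d))
  clamp_negative_branches(tree)
}

# Zero out negative branch lengths, moving the deficit to a sibling edge
# (first sibling in edge-table order) so path lengths through the parent
# are preserved.
clamp_negative_branches <- function(tree) {
  repeat {
    neg <- which(tree$edge.length < -1e-12)
    if (length(neg) == 0) break
    e <- neg[1]
    parent <- tree$edge[e, 1]
    sibs <- setdiff(which(tree$edge[, 1] == parent), e)
    if (length(sibs) > 0) {
      tree$edge.length[sibs[1]] <- tree$edge.length[sibs[1]] +
        tree$edge.length[e]
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

#' Weighted UniFrac distance between two samples
#'
#' Raw form: `sum_i b_i |A_i/A_T - B_i/B_T|` over all branches, where `b_i`
#' is the branch length and `A_i` the reads of sample A on leaves
#' descending from the branch. The normalized form divides by the
#' abundance-weighted tree depth `sum_j d_j (A_j/A_T + B_j/B_T)` (root-to-
#' leaf distances `d_j`), scaling the distance into `[0, 1]`. Unrooted
#' trees are midpoint-rooted for the branch-descent bookkeeping. Tree
#' leaves without abundance rows (e.g. reference sequences) carry zero
#' weight; abundance rows without a matching leaf are an error.
#'
#' @param tree An [ape::phylo] whose tip labels match `rownames(abundance)`.
#' @param abundance Cluster x sample count matrix.
#' @param sample_a,sample_b Sample names.
#' @param normalized Return the normalized form.
#' @return Non-negative distance.
#' @export
weighted_unifrac <- function(tree, abundance, sample_a, sample_b,
                             normalized = FALSE) {
  missing_leaves <- setdiff(rownames(abundance), tree$tip.label)
  if (length(missing_leaves)) {
    stop("abundance rows with no matching tree leaf: ",
         paste(missing_leaves, collapse = ", "))
  }
  if (!all(c(sample_a, sample_b) %in% colnames(abundance))) {
    stop("unknown sample")
  }
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)

  wa <- leaf_weights(tree, abundance[, sample_a])
  wb <- leaf_weights(tree, abundance[, sample_b])
  if (sum(wa) <= 0 || sum(wb) <= 0) stop("sample column sums must be > 0")
  pa <- wa / sum(wa)
  pb <- wb / sum(wb)

  tr <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  accA <- numeric(n_node); accB <- numeric(n_node)
  accA[seq_len(n_tip)] <- pa
  accB[seq_len(n_tip)] <- pb
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
    accA[par] <- accA[par] + accA[child]
    accB[par] <- accB[par] + accB[child]
  }
  d_raw <- sum(tr$edge.length * abs(accA[tr$edge[, 2]] - accB[tr$edge[, 2]]))
  if (!normalized) return(d_raw)
  depth <- ape::node.depth.edgelength(tr)[seq_len(n_tip)]
  scale <- sum(depth * (pa + pb))
  if (scale == 0) return(0)
  d_raw / scale
}

leaf_weights <- function(tree, counts) {
  w <- stats::setNames(numeric(length(tree$tip.label)), tree$tip.label)
  w[names(counts)] <- counts
  unname(w[tree$tip.label])
}

#' Weighted UniFrac distance matrix over all samples
#'
#' @param tree An [ape::phylo]; leaves match the abundance rows.
#' @param abundance Cluster x sample count matrix.
#' @param normalized Use the normalized form.
#' @return Symmetric distance matrix with zero diagonal.
#' @export
unifrac_matrix <- function(tree, abundance, normalized = FALSE) {
  if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
  s <- colnames(abundance)
  m <- matrix(0, length(s), length(s), dimnames = list(s, s))
  for (i in seq_along(s)) {
    for (j in seq_along(s)) {
      if (j >= i) next
      m[i, j] <- m[j, i] <- weighted_unifrac(tree, abundance, s[i], s[j],
                                             normalized = normalized)
    }
  }
  m
}

#' Principal coordinates analysis (classical metric MDS)
#'
#' Gower double-centering `B = -1/2 J D^2 J` followed by
#' eigendecomposition; coordinates are eigenvectors scaled by the square
#' roots of the positive eigenvalues. Axes with non-positive eigenvalues
#' are dropped from the coordinates but their eigenvalues are reported.
#' Axis signs are fixed deterministically (largest-magnitude loading made
#' positive).
#'
#' @param D Distance matrix (symmetric, zero diagonal) or `dist`.
#' @param n_axes Number of axes to return.
#' @return List with `coordinates` (samples x axes, column means zero),
#'   `eigenvalues` (all, descending), `proportion_explained` (over positive
#'   eigenvalues) and `negative_eigenvalues`.
#' @export
pcoa_ordination <- function(D, n_axes = 2L) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) stop("need at least 2 samples")
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  eg <- eigen((B + t(B)) / 2, symmetric = TRUE)
  vals <- eg$values
  tol <- max(abs(vals)) * 1e-9 + 1e-12
  pos <- which(vals > tol)
  k <- min(n_axes, length(pos))
  coords <- matrix(0, n, n_axes,
                   dimnames = list(rownames(D), paste0("PCo", seq_len(n_axes))))
  if (k > 0) {
    v <- eg$vectors[, pos[seq_len(k)], drop = FALSE]
    for (a in seq_len(k)) {
      i_max <- which.max(abs(v[, a]))
      if (v[i_max, a] < 0) v[, a] <- -v[, a]
    }
    coords[, seq_len(k)] <- sweep(v, 2, sqrt(vals[pos[seq_len(k)]]), `*`)
  }
  list(
    coordinates = coords,
    eigenvalues = vals,
    proportion_explained = if (length(pos)) vals[pos] / sum(vals[pos])
                           else numeric(0),
    negative_eigenvalues = vals[vals < -tol]
  )
}
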