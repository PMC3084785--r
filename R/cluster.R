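# Complete-linkage identity clustering at multiple thresholds.
#
# Distances are 100 - percent identity. A cluster at threshold t satisfies
# the diameter property: every within-cluster pair has identity >= t.
# Nestedness across thresholds (every 96% cluster lies inside exactly one
# 92% cluster) is guaranteed by cutting one dendrogram per connected
# component at all thresholds rather than clustering independently.
#
# For large inputs of equal-length peptides, candidate near-pairs are found
# by pigeonhole blocking (a pair within d mismatches of length-L sequences
# shares at least one of d+1 exact blocks), the candidate graph is split
# into connected components, and exact complete linkage runs per component.
# This is exact, not heuristic: all cross-component identities are below
# the loosest threshold, so no complete-linkage cluster can span components.

#' Complete-linkage clustering at one identity threshold
#'
#' @param pset A `protein_set`.
#' @param threshold Percent identity in (0, 100].
#' @return A `cluster_set`; see [cluster_thresholds()].
#' @export
complete_linkage_cluster <- function(pset, threshold) {
  cluster_thresholds(pset, thresholds = threshold)[[1]]
}

#' Hierarchical complete-linkage clustering cut at several thresholds
#'
#' @param pset A `protein_set`.
#' @param thresholds Percent-identity cutoffs (e.g. `c(100, 96, 92)`).
#' @param block_cutoff Input size above which pigeonhole blocking +
#'   connected components are used instead of one full distance matrix.
#' @return Named list (one `cluster_set` per threshold). Each `cluster_set`
#'   has `threshold`, `membership` (seq_id -> cluster_id), `clusters`
#'   (cluster_id, n_members, representative, total reads), `abundance`
#'   (cluster x sample read counts) and `rep_seqs` (representative
#'   sequences).
#' @export
cluster_thresholds <- function(pset, thresholds = c(100, 96, 92),
                               block_cutoff = 1500L) {
  stopifnot(inherits(pset, "protein_set"))
  if (any(thresholds <= 0 | thresholds > 100)) {
    stop("thresholds must be in (0, 100]")
  }
  ids <- sort(names(pset$seqs))
  seqs <- pset$seqs[ids]
  n <- length(seqs)
  thr_min <- min(thresholds)

  if (n == 0) {
    out <- lapply(thresholds, function(t) empty_cluster_set(t, pset))
    names(out) <- as.character(thresholds)
    return(out)
  }

  lens <- unique(nchar(seqs))
  comp <- if (n > block_cutoff && length(lens) == 1L) {
    candidate_components(seqs, lens, thr_min)
  } else rep(1L, n)

  # per-component dendrograms, cut at every threshold
  memb <- matrix(NA_integer_, n, length(thresholds),
                 dimnames = list(ids, as.character(thresholds)))
  offset <- integer(length(thresholds))
  for (cp in sort(unique(comp))) {
    idx <- which(comp == cp)
    if (length(idx) == 1L) {
      for (k in seq_along(thresholds)) {
        memb[idx, k] <- offset[k] + 1L
        offset[k] <- offset[k] + 1L
      }
      next
    }
    d <- 100 - identity_matrix(seqs[idx])
    hc <- stats::hclust(stats::as.dist(d), method = "complete")
    for (k in seq_along(thresholds)) {
      ct <- stats::cutree(hc, h = 100 - thresholds[k] + 1e-7)
      memb[idx, k] <- offset[k] + ct
      offset[k] <- offset[k] + max(ct)
    }
  }

  out <- lapply(seq_along(thresholds), function(k) {
    make_cluster_set(thresholds[k],
                     stats::setNames(memb[, k], rownames(memb)), seqs, pset)
  })
  names(out) <- as.character(thresholds)
  out
}

empty_cluster_set <- function(threshold, pset) {
  structure(list(
    threshold = threshold,
    membership = stats::setNames(character(0), character(0)),
    clusters = data.frame(cluster_id = character(0), n_members = integer(0),
                          representative = character(0), total = integer(0)),
    abundance = matrix(0L, 0, ncol(pset$counts),
                       dimnames = list(NULL, colnames(pset$counts))),
    rep_seqs = stats::setNames(character(0), character(0))
  ), class = "cluster_set")
}

make_cluster_set <- function(threshold, memb_int, seqs, pset) {
  ids <- names(memb_int)
  tot <- rowSums(pset$counts)[ids]
  groups <- split(ids, memb_int)

  # representative: most abundant member, ties -> smallest seq_id
  reps <- vapply(groups, function(g) {
    g[order(-tot[g], g)][1]
  }, character(1))
  g_tot <- vapply(groups, function(g) sum(tot[g]), numeric(1))

  # deterministic cluster ids: decreasing total reads, ties by representative
  ord <- order(-g_tot, reps)
  groups <- groups[ord]; reps <- reps[ord]; g_tot <- g_tot[ord]
  cids <- sprintf("otu%05d", seq_along(groups))

  membership <- stats::setNames(rep(cids, lengths(groups)),
                                unlist(groups, use.names = FALSE))
  membership <- membership[ids]

  abund <- rowsum(pset$counts[ids, , drop = FALSE],
                  group = membership[ids], reorder = FALSE)
  abund <- abund[cids, , drop = FALSE]

  structure(list(
    threshold = threshold,
    membership = membership,
    clusters = data.frame(cluster_id = cids,
                          n_members = as.integer(lengths(groups)),
                          representative = unname(reps),
                          total = as.integer(g_tot),
                          stringsAsFactors = FALSE),
    abundance = abund,
    rep_seqs = stats::setNames(unname(seqs[reps]), cids)
  ), class = "cluster_set")
}

# union-find over pigeonhole block groups (equal-length sequences only)
candidate_components <- function(seqs, L, thr_min) {
  n <- length(seqs)
  max_mm <- floor(L * (100 - thr_min) / 100)
  k <- max_mm + 1L
  bounds <- floor(seq(0, L, length.out = k + 1))
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (b in seq_len(k)) {
    key <- substr(seqs, bounds[b] + 1L, bounds[b + 1L])
    for (grp in split(seq_len(n), key)) {
      if (length(grp) > 1L) {
        r <- find(grp[1])
        for (g in grp[-1]) {
          rg <- find(g)
          if (rg != r) parent[rg] <- r
        }
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Remove clusters below a minimum total read count
#'
#' @param cs A `cluster_set` with populated abundance matrix.
#' @param min_size Minimum total reads for a cluster to be retained.
#' @return List with `cluster_set` (pruned), `removed_fraction` (fraction of
#'   reads lost) and `n_removed_clusters`.
#' @export
prune_small_clusters <- function(cs, min_size = 10L) {
  stopifnot(inherits(cs, "cluster_set"))
  keep <- cs$clusters$total >= min_size
  total_reads <- sum(cs$clusters$total)
  removed_reads <- sum(cs$clusters$total[!keep])
  kept_ids <- cs$clusters$cluster_id[keep]
  pruned <- structure(list(
    threshold = cs$threshold,
    membership = cs$membership[cs$membership %in% kept_ids],
    clusters = cs$clusters[keep, , drop = FALSE],
    abundance = cs$abundance[kept_ids, , drop = FALSE],
    rep_seqs = cs$rep_seqs[kept_ids]
  ), class = "cluster_set")
  rownames(pruned$clusters) <- NULL
  list(cluster_set = pruned,
       removed_fraction = if (total_reads > 0) removed_reads / total_reads
                          else 0,
       n_removed_clusters = sum(!keep))
}

#' Cluster-overlap counts between two samples
#'
#' @param x A `cluster_set` or a cluster x sample abundance matrix.
#' @param sample_a,sample_b Sample names (columns of the abundance matrix).
#' @return Named integer vector `c(j = shared, a = clusters in a,
#'   b = clusters in b)`.
#' @export
overlap_count <- function(x, sample_a, sample_b) {
  abund <- if (inherits(x, "cluster_set")) x$abundance else x
  if (!all(c(sample_a, sample_b) %in% colnames(abund))) {
    stop("unknown sample: ",
         paste(setdiff(c(sample_a, sample_b), colnames(abund)),
               collapse = ", "))
  }
  ina <- abund[, sample_a] > 0
  inb <- abund[, sample_b] > 0
  c(j = sum(ina & inb), a = sum(ina), b = sum(inb))
}
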