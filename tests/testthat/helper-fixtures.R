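# Shared fixtures and independent oracles, built in code at test time.

aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_aa <- function(len) {
  paste0(sample(aa_alphabet, len, replace = TRUE), collapse = "")
}

# mutate `k` distinct positions of an amino-acid string
mutate_aa <- function(seq, k, positions = NULL) {
  ch <- strsplit(seq, "")[[1]]
  if (is.null(positions)) positions <- sample(seq_along(ch), k)
  for (p in positions) ch[p] <- sample(setdiff(aa_alphabet, ch[p]), 1)
  paste0(ch, collapse = "")
}

# build a protein_set directly from sequences and a count matrix
make_pset <- function(seqs, counts = NULL, samples = "S1") {
  if (is.null(counts)) {
    counts <- matrix(1L, length(seqs), length(samples),
                     dimnames = list(NULL, samples))
  }
  ids <- sprintf("p%06d", seq_along(seqs))
  rownames(counts) <- ids
  ps <- list(seqs = stats::setNames(seqs, ids), counts = counts)
  class(ps) <- "protein_set"
  ps
}

# independent Hamming-based identity for equal-length strings
oracle_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  100 * mean(ca == cb)
}

# enumerate all set partitions of n items as restricted growth strings
enumerate_partitions <- function(n) {
  out <- list()
  rgs <- integer(n)
  recurse <- function(i, m) {
    if (i > n) {
      out[[length(out) + 1]] <<- rgs[seq_len(n)]
      return(invisible())
    }
    for (g in seq_len(m + 1)) {
      rgs[i] <<- g
      recurse(i + 1, max(m, g))
    }
  }
  rgs[1] <- 1L
  recurse(2L, 1L)
  out
}

# does a partition (grouping vector) satisfy the complete-linkage diameter
# property under a pairwise identity matrix and threshold?
partition_valid <- function(grp, idm, threshold) {
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) > 1) {
      sub <- idm[idx, idx]
      if (min(sub[upper.tri(sub)]) < threshold) return(FALSE)
    }
  }
  TRUE
}

# no two clusters of the partition can be merged without breaking the
# diameter property (complete-linkage cut partitions are merge-maximal)
partition_maximal <- function(grp, idm, threshold) {
  gs <- unique(grp)
  if (length(gs) < 2) return(TRUE)
  for (i in seq_along(gs)) {
    for (j in seq_len(i - 1)) {
      idx <- c(which(grp == gs[i]), which(grp == gs[j]))
      sub <- idm[idx, idx]
      if (min(sub[upper.tri(sub)]) >= threshold) return(FALSE)
    }
  }
  TRUE
}

# canonical form of a partition for set comparison
partition_canon <- function(grp) {
  unname(split(seq_along(grp), grp))[order(vapply(
    unname(split(seq_along(grp), grp)), min, numeric(1)))]
}

# a small synthetic dataset with no sequencing errors (overridable)
noiseless_config <- function(...) {
  args <- list(sub_rate = 0, homopolymer_indel_rate = 0, ambig_rate = 0,
               short_read_fraction = 0, contaminant_fraction = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}
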