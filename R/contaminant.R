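# Screening against a reagent-contaminant reference set.
#
# nifH-like sequences from Alpha-/Betaproteobacteria are a documented PCR
# reagent contaminant; sequences at or above a percent-identity threshold
# (default 96%, ties removed) to any entry of a curated contaminant set are
# excluded before diversity analysis.

#' Screen a protein set against a contaminant database
#'
#' A sequence is removed iff its maximum [pairwise_identity()] to any
#' database entry is greater than or equal to `threshold` (ties at exactly
#' the threshold are removed). Identity is computed on full-length global
#' alignments - a deterministic, toolkit-free reading of "percent amino
#' acid identity" appropriate for uniformly 60-residue sequences.
#'
#' @param pset A `protein_set` (see [dereplicate()]).
#' @param db Named character vector of contaminant amino-acid sequences.
#' @param threshold Percent-identity removal threshold in (0, 100].
#' @return List with `retained` and `removed` (`protein_set`s partitioning
#'   the input), `max_identity` (named numeric per input sequence) and
#'   `report` (per-sample reads in, reads removed, removed fraction).
#' @export
screen_contaminants <- function(pset, db, threshold = 96) {
  stopifnot(inherits(pset, "protein_set"))
  if (length(db) == 0) {
    stop("contaminant screening enabled but the database is empty")
  }
  if (threshold <= 0 || threshold > 100) {
    stop("threshold must be in (0, 100]")
  }
  n <- length(pset$seqs)
  if (n == 0) {
    rep0 <- data.frame(sample = colnames(pset$counts),
                       n_in = 0L, n_removed = 0L, fraction = NaN)
    return(list(retained = pset, removed = pset,
                max_identity = numeric(0), report = rep0))
  }
  idm <- identity_matrix(pset$seqs, db)
  max_id <- apply(idm, 1, max)
  names(max_id) <- names(pset$seqs)
  removed_ids <- names(pset$seqs)[max_id >= threshold]
  retained <- subset_protein_set(pset, setdiff(names(pset$seqs), removed_ids))
  removed <- subset_protein_set(pset, removed_ids)

  n_in <- colSums(pset$counts)
  n_rm <- colSums(removed$counts)
  report <- data.frame(
    sample = colnames(pset$counts),
    n_in = as.integer(n_in),
    n_removed = as.integer(n_rm),
    fraction = ifelse(n_in > 0, n_rm / n_in, NaN),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(retained = retained, removed = removed,
       max_identity = max_id, report = report)
}
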