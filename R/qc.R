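# Read-level quality control and frame-aware denoising.
#
# Pipeline order mirrors standard practice for protein-coding amplicons on
# homopolymer-error-prone platforms: trim primers, drop short reads and
# reads with undetermined bases, clip to a fixed in-frame window, translate,
# drop in-frame stops, dereplicate, and drop peptides whose optimal
# profile alignment requires insert states (unalignable residues from
# frameshifted tails).

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' Trim primer flanks from reads
#'
#' The forward primer must match at the 5' end with at most `max_mismatch`
#' mismatches (IUPAC degeneracy in the primer is honoured); reads without
#' this anchor are rejected, because the trimmed 5' boundary defines the
#' reading frame. The reverse primer (searched as its reverse complement
#' near the 3' end, exact match) is trimmed when present but its absence is
#' tolerated - reads may terminate before reaching it.
#'
#' @param nt_seq Character vector of read sequences.
#' @param fwd_primer,rev_primer Primer sequences (5'->3'; IUPAC codes allowed
#'   in the forward primer).
#' @param max_mismatch Mismatch tolerance for the forward primer anchor.
#' @return List with `trimmed` (character; `NA` where rejected) and `reason`
#'   (`""` or `"fwd_primer"`).
#' @export
trim_primers <- function(nt_seq, fwd_primer, rev_primer = NULL,
                         max_mismatch = 1L) {
  if (!nzchar(fwd_primer)) stop("fwd_primer must be non-empty")
  fp <- strsplit(toupper(fwd_primer), "")[[1]]
  if (!all(fp %in% names(IUPAC_SETS))) stop("invalid IUPAC code in primer")
  n <- length(nt_seq)
  mm <- integer(n)
  too_short <- nchar(nt_seq) < length(fp)
  for (j in seq_along(fp)) {
    allowed <- IUPAC_SETS[[fp[j]]]
    mm <- mm + !(substr(nt_seq, j, j) %in% allowed)
  }
  ok <- !too_short & mm <= max_mismatch
  trimmed <- rep(NA_character_, n)
  trimmed[ok] <- substr(nt_seq[ok], length(fp) + 1L, nchar(nt_seq[ok]))
  if (!is.null(rev_primer) && nzchar(rev_primer)) {
    rc <- revcomp(gsub("[^ACGT]", "N", toupper(rev_primer)))
    pat <- paste0(vapply(strsplit(rc, "")[[1]], function(b) {
      s <- IUPAC_SETS[[b]]
      if (length(s) == 1) s else paste0("[", paste0(s, collapse = ""), "]")
    }, character(1)), collapse = "")
    hit <- regexpr(pat, trimmed[ok])
    found <- hit > 0
    trimmed[ok][found] <- substr(trimmed[ok][found], 1, hit[found] - 1L)
  }
  list(trimmed = trimmed,
       reason = ifelse(ok, "", "fwd_primer"))
}

#' Length and ambiguity filter
#'
#' Rejects trimmed reads shorter than `min_len` nucleotides or containing
#' any undetermined base ('N').
#'
#' @param nt_seq Character vector of trimmed reads.
#' @param min_len Minimum retained length (nt).
#' @return Character vector of reasons: `""` (retained), `"length"` or
#'   `"ambiguity"`.
#' @export
filter_length_ambiguity <- function(nt_seq, min_len = 200L) {
  reason <- rep("", length(nt_seq))
  reason[nchar(nt_seq) < min_len] <- "length"
  amb <- reason == "" & grepl("N", nt_seq, fixed = TRUE)
  reason[amb] <- "ambiguity"
  reason
}

#' Clip to a fixed in-frame window and translate
#'
#' The first `clip_len` nucleotides (frame 0 from the trimmed forward-primer
#' boundary) are translated with the standard genetic code. Sequences whose
#' 60 codons include any stop are flagged.
#'
#' @param nt_seq Character vector of reads that passed the length filter.
#' @param clip_len Clip length in nt; must be divisible by 3 and not exceed
#'   any input length.
#' @return List with `aa` (translated peptides) and `has_stop` (logical).
#' @export
clip_and_translate <- function(nt_seq, clip_len = 180L) {
  if (clip_len %% 3L != 0L) stop("clip_len must be divisible by 3")
  if (length(nt_seq) == 0) {
    return(list(aa = character(0), has_stop = logical(0)))
  }
  if (any(nchar(nt_seq) < clip_len)) {
    stop("all sequences must be at least clip_len nucleotides long")
  }
  clipped <- substr(nt_seq, 1L, clip_len)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(clipped), no.init.codon = TRUE
  ))
  list(aa = unname(aa), has_stop = grepl("*", aa, fixed = TRUE))
}

#' Dereplicate translated sequences into a protein set
#'
#' One record per distinct amino-acid sequence with per-sample read counts.
#' Sequence ids are assigned deterministically: decreasing total count,
#' ties broken by the sequence string.
#'
#' @param aa_seq Character vector of peptides (equal length).
#' @param sample Parallel character vector of sample labels.
#' @return A `protein_set`: list with `seqs` (named character) and `counts`
#'   (integer matrix, sequences x samples).
#' @export
dereplicate <- function(aa_seq, sample) {
  stopifnot(length(aa_seq) == length(sample))
  samples <- sort(unique(sample))
  if (length(aa_seq) == 0) {
    ps <- list(seqs = stats::setNames(character(0), character(0)),
               counts = matrix(0L, 0, length(samples),
                               dimnames = list(NULL, samples)))
    class(ps) <- "protein_set"
    return(ps)
  }
  tab <- table(factor(aa_seq), factor(sample, levels = samples))
  counts <- matrix(as.integer(tab), nrow = nrow(tab),
                   dimnames = list(rownames(tab), samples))
  ord <- order(-rowSums(counts), rownames(counts))
  counts <- counts[ord, , drop = FALSE]
  ids <- sprintf("p%06d", seq_len(nrow(counts)))
  seqs <- stats::setNames(rownames(counts), ids)
  rownames(counts) <- ids
  ps <- list(seqs = seqs, counts = counts)
  class(ps) <- "protein_set"
  ps
}

#' Subset a protein set by sequence id
#' @param pset A `protein_set`.
#' @param ids Sequence ids to keep.
#' @return A `protein_set` restricted to `ids`.
#' @export
subset_protein_set <- function(pset, ids) {
  stopifnot(inherits(pset, "protein_set"))
  keep <- names(pset$seqs) %in% ids
  ps <- list(seqs = pset$seqs[keep],
             counts = pset$counts[keep, , drop = FALSE])
  class(ps) <- "protein_set"
  ps
}

#' Run the full read-level quality-control stage
#'
#' Applies, in order: primer trimming, length filter, ambiguity filter,
#' in-frame clipping + translation, in-frame stop rejection, dereplication,
#' and the profile-alignment (frameshift) filter. Returns the surviving
#' dereplicated protein set, a per-read status table and a per-sample
#' attrition log whose stage counts are monotone non-increasing.
#'
#' @param reads Data frame with columns `read_id`, `sample`, `nt_seq`.
#' @param profile A `nifh_profile` (see [build_profile()]), or `NULL` to
#'   skip the profile filter.
#' @param fwd_primer,rev_primer Primer sequences.
#' @param min_len,clip_len,max_primer_mismatch Filter parameters.
#' @return List with `proteins` (`protein_set`), `read_status` (read_id,
#'   sample, stage, aa_seq), and `attrition` (per-sample stage counts).
#' @export
qc_reads <- function(reads, profile,
                     fwd_primer = SIM_FWD_PRIMER,
                     rev_primer = SIM_REV_PRIMER,
                     min_len = 200L, clip_len = 180L,
                     max_primer_mismatch = 1L) {
  stopifnot(all(c("read_id", "sample", "nt_seq") %in% colnames(reads)))
  if (min_len < clip_len) stop("min_len must be >= clip_len")
  n <- nrow(reads)
  stage <- rep("passed", n)
  aa_out <- rep(NA_character_, n)

  tr <- trim_primers(reads$nt_seq, fwd_primer, rev_primer,
                     max_mismatch = max_primer_mismatch)
  stage[tr$reason != ""] <- "trim"
  live <- stage == "passed"

  r2 <- filter_length_ambiguity(tr$trimmed[live], min_len = min_len)
  stage[live][r2 != ""] <- r2[r2 != ""]
  live <- stage == "passed"

  ct <- clip_and_translate(tr$trimmed[live], clip_len = clip_len)
  stage[live][ct$has_stop] <- "stop"
  aa_out[live] <- ifelse(ct$has_stop, NA_character_, ct$aa)
  live <- stage == "passed"

  pset <- dereplicate(aa_out[live], reads$sample[live])

  if (!is.null(profile)) {
    pf <- profile_align_filter(pset$seqs, profile)
    bad_seqs <- pset$seqs[!pf$retained]
    if (length(bad_seqs)) {
      stage[live][aa_out[live] %in% bad_seqs] <- "profile"
      pset <- subset_protein_set(pset, names(pset$seqs)[pf$retained])
    }
  }
  aa_out[stage != "passed"] <- NA_character_

  samples <- sort(unique(reads$sample))
  stages <- c("trim", "length", "ambiguity", "clip", "stop", "profile")
  att <- t(vapply(samples, function(s) {
    st <- stage[reads$sample == s]
    tot <- length(st)
    remaining <- tot
    out <- c(input = tot)
    for (g in stages) {
      remaining <- remaining - sum(st == g)
      out[paste0("after_", if (g == "stop") "stop_filter"
                 else if (g == "profile") "profile_filter" else g)] <- remaining
    }
    out
  }, numeric(7)))
  attrition <- data.frame(sample = samples, att, check.names = FALSE,
                          stringsAsFactors = FALSE, row.names = NULL)

  list(
    proteins = pset,
    read_status = data.frame(read_id = reads$read_id, sample = reads$sample,
                             stage = stage, aa_seq = aa_out,
                             stringsAsFactors = FALSE),
    attrition = attrition
  )
}
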