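# Position-specific profile alignment for frameshift detection.
#
# The profile is a plain position-specific score matrix (one row per match
# state, one column per residue) with affine deletion penalties, a flat
# per-residue insert penalty, and glocal (semi-global) terminal gaps:
# skipping profile columns before the first or after the last aligned
# residue costs only the extension penalty, mirroring profile-HMM entry and
# exit transitions. A peptide is "unalignable" when every optimal alignment
# must place at least one residue in an insert state. Under the default
# scoring this happens for (a) any run of two or more interior residues not
# acceptable at their profile positions and (b) any unacceptable residue at
# either terminus - the two signatures of a frameshifted tail, whose
# garbled sequence always extends through the final residue - while
# isolated interior substitutions stay in match states and are retained.

#' Build a position-specific profile from reference peptides
#'
#' Each profile column scores residues observed at that column of the
#' (already aligned, equal-length) reference set with `match_score` and all
#' other residues with `mismatch_score`. The default penalties are chosen so
#' that a single unexpected *interior* residue aligns as a (retained)
#' mismatch, while two or more consecutive unexpected residues are cheaper
#' to route through insert states, marking the sequence unalignable: a run
#' of k interior mismatches scores `k * mismatch_score`, the insert route
#' `k * insert_penalty + gap_open + k * gap_extend`, so the insert route
#' wins for `k >= 2` under the defaults (0, -5, -2, -3, -1). At the termini
#' profile deletions cost extension only (glocal alignment), so even a
#' single unexpected terminal residue is routed to an insert state - the
#' signature of a frameshifted tail, which always garbles the final
#' residue.
#'
#' @param refs Named character vector of equal-length reference peptides.
#' @param match_score,mismatch_score Per-column residue scores.
#' @param gap_open,gap_extend Affine penalties for skipping profile match
#'   states (non-positive).
#' @param insert_penalty Flat per-residue penalty for insert states
#'   (non-positive).
#' @return A `nifh_profile` object.
#' @export
build_profile <- function(refs, match_score = 0, mismatch_score = -5,
                          gap_open = -3, gap_extend = -1,
                          insert_penalty = -2) {
  if (length(refs) == 0) stop("need at least one reference sequence")
  L <- unique(nchar(refs))
  if (length(L) != 1) stop("reference sequences must have equal length")
  if (gap_open > 0 || gap_extend > 0 || insert_penalty > 0) {
    stop("gap penalties must be non-positive")
  }
  scores <- matrix(mismatch_score, nrow = L, ncol = length(AA20),
                   dimnames = list(NULL, AA20))
  chars <- do.call(rbind, strsplit(unname(refs), ""))
  for (j in seq_len(L)) {
    seen <- intersect(unique(chars[, j]), AA20)
    scores[j, seen] <- match_score
  }
  structure(list(length = L, scores = scores,
                 gap_open = gap_open, gap_extend = gap_extend,
                 insert_penalty = insert_penalty),
            class = "nifh_profile")
}

#' Write a profile to a plain-text TSV file
#'
#' Format: '#' header lines carrying the gap parameters, then one row per
#' match state (`pos` + 20 residue scores).
#'
#' @param profile A `nifh_profile`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile <- function(profile, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(
    paste0("#gap_open\t", profile$gap_open),
    paste0("#gap_extend\t", profile$gap_extend),
    paste0("#insert_penalty\t", profile$insert_penalty),
    paste0(c("pos", colnames(profile$scores)), collapse = "\t"),
    vapply(seq_len(profile$length), function(j) {
      paste0(c(j, profile$scores[j, ]), collapse = "\t")
    }, character(1))
  ), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' Read a profile written by [write_profile()]
#' @param path Path to the profile TSV.
#' @return A `nifh_profile`.
#' @export
read_profile <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  get <- function(key) {
    ln <- hdr[startsWith(hdr, paste0("#", key))]
    if (length(ln) != 1) stop("profile file missing header '", key, "'")
    as.numeric(strsplit(ln, "\t")[[1]][2])
  }
  body <- utils::read.table(text = lines[!startsWith(lines, "#")],
                            sep = "\t", header = TRUE, check.names = FALSE)
  scores <- as.matrix(body[, -1, drop = FALSE])
  rownames(scores) <- NULL
  structure(list(length = nrow(scores), scores = scores,
                 gap_open = get("gap_open"), gap_extend = get("gap_extend"),
                 insert_penalty = get("insert_penalty")),
            class = "nifh_profile")
}

# residue characters -> column indices into the profile score matrix;
# unknown residues get a sentinel column of mismatch-level scores
aa_index <- function(chars, scores) {
  idx <- match(chars, colnames(scores))
  idx[is.na(idx)] <- 0L  # handled by caller via score lookup fallback
  idx
}

#' Align one peptide to a profile with full traceback
#'
#' Glocal dynamic-programming alignment against the profile: match states
#' consume one residue and one profile position; interior deletions skip
#' profile positions (affine); terminal deletions cost only the extension
#' penalty (profile-HMM-style entry/exit); inserts consume residues without
#' advancing the profile (flat penalty). Returns the optimal score, the
#' best score attainable without insert states, the residues assigned to
#' insert states on one optimal path, and an audit string.
#'
#' @param aa Peptide string.
#' @param profile A `nifh_profile`.
#' @return List with `score`, `score_no_insert`, `n_unaligned`, `retained`,
#'   and `alignment` (query string with insert-state residues in lowercase
#'   and '-' for skipped profile positions).
#' @export
profile_align <- function(aa, profile) {
  stopifnot(inherits(profile, "nifh_profile"))
  q <- strsplit(aa, "")[[1]]
  nq <- length(q)
  L <- profile$length
  sc <- profile$scores
  go <- profile$gap_open; ge <- profile$gap_extend; ip <- profile$insert_penalty
  mism <- min(sc)

  NEG <- -1e18
  B <- matrix(NEG, nq + 1, L + 1)
  D <- matrix(NEG, nq + 1, L + 1)
  move <- matrix("", nq + 1, L + 1)
  B[1, 1] <- 0
  for (j in seq_len(L)) {
    B[1, j + 1] <- j * ge  # leading terminal deletions: extension only
    move[1, j + 1] <- "d"
  }
  for (i in seq_len(nq)) {
    B[i + 1, 1] <- i * ip
    move[i + 1, 1] <- "i"
    qi <- q[i]
    for (j in seq_len(L)) {
      s <- if (qi %in% colnames(sc)) sc[j, qi] else mism
      diag <- B[i, j] + s
      ins <- B[i, j + 1] + ip
      D[i + 1, j + 1] <- max(B[i + 1, j] + go + ge, D[i + 1, j] + ge)
      best <- max(diag, D[i + 1, j + 1], ins)
      B[i + 1, j + 1] <- best
      move[i + 1, j + 1] <- if (best == diag) "m"
        else if (best == D[i + 1, j + 1]) "d" else "i"
    }
  }
  # trailing terminal deletions: extension only from any final column
  ends <- B[nq + 1, ] + (L - (seq_len(L + 1) - 1)) * ge
  jstar <- which.max(ends)
  score <- ends[jstar]

  # second pass without the insert move
  score_no_insert <- if (nq > L) NEG else {
    B2 <- rep(NEG, L + 1)
    B2[1] <- 0
    for (j in seq_len(L)) B2[j + 1] <- j * ge
    for (i in seq_len(nq)) {
      B2p <- B2; D2 <- rep(NEG, L + 1); B2 <- rep(NEG, L + 1)
      qi <- q[i]
      for (j in seq_len(L)) {
        s <- if (qi %in% colnames(sc)) sc[j, qi] else mism
        D2[j + 1] <- max(B2[j] + go + ge, D2[j] + ge)
        B2[j + 1] <- max(B2p[j] + s, D2[j + 1])
      }
    }
    max(B2 + (L - (seq_len(L + 1) - 1)) * ge)
  }

  # traceback (preferring match over delete over insert at ties)
  i <- nq + 1; j <- jstar
  out <- rep("-", L + 1 - jstar)
  n_ins <- 0L
  while (i > 1 || j > 1) {
    mv <- move[i, j]
    if (mv == "m") {
      out <- c(q[i - 1], out); i <- i - 1; j <- j - 1
    } else if (mv == "d") {
      out <- c("-", out); j <- j - 1
    } else {
      out <- c(tolower(q[i - 1]), out); n_ins <- n_ins + 1L; i <- i - 1
    }
  }
  list(score = score, score_no_insert = score_no_insert,
       n_unaligned = n_ins,
       retained = score_no_insert >= score - 1e-9,
       alignment = paste0(out, collapse = ""))
}

#' Profile-alignment filter for a batch of peptides
#'
#' Vectorised across sequences: computes for every peptide the optimal
#' glocal profile-alignment score and the best score attainable without
#' insert states. A peptide is retained iff some optimal alignment uses no
#' insert state (the two scores agree), i.e. rejected iff any residue is
#' forced into an insert/unaligned state.
#'
#' @param seqs Named character vector of peptides.
#' @param profile A `nifh_profile` with at least 30 match states.
#' @return List with `retained` (named logical), `score` and
#'   `score_no_insert` (named numeric).
#' @export
profile_align_filter <- function(seqs, profile) {
  stopifnot(inherits(profile, "nifh_profile"))
  if (profile$length < 30) {
    stop("profile has fewer than 30 match states; not a usable model")
  }
  n <- length(seqs)
  retained <- stats::setNames(logical(n), names(seqs))
  score <- stats::setNames(rep(NA_real_, n), names(seqs))
  score_ni <- score
  if (n == 0) {
    return(list(retained = retained, score = score,
                score_no_insert = score_ni))
  }
  for (len in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == len)
    r <- profile_filter_batch(seqs[idx], profile)
    retained[idx] <- r$retained
    score[idx] <- r$score
    score_ni[idx] <- r$score_no_insert
  }
  list(retained = retained, score = score, score_no_insert = score_ni)
}

# Batch DP over equal-length peptides; row-wise vectorised across sequences.
profile_filter_batch <- function(seqs, profile) {
  n <- length(seqs)
  nq <- nchar(seqs[[1]])
  L <- profile$length
  sc <- profile$scores
  go <- profile$gap_open; ge <- profile$gap_extend; ip <- profile$insert_penalty
  mism <- min(sc)
  NEG <- -1e18

  Q <- matrix(match(strsplit(paste0(seqs, collapse = ""), "")[[1]],
                    colnames(sc)),
              nrow = n, ncol = nq, byrow = TRUE)

  res_score <- function(j, col) {
    s <- sc[j, ][col]
    s[is.na(s)] <- mism
    s
  }

  trailing <- function(B_last) {
    # glocal exit: trailing profile columns cost extension only
    out <- B_last[, L + 1]
    for (j in 0:(L - 1)) {
      out <- pmax(out, B_last[, j + 1] + (L - j) * ge)
    }
    out
  }

  B_prev <- matrix(NEG, n, L + 1)
  B_prev[, 1] <- 0
  for (j in seq_len(L)) B_prev[, j + 1] <- j * ge  # glocal entry
  for (i in seq_len(nq)) {
    B_cur <- matrix(NEG, n, L + 1)
    D_cur <- matrix(NEG, n, L + 1)
    B_cur[, 1] <- i * ip
    qcol <- Q[, i]
    for (j in seq_len(L)) {
      s <- res_score(j, qcol)
      diag <- B_prev[, j] + s
      ins <- B_prev[, j + 1] + ip
      D_cur[, j + 1] <- pmax(B_cur[, j] + go + ge, D_cur[, j] + ge)
      B_cur[, j + 1] <- pmax(diag, ins, D_cur[, j + 1])
    }
    B_prev <- B_cur
  }
  score <- trailing(B_prev)

  if (nq > L) {
    score_ni <- rep(NEG, n)
  } else if (nq == L) {
    # without inserts and with equal lengths the only path is the diagonal
    score_ni <- rep(0, n)
    for (j in seq_len(L)) score_ni <- score_ni + res_score(j, Q[, j])
  } else {
    B_prev <- matrix(NEG, n, L + 1)
    B_prev[, 1] <- 0
    for (j in seq_len(L)) B_prev[, j + 1] <- j * ge
    for (i in seq_len(nq)) {
      B_cur <- matrix(NEG, n, L + 1)
      D_cur <- matrix(NEG, n, L + 1)
      qcol <- Q[, i]
      for (j in seq_len(L)) {
        s <- res_score(j, qcol)
        D_cur[, j + 1] <- pmax(B_cur[, j] + go + ge, D_cur[, j] + ge)
        B_cur[, j + 1] <- pmax(B_prev[, j] + s, D_cur[, j + 1])
      }
      B_prev <- B_cur
    }
    score_ni <- trailing(B_prev)
  }
  list(retained = score_ni >= score - 1e-9,
       score = score, score_no_insert = score_ni)
}
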