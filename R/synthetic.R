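# Synthetic nifH amplicon communities with full ground truth.
#
# The generator emulates the structure of a multi-sample functional-gene
# pyrosequencing survey: skewed communities of 60-residue protein variants
# organised into designed identity families (so the true cluster counts at
# 100/96/92% are known by construction), back-translated ~358 bp amplicons
# with fixed primer flanks, 454-style homopolymer indels, substitutions,
# ambiguous bases, short reads, and reagent-contaminant spike-ins.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Fixed, non-degenerate primer flanks (17 nt each). The flanks are plumbing:
# they define the trim points and the reading frame, not the biology.
SIM_FWD_PRIMER <- "TGCGACCCGAAGGCTGA"
SIM_REV_PRIMER <- "AGGGCCATCATTTCACC"

#' Configuration for the synthetic read generator
#'
#' @param n_samples Number of samples.
#' @param variants_per_sample Number of true 92%-level variant families per
#'   sample.
#' @param shared_variant_fraction Fraction of each (non-outlier) sample's
#'   families drawn from a pool common to all non-outlier samples.
#' @param reads_per_sample Reads emitted per sample.
#' @param abundance_shape Power-law exponent for the per-sample family
#'   abundance distribution (`p_r` proportional to `r^-shape`).
#' @param sub_rate Per-base substitution probability.
#' @param homopolymer_indel_rate Per-homopolymer-run (length >= 2) probability
#'   of a single-base insertion or deletion.
#' @param ambig_rate Per-base probability of an undetermined base ('N').
#' @param short_read_fraction Fraction of reads truncated so that the trimmed
#'   insert falls below 200 nt.
#' @param contaminant_fraction Fraction of reads drawn from the contaminant
#'   pool instead of the sample community.
#' @param rng_seed Integer seed governing the whole simulation.
#' @param microdiversity Number of unique protein variants per family
#'   (intra-family microdiversity).
#' @param family_design `"radial"` (family diameter <= 2 substitutions; one
#'   96% subcluster per family) or `"nested"` (diameter 4; families with >= 2
#'   variants split into two 96% subclusters).
#' @param n_outlier_samples Number of trailing samples whose families are all
#'   private, sharing no variants with any other sample (the survey-outlier
#'   pattern).
#' @param n_contaminants Size of the contaminant sequence pool.
#' @param conserved_fraction Fraction of the 60 analysed residue positions
#'   held invariant across all families and contaminants, emulating the
#'   conserved catalytic/motif columns of the marker region; the remaining
#'   positions vary freely between families.
#' @param ext_len Length in residues of the full amplicon insert
#'   (back-translated to `3 * ext_len` nt); the analysed region is its first
#'   60 residues.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_samples = 10,
                       variants_per_sample = 25,
                       shared_variant_fraction = 0.3,
                       reads_per_sample = 5000,
                       abundance_shape = 1.0,
                       sub_rate = 0.002,
                       homopolymer_indel_rate = 0.01,
                       ambig_rate = 1e-4,
                       short_read_fraction = 0.01,
                       contaminant_fraction = 0,
                       rng_seed = 1L,
                       microdiversity = 3,
                       family_design = c("radial", "nested"),
                       n_outlier_samples = 0,
                       n_contaminants = 8,
                       conserved_fraction = 0.4,
                       ext_len = 108) {
  family_design <- match.arg(family_design)
  cfg <- list(
    n_samples = as.integer(n_samples),
    variants_per_sample = as.integer(variants_per_sample),
    shared_variant_fraction = shared_variant_fraction,
    reads_per_sample = as.integer(reads_per_sample),
    abundance_shape = abundance_shape,
    sub_rate = sub_rate,
    homopolymer_indel_rate = homopolymer_indel_rate,
    ambig_rate = ambig_rate,
    short_read_fraction = short_read_fraction,
    contaminant_fraction = contaminant_fraction,
    rng_seed = as.integer(rng_seed),
    microdiversity = as.integer(microdiversity),
    family_design = family_design,
    n_outlier_samples = as.integer(n_outlier_samples),
    n_contaminants = as.integer(n_contaminants),
    conserved_fraction = conserved_fraction,
    ext_len = as.integer(ext_len),
    fwd_primer = SIM_FWD_PRIMER,
    rev_primer = SIM_REV_PRIMER
  )
  rates <- c("shared_variant_fraction", "sub_rate", "homopolymer_indel_rate",
             "ambig_rate", "short_read_fraction", "contaminant_fraction")
  for (r in rates) {
    if (!is.numeric(cfg[[r]]) || cfg[[r]] < 0 || cfg[[r]] > 1) {
      stop("'", r, "' must be in [0, 1]")
    }
  }
  if (cfg$n_samples < 1) stop("n_samples must be >= 1")
  if (cfg$reads_per_sample < 1) stop("reads_per_sample must be >= 1")
  if (cfg$variants_per_sample < 1) stop("variants_per_sample must be >= 1")
  if (cfg$abundance_shape <= 0) stop("abundance_shape must be positive")
  if (cfg$n_outlier_samples >= cfg$n_samples && cfg$n_samples > 1) {
    stop("n_outlier_samples must leave at least one regular sample")
  }
  if (cfg$ext_len < 67) stop("ext_len must be >= 67 (insert >= 201 nt)")
  if (cfg$conserved_fraction < 0 || cfg$conserved_fraction > 0.8) {
    stop("conserved_fraction must be in [0, 0.8]")
  }
  if (cfg$microdiversity < 1) stop("microdiversity must be >= 1")
  if (cfg$family_design == "nested" && cfg$microdiversity > 4) {
    stop("impossible identity design: nested families support at most 4 ",
         "unique variants within a 92% diameter")
  }
  if (cfg$family_design == "radial" && cfg$microdiversity > 30) {
    stop("impossible identity design: too many radial variants for a ",
         "60-residue sequence")
  }
  class(cfg) <- "sim_config"
  cfg
}

random_aa_seqs <- function(n, len) {
  if (n == 0) return(character(0))
  m <- matrix(sample(AA20, n * len, replace = TRUE), nrow = n)
  apply(m, 1, paste0, collapse = "")
}

substitute_residues <- function(seq, positions) {
  ch <- strsplit(seq, "")[[1]]
  for (p in positions) {
    ch[p] <- sample(setdiff(AA20, ch[p]), 1)
  }
  paste0(ch, collapse = "")
}

#' Generate the true variant and contaminant pool for a simulation
#'
#' Families of 60-residue variants are designed so that the number of
#' clusters at the 100/96/92% identity thresholds is known exactly by
#' construction: family seeds are mutually < 80% identical, variants within a
#' family stay within the 92% complete-linkage diameter, and (for the
#' `"nested"` design) two 96% subclusters are separated by three
#' substitutions. Contaminants are drawn far (< 80% identity) from every
#' variant so that contaminant screening has unambiguous ground truth.
#'
#' @param config A [sim_config()].
#' @return A `nifh_pool` object: variant table, contaminant table, per-sample
#'   community compositions, and a `truth` list (`true_cluster_count` at the
#'   three thresholds, `true_sorensen` at 96%, per-sample family counts).
#' @export
generate_variant_pool <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$rng_seed)

  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  outliers <- if (cfg$n_outlier_samples > 0) {
    samples[seq(cfg$n_samples - cfg$n_outlier_samples + 1, cfg$n_samples)]
  } else character(0)
  normal <- setdiff(samples, outliers)

  V <- cfg$variants_per_sample
  n_shared <- if (length(normal) >= 2) round(cfg$shared_variant_fraction * V) else 0L
  n_private <- V - n_shared
  n_fam <- n_shared + length(normal) * n_private + length(outliers) * V
  if (length(normal) == 1L) n_fam <- V + length(outliers) * V

  # Family seeds and contaminants are anchored on one consensus: a fixed
  # set of conserved positions (marker-motif columns) is invariant across
  # the whole pool, the remaining positions are drawn freely per family.
  # Mutual identity over the analysed 60 residues must stay < 80% so the
  # designed cluster structure is unambiguous (rejection sampling; failure
  # => the design is infeasible).
  n_pool <- n_fam + cfg$n_contaminants
  n_cons <- round(60 * cfg$conserved_fraction)
  conserved_pos <- sort(sample.int(60, n_cons))
  variable_pos <- setdiff(seq_len(60), conserved_pos)
  if (cfg$family_design == "radial" && cfg$microdiversity - 1 > length(variable_pos) ||
      cfg$family_design == "nested" && cfg$microdiversity > 1 &&
        length(variable_pos) < 5) {
    stop("impossible identity design: not enough variable positions for ",
         "the requested microdiversity")
  }
  consensus <- strsplit(random_aa_seqs(1, cfg$ext_len), "")[[1]]
  draw_pool_seq <- function(n) {
    vapply(seq_len(n), function(i) {
      ch <- consensus
      vp <- c(variable_pos, seq(61, cfg$ext_len))
      ch[vp] <- sample(AA20, length(vp), replace = TRUE)
      paste0(ch, collapse = "")
    }, character(1))
  }
  ext <- draw_pool_seq(n_pool)
  for (attempt in 1:25) {
    id60 <- identity_matrix(substr(ext, 1, 60))
    diag(id60) <- 0
    bad <- which(apply(id60, 1, max) >= 80)
    if (length(bad) == 0) break
    if (attempt == 25) {
      stop("impossible identity design: could not draw ", n_pool,
           " mutually distinct (<80% identity) 60-residue seeds")
    }
    ext[bad] <- draw_pool_seq(length(bad))
  }
  fam_ext <- ext[seq_len(n_fam)]
  contam_ext <- ext[n_fam + seq_len(cfg$n_contaminants)]

  # expand each family into its designed unique variants
  m <- cfg$microdiversity
  variants <- vector("list", n_fam)
  for (f in seq_len(n_fam)) {
    seed60 <- substr(fam_ext[f], 1, 60)
    aa60 <- seed60
    sub96 <- "a"
    if (m > 1) {
      if (cfg$family_design == "radial") {
        pos <- sample(variable_pos, m - 1)
        aa60 <- c(aa60, vapply(pos, function(p)
          substitute_residues(seed60, p), character(1)))
        sub96 <- rep("a", m)
      } else {
        pos <- sample(variable_pos, 5)
        tmpl <- list(
          seed60,
          substitute_residues(seed60, pos[1:3]),
          substitute_residues(seed60, pos[4]),
          substitute_residues(seed60, pos[5])
        )
        aa60 <- unlist(tmpl[seq_len(m)])
        sub96 <- c("a", "b", "a", "a")[seq_len(m)]
      }
    }
    tails <- substr(fam_ext[f], 61, cfg$ext_len)
    variants[[f]] <- data.frame(
      variant_id = sprintf("V%04d.%d", f, seq_len(length(aa60))),
      family_id = sprintf("F%04d", f),
      sub96_id = paste0(sprintf("F%04d", f), sub96),
      aa60 = aa60,
      aa_ext = paste0(aa60, tails),
      stringsAsFactors = FALSE
    )
  }
  variants <- do.call(rbind, variants)
  if (anyDuplicated(variants$aa60)) {
    stop("impossible identity design: duplicate variants generated")
  }

  # family -> sample assignment
  fam_ids <- sprintf("F%04d", seq_len(n_fam))
  assign <- list()
  nxt <- n_shared + 1L
  shared_fams <- fam_ids[seq_len(n_shared)]
  for (s in normal) {
    pf <- if (length(normal) == 1L) V - n_shared else n_private
    priv <- fam_ids[seq(nxt, length.out = pf)]
    nxt <- nxt + pf
    assign[[s]] <- c(shared_fams, priv)
  }
  for (s in outliers) {
    assign[[s]] <- fam_ids[seq(nxt, length.out = V)]
    nxt <- nxt + V
  }

  # per-sample true abundances: power law over families (ranks permuted per
  # sample), fixed within-family split (seed variant 0.6, leaves share 0.4)
  sample_variants <- list()
  for (s in samples) {
    fams <- assign[[s]]
    ranks <- sample(seq_along(fams))
    p_fam <- ranks^(-cfg$abundance_shape)
    p_fam <- p_fam / sum(p_fam)
    rows <- variants[variants$family_id %in% fams, ]
    w_within <- function(k) if (k == 1) 1 else c(0.6, rep(0.4 / (k - 1), k - 1))
    ab <- numeric(nrow(rows))
    for (i in seq_along(fams)) {
      idx <- which(rows$family_id == fams[i])
      ab[idx] <- p_fam[i] * w_within(length(idx))
    }
    sample_variants[[s]] <- data.frame(
      variant_id = rows$variant_id,
      family_id = rows$family_id,
      rel_abundance = ab,
      stringsAsFactors = FALSE
    )
  }

  # ground-truth cluster counts over the whole variant pool
  c100 <- nrow(variants)
  c96 <- length(unique(variants$sub96_id))
  c92 <- n_fam

  # true Sorensen matrix at the 96% level (supports = 96% subclusters)
  sup <- lapply(samples, function(s) {
    unique(variants$sub96_id[variants$family_id %in% assign[[s]]])
  })
  names(sup) <- samples
  cs <- matrix(100, length(samples), length(samples),
               dimnames = list(samples, samples))
  for (i in seq_along(samples)) {
    for (j in seq_along(samples)) {
      if (i == j) next
      jj <- length(intersect(sup[[i]], sup[[j]]))
      cs[i, j] <- 200 * jj / (length(sup[[i]]) + length(sup[[j]]))
    }
  }

  contaminants <- data.frame(
    contam_id = sprintf("CONT%02d", seq_len(cfg$n_contaminants)),
    aa60 = substr(contam_ext, 1, 60),
    aa_ext = contam_ext,
    stringsAsFactors = FALSE
  )

  structure(list(
    config = cfg,
    samples = samples,
    variants = variants,
    contaminants = contaminants,
    sample_variants = sample_variants,
    truth = list(
      true_cluster_count = c("100" = c100, "96" = c96, "92" = c92),
      true_sorensen = cs,
      families_per_sample = stats::setNames(rep(V, length(samples)), samples),
      outlier_samples = outliers
    )
  ), class = "nifh_pool")
}

# inverse genetic code: amino acid -> codons (standard code, no stops)
codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

# Back-translate one amino-acid sequence into n nucleotide copies with
# uniformly random synonymous codons.
back_translate <- function(aa, n) {
  tab <- codon_table()
  ch <- strsplit(aa, "")[[1]]
  codons <- tab[ch]
  lens <- lengths(codons)
  flat <- unlist(codons, use.names = FALSE)
  off <- cumsum(c(0L, lens[-length(lens)]))
  L <- length(ch)
  pick <- matrix(
    flat[rep(off, n) + (floor(stats::runif(L * n) * rep(lens, n)) + 1L)],
    nrow = L
  )
  apply(pick, 2, paste0, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Apply the 454-style error model to one read. Returns the mutated read and
# an event string "pos:type|..." (positions refer to the read as it was when
# the event was applied; indels are applied right-to-left).
mutate_read <- function(nt, sub_rate, indel_rate, ambig_rate) {
  ch <- strsplit(nt, "")[[1]]
  L <- length(ch)
  ev <- character(0)

  ns <- stats::rbinom(1L, L, sub_rate)
  if (ns > 0) {
    pos <- sort(sample.int(L, ns))
    for (p in pos) {
      ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
    }
    ev <- c(ev, paste0(pos, ":sub"))
  }
  na <- stats::rbinom(1L, L, ambig_rate)
  if (na > 0) {
    pos <- sort(sample.int(L, na))
    ch[pos] <- "N"
    ev <- c(ev, paste0(pos, ":ambig"))
  }
  if (indel_rate > 0) {
    r <- rle(ch)
    run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    runs <- which(r$lengths >= 2 & r$values %in% c("A", "C", "G", "T"))
    if (length(runs)) {
      hit <- runs[stats::runif(length(runs)) < indel_rate]
      for (k in rev(hit)) {  # right-to-left keeps positions valid
        p <- run_start[k]
        if (stats::runif(1) < 0.5) {
          ch <- append(ch, r$values[k], after = p)
          ev <- c(ev, paste0(p, ":ins"))
        } else {
          ch <- ch[-p]
          ev <- c(ev, paste0(p, ":del"))
        }
      }
    }
  }
  list(nt = paste0(ch, collapse = ""), events = paste0(ev, collapse = "|"))
}

#' Emit per-sample nucleotide reads with a ground-truth sidecar
#'
#' Back-translates each read's origin sequence (community variant or
#' contaminant) with uniformly random synonymous codons, adds the fixed
#' primer flanks, then injects substitutions, ambiguous bases, per-run
#' homopolymer indels and read truncations at the configured rates. All
#' randomness is governed by the pool's `rng_seed`, so reruns are
#' byte-identical.
#'
#' @param pool A `nifh_pool` from [generate_variant_pool()].
#' @param outdir Optional directory; if given, one FASTA per sample
#'   (`reads_<sample>.fasta`) and a `truth_sidecar.tsv` are written.
#' @return List with `reads` (read_id, sample, nt_seq) and `sidecar`
#'   (read_id, sample, origin_id, is_contaminant, truncated_to,
#'   error_events).
#' @export
emit_reads <- function(pool, outdir = NULL) {
  stopifnot(inherits(pool, "nifh_pool"))
  cfg <- pool$config
  set.seed(cfg$rng_seed + 77003L)

  fwd <- cfg$fwd_primer
  rev3 <- revcomp(cfg$rev_primer)
  out_reads <- list()
  out_sc <- list()

  for (s in pool$samples) {
    n <- cfg$reads_per_sample
    sv <- pool$sample_variants[[s]]
    is_cont <- stats::runif(n) < cfg$contaminant_fraction
    origin <- character(n)
    nc <- sum(is_cont)
    if (nc > 0) {
      origin[is_cont] <- sample(pool$contaminants$contam_id, nc, replace = TRUE)
    }
    if (nc < n) {
      origin[!is_cont] <- sample(sv$variant_id, n - nc,
                                 replace = TRUE, prob = sv$rel_abundance)
    }

    # back-translate per origin batch
    nt <- character(n)
    ext_of <- c(stats::setNames(pool$variants$aa_ext, pool$variants$variant_id),
                stats::setNames(pool$contaminants$aa_ext,
                                pool$contaminants$contam_id))
    for (o in sort(unique(origin))) {
      idx <- which(origin == o)
      nt[idx] <- back_translate(ext_of[[o]], length(idx))
    }
    nt <- paste0(fwd, nt, rev3)

    events <- character(n)
    if (cfg$sub_rate > 0 || cfg$homopolymer_indel_rate > 0 ||
        cfg$ambig_rate > 0) {
      for (i in seq_len(n)) {
        mr <- mutate_read(nt[i], cfg$sub_rate,
                          cfg$homopolymer_indel_rate, cfg$ambig_rate)
        nt[i] <- mr$nt
        events[i] <- mr$events
      }
    }

    trunc_to <- rep(NA_integer_, n)
    short <- stats::runif(n) < cfg$short_read_fraction
    if (any(short)) {
      tgt <- sample(60:(nchar(fwd) + 199), sum(short), replace = TRUE)
      trunc_to[short] <- pmin(tgt, nchar(nt[short]))
      nt[short] <- substr(nt[short], 1, trunc_to[short])
    }

    rid <- sprintf("%s_r%06d", s, seq_len(n))
    out_reads[[s]] <- data.frame(read_id = rid, sample = s, nt_seq = nt,
                                 stringsAsFactors = FALSE)
    out_sc[[s]] <- data.frame(read_id = rid, sample = s, origin_id = origin,
                              is_contaminant = is_cont,
                              truncated_to = trunc_to,
                              error_events = events,
                              stringsAsFactors = FALSE)
  }

  reads <- do.call(rbind, out_reads)
  sidecar <- do.call(rbind, out_sc)
  rownames(reads) <- rownames(sidecar) <- NULL

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (s in pool$samples) {
      r <- out_reads[[s]]
      write_fasta(stats::setNames(r$nt_seq, r$read_id),
                  file.path(outdir, paste0("reads_", s, ".fasta")))
    }
    write_tsv_file(sidecar, file.path(outdir, "truth_sidecar.tsv"))
  }
  list(reads = reads, sidecar = sidecar)
}

#' Emit reads that each carry exactly one homopolymer indel
#'
#' Purpose-built input for measuring frameshift-detection power: each read is
#' an error-free back-translated amplicon of a randomly chosen pool variant,
#' into which exactly one single-base insertion or deletion is placed at a
#' randomly chosen homopolymer run (length >= 2). With `coding_only = TRUE`
#' the run is restricted to the clipped coding window (first `clip_len` nt of
#' the insert), the only region where an indel can shift the analysed
#' reading frame.
#'
#' @param pool A `nifh_pool`.
#' @param n_reads Number of reads.
#' @param seed Integer seed.
#' @param coding_only Restrict the indel to the clipped coding window.
#' @param clip_len Length of the coding window (nt, after the forward
#'   primer).
#' @return List with `reads` (data frame) and `events` (position/type per
#'   read, positions in the pre-indel read).
#' @export
emit_frameshift_reads <- function(pool, n_reads, seed = 1L,
                                  coding_only = TRUE, clip_len = 180L) {
  stopifnot(inherits(pool, "nifh_pool"))
  cfg <- pool$config
  set.seed(seed)
  fwd <- cfg$fwd_primer
  rev3 <- revcomp(cfg$rev_primer)
  vids <- sample(pool$variants$variant_id, n_reads, replace = TRUE)
  ext_of <- stats::setNames(pool$variants$aa_ext, pool$variants$variant_id)

  nt <- character(n_reads)
  for (o in sort(unique(vids))) {
    idx <- which(vids == o)
    nt[idx] <- back_translate(ext_of[[o]], length(idx))
  }
  nt <- paste0(fwd, nt, rev3)

  pos <- integer(n_reads)
  type <- character(n_reads)
  lo <- nchar(fwd) + 1L
  hi <- if (coding_only) nchar(fwd) + clip_len else nchar(nt[1])
  for (i in seq_len(n_reads)) {
    ch <- strsplit(nt[i], "")[[1]]
    r <- rle(ch)
    run_start <- cumsum(c(1L, r$lengths[-length(r$lengths)]))
    ok <- which(r$lengths >= 2 & run_start >= lo &
                  (run_start + r$lengths - 1L) <= hi)
    if (length(ok) == 0) ok <- which(r$lengths >= 2 & run_start >= lo)
    k <- ok[sample.int(length(ok), 1)]
    p <- run_start[k]
    if (stats::runif(1) < 0.5) {
      ch <- append(ch, r$values[k], after = p)
      type[i] <- "ins"
    } else {
      ch <- ch[-p]
      type[i] <- "del"
    }
    pos[i] <- p
    nt[i] <- paste0(ch, collapse = "")
  }
  rid <- sprintf("FS_r%06d", seq_len(n_reads))
  list(
    reads = data.frame(read_id = rid, sample = "FS", nt_seq = nt,
                       stringsAsFactors = FALSE),
    events = data.frame(read_id = rid, origin_id = vids,
                        position = pos, type = type,
                        stringsAsFactors = FALSE)
  )
}

#' Generate a complete synthetic dataset (pool, reads, profile, references)
#'
#' Convenience wrapper: builds the variant pool, emits reads with the
#' configured error model, derives the position-specific profile from the
#' reference amino-acid set (true variants plus contaminants, the synthetic
#' analogue of a curated NifH reference alignment), and exposes the
#' contaminant database.
#'
#' @param config A [sim_config()].
#' @param outdir Optional output directory for FASTA/TSV artefacts.
#' @return List with `pool`, `reads`, `sidecar`, `profile`,
#'   `contaminant_db` (named character) and `reference_seqs`.
#' @export
simulate_dataset <- function(config, outdir = NULL) {
  pool <- generate_variant_pool(config)
  rr <- emit_reads(pool, outdir = outdir)
  refs <- c(stats::setNames(pool$variants$aa60, pool$variants$variant_id),
            stats::setNames(pool$contaminants$aa60,
                            pool$contaminants$contam_id))
  profile <- build_profile(refs)
  db <- stats::setNames(pool$contaminants$aa60, pool$contaminants$contam_id)
  if (!is.null(outdir)) {
    write_fasta(refs, file.path(outdir, "reference_aa.fasta"))
    write_fasta(db, file.path(outdir, "contaminant_db.fasta"))
    write_profile(profile, file.path(outdir, "profile.tsv"))
  }
  list(pool = pool, reads = rr$reads, sidecar = rr$sidecar,
       profile = profile, contaminant_db = db, reference_seqs = refs)
}
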