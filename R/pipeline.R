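# End-to-end orchestration: QC -> contaminant screen -> clustering ->
# diversity -> between-sample comparison, with deterministic seeding and
# plain-text outputs.

#' Pipeline configuration
#'
#' Defaults follow the survey protocol this pipeline implements: minimum
#' trimmed read length 200 nt, in-frame clip at 180 nt (60 codons),
#' contaminant removal at >= 96% identity, clustering at 100/96/92%
#' identity, clusters under 10 reads pruned, subsampling depth 2883 reads.
#'
#' @param min_len,clip_len,max_primer_mismatch QC parameters.
#' @param contaminant_id Percent-identity removal threshold.
#' @param cluster_levels Identity thresholds for clustering.
#' @param min_cluster_size Pruning threshold (total reads per cluster).
#' @param prune_levels Identity levels at which pruning is applied. The
#'   unique-sequence (100%) level is left unpruned by default so that
#'   microdiversity is reported in full; the group levels used for
#'   between-sample comparison and the phylogeny are pruned of sub-10-read
#'   clusters as artifact control.
#' @param subsample_depth Depth for diversity normalization.
#' @param sorensen_level,tree_level Thresholds used for the Sorensen matrix
#'   and for the phylogeny/UniFrac/PCoA stage.
#' @param fwd_primer,rev_primer Primer sequences for trimming.
#' @param seed Integer seed governing all stochastic stages (each stage
#'   derives its own deterministic stream).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(min_len = 200L, clip_len = 180L,
                            max_primer_mismatch = 1L,
                            contaminant_id = 96,
                            cluster_levels = c(100, 96, 92),
                            min_cluster_size = 10L,
                            prune_levels = c(96, 92),
                            subsample_depth = 2883L,
                            sorensen_level = 96,
                            tree_level = 92,
                            fwd_primer = SIM_FWD_PRIMER,
                            rev_primer = SIM_REV_PRIMER,
                            seed = 1L) {
  cfg <- list(min_len = as.integer(min_len), clip_len = as.integer(clip_len),
              max_primer_mismatch = as.integer(max_primer_mismatch),
              contaminant_id = contaminant_id,
              cluster_levels = cluster_levels,
              min_cluster_size = as.integer(min_cluster_size),
              prune_levels = prune_levels,
              subsample_depth = as.integer(subsample_depth),
              sorensen_level = sorensen_level, tree_level = tree_level,
              fwd_primer = fwd_primer, rev_primer = rev_primer,
              seed = as.integer(seed))
  if (cfg$min_len < cfg$clip_len) stop("min_len must be >= clip_len")
  if (cfg$clip_len %% 3L != 0L) stop("clip_len must be divisible by 3")
  if (!cfg$sorensen_level %in% cfg$cluster_levels ||
      !cfg$tree_level %in% cfg$cluster_levels) {
    stop("sorensen_level and tree_level must be among cluster_levels")
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the complete analysis pipeline
#'
#' Executes quality control, contaminant screening, multi-threshold
#' complete-linkage clustering with pruning, depth-normalized diversity
#' estimation, and between-sample comparison (Sorensen and overlap matrices
#' at the phylogenetic-group level; NJ tree, weighted UniFrac and PCoA at
#' the tree level). Reruns with the same inputs and config are
#' byte-identical.
#'
#' @param reads Data frame (`read_id`, `sample`, `nt_seq`) or character
#'   vector of per-sample FASTA paths (sample names taken from file names,
#'   `reads_<sample>.fasta` or `<sample>.fasta`).
#' @param profile A `nifh_profile` or path to a profile TSV; `NULL`
#'   disables the profile filter.
#' @param contaminant_db Named character vector of contaminant peptides or
#'   FASTA path; `NULL` disables screening.
#' @param config A [pipeline_config()].
#' @param outdir Optional output directory for all stage artefacts.
#' @return List with `qc`, `screen`, `clusters` (pruned `cluster_set`s by
#'   threshold), `prune_info`, `diversity`, `comparison` (sorensen,
#'   overlap, tree, unifrac, pcoa) and `manifest`.
#' @export
run_pipeline <- function(reads, profile = NULL, contaminant_db = NULL,
                         config = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(reads)) reads <- read_sample_fastas(reads)
  if (is.character(profile) && length(profile) == 1) {
    profile <- read_profile(profile)
  }
  if (is.character(contaminant_db) && length(contaminant_db) == 1 &&
      file.exists(contaminant_db)) {
    contaminant_db <- read_fasta(contaminant_db)
  }

  qc <- qc_reads(reads, profile,
                 fwd_primer = config$fwd_primer,
                 rev_primer = config$rev_primer,
                 min_len = config$min_len, clip_len = config$clip_len,
                 max_primer_mismatch = config$max_primer_mismatch)

  if (!is.null(contaminant_db)) {
    scr <- screen_contaminants(qc$proteins, contaminant_db,
                               threshold = config$contaminant_id)
    pset <- scr$retained
  } else {
    scr <- NULL
    pset <- qc$proteins
  }

  css <- cluster_thresholds(pset, thresholds = config$cluster_levels)
  prune_info <- lapply(css, function(cs) {
    if (cs$threshold %in% config$prune_levels) {
      prune_small_clusters(cs, min_size = config$min_cluster_size)
    } else {
      list(cluster_set = cs, removed_fraction = 0, n_removed_clusters = 0L)
    }
  })
  pruned <- lapply(prune_info, `[[`, "cluster_set")

  div <- diversity_report(pruned, depth = config$subsample_depth,
                          seed = config$seed)

  # comparison stage on subsampled counts; each level uses the samples that
  # reached the subsampling depth at that level
  comparison <- list()
  s_level <- as.character(config$sorensen_level)
  t_level <- as.character(config$tree_level)
  if (sum(names(div$subsampled[[s_level]]) != "mixed") >= 2) {
    ab96 <- subsample_matrix(div$subsampled[[s_level]],
                             exclude = "mixed",
                             clusters = pruned[[s_level]]$clusters$cluster_id)
    comparison$sorensen <- sorensen_matrix(ab96)
    comparison$overlap <- overlap_matrix(ab96)
  }
  if (sum(names(div$subsampled[[t_level]]) != "mixed") >= 2) {
    ab_tree <- subsample_matrix(div$subsampled[[t_level]],
                                exclude = "mixed",
                                clusters = pruned[[t_level]]$clusters$cluster_id)
    reps <- pruned[[t_level]]$rep_seqs
    if (length(reps) >= 3) {
      comparison$tree <- nj_tree(reps)
      keep <- rownames(ab_tree)[rowSums(ab_tree) > 0]
      comparison$unifrac <- unifrac_matrix(comparison$tree,
                                           ab_tree[keep, , drop = FALSE])
      comparison$pcoa <- pcoa_ordination(comparison$unifrac, n_axes = 2)
    }
  }

  manifest <- build_manifest(config, reads, qc, scr, pruned, div)

  if (!is.null(outdir)) {
    write_pipeline_outputs(outdir, qc, scr, pruned, prune_info, div,
                           comparison, manifest)
  }

  list(qc = qc, screen = scr, clusters = pruned, prune_info = prune_info,
       clusters_unpruned = css, diversity = div, comparison = comparison,
       manifest = manifest)
}

read_sample_fastas <- function(paths) {
  out <- lapply(paths, function(p) {
    s <- sub("\\.(fa|fasta|fna)$", "", basename(p))
    s <- sub("^reads_", "", s)
    x <- read_fasta(p)
    data.frame(read_id = names(x), sample = s, nt_seq = unname(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# subsampled counts (list sample -> named vector) -> cluster x sample matrix
subsample_matrix <- function(subs, exclude = character(0), clusters) {
  subs <- subs[setdiff(names(subs), exclude)]
  m <- matrix(0L, length(clusters), length(subs),
              dimnames = list(clusters, names(subs)))
  for (s in names(subs)) {
    v <- subs[[s]]
    m[names(v), s] <- as.integer(v)
  }
  m
}

overlap_matrix <- function(abund) {
  s <- colnames(abund)
  m <- matrix(0L, length(s), length(s), dimnames = list(s, s))
  for (i in seq_along(s)) {
    for (j in seq_along(s)) {
      oc <- overlap_count(abund, s[i], s[j])
      m[i, j] <- if (i == j) oc[["a"]] else oc[["j"]]
    }
  }
  m
}

build_manifest <- function(config, reads, qc, scr, pruned, div) {
  kv <- c(
    package = "nifhdiv",
    version = as.character(utils::packageVersion("nifhdiv")),
    seed = config$seed,
    n_reads_input = nrow(reads),
    n_samples = length(unique(reads$sample)),
    n_reads_qc_passed = sum(qc$read_status$stage == "passed"),
    n_unique_proteins = length(qc$proteins$seqs),
    subsample_depth = config$subsample_depth
  )
  for (t in names(div$excluded)) {
    kv[paste0("excluded_samples_", t)] <-
      paste(sort(div$excluded[[t]]), collapse = ",")
  }
  if (!is.null(scr)) {
    kv["n_reads_after_screen"] <- sum(scr$retained$counts)
    for (i in seq_len(nrow(scr$report))) {
      kv[paste0("screen_removed_fraction_", scr$report$sample[i])] <-
        format(scr$report$fraction[i], digits = 6)
    }
  }
  for (t in names(pruned)) {
    kv[paste0("n_clusters_", t)] <- nrow(pruned[[t]]$clusters)
  }
  data.frame(key = names(kv), value = unname(kv), stringsAsFactors = FALSE)
}

write_pipeline_outputs <- function(outdir, qc, scr, pruned, prune_info,
                                   div, comparison, manifest) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_file(qc$attrition, file.path(outdir, "attrition.tsv"))
  if (!is.null(scr)) {
    write_tsv_file(scr$report, file.path(outdir, "screen_report.tsv"))
  }
  for (t in names(pruned)) {
    cs <- pruned[[t]]
    write_tsv_file(
      data.frame(seq_id = names(cs$membership),
                 cluster_id = unname(cs$membership)),
      file.path(outdir, paste0("membership_", t, ".tsv"))
    )
    write_matrix_tsv(cs$abundance,
                     file.path(outdir, paste0("abundance_", t, ".tsv")),
                     label = "cluster_id")
    write_fasta(cs$rep_seqs,
                file.path(outdir, paste0("representatives_", t, ".fasta")))
  }
  write_tsv_file(div$table, file.path(outdir, "diversity.tsv"))
  if (!is.null(comparison$sorensen)) {
    write_matrix_tsv(comparison$sorensen,
                     file.path(outdir, "sorensen.tsv"))
    write_matrix_tsv(comparison$overlap, file.path(outdir, "overlap.tsv"))
  }
  if (!is.null(comparison$tree)) {
    write_newick(comparison$tree, file.path(outdir, "tree.nwk"))
    write_matrix_tsv(comparison$unifrac, file.path(outdir, "unifrac.tsv"))
    write_matrix_tsv(comparison$pcoa$coordinates,
                     file.path(outdir, "pcoa.tsv"))
  }
  write_tsv_file(manifest, file.path(outdir, "manifest.tsv"))
  invisible(outdir)
}
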