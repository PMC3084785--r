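test_that("a single variant pool has one cluster at every threshold", {
  cfg <- sim_config(n_samples = 1, variants_per_sample = 1,
                    reads_per_sample = 10, microdiversity = 1, rng_seed = 5)
  pool <- generate_variant_pool(cfg)
  expect_equal(nrow(pool$variants), 1L)
  expect_equal(nchar(pool$variants$aa60), 60L)
  expect_false(grepl("*", pool$variants$aa60, fixed = TRUE))
  expect_equal(unname(pool$truth$true_cluster_count), c(1L, 1L, 1L))
})

test_that("fully shared communities have true Sorensen 100", {
  cfg <- sim_config(n_samples = 2, variants_per_sample = 6,
                    shared_variant_fraction = 1, reads_per_sample = 10,
                    rng_seed = 6)
  pool <- generate_variant_pool(cfg)
  expect_equal(pool$truth$true_sorensen["S01", "S02"], 100)
})

test_that("designed families are mutually below the 92% threshold", {
  cfg <- sim_config(n_samples = 1, variants_per_sample = 5,
                    reads_per_sample = 10, microdiversity = 1, rng_seed = 7)
  pool <- generate_variant_pool(cfg)
  expect_equal(unname(pool$truth$true_cluster_count[["92"]]), 5L)
  # brute-force verification of all pairwise identities
  idm <- identity_matrix(stats::setNames(pool$variants$aa60,
                                         pool$variants$variant_id))
  diag(idm) <- 0
  expect_true(all(idm < 92))
})

test_that("designed truth matches brute-force clustering of the pool", {
  for (design in c("radial", "nested")) {
    cfg <- sim_config(n_samples = 3, variants_per_sample = 4,
                      reads_per_sample = 10, microdiversity = 4,
                      family_design = design, rng_seed = 8)
    pool <- generate_variant_pool(cfg)
    pset <- make_pset(pool$variants$aa60)
    css <- cluster_thresholds(pset)
    got <- vapply(css, function(cs) nrow(cs$clusters), integer(1))
    expect_equal(unname(got),
                 unname(pool$truth$true_cluster_count[names(css)]),
                 label = design)
  }
})

test_that("per-sample true abundances sum to one", {
  cfg <- sim_config(n_samples = 4, variants_per_sample = 7,
                    reads_per_sample = 10, rng_seed = 9,
                    n_outlier_samples = 1)
  pool <- generate_variant_pool(cfg)
  for (s in pool$samples) {
    expect_equal(sum(pool$sample_variants[[s]]$rel_abundance), 1)
  }
  # outlier sample shares nothing
  out <- pool$truth$outlier_samples
  expect_equal(unname(pool$truth$true_sorensen[out,
               setdiff(pool$samples, out)]), rep(0, 3))
})

test_that("infeasible identity designs fail explicitly", {
  expect_error(sim_config(microdiversity = 5, family_design = "nested"),
               "impossible identity design")
  expect_error(sim_config(microdiversity = 40, family_design = "radial"),
               "impossible identity design")
})

test_that("noiseless reads translate back to their origin exactly", {
  cfg <- noiseless_config(n_samples = 2, variants_per_sample = 4,
                          reads_per_sample = 50, rng_seed = 10)
  pool <- generate_variant_pool(cfg)
  rr <- emit_reads(pool)
  tr <- trim_primers(rr$reads$nt_seq, cfg$fwd_primer, cfg$rev_primer)
  expect_true(all(tr$reason == ""))
  aa <- clip_and_translate(tr$trimmed, clip_len = 180L)
  expect_false(any(aa$has_stop))
  origin60 <- stats::setNames(pool$variants$aa60, pool$variants$variant_id)
  expect_identical(unname(aa$aa), unname(origin60[rr$sidecar$origin_id]))
})

test_that("read emission is byte-identical for a fixed seed", {
  cfg <- sim_config(n_samples = 2, variants_per_sample = 3,
                    reads_per_sample = 60, contaminant_fraction = 0.1,
                    rng_seed = 11)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  emit_reads(generate_variant_pool(cfg), outdir = d1)
  emit_reads(generate_variant_pool(cfg), outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("contaminant spike-ins are conserved between reads and sidecar", {
  cfg <- noiseless_config(n_samples = 1, variants_per_sample = 3,
                          reads_per_sample = 1000,
                          contaminant_fraction = 0.1, rng_seed = 12)
  pool <- generate_variant_pool(cfg)
  rr <- emit_reads(pool)
  n_cont <- sum(rr$sidecar$is_contaminant)
  expect_gt(n_cont, 0)
  # every contaminant-labelled read really is of contaminant origin
  expect_true(all(grepl("^CONT",
                        rr$sidecar$origin_id[rr$sidecar$is_contaminant])))
  # label conservation against independently recounted origins
  expect_equal(n_cont, sum(rr$sidecar$origin_id %in%
                             pool$contaminants$contam_id))
})

test_that("an injected homopolymer deletion frameshifts the translation", {
  cfg <- noiseless_config(n_samples = 1, variants_per_sample = 5,
                          reads_per_sample = 10, rng_seed = 13)
  pool <- generate_variant_pool(cfg)
  fs <- emit_frameshift_reads(pool, 200, seed = 14)
  tr <- trim_primers(fs$reads$nt_seq, cfg$fwd_primer, cfg$rev_primer)
  aa <- clip_and_translate(tr$trimmed, clip_len = 180L)
  origin60 <- stats::setNames(pool$variants$aa60, pool$variants$variant_id)
  # reads whose 60 codons escaped a stop must still differ from their origin
  # at the frameshifted tail (unless the indel sits in the final codons and
  # resynchronises by chance)
  ok <- !aa$has_stop
  diverged <- aa$aa[ok] != unname(origin60[fs$events$origin_id[ok]])
  expect_gt(mean(diverged), 0.9)
  expect_gt(mean(aa$has_stop), 0.5)
})

test_that("sidecar error events report real positions and types", {
  cfg <- sim_config(n_samples = 1, variants_per_sample = 3,
                    reads_per_sample = 300, rng_seed = 15)
  rr <- emit_reads(generate_variant_pool(cfg))
  ev <- rr$sidecar$error_events
  ev <- ev[nzchar(ev)]
  expect_gt(length(ev), 0)
  parts <- unlist(strsplit(ev, "|", fixed = TRUE))
  expect_true(all(grepl("^[0-9]+:(sub|ins|del|ambig)$", parts)))
})
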