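fwd <- "TGCGACCCGAAGGCTGA"
rev <- "AGGGCCATCATTTCACC"
rc_rev <- "GGTGAAATGATGGCCCT"

test_that("primer trimming removes exact flanks and anchors the frame", {
  set.seed(31)
  insert <- paste0(sample(c("A", "C", "G", "T"), 240, replace = TRUE),
                   collapse = "")
  tr <- trim_primers(paste0(fwd, insert, rc_rev), fwd, rev)
  expect_equal(tr$trimmed, insert)
  expect_equal(tr$reason, "")
})

test_that("reads lacking the forward primer are rejected", {
  tr <- trim_primers("ACGTACGTACGTACGTACGTACGT", fwd, rev)
  expect_true(is.na(tr$trimmed))
  expect_equal(tr$reason, "fwd_primer")
})

test_that("one forward-primer mismatch is tolerated, two are not", {
  set.seed(32)
  insert <- paste0(sample(c("A", "C", "G", "T"), 240, replace = TRUE),
                   collapse = "")
  f1 <- fwd; substr(f1, 5, 5) <- setdiff(c("A","C","G","T"),
                                         substr(fwd, 5, 5))[1]
  tr1 <- trim_primers(paste0(f1, insert), fwd, rev)
  expect_equal(tr1$trimmed, insert)  # trim point found by construction
  f2 <- f1; substr(f2, 9, 9) <- setdiff(c("A","C","G","T"),
                                        substr(fwd, 9, 9))[1]
  tr2 <- trim_primers(paste0(f2, insert), fwd, rev)
  expect_true(is.na(tr2$trimmed))
})

test_that("degenerate IUPAC primer codes match their expansions", {
  tr <- trim_primers(paste0("ATGC", strrep("A", 220)), "ATGY", NULL)
  expect_equal(tr$reason, "")
  expect_equal(tr$trimmed, strrep("A", 220))
})

test_that("length and ambiguity filters enforce the documented boundaries", {
  r199 <- strrep("A", 199)
  r200 <- strrep("A", 200)
  r200n <- paste0(strrep("A", 199), "N")
  expect_equal(filter_length_ambiguity(c(r199, r200, r200n)),
               c("length", "", "ambiguity"))
})

test_that("clipping translates 60 in-frame codons and flags stops", {
  pep <- clip_and_translate(paste0(strrep("GCT", 60), strrep("T", 40)),
                            clip_len = 180L)
  expect_equal(pep$aa, strrep("A", 60))
  expect_false(pep$has_stop)
  withstop <- paste0(strrep("GCT", 6), "TAA", strrep("GCT", 53),
                     strrep("T", 40))
  expect_true(clip_and_translate(withstop, clip_len = 180L)$has_stop)
  expect_error(clip_and_translate(strrep("A", 300), clip_len = 100L),
               "divisible by 3")
})

test_that("a 1-nt deletion frameshifts the tail and is caught downstream", {
  set.seed(33)
  aa <- rand_aa(60)
  nt <- paste0(vapply(strsplit(aa, "")[[1]], function(a) {
    cands <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == a]
    cands[1]
  }, character(1)), collapse = "")
  nt_del <- paste0(substr(nt, 1, 49), substr(nt, 51, 180), strrep("A", 51))
  pep <- clip_and_translate(nt_del, clip_len = 180L)
  shifted <- as.character(Biostrings::translate(Biostrings::DNAString(
    substr(paste0(nt_del, "A"), 1, 180))))
  expect_equal(pep$has_stop, grepl("*", shifted, fixed = TRUE))
})

test_that("dereplication conserves counts and merges identical peptides", {
  ps <- dereplicate(c("AAW", "AAW", "AAW", "CCY"),
                    c("S1", "S1", "S2", "S2"))
  expect_length(ps$seqs, 2)
  expect_equal(sum(ps$counts), 4L)
  expect_equal(unname(rowSums(ps$counts)[ps$seqs == "AAW"]), 3)
  empty <- dereplicate(character(0), character(0))
  expect_length(empty$seqs, 0)

  set.seed(34)
  seqs <- sample(replicate(10, rand_aa(12)), 200, replace = TRUE)
  smp <- sample(c("a", "b", "c"), 200, replace = TRUE)
  ps2 <- dereplicate(seqs, smp)
  expect_equal(sum(ps2$counts), 200L)
  expect_equal(sort(unique(seqs)), sort(unname(ps2$seqs)))
})

test_that("profile filter retains the consensus and substituted copies", {
  set.seed(35)
  refs <- stats::setNames(replicate(5, rand_aa(60)), paste0("r", 1:5))
  prof <- build_profile(refs)
  cons <- refs[[1]]
  r <- profile_align(cons, prof)
  expect_true(r$retained)
  expect_equal(r$n_unaligned, 0L)
  # 3 scattered substitutions by residues seen elsewhere in the references
  sub3 <- cons
  for (p in c(10, 25, 40)) {
    substr(sub3, p, p) <- substr(refs[[2]], p, p)
  }
  expect_true(profile_align(sub3, prof)$retained)
  # an isolated unexpected residue is a mismatch, not an insert
  expect_true(profile_align(mutate_aa(cons, 1, positions = 30),
                            prof)$retained)
})

test_that("inserted residues force insert states and rejection", {
  set.seed(36)
  refs <- stats::setNames(replicate(5, rand_aa(40)), paste0("r", 1:5))
  prof <- build_profile(refs)
  cons <- refs[[1]]
  ins5 <- paste0(substr(cons, 1, 20), "WWWWW", substr(cons, 21, 40))
  r <- profile_align(ins5, prof)
  expect_false(r$retained)
  expect_gte(r$n_unaligned, 1L)
  # batch filter agrees with the single-sequence aligner
  batch <- profile_align_filter(c(a = cons, b = ins5), prof)
  expect_identical(unname(batch$retained), c(TRUE, FALSE))
  expect_equal(unname(batch$score["b"]), r$score)
})

test_that("profiles need at least 30 match states to be used for filtering", {
  refs <- c(a = rand_aa(20))
  expect_error(profile_align_filter(c(x = rand_aa(20)),
                                    build_profile(refs)), "30 match states")
})

test_that("attrition log is monotone and accounts for every read", {
  cfg <- sim_config(n_samples = 3, variants_per_sample = 5,
                    reads_per_sample = 250, contaminant_fraction = 0.05,
                    rng_seed = 37)
  sd <- simulate_dataset(cfg)
  qc <- qc_reads(sd$reads, sd$profile)
  att <- as.matrix(qc$attrition[, -1])
  expect_true(all(att[, -1] <= att[, -ncol(att)]))
  expect_equal(sum(att[, "after_profile_filter"]),
               sum(qc$read_status$stage == "passed"))
  expect_equal(sum(qc$proteins$counts),
               sum(qc$read_status$stage == "passed"))
})

test_that("noiseless data suffers no stop or profile losses", {
  cfg <- noiseless_config(n_samples = 2, variants_per_sample = 5,
                          reads_per_sample = 200, rng_seed = 38)
  sd <- simulate_dataset(cfg)
  qc <- qc_reads(sd$reads, sd$profile)
  expect_equal(qc$attrition$after_clip, qc$attrition$after_stop_filter)
  expect_equal(qc$attrition$after_clip, qc$attrition$after_profile_filter)
  expect_equal(qc$attrition$input, qc$attrition$after_profile_filter)
})

test_that("filtering before or after dereplication keeps the same peptides", {
  set.seed(39)
  refs <- stats::setNames(replicate(6, rand_aa(60)), paste0("r", 1:6))
  prof <- build_profile(refs)
  good <- refs[[1]]
  bad <- paste0(substr(refs[[2]], 1, 30), rand_aa(10),
                substr(refs[[2]], 41, 60))
  reads_aa <- sample(c(rep(good, 20), rep(bad, 10),
                       rep(mutate_aa(good, 1), 5)))
  smp <- sample(c("x", "y"), length(reads_aa), replace = TRUE)

  # filter then dereplicate
  keep1 <- profile_align_filter(stats::setNames(reads_aa,
             seq_along(reads_aa)), prof)$retained
  setA <- sort(unique(reads_aa[keep1]))
  # dereplicate then filter
  ps <- dereplicate(reads_aa, smp)
  keep2 <- profile_align_filter(ps$seqs, prof)$retained
  setB <- sort(unname(ps$seqs[keep2]))
  expect_identical(setA, setB)
})
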