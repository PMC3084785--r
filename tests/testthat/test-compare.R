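test_that("sorensen follows 2j/(a+b) with its edge cases", {
  ab <- matrix(0L, 8, 3, dimnames = list(paste0("c", 1:8),
                                         c("A", "B", "C")))
  ab[1:3, "A"] <- 2L
  ab[c(2, 3, 4, 5, 6), "B"] <- 1L
  expect_equal(sorensen(ab, "A", "B"), 200 * 2 / (3 + 5))  # 50
  ab[7:8, "C"] <- 4L
  expect_equal(sorensen(ab, "A", "C"), 0)
  ab2 <- ab; ab2[, "C"] <- ab2[, "A"]
  expect_equal(sorensen(ab2, "A", "C"), 100)
  ab3 <- matrix(0L, 2, 2, dimnames = list(c("c1", "c2"), c("A", "B")))
  expect_true(is.na(sorensen(ab3, "A", "B")))
  m <- sorensen_matrix(ab)
  expect_true(isSymmetric(m))
  expect_equal(m["A", "B"], 50)
})

test_that("neighbor joining recovers additive four-taxon trees exactly", {
  # ((A:1,B:2):1.5,(C:0.5,D:3):1); path distances are additive
  D <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 3
  D["A", "C"] <- D["C", "A"] <- 4
  D["A", "D"] <- D["D", "A"] <- 6.5
  D["B", "C"] <- D["C", "B"] <- 5
  D["B", "D"] <- D["D", "B"] <- 7.5
  D["C", "D"] <- D["D", "C"] <- 3.5
  tree <- nj_tree(D)
  back <- ape::cophenetic.phylo(tree)[rownames(D), colnames(D)]
  expect_equal(back, D, tolerance = 1e-9)
  expect_true(all(tree$edge.length >= 0))
})

test_that("three ultrametric taxa resolve to the closed-form star", {
  D <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- nj_tree(D)
  len <- stats::setNames(tree$edge.length[match(seq_len(3),
                                                tree$edge[, 2])],
                         tree$tip.label)
  expect_equal(unname(len[c("A", "B", "C")]), c(1, 1, 3), tolerance = 1e-9)
})

test_that("identical sequences among taxa yield zero-length terminal branches", {
  set.seed(71)
  a <- rand_aa(60)
  seqs <- c(t1 = a, t2 = a, t3 = mutate_aa(a, 10), t4 = mutate_aa(a, 25))
  tree <- nj_tree(seqs)
  tiplen <- tree$edge.length[match(match(c("t1", "t2"), tree$tip.label),
                                   tree$edge[, 2])]
  expect_equal(tiplen, c(0, 0), tolerance = 1e-9)
  expect_error(nj_tree(seqs[1:2]), "at least 3")
})

test_that("weighted unifrac matches hand evaluation on a two-leaf tree", {
  tree <- ape::read.tree(text = "(L1:1,L2:1);")
  ab <- matrix(c(10L, 0L, 0L, 7L), 2, 2,
               dimnames = list(c("L1", "L2"), c("A", "B")))
  expect_equal(weighted_unifrac(tree, ab, "A", "B"), 2)
  expect_equal(weighted_unifrac(tree, ab, "A", "A"), 0)
  # scaling invariance
  ab2 <- ab; ab2[, "A"] <- ab2[, "A"] * 10L
  expect_equal(weighted_unifrac(tree, ab2, "A", "B"), 2)
  # normalized form is 1 for completely disjoint communities
  expect_equal(weighted_unifrac(tree, ab, "A", "B", normalized = TRUE), 1)
  expect_error(weighted_unifrac(tree, rbind(ab, L9 = c(1L, 1L)), "A", "B"),
               "L9")
})

test_that("raw weighted unifrac is a metric on random small instances", {
  set.seed(72)
  for (rep in 1:10) {
    n_leaf <- sample(4:7, 1)
    tree <- ape::rtree(n_leaf, br = stats::runif)
    ab <- matrix(stats::rpois(n_leaf * 3, 5), n_leaf, 3,
                 dimnames = list(tree$tip.label, c("A", "B", "C")))
    ab[1, ] <- ab[1, ] + 1L  # keep column sums positive
    m <- unifrac_matrix(tree, ab)
    expect_true(isSymmetric(m))
    expect_equal(unname(diag(m)), rep(0, 3))
    combs <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3))
    for (cb in combs) {
      expect_lte(m[cb[1], cb[2]],
                 m[cb[1], cb[3]] + m[cb[3], cb[2]] + 1e-12)
    }
  }
})

test_that("weighted unifrac agrees with phyloseq on random instances", {
  skip_if_not_installed("phyloseq")
  set.seed(73)
  for (rep in 1:3) {
    n_leaf <- sample(5:9, 1)
    tree <- ape::rtree(n_leaf, br = stats::runif)
    ab <- matrix(stats::rpois(n_leaf * 2, 6) + 1L, n_leaf, 2,
                 dimnames = list(tree$tip.label, c("A", "B")))
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(ab, taxa_are_rows = TRUE),
      phyloseq::phy_tree(tree)
    )
    ref_raw <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                           normalized = FALSE))["A", "B"]
    expect_equal(weighted_unifrac(tree, ab, "A", "B"), ref_raw,
                 tolerance = 1e-9)
    ref_norm <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                            normalized = TRUE))["A", "B"]
    expect_equal(weighted_unifrac(tree, ab, "A", "B", normalized = TRUE),
                 ref_norm, tolerance = 1e-9)
  }
})

test_that("pcoa reproduces collinear geometry and the two-sample split", {
  pts <- c(0, 1, 3)
  D <- as.matrix(stats::dist(pts))
  dimnames(D) <- list(c("p1", "p2", "p3"), c("p1", "p2", "p3"))
  ord <- pcoa_ordination(D, n_axes = 2)
  x <- ord$coordinates[, 1]
  expect_equal(unname(abs(diff(x[c(1, 2)]))), 1, tolerance = 1e-9)
  expect_equal(unname(abs(diff(x[c(1, 3)]))), 3, tolerance = 1e-9)
  expect_equal(mean(x), 0, tolerance = 1e-12)

  D2 <- matrix(c(0, 4, 4, 0), 2, 2, dimnames = list(c("a", "b"),
                                                    c("a", "b")))
  ord2 <- pcoa_ordination(D2)
  expect_equal(sort(ord2$coordinates[, 1]), c(-2, 2), tolerance = 1e-9,
               ignore_attr = TRUE)

  ord0 <- pcoa_ordination(matrix(0, 3, 3), n_axes = 2)
  expect_true(all(ord0$coordinates == 0))
})

test_that("pcoa on euclidean distances reproduces all pairwise distances", {
  set.seed(74)
  X <- matrix(stats::rnorm(7 * 3), 7, 3)
  D <- as.matrix(stats::dist(X))
  ord <- pcoa_ordination(D, n_axes = 7)
  k <- sum(ord$eigenvalues > 1e-9)
  Dhat <- as.matrix(stats::dist(ord$coordinates[, seq_len(k)]))
  expect_equal(unname(Dhat), unname(D), tolerance = 1e-9)
  expect_equal(ord$eigenvalues, sort(ord$eigenvalues, decreasing = TRUE))
  expect_equal(sum(ord$proportion_explained), 1, tolerance = 1e-12)
  # agreement with the classical scaling in stats
  cmd <- stats::cmdscale(D, k = 2, eig = TRUE)
  expect_equal(abs(unname(ord$coordinates[, 1:2])), abs(unname(cmd$points)),
               tolerance = 1e-9)
})

test_that("sorensen and normalized unifrac rank community overlap concordantly", {
  set.seed(75)
  shared_grid <- rep(seq(0, 1, length.out = 10), 2)
  cs_vals <- numeric(length(shared_grid))
  uf_vals <- numeric(length(shared_grid))
  for (i in seq_along(shared_grid)) {
    cfg <- noiseless_config(n_samples = 2, variants_per_sample = 8,
                            shared_variant_fraction = shared_grid[i],
                            reads_per_sample = 10, microdiversity = 1,
                            rng_seed = 7500 + i)
    pool <- generate_variant_pool(cfg)
    # abundance matrix straight from designed truth
    vids <- pool$variants$variant_id
    ab <- matrix(0, length(vids), 2, dimnames = list(vids, pool$samples))
    for (s in pool$samples) {
      sv <- pool$sample_variants[[s]]
      ab[sv$variant_id, s] <- round(1000 * sv$rel_abundance)
    }
    tree <- nj_tree(stats::setNames(pool$variants$aa60, vids))
    keep <- rowSums(ab) > 0
    cs_vals[i] <- sorensen(ab, "S01", "S02")
    uf_vals[i] <- 1 - weighted_unifrac(tree, ab[keep, ], "S01", "S02",
                                       normalized = TRUE)
  }
  expect_gte(stats::cor(cs_vals, uf_vals, method = "spearman"), 0.8)
})
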