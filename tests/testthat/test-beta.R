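test_that("Bray-Curtis matches hand values and the brute-force double loop", {
  m <- matrix(c(2L, 2L,
                2L, 0L), nrow = 2, byrow = TRUE,
              dimnames = list(c("t1", "t2"), c("A", "B")))
  d <- bray_curtis(m)
  expect_equal(d["A", "B"], 1 / 3)
  expect_equal(diag(d), c(A = 0, B = 0))

  ident <- matrix(c(3L, 1L, 3L, 1L), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(bray_curtis(ident)["x", "y"], 0)
  disjoint <- matrix(c(4L, 0L, 0L, 6L), 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(bray_curtis(disjoint)["x", "y"], 1)

  set.seed(1)
  r <- matrix(rpois(60, 8), nrow = 10,
              dimnames = list(paste0("t", 1:10), paste0("s", 1:6)))
  d <- bray_curtis(r)
  for (i in 1:5) for (j in (i + 1):6) {
    expect_equal(d[i, j], brute_bray(r[, i], r[, j]), tolerance = 1e-12)
  }
})

test_that("weighted UniFrac reduces to hand values on small trees", {
  tree <- ape::read.tree(text = "(t1:1,t2:1);")
  m <- matrix(c(10L, 0L, 0L, 10L), 2,
              dimnames = list(c("t1", "t2"), c("A", "B")))
  expect_equal(weighted_unifrac(m, tree, normalized = TRUE)["A", "B"], 1)
  expect_equal(weighted_unifrac(m, tree, normalized = FALSE)["A", "B"], 2)

  same <- matrix(c(3L, 7L, 3L, 7L), 2,
                 dimnames = list(c("t1", "t2"), c("A", "B")))
  expect_equal(weighted_unifrac(same, tree)["A", "B"], 0)
})

test_that("weighted UniFrac is invariant to taxon row order", {
  tree <- ape::read.tree(text = "((t1:0.5,t2:0.3):0.2,(t3:0.4,t4:0.1):0.6);")
  set.seed(3)
  m <- matrix(rpois(12, 20) + 1L, 4,
              dimnames = list(c("t1", "t2", "t3", "t4"), c("A", "B", "C")))
  d1 <- weighted_unifrac(m, tree)
  d2 <- weighted_unifrac(m[c(3, 1, 4, 2), ], tree)
  expect_equal(d1, d2)
})

test_that("weighted UniFrac agrees with an independent implementation", {
  skip_if_not_installed("phyloseq")
  set.seed(11)
  tree <- ape::rtree(8, rooted = TRUE)
  m <- matrix(rpois(8 * 4, 15) + 1L, 8,
              dimnames = list(tree$tip.label, paste0("s", 1:4)))
  ours <- weighted_unifrac(m, tree, normalized = TRUE)
  ps <- phyloseq::phyloseq(phyloseq::otu_table(m, taxa_are_rows = TRUE),
                           phyloseq::phy_tree(tree))
  ref <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE, normalized = TRUE))
  expect_equal(ours, ref[rownames(ours), colnames(ours)], tolerance = 1e-8)
})

test_that("weighted UniFrac validates its tree", {
  tree <- ape::read.tree(text = "(t1:1,t2:1);")
  m <- matrix(c(1L, 1L, 2L, 1L), 2,
              dimnames = list(c("t1", "tX"), c("A", "B")))
  expect_error(weighted_unifrac(m, tree), "tX")
  tree2 <- ape::read.tree(text = "(t1:1,t2:-1);")
  m2 <- matrix(c(1L, 1L, 2L, 1L), 2, dimnames = list(c("t1", "t2"), c("A", "B")))
  expect_error(weighted_unifrac(m2, tree2), "negative branch length")
})

test_that("PCoA embeds three collinear points on one axis", {
  d <- matrix(c(0, 1, 2,
                1, 0, 1,
                2, 1, 0), 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  ord <- pcoa(d)
  expect_equal(ncol(ord$coordinates), 1)
  expect_equal(ord$percent_explained, 100)
  expect_equal(abs(ord$coordinates[, 1]), c(a = 1, b = 0, c = 1))
  expect_equal(ord$coordinates["a", 1], -ord$coordinates["c", 1])
})

test_that("PCoA of Euclidean distances reproduces the point cloud exactly", {
  set.seed(5)
  pts <- matrix(rnorm(7 * 3), 7, 3)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("s", 1:7), paste0("s", 1:7))
  ord <- pcoa(d)
  rec <- as.matrix(dist(ord$coordinates))
  expect_lt(max(abs(rec - d)), 1e-8)
  # eigenvalues agree with classical MDS
  ref <- cmdscale(d, k = 6, eig = TRUE)
  expect_equal(ord$eigenvalues[1:6], ref$eig[1:6], tolerance = 1e-8)
})

test_that("PCoA gives identical coordinates to identical samples", {
  m <- matrix(c(5L, 2L, 5L, 2L, 1L, 9L), 2,
              dimnames = list(c("a", "b"), c("s1", "s2", "s3")))
  ord <- pcoa(bray_curtis(m))
  expect_equal(ord$coordinates["s1", ], ord$coordinates["s2", ])
})

test_that("PCoA rejects non-symmetric input and reports negative eigenvalues", {
  d <- matrix(c(0, 1, 2, 0), 2)
  expect_error(pcoa(d), "not symmetric")
  # non-Euclidean distances: negative eigenvalues reported, excluded from percents
  dn <- matrix(c(0, 1, 1, 1,
                 1, 0, 1, 1,
                 1, 1, 0, 1.9,
                 1, 1, 1.9, 0), 4, dimnames = list(letters[1:4], letters[1:4]))
  ord <- pcoa(dn)
  expect_true(any(ord$eigenvalues < 0))
  expect_equal(sum(ord$percent_explained), 100)
  expect_true(all(diff(ord$eigenvalues) <= 1e-12))
})
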