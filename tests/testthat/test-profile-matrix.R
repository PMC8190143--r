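test_that("profiles count genes per species and conserve totals", {
  cl <- data.frame(gene_id = c("gA1", "gA2", "gB1"),
                   cluster_id = "c1", stringsAsFactors = FALSE)
  sp <- c(gA1 = "A", gA2 = "A", gB1 = "B")
  m <- build_profiles(cl, sp)
  expect_equal(m["A", "c1"], 2L)
  expect_equal(m["B", "c1"], 1L)
  expect_equal(binarize(m)["A", "c1"], 1L)

  # absent species yields an all-zero row plus a warning
  expect_warning(m2 <- build_profiles(cl, sp, species = c("A", "B", "C")),
                 "C")
  expect_equal(sum(m2["C", ]), 0L)

  # permutation invariance and gene-count conservation
  set.seed(31)
  cl3 <- data.frame(gene_id = sprintf("g%02d", 1:20),
                    cluster_id = sample(c("c1", "c2", "c3"), 20, TRUE))
  sp3 <- stats::setNames(sample(c("A", "B"), 20, TRUE), cl3$gene_id)
  m3 <- build_profiles(cl3, sp3)
  m3p <- build_profiles(cl3[sample(20), ], sp3)
  expect_identical(m3, m3p)
  expect_equal(sum(m3), 20L)
})

test_that("binarize is the presence indicator and idempotent", {
  m <- matrix(c(2L, 0L, 1L, 0L, 0L, 3L), nrow = 2, byrow = TRUE)
  b <- binarize(m)
  expect_equal(b, matrix(c(1L, 0L, 1L, 0L, 0L, 1L), nrow = 2, byrow = TRUE))
  expect_equal(binarize(b), b)
})

test_that("CSSC selection applies median, breadth and group rules", {
  m <- matrix(c(1, 1, 1, 0,
                1, 1, 1, 1,
                3, 3, 3, 3), nrow = 4,
              dimnames = list(paste0("s", 1:4), c("cA", "cB", "cC")))
  groups <- list(g1 = c("s1", "s2"), g2 = c("s3", "s4"))
  sel <- select_cssc(m, min_presence_frac = 0.9, groups = groups)
  expect_false("cA" %in% sel)  # present in 3/4 < ceiling(0.9*4)
  expect_true("cB" %in% sel)   # median 1 < 2, present everywhere
  expect_false("cC" %in% sel)  # median 3 >= 2
  expect_error(select_cssc(m, groups = list(g = character())), "empty group")

  # monotonicity: raising the presence requirement never adds clusters
  set.seed(32)
  big <- matrix(rpois(10 * 40, 0.9), nrow = 10,
                dimnames = list(paste0("s", 1:10), paste0("c", 1:40)))
  big <- big[, colSums(big) > 0]
  lo <- select_cssc(big, min_presence_frac = 0.5)
  hi <- select_cssc(big, min_presence_frac = 0.8)
  expect_true(all(hi %in% lo))
})

test_that("MRL split encoding codes supported bipartitions", {
  tr <- ape::read.tree(text = "((A:1,B:1)90:1,(C:1,D:1)90:1);")
  m <- encode_mrl_splits(tr, min_support = 85)
  # one nontrivial split AB|CD on 4 taxa
  expect_equal(ncol(m), 1L)
  expect_equal(unname(m[, 1]), c(0L, 0L, 1L, 1L))  # A-side coded 0

  low <- ape::read.tree(text = "((A:1,B:1)80:1,(C:1,D:1)80:1);")
  expect_equal(ncol(encode_mrl_splits(low, min_support = 85)), 0L)

  # identical trees contribute one column per tree
  m2 <- encode_mrl_splits(list(tr, tr), min_support = 85)
  expect_equal(ncol(m2), 2L)
  expect_equal(m2[, 1], m2[, 2])

  bad <- ape::read.tree(text = "((A:1,B:1)90:1,(C:1,E:1)90:1);")
  expect_error(encode_mrl_splits(list(tr, bad)), "identical leaf set")
})

test_that("a fully supported binary tree encodes n-3 splits", {
  set.seed(33)
  for (n in c(5, 8, 12)) {
    tr <- ape::rtree(n)
    tr$node.label <- rep("100", tr$Nnode)
    m <- encode_mrl_splits(tr, min_support = 85)
    expect_equal(ncol(m), n - 3L)
  }
})

test_that("split polarity does not change the symmetric-model likelihood", {
  tr <- ape::rtree(6)
  tr$node.label <- rep("100", tr$Nnode)
  m <- encode_mrl_splits(tr, min_support = 85)
  model <- mk_model(pi0 = 0.5, k = 1)
  expect_equal(log_likelihood(tr, m, model),
               log_likelihood(tr, 1L - m, model), tolerance = 1e-10)
})

test_that("clade-signal queries and Jaccard profiles behave as defined", {
  taxa <- c("M1", "M2", "Mo1", "Mo2", "E1", "E2")
  m <- cbind(c1 = c(1, 1, 1, 1, 0, 0),
             c2 = c(1, 1, 1, 1, 1, 0),
             c3 = c(1, 1, 1, 1, 0, 0))
  rownames(m) <- taxa
  hit <- clade_signal_clusters(m, in_taxa = taxa[1:4], out_taxa = taxa[5:6])
  expect_setequal(hit, c("c1", "c3"))

  d <- profile_dendrogram(m)
  dm <- as.matrix(d$dist)
  expect_equal(dm["c1", "c3"], 0)       # identical columns
  disj <- cbind(a = c(1, 1, 0, 0, 0, 0), b = c(0, 0, 1, 1, 0, 0))
  rownames(disj) <- taxa
  expect_equal(as.matrix(profile_dendrogram(disj)$dist)["a", "b"], 1)
  expect_s3_class(d$phylo, "phylo")
})
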