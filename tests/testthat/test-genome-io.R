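test_that("gene positions are ranked per chromosome with deterministic ties", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t100\t200\tg1", "chr1\t50\t80\tg2",
               "chr2\t10\t40\tg3"), f)
  g <- read_gene_positions(f, species = "sp")
  expect_equal(g$rank[g$gene_id == "g2"], 0L)
  expect_equal(g$rank[g$gene_id == "g1"], 1L)
  expect_equal(g$rank[g$gene_id == "g3"], 0L)

  # equal starts: lexicographic gene id breaks the tie
  writeLines(c("chr1\t100\t200\tgB", "chr1\t100\t150\tgA"), f)
  g <- read_gene_positions(f, species = "sp")
  expect_equal(g$gene_id[order(g$rank)], c("gA", "gB"))

  # ranks are a bijection onto 0..n-1 per chromosome
  set.seed(1)
  starts <- sample.int(1e6, 30)
  writeLines(sprintf("chr%d\t%d\t%d\tg%03d", sample(1:3, 30, TRUE),
                     starts, starts + 10L, 1:30), f)
  g <- read_gene_positions(f, species = "sp")
  for (ch in unique(g$chromosome)) {
    expect_setequal(g$rank[g$chromosome == ch],
                    seq_len(sum(g$chromosome == ch)) - 1L)
  }
})

test_that("gene position errors name the offender", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t1\t2\tg1", "chr1\t5\t6\tg1"), f)
  expect_error(read_gene_positions(f, "sp"), "duplicate gene id g1")
  writeLines(c("chr1\t1\t2\tg1", "chr1\tx\t6\tg2"), f)
  expect_error(read_gene_positions(f, "sp"), "line 2")
  writeLines("chr1\t1\tg1", f)
  expect_error(read_gene_positions(f, "sp"), ">= 4")
})

test_that("homology tables drop self hits and validate columns", {
  f <- withr::local_tempfile()
  pad <- paste(rep("0", 8), collapse = "\t")
  writeLines(c(paste("g1", "g1", pad, "1e-50", "200", sep = "\t"),
               paste("g1", "g2", pad, "1e-50", "200", sep = "\t")), f)
  h <- read_homology_table(f)
  expect_equal(nrow(h), 1L)
  expect_equal(h$subject, "g2")
  expect_equal(h$evalue, 1e-50)

  writeLines(character(), f)
  expect_equal(nrow(read_homology_table(f)), 0L)

  writeLines(paste("g1", "g2", "1e-50", "200", sep = "\t"), f)
  expect_error(read_homology_table(f), "line 1")
  writeLines(paste("g1", "g2", pad, "zzz", "200", sep = "\t"), f)
  expect_error(read_homology_table(f), "e-value")
})

test_that("binary PHYLIP writing round trips and stays unwrapped", {
  m <- matrix(c(1L, 0L, 1L, 0L, 1L, 1L), nrow = 2, byrow = TRUE,
              dimnames = list(c("A", "B"), NULL))
  f <- withr::local_tempfile()
  write_binary_phylip(m, f)
  expect_equal(readLines(f), c("2 3", "A 101", "B 011"))
  back <- read_binary_phylip(f)
  expect_equal(unname(back), unname(m))
  expect_equal(rownames(back), rownames(m))

  # wide matrices: one line per species regardless of width
  set.seed(2)
  wide <- matrix(rbinom(3 * 5000, 1, 0.4), nrow = 3,
                 dimnames = list(c("sp1", "sp2", "sp3"), NULL))
  write_binary_phylip(wide, f)
  expect_length(readLines(f), 4L)
  expect_equal(unname(read_binary_phylip(f)), unname(wide))

  rownames(m) <- c("A A", "B")
  expect_error(write_binary_phylip(m, f), "whitespace")
})

test_that("random binary matrices survive the PHYLIP round trip", {
  f <- withr::local_tempfile()
  set.seed(3)
  for (i in 1:5) {
    n <- sample(2:10, 1)
    m <- matrix(rbinom(n * sample(1:50, 1), 1, runif(1)), nrow = n)
    rownames(m) <- sprintf("taxon_%02d", seq_len(n))
    write_binary_phylip(m, f)
    expect_identical(read_binary_phylip(f), m)
  }
})

test_that("newick IO preserves topology, lengths and support labels", {
  f <- withr::local_tempfile()
  writeLines("((A:1,B:1):0.5,C:1.5);", f)
  tr <- read_newick(f)
  f2 <- withr::local_tempfile()
  write_newick(tr, f2)
  tr2 <- read_newick(f2)
  expect_equal(rf_distance(tr, tr2), 0)
  expect_equal(sum(tr$edge.length), sum(tr2$edge.length))

  writeLines("((A,B)95,(C,D)88);", f)
  tr <- read_newick(f)
  expect_true("95" %in% tr$node.label)

  writeLines("((A:1,B:1:0.5,C:1.5);", f)
  expect_error(read_newick(f), "unbalanced")
  writeLines("((A,B),(A,C));", f)
  expect_error(read_newick(f), "duplicate leaf")
})

test_that("cluster assignment ingestion detects conflicts", {
  f <- withr::local_tempfile()
  writeLines(c("g1\tc1", "g2\tc1", "g3\tc2"), f)
  m <- read_cluster_assignments(f)
  expect_equal(m[["g1"]], "c1")
  expect_equal(m[["g3"]], "c2")
  writeLines(character(), f)
  expect_length(read_cluster_assignments(f), 0L)
  writeLines(c("g1\tc1", "g1\tc2"), f)
  expect_error(read_cluster_assignments(f), "more than one cluster")
})
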