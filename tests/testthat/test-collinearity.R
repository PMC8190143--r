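test_that("top-hit filtering ranks by evalue, bitscore, subject", {
  h <- hits_frame(query = rep("q1", 7), subject = sprintf("s%d", 1:7),
                  evalue = c(1e-10, 1e-50, 1e-20, 1e-5, 1e-40, 1e-30, 1e-3),
                  bitscore = 100)
  expect_equal(nrow(filter_top_hits(h, 5)), 5L)
  expect_false(any(filter_top_hits(h, 5)$evalue > 1e-10))
  expect_equal(nrow(filter_top_hits(h[1:3, ], 5)), 3L)

  tie <- hits_frame(query = c("q1", "q1"), subject = c("sA", "sB"),
                    evalue = 1e-20, bitscore = c(180, 200))
  expect_equal(filter_top_hits(tie, 1)$subject, "sB")
  expect_error(filter_top_hits(tie, 0), "b_top")
})

test_that("tandem arrays collapse to the smallest-evalue representative", {
  rec <- random_toy_genomes(8, 8)
  # a1, a2 adjacent, both hit b1
  h <- hits_frame(query = c("x01", "x02"), subject = c("y01", "y01"),
                  evalue = c(1e-50, 1e-30))
  out <- collapse_tandem(h, rec, tandem_gap = 5)
  expect_equal(out$query, "x01")

  # six ranks apart: outside the gap, both kept
  h2 <- hits_frame(query = c("x01", "x08"), subject = c("y01", "y01"),
                   evalue = c(1e-50, 1e-30))
  expect_equal(nrow(collapse_tandem(h2, rec, 5)), 2L)

  # transitive chaining: x1..x3 consecutive, all hitting y1
  h3 <- hits_frame(query = c("x01", "x02", "x03"), subject = "y01",
                   evalue = c(1e-10, 1e-40, 1e-20))
  out3 <- collapse_tandem(h3, rec, 5)
  expect_equal(out3$query, "x02")

  expect_error(collapse_tandem(hits_frame("nope", "y01"), rec, 5),
               "unknown gene")
})

test_that("block detection matches the worked chaining examples", {
  rec <- random_toy_genomes(5, 5, species = c("X", "Y"))
  h <- hits_frame(query = c("x01", "x02", "x04", "x05"),
                  subject = c("y01", "y02", "y04", "y05"))
  b <- detect_blocks(h, rec, collinearity_params(a_min = 4, g_max = 2))
  expect_length(b, 1L)
  expect_equal(b[[1]]$score, 4L)
  expect_equal(b[[1]]$orientation, "forward")

  expect_length(detect_blocks(h, rec,
                              collinearity_params(a_min = 5, g_max = 2)), 0L)

  h_rev <- hits_frame(query = c("x01", "x02", "x03"),
                      subject = c("y05", "y04", "y03"))
  b_rev <- detect_blocks(h_rev, rec,
                         collinearity_params(a_min = 3, g_max = 0))
  expect_length(b_rev, 1L)
  expect_equal(b_rev[[1]]$orientation, "reverse")
  expect_equal(b_rev[[1]]$score, 3L)
})

test_that("reported blocks always satisfy the chain invariants", {
  set.seed(11)
  for (i in 1:20) {
    rec <- random_toy_genomes(12, 12)
    n_hits <- sample(5:15, 1)
    h <- hits_frame(query = sprintf("x%02d", sample(12, n_hits, TRUE)),
                    subject = sprintf("y%02d", sample(12, n_hits, TRUE)),
                    evalue = 10^-sample(5:60, n_hits, TRUE))
    h <- h[!duplicated(h[, 1:2]), ]
    g_max <- sample(0:3, 1)
    blocks <- detect_blocks(h, rec,
                            collinearity_params(a_min = 2, g_max = g_max))
    rank_of <- stats::setNames(rec$rank, rec$gene_id)
    for (b in blocks) {
      qr <- rank_of[b$anchors[, 1]]
      sr <- rank_of[b$anchors[, 2]]
      expect_true(all(diff(qr) > 0))
      if (b$orientation == "forward") {
        expect_true(all(diff(sr) > 0))
      } else {
        expect_true(all(diff(sr) < 0))
      }
      if (length(qr) > 1) {
        expect_true(all(diff(qr) - 1 <= g_max))
        expect_true(all(abs(diff(sr)) - 1 <= g_max))
      }
      expect_gte(b$score, 2L)
    }
  }
})

test_that("raising a_min never adds blocks; raising g_max never shrinks the best chain", {
  set.seed(12)
  for (i in 1:10) {
    rec <- random_toy_genomes(10, 10)
    h <- hits_frame(query = sprintf("x%02d", sample(10, 12, TRUE)),
                    subject = sprintf("y%02d", sample(10, 12, TRUE)))
    h <- h[!duplicated(h[, 1:2]), ]
    n3 <- length(detect_blocks(h, rec, collinearity_params(a_min = 3,
                                                           g_max = 2)))
    n4 <- length(detect_blocks(h, rec, collinearity_params(a_min = 4,
                                                           g_max = 2)))
    expect_lte(n4, n3)
    best_size <- function(g) {
      b <- detect_blocks(h, rec, collinearity_params(a_min = 2, g_max = g))
      if (length(b)) max(vapply(b, `[[`, 0L, "score")) else 0L
    }
    expect_lte(best_size(1), best_size(3))
  }
})

test_that("reciprocal comparisons assemble the same network", {
  set.seed(13)
  rec <- random_toy_genomes(10, 10)
  h <- hits_frame(query = sprintf("x%02d", sample(10, 12, TRUE)),
                  subject = sprintf("y%02d", sample(10, 12, TRUE)))
  h <- h[!duplicated(h[, 1:2]), ]
  h_flipped <- data.frame(query = h$subject, subject = h$query,
                          evalue = h$evalue, bitscore = h$bitscore)
  p <- collinearity_params(a_min = 2, g_max = 2)
  edge_set <- function(hits) {
    net <- build_network(detect_blocks(hits, rec, p))
    el <- igraph::as_edgelist(net$graph)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  expect_equal(edge_set(h), edge_set(h_flipped))
})
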