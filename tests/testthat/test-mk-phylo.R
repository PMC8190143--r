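test_that("transition probabilities satisfy the closed form", {
  m <- mk_model(pi0 = 0.5)
  expect_equal(transition_prob(m, 0), diag(2), ignore_attr = TRUE)
  # long branches reach stationarity
  P <- transition_prob(mk_model(pi0 = 0.3), 50)
  expect_equal(unname(P[1, ]), c(0.3, 0.7), tolerance = 1e-10)
  expect_equal(unname(P[2, ]), c(0.3, 0.7), tolerance = 1e-10)
  # pi = (0.5, 0.5), t = ln2 / 2: P_01 = 0.5 (1 - e^{-2t}) = 1/4
  expect_equal(transition_prob(m, log(2) / 2)[1, 2], 0.25,
               tolerance = 1e-12)
  expect_error(transition_prob(m, -1), "non-negative")
  # rows sum to one for arbitrary parameters
  for (p in c(0.2, 0.5, 0.9)) {
    expect_equal(rowSums(transition_prob(mk_model(pi0 = p), 0.7, 1.3)),
                 c("0" = 1, "1" = 1), tolerance = 1e-12)
  }
})

test_that("two-leaf likelihoods match hand calculation", {
  tr <- ape::read.tree(text = "(A:0,B:0);")
  m <- matrix(c(0L, 0L), ncol = 1, dimnames = list(c("A", "B"), NULL))
  expect_equal(log_likelihood(tr, m, mk_model()), log(0.5),
               tolerance = 1e-12)
  tr2 <- ape::read.tree(text = sprintf("(A:%.17g,B:0);", log(2) / 2))
  m2 <- matrix(c(0L, 1L), ncol = 1, dimnames = list(c("A", "B"), NULL))
  expect_equal(log_likelihood(tr2, m2, mk_model()), log(0.125),
               tolerance = 1e-12)
})

test_that("pruning equals brute-force summation on small trees", {
  set.seed(41)
  for (i in 1:10) {
    tr <- ape::rtree(5)
    tr$edge.length <- runif(nrow(tr$edge), 0.05, 2)
    mat <- matrix(rbinom(5 * 25, 1, 0.5), nrow = 5,
                  dimnames = list(tr$tip.label, NULL))
    model <- mk_model(pi0 = runif(1, 0.2, 0.8), k = sample(1:3, 1))
    expect_equal(log_likelihood(tr, mat, model),
                 brute_force_loglik(tr, mat, model), tolerance = 1e-9)
  }
})

test_that("likelihood is invariant to re-rooting and leaf order", {
  set.seed(42)
  tr <- ape::rtree(7)
  tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
  mat <- matrix(rbinom(7 * 40, 1, 0.5), nrow = 7,
                dimnames = list(tr$tip.label, NULL))
  model <- mk_model(pi0 = 0.35, k = 2)
  base <- log_likelihood(tr, mat, model)
  rerooted <- ape::root(ape::unroot(tr), outgroup = tr$tip.label[3],
                        resolve.root = TRUE)
  expect_equal(log_likelihood(rerooted, mat, model), base,
               tolerance = 1e-8)
  expect_equal(log_likelihood(tr, mat[sample(7), ], model), base,
               tolerance = 1e-10)
  # complementation invariance at symmetric frequencies
  sym <- mk_model(pi0 = 0.5, k = 2)
  expect_equal(log_likelihood(tr, mat, sym),
               log_likelihood(tr, 1L - mat, sym), tolerance = 1e-10)
})

test_that("two-taxon branch MLE matches the closed form", {
  # 40 characters, 10 mismatches: p = 0.25, t_hat = -0.5 ln(1 - 2p)
  mat <- cbind(matrix(rep(c(0L, 0L), 30), nrow = 2),
               matrix(rep(c(0L, 1L), 10), nrow = 2))
  rownames(mat) <- c("A", "B")
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  res <- optimize_branch_lengths(tr, mat, mk_model())
  t_hat <- -0.5 * log(1 - 2 * 0.25)
  expect_equal(sum(res$tree$edge.length), t_hat, tolerance = 1e-6 * t_hat)
})

test_that("model estimation respects constraints and recovers symmetry", {
  set.seed(43)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.2, 1)
  mat <- matrix(rbinom(6 * 150, 1, 0.5), nrow = 6,
                dimnames = list(tr$tip.label, NULL))
  # symmetric data: columns plus their complements
  sym <- cbind(mat, 1L - mat)
  fit <- estimate_model(tr, sym, k = 1)
  expect_equal(fit$model$pi[1], 0.5, tolerance = 0.02)

  # k = 1 leaves the rate mixture degenerate
  expect_equal(fit$model$rates, 1)
  expect_equal(fit$model$weights, 1)
  expect_error(estimate_model(tr, mat, k = 0), "k must be")

  # nesting: the FreeRate fit never falls below the homogeneous fit
  f1 <- estimate_model(tr, mat, k = 1)
  f2 <- estimate_model(tr, mat, k = 2)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
  # normalisation constraints hold after fitting
  expect_equal(sum(f2$model$weights), 1, tolerance = 1e-9)
  expect_equal(sum(f2$model$weights * f2$model$rates), 1, tolerance = 1e-9)
})

test_that("neighbor joining start trees use corrected distances", {
  mat <- rbind(A = c(1L, 1L, 0L, 0L), B = c(1L, 1L, 0L, 0L),
               C = c(0L, 0L, 1L, 1L))
  tr <- nj_start_tree(mat)
  expect_s3_class(tr, "phylo")
  # identical rows: zero distance -> adjacent leaves with ~0 path
  # p = 0.25 -> d = 0.5 ln 2
  m2 <- rbind(A = rep(0L, 8), B = c(rep(0L, 6), 1L, 1L))
  tr2 <- nj_start_tree(m2)
  expect_equal(sum(tr2$edge.length), 0.5 * log(2), tolerance = 1e-9)
  # perfect quartet signal
  q <- rbind(A = c(rep(1L, 10), rep(0L, 10)), B = c(rep(1L, 10), rep(0L, 10)),
             C = c(rep(0L, 10), rep(1L, 10)), D = c(rep(0L, 10), rep(1L, 10)))
  q <- cbind(q, matrix(rbinom(4 * 5, 1, 0.5), nrow = 4))
  tq <- nj_start_tree(q)
  truth <- ape::read.tree(text = "((A,B),(C,D));")
  expect_equal(rf_distance(tq, truth), 0)
})

test_that("NNI search finds the exhaustive optimum on quartets", {
  set.seed(44)
  quartets <- lapply(list(c("A", "B", "C", "D"), c("A", "C", "B", "D"),
                          c("A", "D", "B", "C")), function(p) {
    ape::read.tree(text = sprintf("((%s:0.3,%s:0.3):0.2,(%s:0.3,%s:0.3):0.2);",
                                  p[1], p[2], p[3], p[4]))
  })
  model <- mk_model()
  score_topology <- function(q, mat, model) {
    max(vapply(c(0.1, 0.5, 2), function(s) {
      q$edge.length <- rep(s, nrow(q$edge))
      optimize_branch_lengths(q, mat, model)$loglik
    }, 0))
  }
  for (rep in 1:5) {
    mat <- matrix(rbinom(4 * 80, 1, 0.5), nrow = 4,
                  dimnames = list(c("A", "B", "C", "D"), NULL))
    best <- sapply(quartets, score_topology, mat = mat, model = model)
    res <- nni_search(mat, model)
    expect_gte(res$loglik, max(best) - 1e-5)
  }
  # an already optimal start is returned unchanged
  mat <- rbind(A = c(rep(1L, 20), rep(0L, 5)), B = c(rep(1L, 20), rep(0L, 5)),
               C = c(rep(0L, 20), rep(1L, 5)), D = c(rep(0L, 20), rep(1L, 5)))
  res <- nni_search(mat, model, start = quartets[[1]])
  expect_equal(rf_distance(res$tree, quartets[[1]]), 0)
})

test_that("search log-likelihood never decreases and is NNI-locally optimal", {
  set.seed(45)
  mat <- matrix(rbinom(6 * 120, 1, 0.5), nrow = 6,
                dimnames = list(paste0("s", 1:6), NULL))
  model <- mk_model()
  res <- nni_search(mat, model)
  for (cand in synmrl:::nni_neighbors(res$tree)) {
    alt <- optimize_branch_lengths(cand$tree, mat, model)
    expect_lte(alt$loglik, res$loglik + 1e-5)
  }
})

test_that("Robinson-Foulds distances agree with the independent oracle", {
  t1 <- ape::read.tree(text = "((A,B),(C,D),E);")
  expect_equal(rf_distance(t1, t1), 0)
  q1 <- ape::read.tree(text = "((A,B),(C,D));")
  q2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(q1, q2), 2)
  expect_error(rf_distance(q1, ape::read.tree(text = "((A,B),(C,E));")),
               "leaf sets")
  skip_if_not_installed("phangorn")
  tops <- phangorn::allTrees(5, rooted = FALSE,
                             tip.label = paste0("t", 1:5))
  for (i in seq_along(tops)) {
    for (j in seq_along(tops)) {
      expect_equal(rf_distance(tops[[i]], tops[[j]]),
                   as.numeric(phangorn::RF.dist(tops[[i]], tops[[j]])))
    }
  }
})

test_that("bootstrap supports reflect column resampling", {
  mat <- consistent_six_taxon_matrix(120)
  model <- mk_model()
  fit <- nni_search(mat, model)
  bs <- bootstrap_support(fit$tree, mat, model, n_reps = 20, seed = 9)
  sup <- suppressWarnings(as.numeric(bs$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))
})
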