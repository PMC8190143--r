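#' Binary Mk model with free frequencies and FreeRate heterogeneity
#'
#' The two-state Markov (Mk) model for presence/absence characters, with
#' freely estimated state frequencies (pi0, pi1) and an optional FreeRate
#' mixture of \code{k} relative rate categories. The rate matrix is scaled
#' so that one unit of branch length equals one expected state change per
#' character at relative rate 1; mixture weights sum to 1 and the weighted
#' mean rate is 1.
#'
#' @param pi0 Stationary frequency of state 0 (0 < pi0 < 1).
#' @param k Number of rate categories (>= 1).
#' @param rates,weights Relative rates and mixture weights (length
#'   \code{k}); rescaled to satisfy the normalisation constraints. Defaults
#'   to the homogeneous model when \code{k = 1} and to mildly spread
#'   categories otherwise.
#' @return An object of class \code{mk_model}.
#' @export
mk_model <- function(pi0 = 0.5, k = 1L, rates = NULL, weights = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  if (!is.numeric(pi0) || pi0 <= 0 || pi0 >= 1) {
    stop("pi0 must lie strictly between 0 and 1", call. = FALSE)
  }
  if (is.null(rates)) rates <- if (k == 1L) 1 else seq(0.5, 1.5,
                                                       length.out = k)
  if (is.null(weights)) weights <- rep(1 / k, k)
  if (length(rates) != k || length(weights) != k) {
    stop("rates and weights must have length k", call. = FALSE)
  }
  if (any(rates <= 0) || any(weights <= 0)) {
    stop("rates and weights must be positive", call. = FALSE)
  }
  weights <- weights / sum(weights)
  rates <- rates / sum(weights * rates)
  structure(list(pi = c(pi0, 1 - pi0), k = k, rates = rates,
                 weights = weights),
            class = "mk_model")
}

#' @export
print.mk_model <- function(x, ...) {
  cat("Binary Mk model: pi = (", signif(x$pi[1], 4), ",",
      signif(x$pi[2], 4), "), k =", x$k, "\n")
  if (x$k > 1L) {
    cat("  rates:  ", paste(signif(x$rates, 4), collapse = " "), "\n")
    cat("  weights:", paste(signif(x$weights, 4), collapse = " "), "\n")
  }
  invisible(x)
}

#' Transition probability matrix of the binary Mk model
#'
#' \code{P_ij(t) = pi_j + (delta_ij - pi_j) exp(-beta r t)} with
#' \code{beta = 1 / (2 pi0 pi1)}, so that one unit of branch length is one
#' expected change per character at relative rate \code{r = 1}.
#'
#' @param model An [mk_model()].
#' @param t Branch length (>= 0).
#' @param rate Relative rate category multiplier.
#' @return A 2x2 row-stochastic matrix (states 0 and 1).
#' @export
transition_prob <- function(model, t, rate = 1) {
  stopifnot(inherits(model, "mk_model"))
  if (!is.numeric(t) || length(t) != 1L || is.na(t) || t < 0) {
    stop("branch length t must be a non-negative number", call. = FALSE)
  }
  pi <- model$pi
  beta <- 1 / (2 * pi[1] * pi[2])
  ex <- exp(-beta * rate * t)
  P <- rbind(pi + (c(1, 0) - pi) * ex,
             pi + (c(0, 1) - pi) * ex)
  dimnames(P) <- list(c("0", "1"), c("0", "1"))
  P
}

# Compress a binary species x character matrix into unique site patterns.
# Returns tip-state matrix ordered like `taxa` plus pattern multiplicities.
compress_patterns <- function(mat, taxa) {
  mat <- mat[taxa, , drop = FALSE]
  if (ncol(mat) == 0L) stop("matrix has no characters", call. = FALSE)
  key <- apply(mat, 2L, paste, collapse = "")
  tab <- table(key)
  pat <- matrix(as.integer(unlist(strsplit(names(tab), "", fixed = TRUE))),
                nrow = length(taxa))
  list(states = pat, weights = as.numeric(tab))
}

# Internal evaluation context: postorder edge matrix, branch lengths and
# compressed patterns for one (tree, matrix) pair. Branch lengths can be
# modified in place during optimization; `tree` retains the original object.
mk_prep <- function(tree, mat) {
  if (is.null(rownames(mat))) stop("matrix must have species rownames",
                                   call. = FALSE)
  if (!setequal(tree$tip.label, rownames(mat))) {
    stop("tree leaves and matrix species differ", call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(0.1, nrow(tree$edge))
  }
  post <- ape::reorder.phylo(tree, "postorder")
  cp <- compress_patterns(mat, post$tip.label)
  list(tree = post, edge = post$edge, brlen = post$edge.length,
       n_tip = length(post$tip.label), states = cp$states,
       patw = cp$weights)
}

mk_loglik_prep <- function(prep, model, brlen = prep$brlen) {
  .mk_loglik_cpp(prep$edge, prep$n_tip, brlen, prep$states, prep$patw,
                 model$pi[1], model$rates, model$weights)
}

#' Log-likelihood of a binary matrix on a tree
#'
#' Felsenstein pruning over compressed site patterns, mixing rate
#' categories with the model's FreeRate weights. The result is invariant to
#' leaf order, to re-rooting, and (for symmetric frequencies) to global
#' state complementation. Optionally conditions on characters being
#' variable (ascertainment-bias correction); by default no correction is
#' applied, matching standard practice for synteny-cluster matrices whose
#' constant columns are genuine observations.
#'
#' @param tree An [ape::phylo] tree whose tips match the matrix rows.
#' @param mat Binary matrix (species x characters).
#' @param model An [mk_model()].
#' @param condition_on_variable If \code{TRUE}, subtract the log-probability
#'   of a character being variable.
#' @return The log-likelihood (<= 0).
#' @export
log_likelihood <- function(tree, mat, model, condition_on_variable = FALSE) {
  prep <- mk_prep(tree, mat)
  ll <- mk_loglik_prep(prep, model)
  if (condition_on_variable) {
    const_states <- cbind(rep(0L, prep$n_tip), rep(1L, prep$n_tip))
    # probability of an all-absent or all-present character
    p_const <- sum(exp(vapply(1:2, function(j) {
      .mk_loglik_cpp(prep$edge, prep$n_tip, prep$brlen,
                     const_states[, j, drop = FALSE], 1, model$pi[1],
                     model$rates, model$weights)
    }, 0)))
    ll <- ll - sum(prep$patw) * log(1 - p_const)
  }
  ll
}

# Cycle 1-D bounded optimizations over all branch lengths until the
# log-likelihood gain per cycle drops below eps. Returns updated brlen and
# the final log-likelihood.
# Coordinate ascent over all branch lengths (C++ core): per-edge 1-D
# golden-section optimization with a bracketing grid on the first sweep
# (the per-edge profile can be bimodal on noisy binary data: an interior
# optimum competing with a saturated one), cycled until the per-sweep
# log-likelihood gain drops below eps. Start lengths are clamped into the
# optimizer's bounds: zero-length edges make conflicting patterns
# impossible (likelihood 0).
optimize_branches_prep <- function(prep, model, control = mk_control()) {
  res <- .mk_opt_branches_cpp(prep$edge, prep$n_tip, prep$brlen,
                              prep$states, prep$patw, model$pi[1],
                              model$rates, model$weights, control$bl_min,
                              control$bl_max, control$bl_tol, control$eps,
                              control$max_cycles)
  list(brlen = res$brlen, loglik = res$loglik)
}

#' Numerical control settings for likelihood optimization
#'
#' @param eps Convergence threshold in log-likelihood units.
#' @param bl_min,bl_max Branch length bounds; saturated binary characters
#'   make unbounded lengths numerically unstable, hence the cap.
#' @param bl_tol Tolerance of the 1-D branch length optimizer.
#' @param max_cycles Maximum branch-optimization sweeps.
#' @return A list of control values.
#' @export
mk_control <- function(eps = 1e-6, bl_min = 1e-8, bl_max = 10,
                       bl_tol = 1e-8, max_cycles = 20L) {
  list(eps = eps, bl_min = bl_min, bl_max = bl_max, bl_tol = bl_tol,
       max_cycles = max_cycles)
}

#' Optimize branch lengths of a tree
#'
#' @inheritParams log_likelihood
#' @param control See [mk_control()].
#' @return A list with \code{tree} (branch lengths updated) and
#'   \code{loglik}.
#' @export
optimize_branch_lengths <- function(tree, mat, model,
                                    control = mk_control()) {
  prep <- mk_prep(tree, mat)
  res <- optimize_branches_prep(prep, model, control)
  out <- prep$tree
  out$edge.length <- res$brlen
  list(tree = out, loglik = res$loglik)
}

#' Estimate Mk model parameters by maximum likelihood
#'
#' Optimizes the state frequencies (the "+FO" component) and, for
#' \code{k > 1}, the FreeRate category rates and weights under the
#' constraints sum(w) = 1 and sum(w r) = 1, by bounded/transformed
#' numerical optimization on a fixed tree. The returned log-likelihood is
#' never below that of the initial model.
#'
#' @inheritParams log_likelihood
#' @param k Number of FreeRate categories.
#' @param optimize_branches Also re-optimize branch lengths (alternated
#'   once with the model fit).
#' @param control See [mk_control()].
#' @return A list with \code{model}, \code{loglik} and (when
#'   \code{optimize_branches}) \code{tree}.
#' @export
estimate_model <- function(tree, mat, k = 1L, optimize_branches = FALSE,
                           control = mk_control()) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1", call. = FALSE)
  prep <- mk_prep(tree, mat)
  fit <- estimate_model_prep(prep, k)
  out <- list(model = fit$model, loglik = fit$loglik)
  if (optimize_branches) {
    bl <- optimize_branches_prep(prep, fit$model, control)
    prep$brlen <- bl$brlen
    fit <- estimate_model_prep(prep, k, init = fit$model)
    tr <- prep$tree
    tr$edge.length <- prep$brlen
    out <- list(model = fit$model, loglik = fit$loglik, tree = tr)
  }
  out
}

estimate_model_prep <- function(prep, k, init = NULL) {
  if (is.null(init) || init$k != k) init <- mk_model(k = k)
  if (k > 1L) {
    # fit the nested homogeneous model first: its optimum, expressed as k
    # equal-rate categories, is the fallback floor for the FreeRate fit
    f1 <- estimate_model_prep(prep, 1L)
    nested <- mk_model(pi0 = f1$model$pi[1], k = k, rates = rep(1, k),
                       weights = rep(1 / k, k))
    if (mk_loglik_prep(prep, nested) > mk_loglik_prep(prep, init)) {
      init <- mk_model(pi0 = f1$model$pi[1], k = k)
    }
    init_floor <- nested
  } else {
    init_floor <- NULL
  }
  ll0 <- mk_loglik_prep(prep, init)
  if (!is.null(init_floor)) {
    ll_floor <- mk_loglik_prep(prep, init_floor)
    if (ll_floor > ll0) {
      init <- init_floor
      ll0 <- ll_floor
    }
  }
  build <- function(par) {
    pi0 <- stats::plogis(par[1L])
    pi0 <- min(max(pi0, 1e-6), 1 - 1e-6)
    if (k == 1L) {
      return(mk_model(pi0 = pi0, k = 1L))
    }
    raw_r <- c(1, exp(par[2:k]))
    w <- exp(c(0, par[(k + 1):(2 * k - 1)]))
    w <- w / sum(w)
    mk_model(pi0 = pi0, k = k, rates = raw_r / sum(w * raw_r), weights = w)
  }
  par0 <- if (k == 1L) {
    stats::qlogis(init$pi[1])
  } else {
    c(stats::qlogis(init$pi[1]), log(init$rates[-1L] / init$rates[1L]),
      log(init$weights[-1L] / init$weights[1L]))
  }
  objective <- function(par) {
    m <- try(build(par), silent = TRUE)
    if (inherits(m, "try-error")) return(1e10)
    -mk_loglik_prep(prep, m)
  }
  opt <- if (length(par0) == 1L) {
    o <- stats::optim(par0, objective, method = "Brent", lower = -12,
                      upper = 12)
    o
  } else {
    stats::optim(par0, objective, method = "Nelder-Mead",
                 control = list(maxit = 2000L, reltol = 1e-10))
  }
  if (-opt$value >= ll0) {
    list(model = build(opt$par), loglik = -opt$value)
  } else {
    list(model = init, loglik = ll0)
  }
}

#' Neighbor-joining starting tree from a binary matrix
#'
#' Pairwise distances are the corrected mismatch fractions
#' \code{d = -0.5 log(1 - 2 p)} (the two-state analogue of the
#' Jukes-Cantor correction), with saturated pairs (\code{p >= 0.5}) capped
#' at \code{d_max}; the tree is built with neighbor joining and returned
#' unrooted with non-negative branch lengths.
#'
#' @param mat Binary matrix (species x characters).
#' @param d_max Distance assigned to saturated pairs.
#' @return An unrooted [ape::phylo] tree.
#' @export
nj_start_tree <- function(mat, d_max = 5) {
  n <- nrow(mat)
  if (n < 2L) stop("need at least 2 species", call. = FALSE)
  p <- as.matrix(stats::dist(mat, method = "manhattan")) / ncol(mat)
  d <- suppressWarnings(-0.5 * log(1 - 2 * p))
  d[!is.finite(d) | p >= 0.5] <- d_max
  diag(d) <- 0
  if (n == 2L) {
    tree <- structure(list(
      edge = matrix(c(3L, 3L, 1L, 2L), ncol = 2),
      edge.length = rep(d[1, 2] / 2, 2), Nnode = 1L,
      tip.label = rownames(mat)), class = "phylo")
    attr(tree, "order") <- "cladewise"
    return(tree)
  }
  tree <- ape::nj(stats::as.dist(d))
  tree$edge.length[tree$edge.length < 0] <- 1e-8
  ape::unroot(tree)
}

# All nearest-neighbor-interchange neighbors of an unrooted binary tree.
# For the internal edge (u, v) with v the child, exchanging one child
# subtree of v with a sibling subtree of u realises both alternative
# topologies around that edge. Branch lengths travel with their subtrees.
nni_neighbors <- function(tree) {
  edge <- tree$edge
  n_tip <- length(tree$tip.label)
  out <- list()
  for (e in which(edge[, 2L] > n_tip)) {
    u <- edge[e, 1L]
    v <- edge[e, 2L]
    rows_v <- which(edge[, 1L] == v)
    rows_u <- setdiff(which(edge[, 1L] == u), e)
    if (length(rows_u) == 0L) next
    w_row <- rows_u[1L]
    for (c_row in rows_v[1:2]) {
      nt <- tree
      nt$edge[w_row, 1L] <- v
      nt$edge[c_row, 1L] <- u
      attr(nt, "order") <- NULL
      out[[length(out) + 1L]] <- list(tree = nt, central = e)
    }
  }
  out
}

#' Maximum-likelihood tree search by nearest-neighbor interchange
#'
#' Hill-climbing over NNI rearrangements with per-branch length
#' optimization (bounded 1-D optimization per branch, cycled to
#' convergence). Candidate moves are pre-screened by re-optimizing only the
#' exchanged internal edge, then evaluated with full branch optimization in
#' decreasing order of promise; a move is accepted only if it improves the
#' log-likelihood by more than \code{control$eps}. The search stops at an
#' NNI-local optimum. The procedure is deterministic.
#'
#' @inheritParams log_likelihood
#' @param start Starting tree (defaults to [nj_start_tree()] of the
#'   matrix); multifurcations are resolved arbitrarily.
#' @param control See [mk_control()].
#' @return A list with \code{tree} (optimized branch lengths),
#'   \code{loglik}, and \code{n_moves}.
#' @export
nni_search <- function(mat, model, start = NULL, control = mk_control()) {
  if (is.null(start)) start <- nj_start_tree(mat)
  tree <- ape::unroot(ape::multi2di(start, random = FALSE))
  prep <- mk_prep(tree, mat)
  cur <- optimize_branches_prep(prep, model, control)
  prep$brlen <- cur$brlen
  n_moves <- 0L
  for (outer in 1:3) {
  repeat {
    tr_cur <- prep$tree
    tr_cur$edge.length <- prep$brlen
    cand <- nni_neighbors(tr_cur)
    if (length(cand) == 0L) break
    scores <- vapply(cand, function(cd) {
      p2 <- mk_prep_topology(cd$tree, prep)
      row <- which(p2$edge[, 1L] %in% cd$tree$edge[cd$central, ] &
                     p2$edge[, 2L] %in% cd$tree$edge[cd$central, ])[1L]
      .mk_opt_edge_cpp(p2$edge, p2$n_tip, p2$brlen, p2$states, p2$patw,
                       model$pi[1], model$rates, model$weights, row,
                       control$bl_min, control$bl_max, control$bl_tol * 10)
    }, 0)
    improved <- FALSE
    for (i in order(scores, decreasing = TRUE)) {
      p2 <- mk_prep_topology(cand[[i]]$tree, prep)
      res <- optimize_branches_prep(p2, model, control)
      if (res$loglik > cur$loglik + control$eps) {
        prep <- p2
        prep$brlen <- res$brlen
        cur <- res
        n_moves <- n_moves + 1L
        improved <- TRUE
        break
      }
    }
    if (!improved) break
  }
  # polish: branch lengths can have start-dependent local optima, so
  # re-optimize from fixed alternative starting lengths; if that improves
  # the likelihood, NNI moves may open up again
  polished <- FALSE
  for (s in c(0.1, 0.5, 2)) {
    p3 <- prep
    p3$brlen <- rep(s, length(prep$brlen))
    r3 <- optimize_branches_prep(p3, model, control)
    if (r3$loglik > cur$loglik + control$eps) {
      prep$brlen <- r3$brlen
      cur <- r3
      polished <- TRUE
    }
  }
  if (!polished) break
  }
  out <- prep$tree
  out$edge.length <- prep$brlen
  list(tree = out, loglik = cur$loglik, n_moves = n_moves)
}

# Re-prepare an evaluation context after a topology change, reusing the
# compressed patterns (tip label order is preserved by NNI edits).
mk_prep_topology <- function(tree, prep) {
  post <- ape::reorder.phylo(tree, "postorder")
  list(tree = post, edge = post$edge, brlen = post$edge.length,
       n_tip = prep$n_tip, states = prep$states, patw = prep$patw)
}

#' Infer a tree from a binary matrix
#'
#' Convenience pipeline: neighbor-joining start tree, model fit on the
#' start tree (state frequencies and, for \code{k > 1}, FreeRate
#' categories), then NNI search with branch length optimization.
#'
#' @param mat Binary matrix (species x characters).
#' @param k FreeRate categories for the fitted model.
#' @param control See [mk_control()].
#' @return A list with \code{tree}, \code{model}, \code{loglik}.
#' @export
infer_tree <- function(mat, k = 1L, control = mk_control()) {
  start <- nj_start_tree(mat)
  fit <- estimate_model(start, mat, k = k)
  res <- nni_search(mat, fit$model, start = start, control = control)
  list(tree = res$tree, model = fit$model, loglik = res$loglik)
}

#' Nonparametric bootstrap support values
#'
#' Resamples matrix columns with replacement, reruns the tree search
#' (neighbor-joining start, NNI) on every replicate, and annotates each
#' internal split of the reference tree with the percentage of replicates
#' whose inferred tree contains it.
#'
#' @inheritParams log_likelihood
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer seed controlling the resampling.
#' @param control See [mk_control()].
#' @return The reference tree with \code{node.label} set to support
#'   percentages (internal nodes whose split is nontrivial).
#' @export
bootstrap_support <- function(tree, mat, model, n_reps = 100L, seed = 1L,
                              control = mk_control()) {
  set.seed(seed)
  ref_splits <- split_keys(tree)
  counts <- stats::setNames(numeric(length(ref_splits)), ref_splits)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(mat), replace = TRUE)
    bmat <- mat[, cols, drop = FALSE]
    rep_tree <- nni_search(bmat, model, control = control)$tree
    hit <- intersect(split_keys(rep_tree), ref_splits)
    counts[hit] <- counts[hit] + 1
  }
  support <- 100 * counts / n_reps
  annotate_supports(tree, support)
}

# canonical string keys of the nontrivial bipartitions of a tree
split_keys <- function(tree) {
  sp <- tree_splits(tree)
  taxa <- sort(tree$tip.label)
  vapply(sp, function(s) {
    side <- if (taxa[1L] %in% s$side) setdiff(taxa, s$side) else s$side
    paste(sort(side), collapse = "|")
  }, "")
}

annotate_supports <- function(tree, support) {
  tree <- ape::unroot(tree)
  n_tip <- length(tree$tip.label)
  desc <- descendant_tips(tree)
  taxa <- sort(tree$tip.label)
  labels <- rep("", tree$Nnode)
  for (nd in (n_tip + 1L):(n_tip + tree$Nnode)) {
    side <- tree$tip.label[desc[[nd]]]
    if (length(side) < 2L || length(side) > n_tip - 2L) next
    side <- if (taxa[1L] %in% side) setdiff(taxa, side) else side
    key <- paste(sort(side), collapse = "|")
    if (key %in% names(support)) {
      labels[nd - n_tip] <- format(support[[key]], trim = TRUE)
    }
  }
  tree$node.label <- labels
  tree
}

#' Robinson-Foulds distance between two trees
#'
#' The size of the symmetric difference of the unrooted nontrivial
#' bipartition sets of the two trees: 0 for identical topologies, at most
#' \code{2(n - 3)} for binary trees on n shared leaves.
#'
#' @param tree1,tree2 [ape::phylo] trees on the same leaf set.
#' @return An even non-negative integer.
#' @export
rf_distance <- function(tree1, tree2) {
  if (!setequal(tree1$tip.label, tree2$tip.label)) {
    stop("trees have different leaf sets", call. = FALSE)
  }
  s1 <- unique(split_keys(tree1))
  s2 <- unique(split_keys(tree2))
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}
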