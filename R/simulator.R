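#' Parameters of the gene-family syntenic-network simulator
#'
#' Rates are events per gene per 100 My; species-tree branch lengths must
#' be supplied in the same units. \code{lambda}, \code{mu} and \code{nu}
#' are the duplication, loss and rearrangement rates. On a duplication,
#' each syntenic edge of the parent gene is copied to the new gene with
#' probability \code{p_dup}; on a rearrangement, each incident edge is lost
#' with probability \code{p_rea}. The number of genes at the root of each
#' family follows a Geometric prior on \{1, 2, ...\} with parameter
#' \code{p_root} (mean \code{1 / p_root}): a family must exist to be
#' observed. In hyperprior mode (\code{hyperprior = TRUE}), \code{p_dup}
#' and \code{p_rea} are redrawn once per simulation replicate as
#' independent Beta(b, b) variates with \code{b ~ Beta(2, 2)}.
#'
#' The defaults are the validated study conditions: a single turnover rate
#' \code{lambda = mu = 0.38} events per gene per 100 My (a rate estimated
#' from monocot gene-content data), \code{nu = 0.38}, hyperprior retention
#' probabilities, and \code{p_root = 0.66}.
#'
#' @param lambda,mu,nu Duplication, loss and rearrangement rates (>= 0).
#' @param p_dup,p_rea Edge retention/deletion probabilities in [0, 1];
#'   ignored when \code{hyperprior} is \code{TRUE}.
#' @param p_root Geometric root prior parameter in (0, 1].
#' @param hyperprior Draw \code{p_dup}, \code{p_rea} from the Beta
#'   hyperprior per replicate.
#' @param n_families Number of families per simulated dataset.
#' @param root_complete Start root paralogs fully connected instead of
#'   unlinked (no ancestor exists to license an edge, hence the default).
#' @return A list of class \code{simulation_params}.
#' @export
simulation_params <- function(lambda = 0.38, mu = 0.38, nu = 0.38,
                              p_dup = 0.5, p_rea = 0.5, p_root = 0.66,
                              hyperprior = TRUE, n_families = 1000L,
                              root_complete = FALSE) {
  stopifnot(lambda >= 0, mu >= 0, nu >= 0,
            p_dup >= 0, p_dup <= 1, p_rea >= 0, p_rea <= 1,
            p_root > 0, p_root <= 1, n_families >= 0)
  structure(list(lambda = lambda, mu = mu, nu = nu, p_dup = p_dup,
                 p_rea = p_rea, p_root = p_root,
                 hyperprior = isTRUE(hyperprior),
                 n_families = as.integer(n_families),
                 root_complete = isTRUE(root_complete)),
            class = "simulation_params")
}

check_species_tree <- function(tree, min_tips = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0)) {
    stop("species tree needs positive branch lengths (in 100-My units)",
         call. = FALSE)
  }
  if (length(tree$tip.label) < min_tips) {
    stop("species tree needs >= ", min_tips, " leaves", call. = FALSE)
  }
  if (!ape::is.binary.phylo(tree) || !ape::is.rooted(tree)) {
    stop("species tree must be rooted and binary", call. = FALSE)
  }
  invisible(tree)
}

# Draw per-replicate edge retention probabilities; with the hyperprior,
# b ~ Beta(2, 2) and p_dup, p_rea ~ Beta(b, b) independently.
draw_retention <- function(params) {
  if (!params$hyperprior) {
    return(c(p_dup = params$p_dup, p_rea = params$p_rea))
  }
  b <- stats::rbeta(1L, 2, 2)
  c(p_dup = stats::rbeta(1L, b, b), p_rea = stats::rbeta(1L, b, b))
}

#' Simulate one gene family syntenic network
#'
#' Runs the Gillespie simulation of a single gene family along the species
#' tree and returns the extant part of its syntenic network: the surviving
#' genes at the leaves and the syntenic edges among them. An extinct family
#' yields zero genes.
#'
#' @param tree Rooted binary dated species tree ([ape::phylo], branch
#'   lengths in 100-My units).
#' @param params A [simulation_params()] object; \code{hyperprior} draws
#'   use R's RNG, so wrap calls in \code{set.seed()} for reproducibility.
#' @return A list of class \code{gene_family_network} with \code{genes}
#'   (data.frame: \code{gene}, \code{species}) and \code{edges} (2-column
#'   character matrix of gene ids).
#' @export
simulate_family <- function(tree, params = simulation_params()) {
  check_species_tree(tree)
  ret <- draw_retention(params)
  n_tip <- length(tree$tip.label)
  res <- .sim_family_cpp(tree$edge, tree$edge.length, n_tip,
                         n_tip + tree$Nnode, n_tip + 1L,
                         params$lambda, params$mu, params$nu,
                         ret[["p_dup"]], ret[["p_rea"]], params$p_root,
                         params$root_complete)
  genes <- data.frame(gene = sprintf("g%d", res$gene),
                      species = tree$tip.label[res$species],
                      stringsAsFactors = FALSE)
  edges <- matrix(sprintf("g%d", res$edges), ncol = 2L)
  structure(list(genes = genes, edges = edges),
            class = "gene_family_network")
}

#' @export
print.gene_family_network <- function(x, ...) {
  cat("Gene family syntenic network:", nrow(x$genes), "extant genes,",
      nrow(x$edges), "edges\n")
  invisible(x)
}

#' Synteny clusters of a simulated family network
#'
#' Connected components over the extant leaf genes; singleton components
#' are discarded, mirroring the rule that network nodes are genes occurring
#' in syntenic blocks (a gene with no syntenic partner is invisible to the
#' method).
#'
#' @param family A \code{gene_family_network} from [simulate_family()].
#' @return A data.frame with columns \code{gene_id}, \code{cluster_id},
#'   \code{species}.
#' @export
extract_clusters <- function(family) {
  stopifnot(inherits(family, "gene_family_network"))
  if (nrow(family$edges) == 0L) {
    return(data.frame(gene_id = character(), cluster_id = character(),
                      species = character(), stringsAsFactors = FALSE))
  }
  net <- build_network(family$edges,
                       species_of_gene = stats::setNames(
                         family$genes$species, family$genes$gene))
  cl <- cluster_network(net, method = "components")
  cl$species <- stats::setNames(family$genes$species,
                                family$genes$gene)[cl$gene_id]
  cl
}

#' Simulate a binary synteny matrix
#'
#' Simulates \code{params$n_families} independent gene families (extinct
#' families contribute nothing; the count refers to simulated, not
#' surviving, families), extracts synteny clusters from each, and
#' concatenates their phylogenomic profiles into one binary species x
#' cluster matrix. Deterministic for a fixed \code{set.seed()} state.
#'
#' @inheritParams simulate_family
#' @param counts Return the count matrix instead of the binary view.
#' @return Binary (or count) integer matrix, species x clusters.
#' @export
simulate_dataset <- function(tree, params = simulation_params(),
                             counts = FALSE) {
  check_species_tree(tree, min_tips = 2L)
  if (params$n_families < 1L) stop("n_families must be >= 1", call. = FALSE)
  ret <- draw_retention(params)
  n_tip <- length(tree$tip.label)
  mat <- .sim_dataset_cpp(tree$edge, tree$edge.length, n_tip,
                          n_tip + tree$Nnode, n_tip + 1L,
                          params$lambda, params$mu, params$nu,
                          ret[["p_dup"]], ret[["p_rea"]], params$p_root,
                          params$root_complete, params$n_families)
  rownames(mat) <- tree$tip.label
  if (ncol(mat) > 0L) colnames(mat) <- sprintf("c%d", seq_len(ncol(mat)))
  if (counts) mat else binarize(mat)
}

#' Tree-recovery experiment on simulated synteny matrices
#'
#' The validation experiment for the whole approach: per replicate, a
#' binary matrix is simulated on the known dated species tree, a tree is
#' inferred from it (neighbor-joining start, Mk model fit, NNI search), and
#' the Robinson-Foulds distance to the true topology is recorded. Variable
#' characters are required for inference; replicates whose matrix has no
#' variable column (possible only in degenerate no-event regimes) are
#' recorded as \code{NA} with a warning.
#'
#' @inheritParams simulate_family
#' @param n_reps Number of independent replicates.
#' @param k FreeRate categories used in inference.
#' @param seed Integer seed; replicate r uses \code{seed + r - 1}, so
#'   experiments with different settings can be paired by seed.
#' @return A list with \code{rf} (per-replicate RF distances),
#'   \code{rf0_prop} (proportion of exactly recovered topologies),
#'   \code{mean_rf}, \code{median_rf}, and \code{n_clusters} per replicate.
#' @export
recovery_experiment <- function(tree, params = simulation_params(),
                                n_reps = 10L, k = 1L, seed = 1L) {
  check_species_tree(tree, min_tips = 3L)
  rf <- rep(NA_real_, n_reps)
  ncl <- integer(n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(seed + r - 1L)
    mat <- simulate_dataset(tree, params)
    ncl[r] <- ncol(mat)
    variable <- ncol(mat) > 0L && any(matrixStats_colVar(mat) > 0)
    if (!variable) {
      warning("replicate ", r, ": no variable characters; no tree inferred",
              call. = FALSE)
      next
    }
    fit <- infer_tree(mat, k = k)
    rf[r] <- rf_distance(fit$tree, tree)
  }
  list(rf = rf, rf0_prop = mean(rf == 0, na.rm = TRUE),
       mean_rf = mean(rf, na.rm = TRUE),
       median_rf = stats::median(rf, na.rm = TRUE), n_clusters = ncl)
}

# column variability without extra dependencies
matrixStats_colVar <- function(mat) {
  colSums(mat != mat[rep(1L, nrow(mat)), , drop = FALSE]) > 0
}

#' Example dated species trees
#'
#' Fixed dated species trees used throughout the package's simulation
#' experiments, with branch lengths in 100-My units. The 8-taxon tree is a
#' balanced sample with a crown age of 1.0 (100 My) and internal branches
#' of 15-25 My, the kind of evenly sampled clade (comparable in depth to
#' the monocot timescale used to calibrate the default turnover rate) on
#' which presence/absence synteny characters remain informative for every
#' branch; sparse deep samples with unbroken branches much longer than
#' 100 My saturate (see the methods vignette). The 15-taxon tree is a
#' deeper, ladder-heavy monocot-like shape.
#'
#' @param n_taxa Currently 8 (default) or 15 (a monocot-like shape).
#' @return A rooted binary [ape::phylo] tree.
#' @export
example_species_tree <- function(n_taxa = 8L) {
  txt <- switch(as.character(n_taxa),
    "8" = paste0("(((t1:0.2,t2:0.2):0.25,(t3:0.2,t4:0.2):0.25):0.55,",
                 "((t5:0.25,t6:0.25):0.2,(t7:0.25,t8:0.25):0.2):0.55);"),
    "15" = paste0("(((((((t1:0.3,t2:0.3):0.2,t3:0.5):0.1,t4:0.6):0.2,",
                  "(t5:0.4,t6:0.4):0.4):0.2,((t7:0.5,t8:0.5):0.3,",
                  "t9:0.8):0.2):0.2,((t10:0.6,t11:0.6):0.4,",
                  "t12:1.0):0.2):0.1,((t13:0.7,t14:0.7):0.4,t15:1.1):0.2);"),
    stop("no example tree with ", n_taxa, " taxa", call. = FALSE))
  ape::read.tree(text = txt)
}
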