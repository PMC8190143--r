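#' Build cluster phylogenomic profiles
#'
#' A cluster phylogenomic profile records, for each species, the number of
#' genes (network nodes) the species contributes to a synteny cluster. The
#' profiles of all clusters form a species-by-cluster count matrix; its
#' binary view (presence/absence) is the character matrix for tree
#' inference. Columns are ordered by cluster id, so the matrix is invariant
#' to the input order of cluster assignments.
#'
#' Species listed in \code{species} but absent from every cluster are kept
#' as all-zero rows and reported with a warning (such genomes typically
#' indicate little detectable synteny and deserve scrutiny).
#'
#' @param clusters data.frame with columns \code{gene_id}, \code{cluster_id}
#'   (as returned by [cluster_network()]).
#' @param species_of_gene Named character vector, gene id -> species.
#' @param species Optional character vector fixing the row set and order;
#'   defaults to the sorted species observed among clustered genes.
#' @return Integer count matrix (species x clusters) with dimnames.
#' @export
build_profiles <- function(clusters, species_of_gene, species = NULL) {
  sp <- species_of_gene[clusters$gene_id]
  if (anyNA(sp)) {
    stop("no species known for gene ",
         clusters$gene_id[is.na(sp)][1L], call. = FALSE)
  }
  if (is.null(species)) species <- sort(unique(unname(sp)))
  cluster_ids <- sort(unique(clusters$cluster_id))
  mat <- matrix(0L, nrow = length(species), ncol = length(cluster_ids),
                dimnames = list(species, cluster_ids))
  if (nrow(clusters) > 0L) {
    tab <- table(factor(unname(sp), levels = species),
                 factor(clusters$cluster_id, levels = cluster_ids))
    mat[] <- as.integer(tab)
  }
  empty <- rownames(mat)[rowSums(mat) == 0L]
  if (length(empty) > 0L) {
    warning("species with no genes in any cluster (candidate low-quality ",
            "genomes): ", paste(empty, collapse = ", "), call. = FALSE)
  }
  mat
}

#' Binarize a count matrix to presence/absence
#'
#' @param mat Count matrix from [build_profiles()].
#' @return Integer 0/1 matrix of the same shape; idempotent.
#' @export
binarize <- function(mat) {
  out <- (mat > 0L) + 0L
  dimnames(out) <- dimnames(mat)
  out
}

#' Select conserved single-copy synteny clusters (CSSC)
#'
#' Screens cluster profiles for clusters usable as conserved single-copy
#' markers: the median per-species copy number (computed over all species,
#' zeros included) is below \code{median_copy_below}, the cluster is present
#' in at least \code{ceiling(min_presence_frac * n_species)} species, and it
#' is present in at least \code{group_min_frac} of the species of every
#' named group.
#'
#' @param mat Count matrix (species x clusters).
#' @param min_presence_frac Minimum fraction of species with the cluster.
#' @param median_copy_below Exclusive upper bound on the median copy number.
#' @param groups Named list of character vectors of species; each group must
#'   be non-empty and a subset of the matrix's species.
#' @param group_min_frac Minimum presence fraction within every group.
#' @return Character vector of selected cluster ids.
#' @export
select_cssc <- function(mat, min_presence_frac = 0.90, median_copy_below = 2,
                        groups = list(), group_min_frac = 0.50) {
  n_sp <- nrow(mat)
  for (g in names(groups)) {
    if (length(groups[[g]]) == 0L) stop("empty group ", g, call. = FALSE)
    if (!all(groups[[g]] %in% rownames(mat))) {
      stop("group ", g, " contains unknown species", call. = FALSE)
    }
  }
  pres <- mat > 0L
  ok <- apply(mat, 2L, stats::median) < median_copy_below &
    colSums(pres) >= ceiling(min_presence_frac * n_sp)
  for (g in groups) {
    ok <- ok & colSums(pres[g, , drop = FALSE]) / length(g) >= group_min_frac
  }
  colnames(mat)[ok]
}

#' Encode well-supported splits of input trees as binary characters
#'
#' Matrix-representation-with-likelihood (MRL) supertree encoding: every
#' internal bipartition of every input tree whose support value meets
#' \code{min_support} becomes one binary column over the shared taxon set.
#' Taxa on the side of the split not containing the reference taxon (the
#' lexicographically smallest leaf) are coded 1, the rest 0. Columns are
#' not deduplicated: a split qualifying in several trees contributes one
#' column per tree, as in supertree data matrices. Because all trees must
#' share an identical leaf set, no missing-data symbol is needed (the
#' question mark of classical Baum-Ragan coding only serves taxa absent
#' from a source tree).
#'
#' Under the symmetric binary model the 0/1 polarity of a column does not
#' affect the likelihood, so the choice of reference taxon is a pure
#' bookkeeping convention.
#'
#' @param trees A list of [ape::phylo] trees (or \code{multiPhylo}) with
#'   numeric internal node labels as support values.
#' @param min_support Minimum support for a split to be encoded.
#' @return Binary integer matrix, taxa (sorted) x encoded splits.
#' @export
encode_mrl_splits <- function(trees, min_support = 85) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  taxa <- sort(trees[[1L]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), taxa)) {
      stop("all trees must share an identical leaf set", call. = FALSE)
    }
  }
  cols <- list()
  for (tr in trees) {
    sp <- tree_splits(tr)
    for (s in sp) {
      if (is.na(s$support) || s$support < min_support) next
      side1 <- if (taxa[1L] %in% s$side) setdiff(taxa, s$side) else s$side
      cols[[length(cols) + 1L]] <- as.integer(taxa %in% side1)
    }
  }
  out <- if (length(cols) == 0L) {
    matrix(integer(), nrow = length(taxa), ncol = 0L)
  } else {
    do.call(cbind, cols)
  }
  rownames(out) <- taxa
  if (ncol(out) > 0L) colnames(out) <- sprintf("split%d", seq_len(ncol(out)))
  out
}

# Nontrivial bipartitions of a tree (unrooted view) with support values
# taken from the internal node labels. Returns a list of
# list(side = <tips on the child side>, support = <numeric or NA>).
tree_splits <- function(tree) {
  tree <- ape::unroot(tree)
  n_tip <- length(tree$tip.label)
  desc <- descendant_tips(tree)
  out <- list()
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    if (child <= n_tip) next
    side <- tree$tip.label[desc[[child]]]
    if (length(side) < 2L || length(side) > n_tip - 2L) next
    lab <- if (!is.null(tree$node.label)) {
      tree$node.label[child - n_tip]
    } else {
      NA_character_
    }
    sup <- suppressWarnings(as.numeric(lab))
    out[[length(out) + 1L]] <- list(side = side, support = sup)
  }
  out
}

# tip indices descending from every node, via one postorder pass
descendant_tips <- function(tree) {
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  desc <- vector("list", n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- i
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(edges))) {
    p <- edges[e, 1L]; ch <- edges[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  desc
}

#' Query clusters carrying a clade-specific signal
#'
#' Returns the clusters present in at least \code{min_in_frac} of the
#' in-group species and at most \code{max_out_frac} of the out-group
#' species -- e.g. clusters shared by magnoliids and monocots to the
#' exclusion of eudicots. For visual exploration of such signals,
#' [profile_dendrogram()] clusters profile columns by Jaccard distance with
#' Ward linkage.
#'
#' @param binary Binary matrix (species x clusters).
#' @param in_taxa,out_taxa Character vectors of species.
#' @param min_in_frac Minimum presence fraction within \code{in_taxa}.
#' @param max_out_frac Maximum presence fraction within \code{out_taxa}.
#' @return Character vector of cluster ids.
#' @export
clade_signal_clusters <- function(binary, in_taxa, out_taxa,
                                  min_in_frac = 1.0, max_out_frac = 0.0) {
  stopifnot(all(in_taxa %in% rownames(binary)),
            all(out_taxa %in% rownames(binary)),
            length(in_taxa) > 0L, length(out_taxa) > 0L)
  in_frac <- colSums(binary[in_taxa, , drop = FALSE] > 0) / length(in_taxa)
  out_frac <- colSums(binary[out_taxa, , drop = FALSE] > 0) / length(out_taxa)
  colnames(binary)[in_frac >= min_in_frac & out_frac <= max_out_frac]
}

#' Ward dendrogram of cluster profiles under Jaccard distance
#'
#' Computes pairwise Jaccard distances between the binary profile columns
#' and a Ward-linkage agglomerative dendrogram, for exploring families of
#' clusters with similar taxonomic distributions.
#'
#' @param binary Binary matrix (species x clusters), >= 2 columns.
#' @return A list with \code{dist} (a \code{dist} of Jaccard distances
#'   between columns), \code{hclust} (Ward dendrogram), and \code{phylo}
#'   (the dendrogram as an [ape::phylo], exportable to Newick).
#' @export
profile_dendrogram <- function(binary) {
  if (ncol(binary) < 2L) stop("need >= 2 profile columns", call. = FALSE)
  d <- stats::dist(t(binary), method = "binary") # Jaccard distance
  hc <- stats::hclust(d, method = "ward.D")
  list(dist = d, hclust = hc, phylo = ape::as.phylo(hc))
}
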