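#' Assemble the synteny network from collinear blocks
#'
#' The synteny network is an undirected, unweighted simple graph whose
#' nodes are genes appearing in synteny blocks and whose edges are syntenic
#' anchor pairs. Anchor pairs are pooled across all blocks and deduplicated,
#' both across blocks and across reciprocal genome comparisons, so the
#' network is independent of block order and comparison direction. Nodes
#' exist only via blocks, hence every node has degree >= 1.
#'
#' @param blocks List of blocks from [detect_blocks()], or a 2-column
#'   matrix/data.frame of gene-id pairs (an edge list).
#' @param species_of_gene Optional named character vector mapping gene id to
#'   species; when \code{blocks} is a block list the mapping is derived from
#'   the blocks themselves and this argument is only consulted for genes not
#'   covered (not normally needed).
#' @return An object of class \code{synteny_network} wrapping an
#'   [igraph::graph] with a \code{species} vertex attribute.
#' @export
build_network <- function(blocks, species_of_gene = NULL) {
  if (is.matrix(blocks) || is.data.frame(blocks)) {
    edges <- as.matrix(blocks)[, 1:2, drop = FALSE]
    sp <- species_of_gene
  } else {
    if (length(blocks) == 0L) {
      edges <- matrix(character(), ncol = 2L)
      sp <- species_of_gene
    } else {
      edges <- do.call(rbind, lapply(blocks, function(b) b$anchors))
      sp_pairs <- do.call(rbind, lapply(blocks, function(b) {
        cbind(gene = as.vector(b$anchors),
              species = rep(b$species, each = nrow(b$anchors)))
      }))
      sp <- stats::setNames(sp_pairs[, 2L], sp_pairs[, 1L])
      sp <- sp[!duplicated(names(sp))]
      if (!is.null(species_of_gene)) {
        extra <- setdiff(names(species_of_gene), names(sp))
        sp <- c(sp, species_of_gene[extra])
      }
    }
  }
  mode(edges) <- "character"
  # canonical undirected representation + dedup
  if (nrow(edges) > 0L) {
    a <- pmin(edges[, 1L], edges[, 2L])
    b <- pmax(edges[, 1L], edges[, 2L])
    keep <- a != b & !duplicated(paste(a, b, sep = "\r"))
    edges <- cbind(a[keep], b[keep])
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (!is.null(sp)) {
    igraph::V(g)$species <- unname(sp[igraph::V(g)$name])
  }
  structure(list(graph = g), class = "synteny_network")
}

#' @export
print.synteny_network <- function(x, ...) {
  cat("Synteny network:", igraph::vcount(x$graph), "genes,",
      igraph::ecount(x$graph), "anchor-pair edges\n")
  invisible(x)
}

#' Cluster the synteny network
#'
#' Default clustering identifies connected components, the definition used
#' by the simulation methodology. Alternatively, an externally computed
#' partition (e.g. map-equation community detection) can be ingested via
#' \code{method = "external"}; nodes without an assignment are dropped with
#' a warning reporting their count. Clusters smaller than \code{min_size}
#' (default 2) are discarded.
#'
#' @param network A \code{synteny_network}.
#' @param method \code{"components"} or \code{"external"}.
#' @param assignments Named character vector (gene id -> cluster label),
#'   required for \code{method = "external"}.
#' @param min_size Minimum cluster size retained.
#' @return A data.frame with columns \code{gene_id}, \code{cluster_id}.
#' @export
cluster_network <- function(network, method = c("components", "external"),
                            assignments = NULL, min_size = 2L) {
  stopifnot(inherits(network, "synteny_network"))
  method <- match.arg(method)
  genes <- igraph::V(network$graph)$name
  if (method == "components") {
    comp <- igraph::components(network$graph)
    cl <- data.frame(gene_id = genes,
                     cluster_id = sprintf("c%d", comp$membership),
                     stringsAsFactors = FALSE)
  } else {
    if (is.null(assignments)) {
      stop("method = \"external\" requires an assignment mapping",
           call. = FALSE)
    }
    lab <- assignments[genes]
    n_drop <- sum(is.na(lab))
    if (n_drop > 0L) {
      warning(n_drop, " network node(s) without an external assignment ",
              "were dropped", call. = FALSE)
    }
    cl <- data.frame(gene_id = genes[!is.na(lab)],
                     cluster_id = unname(lab[!is.na(lab)]),
                     stringsAsFactors = FALSE)
  }
  size <- table(cl$cluster_id)
  cl <- cl[cl$cluster_id %in% names(size)[size >= min_size], , drop = FALSE]
  cl <- cl[order(cl$cluster_id, cl$gene_id, method = "radix"), , drop = FALSE]
  rownames(cl) <- NULL
  cl
}

#' Summary statistics of a synteny network
#'
#' Reports the node and edge counts, the degree distribution, the mean
#' local clustering coefficient (nodes of degree < 2 contribute 0), and the
#' number of connected components.
#'
#' @param network A \code{synteny_network}.
#' @return A list with elements \code{n_nodes}, \code{n_edges},
#'   \code{mean_degree}, \code{degree_distribution} (named table),
#'   \code{mean_clustering_coefficient}, \code{n_components}.
#' @export
network_stats <- function(network) {
  stopifnot(inherits(network, "synteny_network"))
  g <- network$graph
  deg <- igraph::degree(g)
  cc <- igraph::transitivity(g, type = "localaverage", isolates = "zero")
  if (igraph::vcount(g) == 0L) cc <- NA_real_
  list(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    mean_degree = if (length(deg)) mean(deg) else NA_real_,
    degree_distribution = table(deg),
    mean_clustering_coefficient = cc,
    n_components = igraph::components(g)$no
  )
}

#' Syntenic percentage between two genomes
#'
#' The fraction of genes retained in synteny between two genomes: the
#' number of genes of species A with at least one syntenic edge to a gene
#' of species B, plus the converse, divided by the summed gene counts of
#' both genomes. For a self comparison (\code{species_a == species_b}) the
#' value is the fraction of the genome's genes with at least one
#' intra-genome syntenic edge.
#'
#' @param network A \code{synteny_network} whose vertices carry a
#'   \code{species} attribute.
#' @param species_a,species_b Species labels.
#' @param genome_sizes Named numeric vector of total gene counts per genome.
#' @return A fraction in [0, 1].
#' @export
syntenic_percentage <- function(network, species_a, species_b, genome_sizes) {
  stopifnot(inherits(network, "synteny_network"))
  for (s in unique(c(species_a, species_b))) {
    if (!s %in% names(genome_sizes)) {
      stop("species ", s, " absent from genome_sizes", call. = FALSE)
    }
  }
  g <- network$graph
  sp <- igraph::V(g)$species
  if (is.null(sp)) stop("network lacks a species vertex attribute",
                        call. = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  s1 <- sp[el[, 1L]]; s2 <- sp[el[, 2L]]
  if (species_a == species_b) {
    sel <- s1 == species_a & s2 == species_a
    n_syn <- length(unique(c(el[sel, 1L], el[sel, 2L])))
    return(n_syn / genome_sizes[[species_a]])
  }
  ab <- (s1 == species_a & s2 == species_b)
  ba <- (s1 == species_b & s2 == species_a)
  a_genes <- unique(c(el[ab, 1L], el[ba, 2L]))
  b_genes <- unique(c(el[ab, 2L], el[ba, 1L]))
  (length(a_genes) + length(b_genes)) /
    (genome_sizes[[species_a]] + genome_sizes[[species_b]])
}

#' Proportion of network nodes belonging to one species
#'
#' @param network A \code{synteny_network} with a \code{species} attribute.
#' @param species Species label.
#' @return Nodes of \code{species} divided by total nodes (0 for an absent
#'   species).
#' @export
node_percentage <- function(network, species) {
  stopifnot(inherits(network, "synteny_network"))
  sp <- igraph::V(network$graph)$species
  if (length(sp) == 0L) return(0)
  sum(sp == species) / length(sp)
}
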