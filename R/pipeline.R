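#' Assemble and validate a pipeline configuration
#'
#' The configuration bundles everything one end-to-end run needs: the
#' per-species gene-position tables, the homology table(s), the
#' collinearity parameters, the clustering method, the ML settings, and an
#' output directory. Supply either a named list or a path to a YAML file
#' with the same fields.
#'
#' Fields: \code{genomes} (named list/vector: species -> BED-like TSV
#' path), \code{homology} (one or more BLAST-tabular paths),
#' \code{collinearity} (list passed to [collinearity_params()]),
#' \code{clustering} (\code{"components"} or \code{"external"}),
#' \code{cluster_assignments} (TSV path, external mode only),
#' \code{k} (FreeRate categories), \code{bootstrap} (replicates, 0 to
#' skip), \code{seed}, \code{outdir}.
#'
#' @param config Named list or YAML file path.
#' @return Validated config list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(collinearity = list(), clustering = "components",
                   cluster_assignments = NULL, k = 1L, bootstrap = 0L,
                   seed = 1L, outdir = "synmrl_out")
  for (f in names(defaults)) {
    if (is.null(config[[f]])) config[[f]] <- defaults[[f]]
  }
  if (is.null(config$genomes) || length(config$genomes) < 3L) {
    stop("config must list gene tables for >= 3 species", call. = FALSE)
  }
  if (is.null(names(config$genomes)) || any(!nzchar(names(config$genomes)))) {
    stop("config$genomes must be named by species", call. = FALSE)
  }
  for (s in names(config$genomes)) {
    if (!file.exists(config$genomes[[s]])) {
      stop("missing gene table for species ", s, ": ",
           config$genomes[[s]], call. = FALSE)
    }
  }
  if (is.null(config$homology)) {
    stop("config must name at least one homology table", call. = FALSE)
  }
  for (h in unlist(config$homology)) {
    if (!file.exists(h)) stop("missing homology table: ", h, call. = FALSE)
  }
  config$collinearity <- do.call(collinearity_params, config$collinearity)
  config$clustering <- match.arg(config$clustering,
                                 c("components", "external"))
  if (config$clustering == "external" &&
        is.null(config$cluster_assignments)) {
    stop("external clustering requires cluster_assignments", call. = FALSE)
  }
  structure(config, class = c("pipeline_config", "list"))
}

#' Run the full synteny-to-tree pipeline
#'
#' Executes the four stages end to end: (1) collinear block detection from
#' gene order and homology hits and synteny network construction, (2)
#' network clustering, (3) matrix representation of the cluster
#' phylogenomic profiles, and (4) maximum-likelihood tree inference (with
#' optional bootstrap supports). All intermediates are written to
#' \code{config$outdir} together with a manifest recording parameters and
#' input checksums; a rerun with an identical config and seed reproduces
#' every output byte for byte.
#'
#' @param config A [pipeline_config()] (or list/YAML path coercible to one).
#' @return Invisibly, a list with \code{matrix}, \code{tree},
#'   \code{model}, \code{stats}, \code{clusters}, and the output paths.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- pipeline_config(config)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out_path <- function(f) file.path(config$outdir, f)

  stage <- "reading gene positions"
  records <- tryCatch({
    bind_gene_tables(lapply(names(config$genomes), function(s) {
      read_gene_positions(config$genomes[[s]], species = s)
    }))
  }, error = function(e) stop("pipeline failed at stage '", stage, "': ",
                              conditionMessage(e), call. = FALSE))

  stage <- "reading homology tables"
  hits <- tryCatch({
    do.call(rbind, lapply(unlist(config$homology), read_homology_table))
  }, error = function(e) stop("pipeline failed at stage '", stage, "': ",
                              conditionMessage(e), call. = FALSE))

  stage <- "block detection"
  blocks <- tryCatch({
    pp <- config$collinearity
    h <- filter_top_hits(hits, pp$b_top)
    h <- collapse_tandem(h, records, pp$tandem_gap)
    detect_blocks(h, records, pp)
  }, error = function(e) stop("pipeline failed at stage '", stage, "': ",
                              conditionMessage(e), call. = FALSE))
  write_blocks_tsv(blocks, out_path("blocks.tsv"))

  stage <- "network construction"
  net <- build_network(blocks)
  write_edge_list(igraph::as_edgelist(net$graph), out_path("edges.tsv"))
  stats <- network_stats(net)
  genome_sizes <- table(records$species)
  species <- sort(names(config$genomes))
  stats$syntenic_percentage <- sapply(species, function(a) {
    sapply(species, function(b) syntenic_percentage(net, a, b, genome_sizes))
  })
  stats$node_percentage <- sapply(species, function(s)
    node_percentage(net, s))
  stats$degree_distribution <- as.list(stats$degree_distribution)
  jsonlite::write_json(stats, out_path("stats.json"), auto_unbox = TRUE,
                       digits = NA)

  stage <- "network clustering"
  assignments <- if (config$clustering == "external") {
    read_cluster_assignments(config$cluster_assignments)
  }
  clusters <- cluster_network(net, method = config$clustering,
                              assignments = assignments)

  stage <- "matrix representation"
  sp_of_gene <- stats::setNames(records$species, records$gene_id)
  counts <- build_profiles(clusters, sp_of_gene, species = species)
  if (ncol(counts) == 0L) {
    stop("pipeline failed at stage '", stage,
         "': no synteny clusters found", call. = FALSE)
  }
  mat <- binarize(counts)
  write_binary_phylip(mat, out_path("matrix.phy"))

  stage <- "tree inference"
  fit <- tryCatch(infer_tree(mat, k = config$k),
                  error = function(e) stop("pipeline failed at stage '",
                                           stage, "': ",
                                           conditionMessage(e),
                                           call. = FALSE))
  tree <- fit$tree
  if (config$bootstrap > 0L) {
    tree <- bootstrap_support(tree, mat, fit$model,
                              n_reps = config$bootstrap,
                              seed = config$seed)
  }
  write_newick(tree, out_path("tree.nwk"))

  manifest <- list(
    parameters = list(collinearity = unclass(config$collinearity),
                      clustering = config$clustering, k = config$k,
                      bootstrap = config$bootstrap, seed = config$seed),
    inputs = as.list(tools::md5sum(c(unlist(config$genomes),
                                     unlist(config$homology)))),
    network = list(nodes = stats$n_nodes, edges = stats$n_edges,
                   clusters = length(unique(clusters$cluster_id)))
  )
  jsonlite::write_json(manifest, out_path("manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  message("synteny network: ", stats$n_nodes, " nodes, ", stats$n_edges,
          " edges, ", length(unique(clusters$cluster_id)), " clusters")
  invisible(list(matrix = mat, tree = tree, model = fit$model,
                 loglik = fit$loglik, stats = stats, clusters = clusters,
                 outdir = config$outdir))
}
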