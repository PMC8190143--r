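#' Read a BED-like gene position table
#'
#' Reads a tab-separated table of gene positions (chromosome, start, end,
#' gene id, and optionally score and strand in columns 5-6) and assigns each
#' gene an integer rank along its chromosome. All downstream synteny logic
#' operates on these 0-based ranks, i.e. on gene order, not on base-pair
#' coordinates; the start coordinate is used for sorting only, so the 0- vs
#' 1-based convention of the input is irrelevant.
#'
#' Genes on each chromosome are sorted by (start, gene id) -- the gene id is
#' the deterministic tie-break for identical starts -- and ranked 0..n-1.
#'
#' @param path Path to a tab-separated file with at least 4 columns:
#'   chromosome, start, end, gene id.
#' @param species Species label attached to every record.
#' @return A data.frame with columns \code{gene_id}, \code{species},
#'   \code{chromosome}, \code{rank}, \code{start}, \code{end},
#'   \code{strand} (\code{NA} when absent from the input).
#' @export
read_gene_positions <- function(path, species) {
  stopifnot(is.character(species), length(species) == 1L, nzchar(species))
  lines <- read_data_lines(path)
  if (length(lines) == 0L) {
    return(empty_gene_table())
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    bad <- which(nf < 4L)[1L]
    stop("line ", bad, ": expected >= 4 tab-separated columns, found ",
         nf[bad], call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- parse_int_column(vapply(fields, `[[`, "", 2L), "start")
  end <- parse_int_column(vapply(fields, `[[`, "", 3L), "end")
  gene_id <- vapply(fields, `[[`, "", 4L)
  strand <- vapply(fields, function(f)
    if (length(f) >= 6L && f[[6L]] %in% c("+", "-")) f[[6L]] else NA_character_,
    "")
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup) > 0L) {
    stop("duplicate gene id ", dup[1L], call. = FALSE)
  }
  ord <- order(chrom, start, gene_id, method = "radix")
  out <- data.frame(
    gene_id = gene_id[ord], species = species, chromosome = chrom[ord],
    rank = NA_integer_, start = start[ord], end = end[ord],
    strand = strand[ord], stringsAsFactors = FALSE
  )
  out$rank <- stats::ave(seq_len(nrow(out)), out$chromosome,
                         FUN = seq_along) - 1L
  out
}

empty_gene_table <- function() {
  data.frame(gene_id = character(), species = character(),
             chromosome = character(), rank = integer(), start = integer(),
             end = integer(), strand = character(), stringsAsFactors = FALSE)
}

read_data_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

parse_int_column <- function(x, what) {
  val <- suppressWarnings(as.integer(x))
  bad <- which(is.na(val) | as.character(val) != sub("^\\+", "", x))
  # allow leading zeros etc.: re-check with numeric equality
  if (length(bad) > 0L) {
    num <- suppressWarnings(as.numeric(x[bad]))
    still <- bad[is.na(num) | num != floor(num)]
    if (length(still) > 0L) {
      stop("line ", still[1L], ": non-integer ", what, " coordinate '",
           x[still[1L]], "'", call. = FALSE)
    }
    val[bad] <- as.integer(num)
  }
  val
}

#' Combine per-species gene tables
#'
#' Row-binds gene tables read with [read_gene_positions()], enforcing global
#' uniqueness of gene ids across the dataset.
#'
#' @param ... Gene tables, or a single list of them.
#' @return A single gene table data.frame.
#' @export
bind_gene_tables <- function(...) {
  tabs <- list(...)
  if (length(tabs) == 1L && is.list(tabs[[1L]]) && !is.data.frame(tabs[[1L]])) {
    tabs <- tabs[[1L]]
  }
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup) > 0L) {
    stop("duplicate gene id ", dup[1L], " across species tables",
         call. = FALSE)
  }
  out
}

#' Read a 12-column BLAST tabular homology table
#'
#' Parses the standard 12-column tabular output of an all-vs-all sequence
#' similarity search. Only the query, subject, e-value and bitscore columns
#' (1, 2, 11, 12) are used. Self hits (query == subject) are dropped; the
#' order of the remaining rows is preserved.
#'
#' @param path Path to a tab-separated file with 12 columns per row.
#' @return A data.frame with columns \code{query}, \code{subject},
#'   \code{evalue}, \code{bitscore}.
#' @export
read_homology_table <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines) == 0L) {
    return(data.frame(query = character(), subject = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- which(nf < 12L)[1L]
    stop("line ", bad, ": expected 12 tab-separated columns, found ",
         nf[bad], call. = FALSE)
  }
  evalue <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 11L)))
  if (anyNA(evalue)) {
    stop("line ", which(is.na(evalue))[1L], ": unparsable e-value",
         call. = FALSE)
  }
  if (any(evalue < 0)) {
    stop("line ", which(evalue < 0)[1L], ": negative e-value", call. = FALSE)
  }
  bitscore <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 12L)))
  if (anyNA(bitscore)) {
    stop("line ", which(is.na(bitscore))[1L], ": unparsable bitscore",
         call. = FALSE)
  }
  out <- data.frame(
    query = vapply(fields, `[[`, "", 1L),
    subject = vapply(fields, `[[`, "", 2L),
    evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE
  )
  out <- out[out$query != out$subject, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a binary matrix in relaxed PHYLIP format
#'
#' Writes the header line "n_species n_characters" followed by one row per
#' species: the species name, a space, and the unwrapped 0/1 character
#' string. Rows are never line-wrapped, so arbitrarily wide matrices (the
#' empirical use case has > 100,000 columns) remain one line per species.
#'
#' @param mat Binary 0/1 matrix with species as rownames.
#' @param path Output file path.
#' @export
write_binary_phylip <- function(mat, path) {
  mat <- as.matrix(mat)
  if (nrow(mat) == 0L || ncol(mat) == 0L) stop("empty matrix", call. = FALSE)
  if (is.null(rownames(mat))) stop("matrix must have species rownames",
                                   call. = FALSE)
  if (any(grepl("[[:space:]]", rownames(mat)))) {
    stop("species name containing whitespace: ",
         rownames(mat)[grepl("[[:space:]]", rownames(mat))][1L],
         call. = FALSE)
  }
  if (!all(mat %in% c(0L, 1L))) stop("matrix is not binary", call. = FALSE)
  rows <- apply(mat, 1L, paste, collapse = "")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(paste(nrow(mat), ncol(mat)),
               paste(rownames(mat), rows)), con)
  invisible(NULL)
}

#' Read a relaxed PHYLIP binary matrix
#'
#' Inverse of [write_binary_phylip()]: a round trip reproduces the matrix
#' exactly (names, order and values).
#'
#' @param path Path to a relaxed PHYLIP file with a 0/1 alphabet.
#' @return Binary integer matrix with species rownames.
#' @export
read_binary_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  hdr <- scan(text = lines[1L], what = integer(), quiet = TRUE)
  if (length(hdr) != 2L) stop("malformed PHYLIP header", call. = FALSE)
  n <- hdr[1L]; m <- hdr[2L]
  if (length(lines) != n + 1L) {
    stop("expected ", n, " sequence rows, found ", length(lines) - 1L,
         call. = FALSE)
  }
  parts <- regmatches(lines[-1L], regexpr("^\\S+", lines[-1L]))
  seqs <- gsub("[[:space:]]", "", sub("^\\S+", "", lines[-1L]))
  if (any(nchar(seqs) != m)) {
    stop("row length differs from header character count", call. = FALSE)
  }
  if (any(grepl("[^01]", seqs))) stop("non-binary character state",
                                      call. = FALSE)
  mat <- matrix(as.integer(unlist(strsplit(seqs, "", fixed = TRUE))),
                nrow = n, ncol = m, byrow = TRUE)
  rownames(mat) <- parts
  mat
}

#' Read and write Newick trees
#'
#' Thin validating wrappers around [ape::read.tree()] and
#' [ape::write.tree()]. Branch lengths and internal node (support) labels
#' round trip; unbalanced parentheses are reported with the character offset
#' of the first imbalance; duplicate leaf labels are an error.
#'
#' @param path File path.
#' @return \code{read_newick}: an [ape::phylo] object.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  check_parens(txt)
  tree <- ape::read.tree(text = txt)
  if (is.null(tree)) stop("could not parse Newick tree", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label: ",
         tree$tip.label[duplicated(tree$tip.label)][1L], call. = FALSE)
  }
  tree
}

check_parens <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  neg <- which(depth < 0L)
  if (length(neg) > 0L) {
    stop("unbalanced parentheses at character ", neg[1L], call. = FALSE)
  }
  if (length(depth) > 0L && depth[length(depth)] != 0L) {
    stop("unbalanced parentheses: ", depth[length(depth)],
         " unclosed '(' at character ", length(depth), call. = FALSE)
  }
  invisible(NULL)
}

#' @rdname read_newick
#' @param tree An [ape::phylo] object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(NULL)
}

#' Read externally computed cluster assignments
#'
#' Adapter for ingesting the output of an external community-detection run
#' (e.g. map-equation clustering of the synteny network): a 2-column
#' tab-separated file of gene id and cluster label. Cluster labels are
#' opaque. A gene listed twice with conflicting labels is an error;
#' exact duplicate rows are tolerated.
#'
#' @param path Path to a 2-column TSV (gene_id, cluster_id).
#' @return Named character vector mapping gene id to cluster label.
#' @export
read_cluster_assignments <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines) == 0L) {
    return(stats::setNames(character(), character()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("line ", which(nf < 2L)[1L], ": expected 2 tab-separated columns",
         call. = FALSE)
  }
  gene <- vapply(fields, `[[`, "", 1L)
  clu <- vapply(fields, `[[`, "", 2L)
  keep <- !duplicated(paste0(gene, "\r", clu))
  gene <- gene[keep]; clu <- clu[keep]
  if (anyDuplicated(gene)) {
    stop("gene ", gene[duplicated(gene)][1L],
         " assigned to more than one cluster", call. = FALSE)
  }
  stats::setNames(clu, gene)
}

#' Read and write network edge lists
#'
#' 2-column tab-separated edge list (gene_a, gene_b), one undirected edge
#' per row.
#'
#' @param path File path.
#' @param edges 2-column character matrix or data.frame of gene-id pairs.
#' @export
write_edge_list <- function(edges, path) {
  edges <- as.matrix(edges)
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(NULL)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  lines <- read_data_lines(path)
  if (length(lines) == 0L) {
    return(matrix(character(), ncol = 2L))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("line ", which(lengths(fields) < 2L)[1L],
         ": expected 2 tab-separated columns", call. = FALSE)
  }
  cbind(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L))
}

#' Write a synteny block report
#'
#' One anchor per row: block id, species pair, chromosome pair, orientation,
#' query gene, subject gene. The dialect mirrors per-block collinearity
#' reports of standard synteny callers in spirit.
#'
#' @param blocks List of synteny blocks from [detect_blocks()].
#' @param path Output TSV path.
#' @export
write_blocks_tsv <- function(blocks, path) {
  rows <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    data.frame(block = i, species_a = b$species[1L], species_b = b$species[2L],
               chrom_a = b$chromosomes[1L], chrom_b = b$chromosomes[2L],
               orientation = b$orientation,
               query = b$anchors[, 1L], subject = b$anchors[, 2L],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
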