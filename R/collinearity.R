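#' Collinearity parameters
#'
#' Parameter set for pairwise collinear block detection. The defaults are
#' the "b5s5m25" setting commonly used for angiosperm-scale comparisons:
#' \code{b_top} best homologs kept per query, blocks require at least
#' \code{a_min} anchors ("s"), and at most \code{g_max} intervening genes
#' are allowed between consecutive anchors on either genome ("m").
#' \code{tandem_gap} is the maximum rank distance used when collapsing
#' tandem arrays to a single representative hit.
#'
#' @param b_top Number of top homologous pairs kept per query (>= 1).
#' @param a_min Minimum number of matched syntenic anchors per block (>= 2).
#' @param g_max Maximum number of gene gaps between consecutive anchors,
#'   enforced independently on each genome (>= 0).
#' @param tandem_gap Maximum rank separation for tandem-array collapsing.
#' @return A list of class \code{collinearity_params}.
#' @export
collinearity_params <- function(b_top = 5L, a_min = 5L, g_max = 25L,
                                tandem_gap = 5L) {
  b_top <- as.integer(b_top); a_min <- as.integer(a_min)
  g_max <- as.integer(g_max); tandem_gap <- as.integer(tandem_gap)
  if (is.na(b_top) || b_top < 1L) stop("b_top must be >= 1", call. = FALSE)
  if (is.na(a_min) || a_min < 2L) stop("a_min must be >= 2", call. = FALSE)
  if (is.na(g_max) || g_max < 0L) stop("g_max must be >= 0", call. = FALSE)
  if (is.na(tandem_gap) || tandem_gap < 0L) {
    stop("tandem_gap must be >= 0", call. = FALSE)
  }
  structure(list(b_top = b_top, a_min = a_min, g_max = g_max,
                 tandem_gap = tandem_gap),
            class = "collinearity_params")
}

#' Keep the best hits per query
#'
#' For each query gene, retains the \code{b_top} best homology hits ranked
#' by e-value ascending, then bitscore descending, then subject id.
#'
#' @param hits Homology hit data.frame (see [read_homology_table()]).
#' @param b_top Number of hits retained per query.
#' @return Filtered hit data.frame.
#' @export
filter_top_hits <- function(hits, b_top = 5L) {
  b_top <- as.integer(b_top)
  if (is.na(b_top) || b_top < 1L) stop("b_top must be >= 1", call. = FALSE)
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query, hits$evalue, -hits$bitscore, hits$subject,
               method = "radix")
  hits <- hits[ord, , drop = FALSE]
  within <- stats::ave(seq_len(nrow(hits)), hits$query, FUN = seq_along)
  out <- hits[within <= b_top, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse tandem-array hits to one representative
#'
#' Local tandem duplications generate stacks of hits that would inflate
#' collinear chains. Hits sharing one endpoint whose other endpoints lie on
#' the same chromosome and form a tandem array (each within
#' \code{tandem_gap} ranks of the next, chained transitively) are collapsed
#' to the single hit with the smallest e-value (ties: larger bitscore, then
#' smaller gene id).
#'
#' @param hits Homology hit data.frame.
#' @param records Gene table covering every gene in \code{hits}.
#' @param tandem_gap Maximum rank separation within a tandem array.
#' @return Collapsed hit data.frame.
#' @export
collapse_tandem <- function(hits, records, tandem_gap = 5L) {
  if (nrow(hits) == 0L) return(hits)
  idx <- match(c(hits$query, hits$subject), records$gene_id)
  if (anyNA(idx)) {
    missing <- c(hits$query, hits$subject)[is.na(idx)][1L]
    stop("hit references unknown gene ", missing, call. = FALSE)
  }
  chrom <- paste(records$species, records$chromosome, sep = "\r")
  rank <- records$rank
  qi <- idx[seq_len(nrow(hits))]
  si <- idx[nrow(hits) + seq_len(nrow(hits))]

  # Group hits by (shared endpoint, chromosome of the other endpoint), sort
  # the other endpoints by rank, cut where the rank step exceeds tandem_gap
  # (transitive chaining), keep the best hit per resulting tandem array.
  # Two passes: arrays on the query side sharing a subject, then arrays on
  # the subject side sharing a query.
  keep <- collapse_side(hits, anchor = hits$subject,
                        other_chrom = chrom[qi], other_rank = rank[qi],
                        tandem_gap = tandem_gap)
  hits <- hits[keep, , drop = FALSE]
  qi <- qi[keep]; si <- si[keep]
  keep <- collapse_side(hits, anchor = hits$query,
                        other_chrom = chrom[si], other_rank = rank[si],
                        tandem_gap = tandem_gap)
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

collapse_side <- function(hits, anchor, other_chrom, other_rank, tandem_gap) {
  n <- nrow(hits)
  grp <- paste(anchor, other_chrom, sep = "\r")
  ord <- order(grp, other_rank, method = "radix")
  same <- c(FALSE, grp[ord][-1L] == grp[ord][-n])
  step_ok <- c(FALSE, diff(other_rank[ord]) <= tandem_gap)
  array_id <- cumsum(!(same & step_ok))
  # best hit per array: min evalue, then max bitscore, then smaller ids
  o2 <- order(array_id, hits$evalue[ord], -hits$bitscore[ord],
              hits$query[ord], hits$subject[ord], method = "radix")
  first <- !duplicated(array_id[o2])
  sort(ord[o2][first])
}

#' Detect collinear synteny blocks
#'
#' Chains homology hits into collinear blocks by dynamic programming. For
#' every pair of chromosomes (across genome pairs and within a genome,
#' including intra-chromosome comparisons arising from ancient duplications)
#' and each orientation, maximal-cardinality chains are extracted whose
#' query ranks strictly increase, whose subject ranks strictly increase
#' (forward) or decrease (reverse), and whose consecutive anchors are
#' separated by at most \code{g_max} intervening genes on both genomes.
#' Chains are reported best-first; each hit is used by at most one block per
#' chromosome-pair comparison, and only chains with at least \code{a_min}
#' anchors are returned. Chain score is the anchor count.
#'
#' Hits are canonicalised to undirected anchor pairs before chaining, so the
#' block set does not depend on which genome served as query in the
#' similarity search. Identical-gene self pairs are excluded.
#'
#' @param hits Homology hits, already top-b filtered and tandem-collapsed.
#' @param records Gene table covering every gene in \code{hits}.
#' @param params A [collinearity_params()] object.
#' @return List of blocks; each block is a list with elements
#'   \code{species} (length-2), \code{chromosomes} (length-2),
#'   \code{orientation} ("forward"/"reverse"), \code{anchors} (2-column
#'   matrix of gene ids, chain order), and \code{score} (anchor count).
#' @export
detect_blocks <- function(hits, records, params = collinearity_params()) {
  stopifnot(inherits(params, "collinearity_params"))
  if (nrow(hits) == 0L) return(list())
  idx_q <- match(hits$query, records$gene_id)
  idx_s <- match(hits$subject, records$gene_id)
  if (anyNA(idx_q) || anyNA(idx_s)) {
    missing <- c(hits$query[is.na(idx_q)], hits$subject[is.na(idx_s)])[1L]
    stop("hit references unknown gene ", missing, call. = FALSE)
  }
  key <- function(i) paste(records$species[i], records$chromosome[i],
                           sep = "\r")
  kq <- key(idx_q); ks <- key(idx_s)
  # canonical orientation of each anchor pair: smaller (species, chromosome,
  # rank) first; drop identical-gene pairs; dedupe reciprocal duplicates
  flip <- kq > ks | (kq == ks & records$rank[idx_q] > records$rank[idx_s])
  a <- ifelse(flip, idx_s, idx_q)
  b <- ifelse(flip, idx_q, idx_s)
  self <- a == b
  a <- a[!self]; b <- b[!self]
  dup <- duplicated(paste(a, b))
  a <- a[!dup]; b <- b[!dup]
  if (length(a) == 0L) return(list())

  comp <- paste(key(a), key(b), sep = "\n")
  blocks <- list()
  for (cmp in sort(unique(comp))) {
    sel <- comp == cmp
    blocks <- c(blocks, chain_chromosome_pair(
      qrank = records$rank[a[sel]], srank = records$rank[b[sel]],
      qgene = records$gene_id[a[sel]], sgene = records$gene_id[b[sel]],
      species = c(records$species[a[sel]][1L], records$species[b[sel]][1L]),
      chroms = c(records$chromosome[a[sel]][1L],
                 records$chromosome[b[sel]][1L]),
      a_min = params$a_min, g_max = params$g_max))
  }
  blocks
}

# Greedy best-first extraction of gap-legal chains within one chromosome
# pair. Anchors live on (qrank, srank); both orientations are scored and the
# larger chain extracted first; ties broken towards forward orientation,
# then smaller starting (query, subject) rank.
chain_chromosome_pair <- function(qrank, srank, qgene, sgene, species,
                                  chroms, a_min, g_max) {
  active <- rep(TRUE, length(qrank))
  out <- list()
  repeat {
    if (sum(active) < a_min) break
    fwd <- best_chain(qrank[active], srank[active], g_max)
    rev <- best_chain(qrank[active], -srank[active], g_max)
    if (max(length(fwd), length(rev)) < a_min) break
    if (length(fwd) >= length(rev)) {
      chain <- which(active)[fwd]; orientation <- "forward"
    } else {
      chain <- which(active)[rev]; orientation <- "reverse"
    }
    out[[length(out) + 1L]] <- list(
      species = species, chromosomes = chroms, orientation = orientation,
      anchors = cbind(query = qgene[chain], subject = sgene[chain]),
      score = length(chain))
    active[chain] <- FALSE
  }
  out
}

# Longest strictly-increasing gap-constrained chain by O(m^2) DP. Returns
# the indices of the best chain (in chain order). Deterministic tie-breaks:
# among equally long chains, the one with the lexicographically smallest
# (qrank, srank) start; then smallest end.
best_chain <- function(q, s, g_max) {
  m <- length(q)
  ord <- order(q, s, method = "radix")
  q <- q[ord]; s <- s[ord]
  dp <- rep(1L, m)
  pred <- rep(0L, m)
  start_q <- q; start_s <- s
  for (i in seq_len(m)) {
    for (j in seq_len(i - 1L)) {
      if (q[j] < q[i] && s[j] < s[i] &&
          (q[i] - q[j] - 1L) <= g_max && (abs(s[i] - s[j]) - 1L) <= g_max) {
        better <- dp[j] + 1L > dp[i] ||
          (dp[j] + 1L == dp[i] &&
             (start_q[j] < start_q[i] ||
                (start_q[j] == start_q[i] && start_s[j] < start_s[i])))
        if (better) {
          dp[i] <- dp[j] + 1L
          pred[i] <- j
          start_q[i] <- start_q[j]; start_s[i] <- start_s[j]
        }
      }
    }
  }
  best <- max(dp)
  cand <- which(dp == best)
  o <- order(start_q[cand], start_s[cand], q[cand], s[cand])
  i <- cand[o[1L]]
  chain <- integer(best)
  k <- best
  while (i > 0L) {
    chain[k] <- i
    k <- k - 1L
    i <- pred[i]
  }
  ord[chain]
}
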