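# Independent oracles and fixture builders used across the suite.

# Brute-force log-likelihood: sum over all interior state assignments.
# Deliberately naive; shares no code with the pruning implementation.
brute_force_loglik <- function(tree, mat, model) {
  tree <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  nt <- length(tree$tip.label)
  E <- tree$edge
  interior <- sort(unique(as.vector(E)))
  interior <- interior[interior > nt]
  root <- E[nrow(E), 1L]
  P_all <- lapply(seq_along(model$rates), function(k)
    lapply(seq_len(nrow(E)), function(e)
      transition_prob(model, tree$edge.length[e], model$rates[k])))
  total <- 0
  for (col in seq_len(ncol(mat))) {
    site <- 0
    for (k in seq_along(model$rates)) {
      P <- P_all[[k]]
      s <- 0
      for (assign in 0:(2^length(interior) - 1)) {
        st <- integer(nt + tree$Nnode)
        st[seq_len(nt)] <- mat[tree$tip.label, col]
        st[interior] <- as.integer(intToBits(assign))[seq_along(interior)]
        p <- model$pi[st[root] + 1L]
        for (e in seq_len(nrow(E))) {
          p <- p * P[[e]][st[E[e, 1L]] + 1L, st[E[e, 2L]] + 1L]
        }
        s <- s + p
      }
      site <- site + model$weights[k] * s
    }
    total <- total + log(site)
  }
  total
}

# Exhaustive enumeration of gap-legal collinear chains over anchors given
# as (qrank, srank) pairs; returns the maximum chain size and all maximum
# chains (as index sets, chain-ordered), considering both orientations.
enumerate_max_chains <- function(qrank, srank, g_max) {
  m <- length(qrank)
  best <- list(size = 0L, chains = list())
  legal <- function(i, j, dir) {
    qrank[j] > qrank[i] && (qrank[j] - qrank[i] - 1L) <= g_max &&
      (if (dir > 0) srank[j] > srank[i] else srank[j] < srank[i]) &&
      (abs(srank[j] - srank[i]) - 1L) <= g_max
  }
  grow <- function(chain, dir) {
    n <- length(chain)
    if (n > best$size) {
      best$size <<- n
      best$chains <<- list(chain)
    } else if (n == best$size) {
      best$chains <<- c(best$chains, list(chain))
    }
    last <- chain[n]
    for (j in seq_len(m)) {
      if (legal(last, j, dir)) grow(c(chain, j), dir)
    }
  }
  for (i in seq_len(m)) {
    grow(i, +1)
    grow(i, -1)
  }
  best
}

# random gene tables for two toy single-chromosome genomes
random_toy_genomes <- function(n_x, n_y, species = c("A", "B")) {
  gx <- data.frame(gene_id = sprintf("x%02d", seq_len(n_x)),
                   species = species[1], chromosome = "chr1",
                   rank = seq_len(n_x) - 1L, start = seq_len(n_x) * 100L,
                   end = seq_len(n_x) * 100L + 50L, strand = NA_character_,
                   stringsAsFactors = FALSE)
  gy <- data.frame(gene_id = sprintf("y%02d", seq_len(n_y)),
                   species = species[2], chromosome = "chr1",
                   rank = seq_len(n_y) - 1L, start = seq_len(n_y) * 100L,
                   end = seq_len(n_y) * 100L + 50L, strand = NA_character_,
                   stringsAsFactors = FALSE)
  rbind(gx, gy)
}

hits_frame <- function(query, subject, evalue = 1e-30, bitscore = 100) {
  data.frame(query = query, subject = subject,
             evalue = rep_len(evalue, length(query)),
             bitscore = rep_len(bitscore, length(query)),
             stringsAsFactors = FALSE)
}

# matrix whose columns are clade indicators of a fixed 6-taxon tree; all
# columns are mutually consistent and jointly resolve the tree
consistent_six_taxon_matrix <- function(n_cols = 500L) {
  taxa <- paste0("s", 1:6)
  clades <- list(c("s1", "s2"), c("s3", "s4"), c("s5", "s6"),
                 c("s1", "s2", "s3", "s4"))
  cols <- lapply(seq_len(n_cols), function(i) {
    as.integer(taxa %in% clades[[((i - 1L) %% length(clades)) + 1L]])
  })
  mat <- do.call(cbind, cols)
  rownames(mat) <- taxa
  mat
}

six_taxon_tree <- function() {
  ape::read.tree(text = "(((s1:1,s2:1):1,(s3:1,s4:1):1):1,(s5:1,s6:1):2);")
}
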