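# Independent oracles used by the unit and acceptance tests.  These are
# deliberately written by different routes than the package code paths:
# enumeration instead of pruning, ape matrix exponentials instead of the
# closed form, ape clade extraction instead of bipartition bookkeeping.

# random ultrametric-free tree with branch lengths in [0, 2]
random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0, 2)
  tr
}

# Brute-force Mk likelihood: sum over all state assignments to internal
# nodes (and to unknown tips), products of ape::matexpo transition
# probabilities and the root prior.  Optionally fixes one node's state.
brute_mk_lik <- function(tree, traits, q01, q10, prior = c(0.5, 0.5),
                         fix_node = NULL, fix_state = NULL) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  Q <- matrix(c(-q01, q10, q01, -q10), 2L, 2L)
  Pm <- lapply(seq_len(nrow(tree$edge)), function(i)
    ape::matexpo(Q * tree$edge.length[i]))
  obs <- as.character(traits[tree$tip.label])
  free <- c(which(is.na(obs) | obs %in% c("unknown", "both")),
            (ntip + 1L):nn)
  known <- setdiff(seq_len(ntip), free)
  grid <- as.matrix(expand.grid(rep(list(0:1), length(free))))
  stmat <- matrix(0L, nrow(grid), nn)
  for (j in seq_along(known)) stmat[, known[j]] <- as.integer(obs[known[j]])
  for (j in seq_along(free)) stmat[, free[j]] <- grid[, j]
  if (!is.null(fix_node))
    stmat <- stmat[stmat[, fix_node] == fix_state, , drop = FALSE]
  pr <- prior[stmat[, root] + 1L]
  for (i in seq_len(nrow(tree$edge)))
    pr <- pr * Pm[[i]][cbind(stmat[, tree$edge[i, 1L]] + 1L,
                             stmat[, tree$edge[i, 2L]] + 1L)]
  sum(pr)
}

# Simple Smith-Waterman with linear gap penalty g (score-only DP), the
# reduced case an affine implementation must reproduce when
# gap_open == gap_extend == g.
sw_linear_oracle <- function(a, b, scores, g) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  H <- matrix(0, n + 1L, m + 1L)
  best <- 0
  for (i in seq_len(n)) for (j in seq_len(m)) {
    H[i + 1L, j + 1L] <- max(0,
                             H[i, j] + scores[av[i], bv[j]],
                             H[i, j + 1L] - g,
                             H[i + 1L, j] - g)
    best <- max(best, H[i + 1L, j + 1L])
  }
  best
}

# Direct enumeration of weighted pair counts over blocks (upper-triangle
# storage, total over unordered cells).
pair_count_oracle <- function(blocks, weights, alphabet) {
  A <- length(alphabet)
  counts <- matrix(0, A, A, dimnames = list(alphabet, alphabet))
  for (b in seq_along(blocks)) {
    rows <- strsplit(blocks[[b]]$seqs, "")
    w <- weights[[b]]
    width <- length(rows[[1]])
    for (col in seq_len(width)) {
      for (i in seq_len(length(rows) - 1L)) for (j in (i + 1L):length(rows)) {
        x <- rows[[i]][col]; y <- rows[[j]][col]
        if (!(x %in% alphabet) || !(y %in% alphabet)) next
        lo <- min(x, y); hi <- max(x, y)
        counts[lo, hi] <- counts[lo, hi] + w[i] * w[j]
      }
    }
  }
  counts + t(counts) - diag(diag(counts))
}

# Exhaustive maximally-inclusive-subtree search using ape primitives:
# candidates are the clades of the rooted gene tree (every node); a
# candidate is valid when each taxon with several leaves inside it is
# monophyletic within the extracted subtree.
oracle_max_subtree <- function(tree) {
  ntip <- length(tree$tip.label)
  cands <- list()
  for (node in seq_len(ntip + tree$Nnode)) {
    if (node <= ntip) {
      cands[[node]] <- list(labels = tree$tip.label[node], sub = NULL)
    } else {
      sub <- if (node == ntip + 1L) tree else ape::extract.clade(tree, node)
      cands[[node]] <- list(labels = sub$tip.label, sub = sub)
    }
  }
  best <- NULL
  for (cand in cands) {
    labs <- cand$labels
    taxa <- sub("@.*$", "", labs)
    ok <- TRUE
    if (!is.null(cand$sub)) {
      for (tx in unique(taxa[duplicated(taxa)])) {
        mem <- labs[taxa == tx]
        if (length(mem) == length(labs)) next
        if (!ape::is.monophyletic(cand$sub, mem)) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    entry <- list(labels = sort(labs), ntaxa = length(unique(taxa)),
                  nseq = length(labs),
                  key = paste(sort(labs), collapse = "\r"))
    if (is.null(best) ||
        entry$ntaxa > best$ntaxa ||
        (entry$ntaxa == best$ntaxa && entry$nseq > best$nseq) ||
        (entry$ntaxa == best$ntaxa && entry$nseq == best$nseq &&
         entry$key < best$key))
      best <- entry
  }
  best$labels
}

# random gene tree with out-paralogs planted by duplicated taxon labels
random_gene_tree <- function(n_leaves, n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_leaves)
  taxa <- sample(paste0("T", seq_len(n_taxa)), n_leaves, replace = TRUE)
  counter <- integer(0)
  labs <- character(n_leaves)
  for (i in seq_len(n_leaves)) {
    k <- (if (taxa[i] %in% names(counter)) counter[[taxa[i]]] else 0L) + 1L
    counter[[taxa[i]]] <- k
    labs[i] <- paste0(taxa[i], "@", k)
  }
  tr$tip.label <- labs
  tr
}

# tiny substitution matrix over an arbitrary alphabet for alignment tests
toy_submat <- function(alphabet = c("A", "C", "D", "E"), match = 4,
                       mismatch = -2) {
  s <- matrix(mismatch, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(s) <- match
  structure(list(scores = s, scale = 2, bg = NULL, pseudocount = 0,
                 alphabet = alphabet), class = "ppy_submat")
}
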