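# Out-paralog removal by maximally-inclusive-subtree selection on gene
# trees (leaf labels "taxon@seq_id"), in-paralog consensus, and the
# taxon-occupancy filter.

# split "taxon@seq" labels
leaf_taxon <- function(labels) sub("@.*$", "", labels)

#' Collapse poorly supported internal edges into polytomies
#'
#' Internal edges whose support value is below `threshold` are
#' contracted; `threshold = 0` is the identity.  Supports are read from
#' the tree's internal node labels (the common Newick dialect); the
#' support scale (`[0,1]` or `[0,100]`) is auto-detected.
#'
#' @param tree `phylo` gene tree with support values as node labels.
#' @param threshold support below which an edge is contracted.
#' @return the (possibly multifurcating) collapsed tree.
#' @export
collapse_low_support <- function(tree, threshold = 0) {
  if (threshold == 0) return(tree)
  supports <- suppressWarnings(as.numeric(tree$node.label))
  if (is.null(tree$node.label) || all(is.na(supports)))
    stop("threshold > 0 requires support values in node labels")
  dialect_max <- if (max(supports, na.rm = TRUE) <= 1) 1 else 100
  if (threshold > dialect_max)
    stop("threshold exceeds the support dialect range [0, ", dialect_max, "]")
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  # internal (non-root) nodes whose incoming edge collapses
  drop_nodes <- which(!is.na(supports) & supports < threshold) + ntip
  drop_nodes <- setdiff(drop_nodes, root)
  if (!length(drop_nodes)) return(tree)
  edge <- tree$edge
  len <- tree$edge.length
  parent_of <- integer(max(edge))
  parent_of[edge[, 2L]] <- edge[, 1L]
  # contract: re-parent children of each dropped node to its parent,
  # adding the dropped edge length to nothing (the edge vanishes)
  final_parent <- function(p) {
    while (p %in% drop_nodes) p <- parent_of[p]
    p
  }
  keep <- !(edge[, 2L] %in% drop_nodes)
  new_edge <- edge[keep, , drop = FALSE]
  new_len <- len[keep]
  new_edge[, 1L] <- vapply(new_edge[, 1L], final_parent, numeric(1))
  # renumber internal nodes consecutively
  kept_internal <- sort(unique(new_edge[, 1L]))
  map <- integer(max(edge))
  map[seq_len(ntip)] <- seq_len(ntip)
  map[kept_internal] <- ntip + seq_along(kept_internal)
  out <- list(edge = cbind(map[new_edge[, 1L]], map[new_edge[, 2L]]),
              edge.length = new_len,
              Nnode = length(kept_internal),
              tip.label = tree$tip.label)
  if (!is.null(tree$node.label))
    out$node.label <- tree$node.label[kept_internal - ntip]
  class(out) <- "phylo"
  ape::reorder.phylo(out, "cladewise")
}

# descendant clades (leaf-index sets) per edge of a tree as given
tree_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  nn <- ntip + po$Nnode
  below <- vector("list", nn)
  for (i in seq_len(ntip)) below[[i]] <- i
  for (i in seq_len(nrow(po$edge))) {
    p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  lapply(seq_len(nrow(po$edge)),
         function(i) sort(below[[po$edge[i, 2L]]]))
}

#' Select the maximally inclusive subtree free of out-paralogs
#'
#' Selects, over the candidate rooted subtrees of the gene tree, the one
#' containing the greatest number of distinct taxa such that, within the
#' subtree, every taxon represented more than once has all its sequences
#' forming a clade (in-paralogs allowed, out-paralogs excluded).  For a
#' rooted input the candidates are the clades of the tree as given
#' (including the whole tree); for an unrooted input both orientations of
#' every edge are evaluated instead of choosing a root heuristically.
#' Ties break by more sequences, then by the lexicographically smallest
#' sorted leaf-label list.
#'
#' @param tree `phylo` gene tree with `taxon@seq_id` leaf labels.
#' @return character vector: the selected leaf labels.
#' @export
max_inclusive_subtree <- function(tree) {
  labels <- tree$tip.label
  ntip <- length(labels)
  if (ntip < 2L) stop("need >= 2 leaves")
  taxa <- leaf_taxon(labels)
  clades <- tree_clades(tree)
  rooted <- ape::is.rooted(tree)
  cands <- c(list(seq_len(ntip)), clades)
  if (!rooted) {
    all_leaves <- seq_len(ntip)
    cands <- c(cands, lapply(clades, function(cl)
      setdiff(all_leaves, cl)))
  }
  cands <- unique(cands)
  # clades of a candidate subtree: for rooted input, descendant clades
  # contained in it; for unrooted input, any bipartition side contained
  # in it (the subtree is rooted at its defining edge, so every side it
  # contains is one of its clades)
  inner_keys <- vapply(clades, paste, character(1), collapse = ",")
  if (!rooted) {
    all_leaves <- seq_len(ntip)
    inner_keys <- unique(c(inner_keys,
      vapply(clades, function(cl)
        paste(setdiff(all_leaves, cl), collapse = ","), character(1))))
  }
  valid_subtree <- function(S) {
    tax_in <- taxa[S]
    for (tx in unique(tax_in[duplicated(tax_in)])) {
      TS <- S[tax_in == tx]
      if (length(TS) == length(S)) next
      key <- paste(TS, collapse = ",")
      if (!key %in% inner_keys) return(FALSE)
    }
    TRUE
  }
  best <- NULL
  for (S in cands) {
    if (length(S) < 1L || !valid_subtree(S)) next
    cand <- list(S = S, ntaxa = length(unique(taxa[S])), nseq = length(S),
                 key = paste(sort(labels[S]), collapse = "\r"))
    if (is.null(best) ||
        cand$ntaxa > best$ntaxa ||
        (cand$ntaxa == best$ntaxa && cand$nseq > best$nseq) ||
        (cand$ntaxa == best$ntaxa && cand$nseq == best$nseq &&
         cand$key < best$key))
      best <- cand
  }
  if (is.null(best)) stop("no valid subtree found")   # nocov
  sort(labels[best$S])
}

#' Consensus of same-taxon in-paralog sequences
#'
#' Aligned inputs (equal length) are combined column-wise by majority
#' rule; ties yield `X` (protein) / `N` (nucleotide).  Unaligned inputs
#' are first anchored onto the longest member by Smith-Waterman local
#' alignment: each other sequence's residues are placed at the longest
#' member's coordinates via the alignment traceback, and the consensus is
#' taken over those coordinates.  A single input is returned unchanged.
#'
#' @param seqs character vector of sequences from one taxon.
#' @param type `"protein"` (default) or `"nucleotide"` (tie character).
#' @param submat substitution matrix for the anchoring alignment
#'   (required only for unaligned input).
#' @return single consensus sequence.
#' @export
consensus_inparalogs <- function(seqs, type = c("protein", "nucleotide"),
                                 submat = NULL) {
  type <- match.arg(type)
  if (!length(seqs)) stop("empty input")
  if (length(seqs) == 1L) return(unname(seqs[1L]))
  tiechar <- if (type == "protein") "X" else "N"
  if (length(unique(nchar(seqs))) > 1L) {
    if (is.null(submat))
      stop("unaligned in-paralogs require `submat` for anchoring")
    anchor <- seqs[[which.max(nchar(seqs))]]
    W <- nchar(anchor)
    placed <- matrix(NA_character_, length(seqs), W)
    placed[1L, ] <- strsplit(anchor, "")[[1]]
    others <- setdiff(seq_along(seqs), which.max(nchar(seqs)))
    for (k in seq_along(others)) {
      aln <- smith_waterman(anchor, seqs[[others[k]]], submat)
      ac <- strsplit(aln$a_aln, "")[[1]]
      bc <- strsplit(aln$b_aln, "")[[1]]
      pos <- aln$a_range[1L]          # 0-based position in anchor
      row <- k + 1L
      for (ci in seq_along(ac)) {
        if (ac[ci] != "-") {
          pos <- pos + 1L
          if (bc[ci] != "-") placed[row, pos] <- bc[ci]
        }
      }
    }
    m <- placed
  } else {
    m <- aln_matrix(seqs)
  }
  cons <- vapply(seq_len(ncol(m)), function(col) {
    res <- m[, col]
    res <- res[!is.na(res) & !(res %in% GAP_CHARS)]
    if (!length(res)) return("-")
    tab <- table(res)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1L) tiechar else winners
  }, character(1))
  paste(cons, collapse = "")
}

#' Taxon-occupancy filter over pruned groups
#'
#' Keeps groups in which at least `min_fraction` of the run's taxa remain
#' (boundary inclusive: 27 of 36 taxa = 75.0% is retained).
#'
#' @param groups list of [prune_group()] results.
#' @param total_taxa the run's taxon-set size.
#' @param min_fraction default 0.75.
#' @return filtered list.
#' @export
occupancy_filter <- function(groups, total_taxa, min_fraction = 0.75) {
  if (total_taxa < 1) stop("`total_taxa` must be >= 1")
  Filter(function(g) {
    n <- length(g$seqs)
    n / total_taxa >= min_fraction
  }, groups)
}

#' Prune a gene tree and its sequences to a one-per-taxon group
#'
#' Composition of [collapse_low_support()], [max_inclusive_subtree()] and
#' per-taxon [consensus_inparalogs()].  The result records which leaves
#' were pruned and whether the group showed evidence of out-paralogs
#' (i.e. selection dropped at least one leaf).
#'
#' @param tree `phylo` gene tree, leaves `taxon@seq_id`.
#' @param sequences named character vector (names = leaf labels).
#' @param support_cutoff collapse threshold (default 0 = no collapse).
#' @param type sequence type for consensus ties.
#' @param submat matrix for anchoring unaligned in-paralogs.
#' @return `ppy_pruned_group`: `seqs` (one per taxon, named by taxon),
#'   `pruned` (dropped leaf labels), `collapsed` (per-taxon in-paralog
#'   leaves merged), `outparalogs` flag.
#' @export
prune_group <- function(tree, sequences, support_cutoff = 0,
                        type = c("protein", "nucleotide"), submat = NULL) {
  type <- match.arg(type)
  missing_seqs <- setdiff(tree$tip.label, names(sequences))
  if (length(missing_seqs))
    stop("sequences missing for leaves: ",
         paste(missing_seqs, collapse = ", "))
  tree2 <- collapse_low_support(tree, support_cutoff)
  keep <- if (length(tree2$tip.label) >= 2L) max_inclusive_subtree(tree2)
          else tree2$tip.label
  pruned <- setdiff(tree$tip.label, keep)
  taxa <- leaf_taxon(keep)
  collapsed <- list()
  seqs <- character(0)
  for (tx in sort(unique(taxa))) {
    members <- keep[taxa == tx]
    if (length(members) > 1L) collapsed[[tx]] <- members
    seqs[tx] <- consensus_inparalogs(sequences[members], type = type,
                                     submat = submat)
  }
  structure(list(seqs = seqs, pruned = pruned, collapsed = collapsed,
                 outparalogs = length(pruned) > 0L),
            class = "ppy_pruned_group")
}
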