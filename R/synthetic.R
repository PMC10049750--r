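# Synthetic-data generators: protein clusters at a target identity, gene
# families with duplication/loss paralogs on a species tree, binary traits
# evolved under two-state Markov models, and exact-count missingness.
# Every generator takes an explicit seed and leaves the caller's RNG state
# untouched.

AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# run code under a given seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
    get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
        rm(".Random.seed", envir = .GlobalEnv)
    } else assign(".Random.seed", old, envir = .GlobalEnv)
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulate an aligned protein cluster at a target mean pairwise identity
#'
#' All members derive from one random ancestor; each copy is mutated
#' per site independently with probability `p`, replacement uniform over
#' the other residues.  `p` is calibrated so the expected identity of two
#' independently mutated copies equals `target_identity`: with alphabet
#' size `A`, identity `I(p) = (1-p)^2 + p^2/(A-1)`, inverted as
#' `p = (A-1)/A * (1 - sqrt(1 - A(1-I)/(A-1)))`.  Realized identity is
#' within sampling error of the target (about `sqrt(I(1-I)/length)` per
#' pair), so the calibration is accurate for lengths of a few hundred.
#'
#' @param n_seqs number of member sequences (>= 2).
#' @param length alignment length in residues (gap-free).
#' @param target_identity target mean pairwise identity in (0, 1];
#'   must be at least `1/A` (0.05 for the 20-letter alphabet).
#' @param seed integer seed; results are deterministic given the seed.
#' @param id cluster identifier.
#' @param alphabet residue alphabet (default the 20 canonical amino acids).
#' @return a [new_cluster()] with members `tax1 ... taxN`.
#' @export
simulate_cluster <- function(n_seqs, length, target_identity, seed,
                             id = "sim", alphabet = AA_ALPHABET) {
  if (n_seqs < 2) stop("`n_seqs` must be >= 2")
  if (length < 1) stop("`length` must be >= 1")
  A <- base::length(alphabet)
  if (target_identity <= 0 || target_identity > 1)
    stop("`target_identity` must be in (0, 1]")
  if (target_identity < 1 / A)
    stop("`target_identity` below the alphabet floor 1/", A)
  p <- (A - 1) / A * (1 - sqrt(max(0, 1 - A * (1 - target_identity) / (A - 1))))
  with_seed(seed, {
    anc_idx <- sample.int(A, length, replace = TRUE)
    # all randomness drawn up front: per-site mutation uniforms and a
    # replacement offset in 1..(A-1); mutation is then a threshold on the
    # fixed uniforms, so realized identity is monotone in the target at a
    # fixed seed
    u <- matrix(stats::runif(n_seqs * length), n_seqs, length)
    off <- matrix(sample.int(A - 1L, n_seqs * length, replace = TRUE),
                  n_seqs, length)
    seqs <- vapply(seq_len(n_seqs), function(i) {
      idx <- anc_idx
      hit <- u[i, ] < p
      idx[hit] <- ((anc_idx[hit] - 1L + off[i, hit]) %% A) + 1L
      paste(alphabet[idx], collapse = "")
    }, character(1))
    new_cluster(id, taxon = paste0("tax", seq_len(n_seqs)),
                seq_id = paste0(id, "_", seq_len(n_seqs)), seqs = seqs)
  })
}

#' Simulate a gene family by duplication and loss along a species tree
#'
#' A single ancestral gene enters the root.  Along every species-tree
#' branch each gene lineage independently waits an exponential time with
#' rate `dup_rate + loss_rate`; a duplication splits the lineage into two
#' copies that evolve independently from the event point, a loss prunes
#' the lineage (and so the whole subtree below it).  Sequences evolve by
#' per-site substitution with rate `subs_rate` per unit branch length.
#' With both rates zero the gene tree is label-isomorphic to the species
#' tree with one copy per taxon.
#'
#' @param species_tree rooted `phylo` with branch lengths and unique tip
#'   labels.
#' @param dup_rate,loss_rate events per unit branch length, `>= 0`.
#' @param seed integer seed.
#' @param seq_length ancestral protein length (default 200).
#' @param subs_rate substitutions per site per unit branch length
#'   (default 0.3).
#' @return `ppy_family`: `gene_tree` (phylo with leaves `taxon@copyN`, or
#'   `NULL` if the family went extinct), `seqs` (named by leaf), and
#'   `events` log (`event`, `species_node`, `time`).
#' @export
simulate_gene_family <- function(species_tree, dup_rate, loss_rate, seed,
                                 seq_length = 200, subs_rate = 0.3) {
  if (!inherits(species_tree, "phylo")) stop("`species_tree` must be a phylo")
  if (is.null(species_tree$edge.length)) stop("species tree needs branch lengths")
  if (dup_rate < 0 || loss_rate < 0) stop("rates must be >= 0")
  env <- new.env()
  with_seed(seed, {
    env$copies <- integer(0)      # per-taxon copy counters
    env$seqs <- list()
    env$events <- list()
    tree <- species_tree
    ntip <- length(tree$tip.label)
    kids <- vector("list", ntip + tree$Nnode)
    for (i in seq_len(nrow(tree$edge)))
      kids[[tree$edge[i, 1L]]] <- c(kids[[tree$edge[i, 1L]]], i)

    mutate <- function(seq, t) {
      if (t <= 0 || subs_rate <= 0) return(seq)
      p <- 1 - exp(-subs_rate * t)
      hit <- stats::runif(length(seq)) < p
      if (any(hit))
        seq[hit] <- vapply(seq[hit], function(r)
          sample(setdiff(AA_ALPHABET, r), 1L), character(1))
      seq
    }
    log_event <- function(event, node, time)
      env$events[[length(env$events) + 1L]] <-
        data.frame(event = event, species_node = node_name(tree, node),
                   time = time, stringsAsFactors = FALSE)

    # fragments are list(text = newick without top length, toplen)
    at_node <- function(seq, node) {
      if (node <= ntip) {
        taxon <- tree$tip.label[node]
        n <- (env$copies[taxon] %||% 0L) + 1L
        env$copies[taxon] <- n
        label <- paste0(taxon, "@copy", n)
        env$seqs[[label]] <- paste(seq, collapse = "")
        return(list(text = label, toplen = 0))
      }
      frags <- list()
      for (ei in kids[[node]]) {
        f <- evolve(seq, tree$edge.length[ei], tree$edge[ei, 2L])
        if (!is.null(f)) frags[[length(frags) + 1L]] <- f
      }
      join_frags(frags)
    }
    evolve <- function(seq, t_remaining, dest) {
      total <- dup_rate + loss_rate
      repeat {
        tau <- if (total > 0) stats::rexp(1L, total) else Inf
        if (tau >= t_remaining) {
          f <- at_node(mutate(seq, t_remaining), dest)
          if (is.null(f)) return(NULL)
          f$toplen <- f$toplen + t_remaining
          return(f)
        }
        seq <- mutate(seq, tau)
        if (stats::runif(1L) < dup_rate / total) {
          log_event("duplication", dest, tau)
          l <- evolve(seq, t_remaining - tau, dest)
          r <- evolve(seq, t_remaining - tau, dest)
          f <- join_frags(Filter(Negate(is.null), list(l, r)))
          if (is.null(f)) return(NULL)
          f$toplen <- f$toplen + tau
          return(f)
        }
        log_event("loss", dest, tau)
        return(NULL)
      }
    }

    root <- ntip + 1L
    anc <- sample(AA_ALPHABET, seq_length, replace = TRUE)
    frag <- at_node(anc, root)
    events <- if (length(env$events)) do.call(rbind, env$events)
              else data.frame(event = character(0), species_node = character(0),
                              time = numeric(0), stringsAsFactors = FALSE)
    gene_tree <- NULL
    if (!is.null(frag)) {
      txt <- if (grepl("^\\(", frag$text)) paste0(frag$text, ";")
             else paste0("(", frag$text, ":", format(frag$toplen, digits = 12),
                         ");")    # single survivor: keep a valid topology
      gene_tree <- ape::read.tree(text = txt)
    }
    structure(list(gene_tree = gene_tree,
                   seqs = unlist(env$seqs),
                   events = events, seed = seed),
              class = "ppy_family")
  })
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

join_frags <- function(frags) {
  if (!length(frags)) return(NULL)
  if (length(frags) == 1L) return(frags[[1L]])
  inner <- vapply(frags, function(f)
    paste0(f$text, ":", format(f$toplen, digits = 12)), character(1))
  list(text = paste0("(", paste(inner, collapse = ","), ")"), toplen = 0)
}

node_name <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) tree$tip.label[node] else paste0("node", node)
}

#' Simulate a binary trait on a tree under a two-state Markov model
#'
#' States evolve by the continuous-time chain of [transition_matrix()]
#' along each branch, from the root towards the tips.  Both tip and
#' internal-node states are recorded (ground truth for reconstruction
#' benchmarks).
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param model a [rate_model()].
#' @param root_state `0`, `1`, or a length-2 prior to draw from
#'   (default equal prior).
#' @param seed integer seed.
#' @return `ppy_traitsim`: `tip_states` (named 0/1 integer vector),
#'   `node_states` (named by node number), `model`, `seed`.
#' @export
simulate_binary_trait <- function(tree, model, root_state = c(0.5, 0.5), seed) {
  stopifnot(inherits(model, "ppy_rate_model"))
  if (!inherits(tree, "phylo")) stop("`tree` must be a phylo")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  with_seed(seed, {
    ntip <- length(tree$tip.label)
    nn <- ntip + tree$Nnode
    root <- ntip + 1L
    st <- integer(nn)
    st[root] <- if (length(root_state) == 2L)
      sample(0:1, 1L, prob = root_state) else as.integer(root_state)
    edge <- tree$edge
    ord <- rev(seq_len(nrow(edge)))
    po <- ape::reorder.phylo(tree, "postorder")
    for (i in rev(seq_len(nrow(po$edge)))) {     # preorder
      p <- po$edge[i, 1L]; ch <- po$edge[i, 2L]
      P <- mk_pmat(model$q01, model$q10, po$edge.length[i])
      st[ch] <- sample(0:1, 1L, prob = P[st[p] + 1L, ])
    }
    tip_states <- stats::setNames(st[seq_len(ntip)], tree$tip.label)
    node_states <- stats::setNames(st[(ntip + 1L):nn], (ntip + 1L):nn)
    structure(list(tip_states = tip_states, node_states = node_states,
                   model = model, seed = seed),
              class = "ppy_traitsim")
  })
}

#' Recode an exact fraction of tips as unknown
#'
#' Exactly `round(fraction_unknown * n)` tips, sampled without
#' replacement, are recoded `NA` (unknown).  The study-scale default
#' corresponds to 11 unknown of 36 tips.
#'
#' @param traits named vector of tip states.
#' @param fraction_unknown fraction in `[0, 1]`.
#' @param seed integer seed.
#' @return the vector with the selected tips set to `NA`.
#' @export
apply_missingness <- function(traits, fraction_unknown, seed) {
  if (fraction_unknown < 0 || fraction_unknown > 1)
    stop("`fraction_unknown` must be in [0, 1]")
  n <- length(traits)
  k <- round(fraction_unknown * n)
  if (k == 0) return(traits)
  with_seed(seed, {
    drop <- sample(seq_len(n), k)
    traits[drop] <- NA
    traits
  })
}
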