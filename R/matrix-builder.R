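# Clade-specific BLOSUM-style log-odds substitution matrix built from
# conserved, gap-free blocks of curated similarity clusters, plus the
# cluster-set curation used to pick a core-orthologue reference taxon.

GAP_CHARS <- c("-", ".")

#' Construct an aligned protein cluster
#'
#' @param id cluster identifier.
#' @param taxon,seq_id character vectors, one entry per member.
#' @param seqs aligned member sequences (equal length; gaps `-`).
#' @return object of class `ppy_cluster`.
#' @export
new_cluster <- function(id, taxon, seq_id, seqs) {
  if (length(seqs) < 1L) stop("cluster needs >= 1 member")
  if (length(unique(nchar(seqs))) != 1L)
    stop("member sequences must be aligned (equal length)")
  stopifnot(length(taxon) == length(seqs), length(seq_id) == length(seqs))
  structure(list(id = id, taxon = as.character(taxon),
                 seq_id = as.character(seq_id),
                 seqs = toupper(as.character(seqs)),
                 width = nchar(seqs[1L])),
            class = "ppy_cluster")
}

#' @export
print.ppy_cluster <- function(x, ...) {
  cat(sprintf("Cluster %s: %d sequences x %d columns\n",
              x$id, length(x$seqs), x$width))
  invisible(x)
}

# character matrix view of an alignment (rows = sequences)
aln_matrix <- function(seqs) {
  do.call(rbind, strsplit(seqs, ""))
}

#' Mean pairwise percent identity of a cluster
#'
#' Mean over all unordered member pairs of identical aligned positions
#' divided by positions where both members are non-gap (gapped positions
#' are ignored, the standard convention).
#'
#' @param cluster a [new_cluster()] with at least two members.
#' @return fraction in `[0, 1]`.
#' @export
percent_identity <- function(cluster) {
  n <- length(cluster$seqs)
  if (n < 2L) stop("percent identity undefined for singleton clusters")
  m <- aln_matrix(cluster$seqs)
  gap <- matrix(m %in% GAP_CHARS, nrow(m), ncol(m))
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    use <- !gap[i, ] & !gap[j, ]
    if (!any(use)) next                # fully gap-disjoint pair contributes 0
    tot <- tot + sum(m[i, use] == m[j, use]) / sum(use)
  }
  tot / (n * (n - 1L) / 2L)
}

#' Curate a cluster set for matrix building
#'
#' Removes singleton clusters first, then clusters whose mean pairwise
#' identity is strictly below `min_identity` (a cluster at exactly the
#' threshold is retained).  Input order is preserved.
#'
#' @param clusters list of clusters.
#' @param min_identity identity threshold, default 0.70.
#' @param drop_singletons remove single-member clusters first (default TRUE).
#' @return filtered list.
#' @export
curate_clusters <- function(clusters, min_identity = 0.70,
                            drop_singletons = TRUE) {
  if (drop_singletons)
    clusters <- Filter(function(cl) length(cl$seqs) >= 2L, clusters)
  Filter(function(cl) percent_identity(cl) >= min_identity, clusters)
}

#' Pick the reference taxon for a core-orthologue set
#'
#' The taxon present in the greatest number of clusters wins; ties are
#' broken by a caller-supplied priority (relatedness) ranking, then
#' lexicographically.
#'
#' @param clusters non-empty list of clusters.
#' @param priority optional ordered character vector of taxa (earlier =
#'   preferred on ties).
#' @return list with `taxon` and `count` (clusters containing it).
#' @export
select_reference_taxon <- function(clusters, priority = NULL) {
  if (!length(clusters)) stop("empty cluster list")
  taxa <- unlist(lapply(clusters, function(cl) unique(cl$taxon)))
  counts <- table(taxa)
  best <- max(counts)
  cand <- sort(names(counts)[counts == best])     # lexicographic fallback
  if (!is.null(priority)) {
    ranked <- intersect(priority, cand)
    if (length(ranked)) cand <- c(ranked, setdiff(cand, ranked))
  }
  list(taxon = cand[1L], count = as.integer(best))
}

#' Extract conserved gap-free blocks from a cluster alignment
#'
#' A block is a maximal run of columns with no gap character in any
#' member; optionally each column must also have a majority-residue
#' fraction at least `min_column_identity`.  Runs shorter than
#' `min_width` are discarded.  Column ranges are 0-based, half-open.
#'
#' @param cluster a [new_cluster()].
#' @param min_width minimum block width in columns (default 1).
#' @param min_column_identity per-column majority fraction required
#'   (default 0 = gap-free only).
#' @return list of `ppy_block` objects ordered by start column.
#' @export
extract_blocks <- function(cluster, min_width = 1L, min_column_identity = 0) {
  m <- aln_matrix(cluster$seqs)
  ok <- apply(m, 2L, function(col) {
    if (any(col %in% GAP_CHARS)) return(FALSE)
    if (min_column_identity > 0 &&
        max(table(col)) / length(col) < min_column_identity) return(FALSE)
    TRUE
  })
  blocks <- list()
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$values)) {
    if (!r$values[k] || r$lengths[k] < min_width) next
    cols <- starts[k]:ends[k]
    blocks[[length(blocks) + 1L]] <- structure(
      list(cluster_id = cluster$id,
           start = starts[k] - 1L, end = ends[k],   # 0-based half-open
           seqs = apply(m[, cols, drop = FALSE], 1L, paste, collapse = ""),
           seq_id = cluster$seq_id),
      class = "ppy_block")
  }
  blocks
}

#' Henikoff-style sequence weights within a block
#'
#' Sequences whose pairwise identity within the block reaches
#' `clustering_threshold` are grouped by single linkage; each sequence is
#' weighted `1 / group size`, so each group contributes one unit of
#' evidence to pair counting.
#'
#' @param block a block from [extract_blocks()].
#' @param clustering_threshold identity threshold, default 0.90 (a value
#'   above 1 disables grouping: all weights 1).
#' @return numeric weight per sequence.
#' @export
weight_sequences <- function(block, clustering_threshold = 0.90) {
  seqs <- block$seqs
  n <- length(seqs)
  if (!n) stop("empty block")
  if (n == 1L) return(1)
  m <- aln_matrix(seqs)
  grp <- seq_len(n)                      # union-find by relabeling
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    pid <- mean(m[i, ] == m[j, ])
    if (pid >= clustering_threshold) {
      old <- grp[j]
      grp[grp == old] <- grp[i]
    }
  }
  sizes <- table(grp)
  as.numeric(1 / sizes[as.character(grp)])
}

#' Accumulate weighted residue-pair counts over blocks
#'
#' Within each column every unordered sequence pair contributes the
#' product of the two sequence weights to the count of its residue pair;
#' counts are accumulated over all columns of all blocks into a symmetric
#' matrix.
#'
#' @param blocks list of blocks.
#' @param weights list of per-sequence weight vectors, parallel to
#'   `blocks` (default: [weight_sequences()] with its default threshold).
#' @param alphabet residue alphabet.
#' @param on_bad_residue `"skip"` (default; skipped letters are reported
#'   in attribute `"skipped"`) or `"error"`.
#' @return `ppy_paircounts`: symmetric counts matrix and `total`.
#' @export
count_pairs <- function(blocks, weights = NULL, alphabet = AA_ALPHABET,
                        on_bad_residue = c("skip", "error")) {
  on_bad_residue <- match.arg(on_bad_residue)
  if (is.null(weights)) weights <- lapply(blocks, weight_sequences)
  A <- length(alphabet)
  counts <- matrix(0, A, A, dimnames = list(alphabet, alphabet))
  skipped <- character(0)
  for (b in seq_along(blocks)) {
    m <- aln_matrix(blocks[[b]]$seqs)
    w <- weights[[b]]
    if (length(w) != nrow(m)) stop("weights do not match block sequences")
    for (col in seq_len(ncol(m))) {
      res <- m[, col]
      keep <- res %in% alphabet
      if (!all(keep)) {
        if (on_bad_residue == "error")
          stop("residue outside alphabet: ", paste(res[!keep], collapse = ","))
        skipped <- union(skipped, res[!keep])
      }
      idx <- which(keep)
      if (length(idx) < 2L) next
      for (ii in seq_len(length(idx) - 1L)) for (jj in (ii + 1L):length(idx)) {
        a <- res[idx[ii]]; bb <- res[idx[jj]]
        wprod <- w[idx[ii]] * w[idx[jj]]
        if (a == bb) counts[a, bb] <- counts[a, bb] + wprod
        else {
          # full unordered count mirrored into both cells
          counts[a, bb] <- counts[a, bb] + wprod
          counts[bb, a] <- counts[bb, a] + wprod
        }
      }
    }
  }
  total <- sum(counts[upper.tri(counts, diag = TRUE)])
  out <- structure(list(counts = counts, total = total, alphabet = alphabet),
                   class = "ppy_paircounts")
  attr(out, "skipped") <- skipped
  out
}

# round half away from zero, the convention of common matrix tooling
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Turn pair counts into an integer log-odds substitution matrix
#'
#' Observed pair frequencies `q_ij` are the (pseudocounted) unordered-pair
#' counts normalized by the total; background frequencies
#' `p_i = q_ii + sum_{j != i} q_ij / 2`; expected frequencies
#' `e_ii = p_i^2`, `e_ij = 2 p_i p_j`; scores
#' `s_ij = round(scale * log2(q_ij / e_ij))` (rounding half away from
#' zero).  With `pseudocount = 0`, cells with `q_ij = 0` get the floor
#' score `round(scale * log2(eps))` with `eps = 1 / (2 * total)`, with a
#' warning.
#'
#' @param counts a [count_pairs()] result.
#' @param scale bits divisor; 2 = half-bit scores (default).
#' @param pseudocount count added to every unordered cell (default 0).
#' @return `ppy_submat`: integer `scores`, `scale`, background `bg`,
#'   `pseudocount`, `alphabet`.
#' @export
compute_log_odds <- function(counts, scale = 2, pseudocount = 0) {
  stopifnot(inherits(counts, "ppy_paircounts"))
  if (counts$total <= 0) stop("no counts")
  A <- length(counts$alphabet)
  ncell <- A * (A + 1) / 2
  cmat <- counts$counts + pseudocount     # symmetric storage
  total <- counts$total + pseudocount * ncell
  q <- cmat / total
  p <- diag(q) + (rowSums(q) - diag(q)) / 2
  e <- 2 * outer(p, p)
  diag(e) <- p^2
  s <- matrix(NA_real_, A, A, dimnames = dimnames(q))
  zero <- q == 0
  if (any(zero & e > 0)) {
    warning("zero-count cells floored at round(scale * log2(1/(2 total)))")
    floorval <- round_half_away(scale * log2(1 / (2 * counts$total)))
  }
  for (i in seq_len(A)) for (j in seq_len(A)) {
    s[i, j] <- if (e[i, j] == 0) 0
               else if (q[i, j] == 0) floorval
               else round_half_away(scale * log2(q[i, j] / e[i, j]))
  }
  structure(list(scores = s, scale = scale, bg = p,
                 pseudocount = pseudocount, alphabet = counts$alphabet),
            class = "ppy_submat")
}

#' @export
print.ppy_submat <- function(x, ...) {
  cat(sprintf("Log-odds substitution matrix (%d letters, scale %s, pseudocount %s)\n",
              length(x$alphabet), format(x$scale), format(x$pseudocount)))
  print(x$scores)
  invisible(x)
}

#' Full matrix-building pipeline over curated clusters
#'
#' Composition of [extract_blocks()], [weight_sequences()],
#' [count_pairs()] and [compute_log_odds()].  The number of blocks and
#' the pair-count total are attached as attributes.
#'
#' @param clusters curated list of clusters (see [curate_clusters()]).
#' @param min_block_width,min_column_identity passed to [extract_blocks()].
#' @param clustering_threshold passed to [weight_sequences()].
#' @param scale,pseudocount passed to [compute_log_odds()].
#' @param alphabet residue alphabet.
#' @return a `ppy_submat` with attributes `n_blocks` and `total_pairs`.
#' @export
build_matrix_pipeline <- function(clusters, min_block_width = 1L,
                                  min_column_identity = 0,
                                  clustering_threshold = 0.90,
                                  scale = 2, pseudocount = 0,
                                  alphabet = AA_ALPHABET) {
  if (!length(clusters)) stop("no usable blocks: empty cluster list")
  blocks <- unlist(lapply(clusters, extract_blocks,
                          min_width = min_block_width,
                          min_column_identity = min_column_identity),
                   recursive = FALSE)
  if (!length(blocks)) stop("no usable blocks")
  weights <- lapply(blocks, weight_sequences,
                    clustering_threshold = clustering_threshold)
  pc <- count_pairs(blocks, weights, alphabet = alphabet)
  mat <- compute_log_odds(pc, scale = scale, pseudocount = pseudocount)
  attr(mat, "n_blocks") <- length(blocks)
  attr(mat, "total_pairs") <- pc$total
  mat
}

#' Write / read a scoring matrix in the standard text format
#'
#' Whitespace-delimited square matrix with a header row of residues and
#' one labelled row per residue, `#`-prefixed metadata lines, readable by
#' common alignment tools.
#'
#' @param mat a `ppy_submat`.
#' @param path output file.
#' @export
write_score_matrix <- function(mat, path) {
  stopifnot(inherits(mat, "ppy_submat"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# log-odds substitution matrix, scale 1/%s bits, pseudocount %s",
                     format(mat$scale), format(mat$pseudocount)), con)
  writeLines(paste(c(" ", mat$alphabet), collapse = "  "), con)
  for (a in mat$alphabet)
    writeLines(paste(c(a, format(mat$scores[a, ], width = 2)), collapse = " "),
               con)
}

#' @rdname write_score_matrix
#' @param path input file.
#' @export
read_score_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1L]), "\\s+")[[1]]
  rows <- lapply(lines[-1L], function(l) strsplit(trimws(l), "\\s+")[[1]])
  alphabet <- header
  s <- matrix(NA_real_, length(rows), length(alphabet),
              dimnames = list(vapply(rows, `[`, character(1), 1L), alphabet))
  for (r in rows) s[r[1L], ] <- as.numeric(r[-1L])
  if (!identical(rownames(s), colnames(s)))
    stop("malformed scoring matrix: row/column labels differ")
  structure(list(scores = s, scale = NA_real_, bg = NULL,
                 pseudocount = NA_real_, alphabet = alphabet),
            class = "ppy_submat")
}
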