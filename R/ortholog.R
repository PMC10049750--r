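# Orthology assignment: six-frame translation of transcript fragments, a
# position-specific score-matrix (PSSM) profile scorer with empirical
# Gumbel E-values, E-value + top-quartile hit filtering, Smith-Waterman
# local alignment under a custom substitution matrix, and the reciprocal
# best-hit confirmation against the reference taxon.
#
# The profile scorer is a documented stand-in for profile-HMM search: an
# ungapped PSSM whose column scores are averages of substitution-matrix
# scores to the column residues.  Externally produced hit tables (HMMER
# per-domain tabular dialect) can replace it via `hits` in
# assign_orthologs(), with identical downstream filtering.

#' Translate a nucleotide sequence in all six reading frames
#'
#' Three forward frames and three frames of the reverse complement; stop
#' codons are rendered `*`, ambiguous codons `X`, and trailing partial
#' codons are dropped.
#'
#' @param nt nucleotide sequence over `A,C,G,T,N` (case-insensitive).
#' @return named character vector `F1,F2,F3,R1,R2,R3`.
#' @export
translate_six_frames <- function(nt) {
  nt <- toupper(nt)
  if (!nzchar(nt))
    return(stats::setNames(rep("", 6L), c("F1", "F2", "F3", "R1", "R2", "R3")))
  fwd <- Biostrings::DNAString(nt)
  rev <- Biostrings::reverseComplement(fwd)
  tr1 <- function(s, off) {
    n <- length(s) - off
    if (n < 3L) return("")
    sub <- Biostrings::subseq(s, off + 1L, off + (n %/% 3L) * 3L)
    as.character(Biostrings::translate(sub, if.fuzzy.codon = "solve"))
  }
  out <- c(tr1(fwd, 0L), tr1(fwd, 1L), tr1(fwd, 2L),
           tr1(rev, 0L), tr1(rev, 1L), tr1(rev, 2L))
  stats::setNames(out, c("F1", "F2", "F3", "R1", "R2", "R3"))
}

#' Build a PSSM profile model from a cluster alignment
#'
#' The score of residue `a` at column `c` is the mean substitution-matrix
#' score of `a` against the non-gap residues observed in column `c`
#' (all-gap columns score 0 for every residue).  The profile's reference
#' sequence is the member from `ref_taxon` (ungapped).
#'
#' @param cluster a [new_cluster()] (the orthologous-group alignment).
#' @param submat a `ppy_submat`.
#' @param ref_taxon reference taxon whose member anchors the group.
#' @return `ppy_profile`: `group_id`, `pssm` (width x alphabet),
#'   `consensus`, `ref_id`, `ref_seq`, `alphabet`.
#' @export
build_profile <- function(cluster, submat, ref_taxon) {
  stopifnot(inherits(cluster, "ppy_cluster"), inherits(submat, "ppy_submat"))
  ri <- which(cluster$taxon == ref_taxon)
  if (!length(ri))
    stop("reference taxon ", ref_taxon, " absent from cluster ", cluster$id)
  ri <- ri[1L]
  m <- aln_matrix(cluster$seqs)
  A <- submat$alphabet
  pssm <- matrix(0, ncol(m), length(A), dimnames = list(NULL, A))
  consensus <- character(ncol(m))
  for (col in seq_len(ncol(m))) {
    res <- m[, col]
    res <- res[res %in% A]
    if (!length(res)) { consensus[col] <- "X"; next }
    pssm[col, ] <- rowMeans(submat$scores[A, res, drop = FALSE])
    tab <- table(res)
    consensus[col] <- sort(names(tab)[tab == max(tab)])[1L]
  }
  structure(list(group_id = cluster$id, pssm = pssm,
                 consensus = paste(consensus, collapse = ""),
                 ref_id = cluster$seq_id[ri],
                 ref_seq = gsub("[-.]", "", cluster$seqs[ri]),
                 alphabet = A),
            class = "ppy_profile")
}

# best ungapped placement of a residue vector against a PSSM; returns
# score and the 0-based half-open query region used
pssm_best_placement <- function(pssm, qres) {
  W <- nrow(pssm); m <- length(qres)
  A <- colnames(pssm)
  qi <- match(qres, A)                     # NA = unscored residue
  best <- -Inf; bstart <- 0L; blen <- 0L
  if (m >= W) {
    for (d in 0:(m - W)) {
      idx <- qi[(d + 1L):(d + W)]
      ok <- !is.na(idx)
      s <- sum(pssm[cbind(which(ok), idx[ok])])
      if (s > best) { best <- s; bstart <- d; blen <- W }
    }
  } else {
    for (d in 0:(W - m)) {
      ok <- !is.na(qi)
      s <- sum(pssm[cbind(which(ok) + d, qi[ok])])
      if (s > best) { best <- s; bstart <- 0L; blen <- m }
    }
  }
  list(score = best, start = bstart, end = bstart + blen)
}

# Gumbel tail fit by method of moments over an empirical null
gumbel_evalue <- function(null_scores, s) {
  mu_ <- mean(null_scores); sd_ <- stats::sd(null_scores)
  if (!is.finite(sd_) || sd_ == 0)
    return(if (s > mu_) 0 else 1)
  beta <- sd_ * sqrt(6) / pi
  mu <- mu_ - 0.57721566 * beta
  z <- (s - mu) / beta
  # P(S >= s) under Gumbel; expected hits per comparison
  -expm1(-exp(-z))
}

#' Score a translated query against a profile
#'
#' Best ungapped sliding-window placement of the query against the PSSM.
#' The E-value is estimated from an empirical null of `n_shuffles` seeded
#' residue shuffles of the query, with a Gumbel tail fit (method of
#' moments).
#'
#' @param profile a [build_profile()] result.
#' @param query protein sequence.
#' @param query_id identifier recorded in the hit.
#' @param n_shuffles shuffles for the empirical null (default 200).
#' @param seed seed for the shuffles (default 1).
#' @param min_query_length queries shorter than this return `NULL`
#'   (default 10).
#' @return one-row hit data frame (`query`, `group`, `score`, `evalue`,
#'   `start`, `end`; region 0-based half-open) or `NULL`.
#' @export
score_query <- function(profile, query, query_id = "query",
                        n_shuffles = 200L, seed = 1L,
                        min_query_length = 10L) {
  stopifnot(inherits(profile, "ppy_profile"))
  if (!nrow(profile$pssm)) stop("empty profile")
  qres <- strsplit(toupper(query), "")[[1]]
  if (length(qres) < min_query_length) {
    message("query ", query_id, " shorter than ", min_query_length,
            " residues; skipped")
    return(NULL)
  }
  obs <- pssm_best_placement(profile$pssm, qres)
  null_scores <- with_seed(seed, vapply(seq_len(n_shuffles), function(i)
    pssm_best_placement(profile$pssm, sample(qres))$score, numeric(1)))
  data.frame(query = query_id, group = profile$group_id,
             score = obs$score,
             evalue = gumbel_evalue(null_scores, obs$score),
             start = obs$start, end = obs$end,
             stringsAsFactors = FALSE)
}

#' Filter a hit table by E-value and top-scoring quartile
#'
#' Per group: hits with `evalue > evalue_cutoff` are dropped; the
#' remainder are sorted by score (descending) and the top
#' `ceiling(n * quartile_fraction)` retained, with all hits tied at the
#' boundary score also kept.  Never empties a group that had at least one
#' passing hit.
#'
#' @param hits hit data frame (columns `query`, `group`, `score`,
#'   `evalue`, ...).
#' @param evalue_cutoff default `1e-5`.
#' @param quartile_fraction default 0.25.
#' @return filtered hit data frame.
#' @export
filter_hits <- function(hits, evalue_cutoff = 1e-5, quartile_fraction = 0.25) {
  if (is.null(hits) || !nrow(hits)) return(hits[0, , drop = FALSE])
  hits <- hits[hits$evalue <= evalue_cutoff, , drop = FALSE]
  out <- lapply(split(hits, hits$group), function(h) {
    h <- h[order(-h$score, h$query), , drop = FALSE]
    k <- ceiling(nrow(h) * quartile_fraction)
    if (k < 1L) return(h[0, , drop = FALSE])
    boundary <- h$score[k]
    h[h$score >= boundary, , drop = FALSE]
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Smith-Waterman local alignment with affine gaps
#'
#' Optimal local alignment under a substitution matrix with affine gap
#' penalties: a gap of length `L` costs `gap_open + (L - 1) * gap_extend`.
#' Traceback is deterministic with tie order diagonal > up (gap in `b`) >
#' left (gap in `a`); among equal-scoring end cells the smallest
#' `(i, j)` wins.  Residues absent from the matrix alphabet score 0.
#'
#' @param a,b protein sequences.
#' @param submat a `ppy_submat`.
#' @param gap_open,gap_extend positive penalties (defaults 11 and 1, the
#'   standard protein defaults).
#' @return list with `score`, aligned strings `a_aln`, `b_aln`, and
#'   0-based half-open ranges `a_range`, `b_range`.
#' @export
smith_waterman <- function(a, b, submat, gap_open = 11, gap_extend = 1) {
  stopifnot(inherits(submat, "ppy_submat"))
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be > 0")
  av <- strsplit(toupper(a), "")[[1]]
  bv <- strsplit(toupper(b), "")[[1]]
  n <- length(av); m <- length(bv)
  empty <- list(score = 0, a_aln = "", b_aln = "",
                a_range = c(0L, 0L), b_range = c(0L, 0L))
  if (!n || !m) return(empty)
  S <- matrix(0, length(submat$alphabet), length(submat$alphabet),
              dimnames = list(submat$alphabet, submat$alphabet))
  S[, ] <- submat$scores[submat$alphabet, submat$alphabet]
  ai <- match(av, submat$alphabet)
  bi <- match(bv, submat$alphabet)
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(-Inf, n + 1L, m + 1L)   # gap in a (left moves)
  F_ <- matrix(-Inf, n + 1L, m + 1L)  # gap in b (up moves)
  best <- 0; bi_ <- 0L; bj_ <- 0L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sc <- if (is.na(ai[i]) || is.na(bi[j])) 0 else S[ai[i], bi[j]]
      E[i + 1L, j + 1L] <- max(H[i + 1L, j] - gap_open,
                               E[i + 1L, j] - gap_extend)
      F_[i + 1L, j + 1L] <- max(H[i, j + 1L] - gap_open,
                                F_[i, j + 1L] - gap_extend)
      h <- max(0, H[i, j] + sc, F_[i + 1L, j + 1L], E[i + 1L, j + 1L])
      H[i + 1L, j + 1L] <- h
      if (h > best) { best <- h; bi_ <- i; bj_ <- j }
    }
  }
  if (best == 0) return(empty)
  # traceback from (bi_, bj_); tie order diagonal > up > left
  i <- bi_; j <- bj_
  a_aln <- character(0); b_aln <- character(0)
  state <- "H"
  repeat {
    if (state == "H") {
      if (H[i + 1L, j + 1L] == 0) break
      sc <- if (is.na(ai[i]) || is.na(bi[j])) 0 else S[ai[i], bi[j]]
      if (i >= 1L && j >= 1L && H[i + 1L, j + 1L] == H[i, j] + sc) {
        a_aln <- c(av[i], a_aln); b_aln <- c(bv[j], b_aln)
        i <- i - 1L; j <- j - 1L
      } else if (H[i + 1L, j + 1L] == F_[i + 1L, j + 1L]) {
        state <- "F"
      } else if (H[i + 1L, j + 1L] == E[i + 1L, j + 1L]) {
        state <- "E"
      } else stop("traceback failure")     # nocov
    } else if (state == "F") {             # up: gap in b, consume a
      a_aln <- c(av[i], a_aln); b_aln <- c("-", b_aln)
      from_h <- H[i, j + 1L] - gap_open
      from_f <- F_[i, j + 1L] - gap_extend
      state <- if (F_[i + 1L, j + 1L] == from_h) "H" else "F"
      i <- i - 1L
    } else {                               # left: gap in a, consume b
      a_aln <- c("-", a_aln); b_aln <- c(bv[j], b_aln)
      from_h <- H[i + 1L, j] - gap_open
      from_e <- E[i + 1L, j] - gap_extend
      state <- if (E[i + 1L, j + 1L] == from_h) "H" else "E"
      j <- j - 1L
    }
    if (i == 0L || j == 0L) break
  }
  list(score = best,
       a_aln = paste(a_aln, collapse = ""),
       b_aln = paste(b_aln, collapse = ""),
       a_range = c(i, bi_), b_range = c(j, bj_))
}

# E-value for a local-alignment score: empirical null from shuffles of `a`
sw_evalue <- function(a, b, submat, score, gap_open = 11, gap_extend = 1,
                      n_shuffles = 100L, seed = 1L) {
  av <- strsplit(toupper(a), "")[[1]]
  null_scores <- with_seed(seed, vapply(seq_len(n_shuffles), function(i)
    smith_waterman(paste(sample(av), collapse = ""), b, submat,
                   gap_open, gap_extend)$score, numeric(1)))
  gumbel_evalue(null_scores, score)
}

#' Reciprocal best-hit confirmation against the reference taxon
#'
#' A candidate is accepted iff (i) its best local-alignment hit in the
#' reference proteome is the group's reference sequence, (ii) the
#' reference sequence's best hit among the same taxon's candidate set is
#' the candidate, and (iii) both alignments meet the E-value cutoff
#' (empirical Gumbel null, as in [score_query()]).  Ties on score break
#' lexicographically by sequence id.
#'
#' @param candidate named length-1 character vector (name = sequence id).
#' @param profile the group's [build_profile()].
#' @param reference_proteome named character vector of reference-taxon
#'   proteins; must contain the group's reference sequence.
#' @param candidate_set named character vector: the run's candidates for
#'   this query's taxon (reverse search space).
#' @param submat substitution matrix.
#' @param evalue_cutoff default `1e-5`.
#' @param gap_open,gap_extend,n_shuffles,seed alignment and null options.
#' @return list with `accept` (logical), `reason`, and diagnostic scores.
#' @export
reciprocal_best_hit <- function(candidate, profile, reference_proteome,
                                candidate_set = candidate, submat,
                                evalue_cutoff = 1e-5,
                                gap_open = 11, gap_extend = 1,
                                n_shuffles = 100L, seed = 1L) {
  if (!length(reference_proteome)) stop("empty reference proteome")
  if (!profile$ref_id %in% names(reference_proteome))
    stop("reference proteome lacks the group's reference sequence ",
         profile$ref_id)
  cand_id <- names(candidate) %||% "candidate"
  cand_seq <- unname(candidate[1L])
  fwd <- vapply(reference_proteome, function(ref)
    smith_waterman(cand_seq, ref, submat, gap_open, gap_extend)$score,
    numeric(1))
  fwd_best <- sort(names(fwd)[fwd == max(fwd)])[1L]
  if (fwd_best != profile$ref_id)
    return(list(accept = FALSE, reason = "forward best-hit mismatch",
                forward_best = fwd_best, forward_scores = fwd))
  if (!cand_id %in% names(candidate_set))
    candidate_set <- c(candidate_set, stats::setNames(cand_seq, cand_id))
  ref_seq <- reference_proteome[[profile$ref_id]]
  rev <- vapply(candidate_set, function(s)
    smith_waterman(ref_seq, s, submat, gap_open, gap_extend)$score,
    numeric(1))
  rev_best <- sort(names(rev)[rev == max(rev)])[1L]
  if (rev_best != cand_id)
    return(list(accept = FALSE, reason = "reverse best-hit mismatch",
                reverse_best = rev_best, reverse_scores = rev))
  e_fwd <- sw_evalue(cand_seq, ref_seq, submat, fwd[[profile$ref_id]],
                     gap_open, gap_extend, n_shuffles, seed)
  e_rev <- sw_evalue(ref_seq, cand_seq, submat, rev[[cand_id]],
                     gap_open, gap_extend, n_shuffles, seed + 1L)
  if (e_fwd > evalue_cutoff || e_rev > evalue_cutoff)
    return(list(accept = FALSE, reason = "E-value above cutoff",
                evalue_forward = e_fwd, evalue_reverse = e_rev))
  list(accept = TRUE, reason = "reciprocal best hit",
       evalue_forward = e_fwd, evalue_reverse = e_rev,
       score_forward = fwd[[profile$ref_id]], score_reverse = rev[[cand_id]])
}

#' Read a HMMER per-domain tabular hit file
#'
#' Whitespace-delimited per-domain table with `#` comment lines, as
#' written by `hmmsearch --domtblout`.  Mapped columns: sequence name
#' (1), profile/group name (4), independent E-value (13), domain score
#' (14) and alignment coordinates (18, 19; converted to 0-based
#' half-open).
#'
#' @param path file path.
#' @return hit data frame compatible with [filter_hits()].
#' @export
read_hmmer_domtbl <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(query = character(0), group = character(0),
                      score = numeric(0), evalue = numeric(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- vapply(fields, length, integer(1)) < 19L
  if (any(bad)) stop("malformed per-domain table at line(s): ",
                     paste(which(bad), collapse = ", "))
  data.frame(
    query = vapply(fields, `[`, character(1), 1L),
    group = vapply(fields, `[`, character(1), 4L),
    score = as.numeric(vapply(fields, `[`, character(1), 14L)),
    evalue = as.numeric(vapply(fields, `[`, character(1), 13L)),
    start = as.integer(vapply(fields, `[`, character(1), 18L)) - 1L,
    end = as.integer(vapply(fields, `[`, character(1), 19L)),
    stringsAsFactors = FALSE)
}

#' Assign transcript-derived sequences to orthologous groups
#'
#' The two-step procedure: (1) six-frame translation (for nucleotide
#' input) and PSSM profile search with E-value cutoff and top-quartile
#' retention; (2) reciprocal-best-hit confirmation of each surviving hit
#' against the reference proteome under the custom matrix.  An externally
#' produced hit table (see [read_hmmer_domtbl()]) may replace the
#' built-in scorer; downstream filtering is identical.
#'
#' @param queries named list: taxon -> named character vector of
#'   sequences (nucleotide if `translate = TRUE`, protein otherwise).
#' @param profiles list of [build_profile()] results.
#' @param reference_proteome named character vector.
#' @param submat substitution matrix.
#' @param evalue_cutoff,quartile_fraction filter settings (defaults
#'   `1e-5`, 0.25).
#' @param translate six-frame-translate queries first (default TRUE).
#' @param hits optional external hit table; query ids must be
#'   `taxon|seq_id` (protein input assumed).
#' @param gap_open,gap_extend,n_shuffles,seed alignment/null settings.
#' @return list of `ppy_ortholog_group` objects (`id`, `members` data
#'   frame with `taxon`, `seq_id`, `sequence`, `score`, `evalue`).
#' @export
assign_orthologs <- function(queries, profiles, reference_proteome, submat,
                             evalue_cutoff = 1e-5, quartile_fraction = 0.25,
                             translate = TRUE, hits = NULL,
                             gap_open = 11, gap_extend = 1,
                             n_shuffles = 100L, seed = 1L) {
  if (!length(profiles)) stop("no profiles")
  if (quartile_fraction <= 0 || quartile_fraction > 1)
    stop("`quartile_fraction` must be in (0, 1]")
  prof_ids <- vapply(profiles, function(p) p$group_id, character(1))
  names(profiles) <- prof_ids
  # candidate protein store: query id -> protein sequence
  prot <- list()
  if (is.null(hits)) {
    rows <- list()
    for (taxon in names(queries)) {
      qs <- queries[[taxon]]
      for (qid in names(qs)) {
        frames <- if (translate) translate_six_frames(qs[[qid]])
                  else stats::setNames(qs[qid], "P")
        for (fr in names(frames)) {
          pep <- frames[[fr]]
          if (!nzchar(pep)) next
          full_id <- paste(taxon, qid, fr, sep = "|")
          prot[[full_id]] <- pep
          for (p in profiles) {
            h <- score_query(p, pep, query_id = full_id,
                             n_shuffles = max(200L, n_shuffles),
                             seed = seed)
            if (!is.null(h)) rows[[length(rows) + 1L]] <- h
          }
        }
      }
    }
    hits <- if (length(rows)) do.call(rbind, rows)
            else data.frame(query = character(0), group = character(0),
                            score = numeric(0), evalue = numeric(0),
                            start = integer(0), end = integer(0))
    # keep only each query's best frame per group
    if (nrow(hits)) {
      key <- paste(sub("\\|[^|]+$", "", hits$query), hits$group)
      hits <- do.call(rbind, lapply(split(hits, key), function(h)
        h[order(-h$score, h$query), ][1L, , drop = FALSE]))
      rownames(hits) <- NULL
    }
  } else {
    for (taxon in names(queries)) {
      qs <- queries[[taxon]]
      for (qid in names(qs))
        prot[[paste(taxon, qid, sep = "|")]] <- qs[[qid]]
    }
    missing_q <- setdiff(hits$query, names(prot))
    if (length(missing_q))
      stop("hit table references unknown queries: ",
           paste(utils::head(missing_q, 5L), collapse = ", "))
  }
  # each taxon's transcriptome is searched independently, so the E-value /
  # top-quartile filter applies per group within each taxon's hit set
  taxon_of <- sub("\\|.*$", "", hits$query)
  kept <- do.call(rbind, lapply(split(hits, taxon_of), filter_hits,
                                evalue_cutoff = evalue_cutoff,
                                quartile_fraction = quartile_fraction))
  if (is.null(kept))
    kept <- hits[0, , drop = FALSE]
  rownames(kept) <- NULL
  groups <- list()
  for (gid in prof_ids)
    groups[[gid]] <- list(id = gid,
                          members = data.frame(taxon = character(0),
                                               seq_id = character(0),
                                               sequence = character(0),
                                               score = numeric(0),
                                               evalue = numeric(0),
                                               stringsAsFactors = FALSE))
  audit <- list()
  if (nrow(kept)) for (r in seq_len(nrow(kept))) {
    gid <- kept$group[r]
    if (!gid %in% prof_ids) next
    full_id <- kept$query[r]
    taxon <- strsplit(full_id, "|", fixed = TRUE)[[1]][1L]
    pep <- prot[[full_id]]
    # candidate = the matched substring when region info is present
    if (!is.null(kept$start) && !is.na(kept$start[r]) &&
        kept$end[r] > kept$start[r])
      pep <- substr(pep, kept$start[r] + 1L, kept$end[r])
    same_taxon <- grepl(paste0("^", taxon, "\\|"), names(prot))
    cand_set <- vapply(prot[same_taxon], identity, character(1))
    rbh <- reciprocal_best_hit(stats::setNames(pep, full_id),
                               profiles[[gid]], reference_proteome,
                               cand_set, submat, evalue_cutoff,
                               gap_open, gap_extend, n_shuffles, seed)
    audit[[length(audit) + 1L]] <- data.frame(
      query = full_id, group = gid, accepted = rbh$accept,
      reason = rbh$reason, stringsAsFactors = FALSE)
    if (rbh$accept)
      groups[[gid]]$members <- rbind(
        groups[[gid]]$members,
        data.frame(taxon = taxon, seq_id = full_id, sequence = pep,
                   score = kept$score[r], evalue = kept$evalue[r],
                   stringsAsFactors = FALSE))
  }
  out <- lapply(groups, function(g) structure(g, class = "ppy_ortholog_group"))
  attr(out, "audit") <- if (length(audit)) do.call(rbind, audit)
                        else data.frame(query = character(0),
                                        group = character(0),
                                        accepted = logical(0),
                                        reason = character(0))
  out
}
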