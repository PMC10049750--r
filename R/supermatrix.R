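# Codon-aware supermatrix assembly: back-translation of protein
# alignments to codon alignments, concatenation with per-gene coordinate
# maps and codon-position partitions, the >=4-taxon codon-column filter,
# matrix statistics, and PHYLIP/FASTA/partition-file export.

IUPAC_AMBIG <- c("N", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' Back-translate a protein alignment to a codon alignment
#'
#' Each residue is replaced by its source codon in order; each protein
#' gap becomes `---`.  For every taxon the ungapped protein must equal
#' the translation of its CDS (after trimming one trailing stop codon),
#' otherwise an error names the taxon and the first mismatching residue.
#'
#' @param protein named character vector: aligned protein sequences
#'   (gaps `-`), one per taxon.
#' @param cds named character vector: unaligned coding sequences.
#' @param id group identifier.
#' @return `ppy_codon_aln`: named nucleotide alignment of width
#'   `3 * protein width`, with attributes `id` and `width`.
#' @export
backtranslate <- function(protein, cds, id = "group") {
  if (is.null(names(protein))) stop("`protein` must be named by taxon")
  width <- unique(nchar(protein))
  if (length(width) != 1L) stop("protein alignment rows differ in length")
  out <- character(length(protein))
  names(out) <- names(protein)
  for (tx in names(protein)) {
    prow <- strsplit(protein[[tx]], "")[[1]]
    ungapped <- prow[!(prow %in% GAP_CHARS)]
    if (!length(ungapped)) {                    # all-gap row
      out[tx] <- strrep("-", 3L * width)
      next
    }
    if (!tx %in% names(cds)) stop("no CDS for taxon ", tx)
    nt <- toupper(cds[[tx]])
    if (nchar(nt) == 3L * (length(ungapped) + 1L)) {
      # allow (and trim) one trailing stop codon
      last <- substr(nt, nchar(nt) - 2L, nchar(nt))
      if (last %in% c("TAA", "TAG", "TGA"))
        nt <- substr(nt, 1L, nchar(nt) - 3L)
    }
    if (nchar(nt) != 3L * length(ungapped))
      stop("CDS length for taxon ", tx, " is not 3x the ungapped protein")
    trans <- as.character(Biostrings::translate(
      Biostrings::DNAString(nt), if.fuzzy.codon = "solve"))
    tr <- strsplit(trans, "")[[1]]
    mism <- which(tr != ungapped & tr != "X" & ungapped != "X")
    if (length(mism))
      stop("translation mismatch for taxon ", tx, " at residue ",
           mism[1L], ": CDS gives ", tr[mism[1L]], ", protein has ",
           ungapped[mism[1L]])
    codons <- substring(nt, 3L * (seq_along(ungapped) - 1L) + 1L,
                        3L * seq_along(ungapped))
    row <- character(width)
    ci <- 0L
    for (k in seq_len(width)) {
      if (prow[k] %in% GAP_CHARS) row[k] <- "---"
      else { ci <- ci + 1L; row[k] <- codons[ci] }
    }
    out[tx] <- paste(row, collapse = "")
  }
  structure(out, id = id, width = 3L * width, class = "ppy_codon_aln")
}

#' Concatenate codon alignments into a supermatrix
#'
#' Groups are appended in stable sorted-group-id order; taxa missing from
#' a group are filled with gaps; the per-gene coordinate map (0-based,
#' half-open) is recorded.
#'
#' @param alignments list of [backtranslate()] results.
#' @param taxon_set character vector: the run's full taxon set.
#' @return `ppy_supermatrix`: `seqs` (named by taxon), `map` (data frame
#'   `group`, `start`, `end`).
#' @export
concatenate_codon_alignments <- function(alignments, taxon_set) {
  ids <- vapply(alignments, function(a) attr(a, "id"), character(1))
  if (anyDuplicated(ids)) stop("duplicate group ids")
  ord <- order(ids)
  alignments <- alignments[ord]; ids <- ids[ord]
  rows <- stats::setNames(rep("", length(taxon_set)), taxon_set)
  map <- data.frame(group = character(0), start = integer(0),
                    end = integer(0), stringsAsFactors = FALSE)
  pos <- 0L
  for (k in seq_along(alignments)) {
    a <- alignments[[k]]
    w <- attr(a, "width")
    extra <- setdiff(names(a), taxon_set)
    if (length(extra)) stop("alignment ", ids[k],
                            " has taxa outside the taxon set: ",
                            paste(extra, collapse = ", "))
    if (anyDuplicated(names(a)))
      stop("duplicate taxon within group ", ids[k])
    for (tx in taxon_set)
      rows[tx] <- paste0(rows[tx],
                         if (tx %in% names(a)) a[[tx]] else strrep("-", w))
    map <- rbind(map, data.frame(group = ids[k], start = pos,
                                 end = pos + w, stringsAsFactors = FALSE))
    pos <- pos + w
  }
  structure(list(seqs = rows, map = map), class = "ppy_supermatrix")
}

#' @export
print.ppy_supermatrix <- function(x, ...) {
  cat(sprintf("Supermatrix: %d taxa x %d sites, %d groups\n",
              length(x$seqs), nchar(x$seqs[1L]) %||% 0L, nrow(x$map)))
  invisible(x)
}

# taxon x site character matrix
sm_matrix <- function(sm) aln_matrix(sm$seqs)

#' Remove codon columns represented in too few taxa
#'
#' A taxon represents a codon when the triple contains at least one
#' unambiguous, non-gap nucleotide (configurable to require a complete
#' codon).  Codon triples represented in fewer than `min_taxa` taxa are
#' removed and the coordinate map re-indexed.
#'
#' @param sm a supermatrix.
#' @param min_taxa default 4.
#' @param representation `"any"` (default: >= 1 unambiguous nucleotide)
#'   or `"complete"` (all three unambiguous).
#' @return filtered supermatrix.
#' @export
filter_codon_columns <- function(sm, min_taxa = 4L,
                                 representation = c("any", "complete")) {
  representation <- match.arg(representation)
  m <- sm_matrix(sm)
  w <- ncol(m)
  if (w %% 3L != 0L) stop("matrix width not divisible by 3")
  informative <- !(m %in% c(GAP_CHARS, "?", IUPAC_AMBIG))
  dim(informative) <- dim(m)
  keep_codon <- logical(w %/% 3L)
  for (cd in seq_len(w %/% 3L)) {
    cols <- (3L * (cd - 1L) + 1L):(3L * cd)
    rep_by <- if (representation == "any")
      rowSums(informative[, cols, drop = FALSE]) >= 1L
    else rowSums(informative[, cols, drop = FALSE]) == 3L
    keep_codon[cd] <- sum(rep_by) >= min_taxa
  }
  keep_cols <- rep(keep_codon, each = 3L)
  new_seqs <- apply(m[, keep_cols, drop = FALSE], 1L, paste, collapse = "")
  new_seqs <- stats::setNames(new_seqs, names(sm$seqs))
  # re-index the gene map against removed columns
  removed_before <- cumsum(!keep_cols)
  remap <- function(x) {       # 0-based coordinate -> new coordinate
    if (x == 0L) return(0L)
    x - removed_before[x]
  }
  map <- sm$map
  new_map <- data.frame(group = character(0), start = integer(0),
                        end = integer(0), stringsAsFactors = FALSE)
  for (r in seq_len(nrow(map))) {
    s <- remap(map$start[r]); e <- remap(map$end[r])
    if (e > s)
      new_map <- rbind(new_map,
                       data.frame(group = map$group[r], start = as.integer(s),
                                  end = as.integer(e),
                                  stringsAsFactors = FALSE))
  }
  structure(list(seqs = new_seqs, map = new_map), class = "ppy_supermatrix")
}

#' Completeness and ambiguity statistics of a supermatrix
#'
#' Completeness is the percentage of non-gap cells (`-` and `?` count as
#' gaps); ambiguity is the percentage of `N`/IUPAC-ambiguous cells.
#' Per-taxon aligned bp (non-gap cells) and fraction of the full
#' alignment length are included.
#'
#' @param sm a supermatrix.
#' @return `ppy_matrix_stats`: `n_groups`, `n_sites`, `pct_complete`,
#'   `pct_ambiguous`, `per_taxon` data frame.
#' @export
matrix_stats <- function(sm) {
  m <- sm_matrix(sm)
  n_taxa <- nrow(m); n_sites <- ncol(m)
  gap <- m %in% c(GAP_CHARS, "?"); dim(gap) <- dim(m)
  ambig <- m %in% IUPAC_AMBIG; dim(ambig) <- dim(m)
  per_taxon_bp <- rowSums(!gap)
  structure(list(
    n_groups = nrow(sm$map), n_sites = n_sites, n_taxa = n_taxa,
    pct_complete = 100 * sum(!gap) / (n_taxa * n_sites),
    pct_ambiguous = 100 * sum(ambig) / (n_taxa * n_sites),
    per_taxon = data.frame(taxon = names(sm$seqs),
                           aligned_bp = per_taxon_bp,
                           fraction_full = per_taxon_bp / n_sites,
                           row.names = NULL, stringsAsFactors = FALSE)),
    class = "ppy_matrix_stats")
}

#' @export
print.ppy_matrix_stats <- function(x, ...) {
  cat(sprintf("%d groups, %d sites, %d taxa: %.1f%% complete, %.2f%% ambiguous\n",
              x$n_groups, x$n_sites, x$n_taxa, x$pct_complete,
              x$pct_ambiguous))
  invisible(x)
}

#' Export a supermatrix with codon-position partitions
#'
#' Writes relaxed PHYLIP and/or FASTA plus a partition file with three
#' codon-position partitions per gene range in the 1-based inclusive
#' `start-end\3` stride syntax of common ML tools.
#'
#' @param sm a supermatrix.
#' @param basename output path prefix; files `<basename>.phy`,
#'   `<basename>.fasta`, `<basename>.partitions` are produced.
#' @param formats subset of `c("phylip", "fasta")`.
#' @return invisibly, the named vector of files written.
#' @export
export_supermatrix <- function(sm, basename,
                               formats = c("phylip", "fasta")) {
  formats <- match.arg(formats, several.ok = TRUE)
  files <- character(0)
  n_sites <- nchar(sm$seqs[[1L]])
  if ("phylip" %in% formats) {
    f <- paste0(basename, ".phy")
    con <- file(f, "w")
    writeLines(sprintf("%d %d", length(sm$seqs), n_sites), con)
    for (tx in names(sm$seqs))
      writeLines(paste(tx, sm$seqs[[tx]]), con)
    close(con)
    files["phylip"] <- f
  }
  if ("fasta" %in% formats) {
    f <- paste0(basename, ".fasta")
    write_fasta(sm$seqs, f)
    files["fasta"] <- f
  }
  pf <- paste0(basename, ".partitions")
  con <- file(pf, "w")
  for (pos in 1:3) {
    ranges <- sprintf("%d-%d\\3", sm$map$start + pos, sm$map$end)
    writeLines(sprintf("DNA, pos%d = %s", pos,
                       paste(ranges, collapse = ", ")), con)
  }
  close(con)
  files["partitions"] <- pf
  invisible(files)
}

#' Read a relaxed PHYLIP alignment written by [export_supermatrix()]
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path)
  hdr <- as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1]])
  rows <- strsplit(trimws(lines[-1L][nzchar(trimws(lines[-1L]))]), "\\s+")
  seqs <- stats::setNames(vapply(rows, `[`, character(1), 2L),
                          vapply(rows, `[`, character(1), 1L))
  if (length(seqs) != hdr[1L] || any(nchar(seqs) != hdr[2L]))
    stop("malformed PHYLIP file: dimensions disagree with header")
  seqs
}
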