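# Shared readers/writers (FASTA, Newick in two support dialects, trait
# CSV) and the run configuration.

#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings that exchange named character vectors;
#' order and sequence content (including case) round-trip exactly.
#'
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- Biostrings::readBStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector.
#' @param width line-wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  if (length(seqs) && is.null(names(seqs))) stop("sequences must be named")
  x <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = max(1L, width))
  invisible(path)
}

#' Read and write Newick trees with support values
#'
#' Two support dialects are handled: support as internal-node labels
#' (`((A:1,B:2)90:0.5,C:1);`) and support as bracketed branch comments
#' (`((A:1,B:2):0.5[90],C:1);`); `"auto"` detects the comment dialect by
#' the presence of `[`.  The dialect found is recorded in attribute
#' `"support_dialect"`.  Duplicate tip labels are an error.
#'
#' @param path file path (or use `text`).
#' @param dialect `"auto"`, `"internal-label"` or `"branch-comment"`.
#' @param text optional literal Newick string instead of a file.
#' @return an `ape` `phylo` object.
#' @export
read_newick <- function(path = NULL, dialect = c("auto", "internal-label",
                                                 "branch-comment"),
                        text = NULL) {
  dialect <- match.arg(dialect)
  if (is.null(text)) {
    if (!file.exists(path)) stop("no such file: ", path)
    text <- paste(readLines(path), collapse = "")
  }
  used <- dialect
  if (dialect == "auto")
    used <- if (grepl("\\[", text)) "branch-comment" else "internal-label"
  if (used == "branch-comment")   # move [support] after a length up to the label slot
    text <- gsub("\\)([^,():\\[\\]]*):([0-9.eE+-]+)\\[([0-9.]+)\\]",
                 ")\\3:\\2", text, perl = TRUE)
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("unparseable Newick")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  attr(tree, "support_dialect") <- used
  tree
}

#' @rdname read_newick
#' @param tree a `phylo` object.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read and write trait tables as CSV
#'
#' Two columns: `tip`, `observation` (values among `indirect`, `direct`,
#' `both`, `unknown`, or `0`/`1`).
#'
#' @param path file path.
#' @return `ppy_traits` data frame.
#' @export
read_traits_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  names(df)[1:2] <- c("tip", "observation")
  class(df) <- c("ppy_traits", "data.frame")
  df
}

#' @rdname read_traits_csv
#' @param traits a trait table or named vector of states.
#' @export
write_traits_csv <- function(traits, path) {
  if (!is.data.frame(traits))
    traits <- data.frame(tip = names(traits),
                         observation = ifelse(is.na(traits), "unknown",
                                              as.character(traits)),
                         stringsAsFactors = FALSE)
  utils::write.csv(traits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration with the study thresholds as defaults
#'
#' All tunables in one validated list: cluster curation identity 0.70,
#' hit E-value cutoff 1e-5, top-scoring quartile 0.25, taxon occupancy
#' 0.75, codon-column minimum 4 taxa, significance threshold 2, support
#' collapse 0 (off).  Serializes round-trip to JSON.
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return `ppy_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    stages = c("simulate", "build-matrix", "assign", "prune",
               "supermatrix", "asr"),
    seed = 1L,
    # matrix building
    min_identity = 0.70, clustering_threshold = 0.90,
    scale = 2, pseudocount = 0, min_block_width = 1L,
    n_clusters = 8L, cluster_size = 4L, cluster_length = 120L,
    cluster_identity = 0.95,
    # orthology
    evalue_cutoff = 1e-5, quartile_fraction = 0.25,
    gap_open = 11, gap_extend = 1, n_shuffles = 30L,
    # family simulation
    n_taxa_seq = 6L, n_groups = 5L, dup_rate = 0.1, loss_rate = 0.05,
    seq_length = 60L, subs_rate = 0.2,
    # pruning / supermatrix
    support_cutoff = 0, min_occupancy = 0.75, min_col_taxa = 4L,
    # ancestral state reconstruction (study scale: 36 taxa, 11 unknown)
    n_taxa_trait = 36L, trait_q = 0.1, fraction_unknown = 11 / 36,
    sig_threshold = 2, root_prior = c(0.5, 0.5),
    out_dir = NULL)
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(dots)] <- dots
  validate_config(cfg)
  structure(cfg, class = "ppy_config")
}

validate_config <- function(cfg) {
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg)
  chk(cfg$min_identity >= 0 && cfg$min_identity <= 1, "min_identity in [0,1]")
  chk(cfg$evalue_cutoff > 0, "evalue_cutoff > 0")
  chk(cfg$quartile_fraction > 0 && cfg$quartile_fraction <= 1,
      "quartile_fraction in (0,1]")
  chk(cfg$min_occupancy >= 0 && cfg$min_occupancy <= 1,
      "min_occupancy in [0,1]")
  chk(cfg$min_col_taxa >= 1, "min_col_taxa >= 1")
  chk(cfg$sig_threshold >= 0, "sig_threshold >= 0")
  chk(cfg$fraction_unknown >= 0 && cfg$fraction_unknown <= 1,
      "fraction_unknown in [0,1]")
  chk(all(cfg$stages %in% c("simulate", "build-matrix", "assign", "prune",
                            "supermatrix", "asr")), "unknown stage name")
  invisible(cfg)
}

#' @rdname pipeline_config
#' @param cfg a `ppy_config`.
#' @param path JSON file path.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname pipeline_config
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw <- raw[!vapply(raw, is.null, logical(1))]
  do.call(pipeline_config, raw)
}
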