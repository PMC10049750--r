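# End-to-end orchestrator over synthetic inputs: simulate -> build-matrix
# -> assign -> prune -> supermatrix -> asr, with a manifest of per-stage
# input/output counts.

# deterministic reverse translation for demo CDS: lexicographically first
# codon per amino acid
demo_codon <- function() {
  gc <- Biostrings::GENETIC_CODE
  tab <- vapply(sort(unique(gc)), function(a) min(names(gc)[gc == a]),
                character(1))
  tab
}

reverse_translate <- function(protein, codon_table = demo_codon()) {
  res <- strsplit(protein, "")[[1]]
  paste(codon_table[res], collapse = "")
}

#' Run the full synthetic-data pipeline
#'
#' Executes the enabled stages in order on generated inputs with known
#' ground truth: cluster simulation and substitution-matrix construction;
#' gene-family simulation, orthology assignment (profile search,
#' E-value/quartile filtering, reciprocal best hit); paralog pruning and
#' occupancy filtering; codon supermatrix assembly, codon-column
#' filtering and export; and the Mk ancestral-state analysis (ER/ARD
#' fits, AICc selection, marginal reconstruction) on a separate
#' study-scale trait simulation (36 tips, 11 unknown by default).
#'
#' @param config a [pipeline_config()].
#' @return list with `manifest` (per-stage counts; class `ppy_manifest`)
#'   and `results` (the stage objects).  If `config$out_dir` is set, the
#'   primary outputs and a JSON manifest are written there.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  validate_config(config)
  seed <- as.integer(config$seed)
  manifest <- list()
  res <- list()
  need <- function(what, stage)
    if (is.null(res[[what]]))
      stop("stage '", stage, "' requires earlier stage output '", what, "'")

  if ("simulate" %in% config$stages) {
    sp_tree <- with_seed(seed, ape::rtree(config$n_taxa_seq))
    sp_tree$tip.label <- paste0("t", seq_len(config$n_taxa_seq))
    families <- lapply(seq_len(config$n_groups), function(g)
      simulate_gene_family(sp_tree, config$dup_rate, config$loss_rate,
                           seed = seed + g,
                           seq_length = config$seq_length,
                           subs_rate = config$subs_rate))
    names(families) <- sprintf("og%03d", seq_len(config$n_groups))
    clusters <- lapply(seq_len(config$n_clusters), function(k)
      simulate_cluster(config$cluster_size, config$cluster_length,
                       config$cluster_identity, seed = seed + 100L + k,
                       id = sprintf("cl%03d", k)))
    res$species_tree <- sp_tree
    res$families <- families
    res$clusters <- clusters
    manifest$simulate <- list(
      n_taxa = config$n_taxa_seq,
      n_families = length(families),
      n_families_surviving = sum(!vapply(families, function(f)
        is.null(f$gene_tree), logical(1))),
      n_clusters = length(clusters))
  }

  if ("build-matrix" %in% config$stages) {
    need("clusters", "build-matrix")
    curated <- curate_clusters(res$clusters, config$min_identity)
    submat <- build_matrix_pipeline(
      curated, min_block_width = config$min_block_width,
      clustering_threshold = config$clustering_threshold,
      scale = config$scale, pseudocount = config$pseudocount)
    res$submat <- submat
    manifest$`build-matrix` <- list(
      clusters_in = length(res$clusters),
      clusters_kept = length(curated),
      n_blocks = attr(submat, "n_blocks"),
      total_pairs = attr(submat, "total_pairs"))
  }

  if ("assign" %in% config$stages) {
    need("families", "assign"); need("submat", "assign")
    sp_tree <- res$species_tree
    ref_taxon <- sp_tree$tip.label[1L]
    codon_table <- demo_codon()
    live <- Filter(function(f) !is.null(f$gene_tree) &&
                     length(f$seqs) >= 2L, res$families)
    profiles <- list(); ref_proteome <- character(0)
    queries <- list(); cds_store <- list()
    for (gid in names(live)) {
      fam <- live[[gid]]
      taxa <- leaf_taxon(names(fam$seqs))
      if (!ref_taxon %in% taxa) next
      # reference-proteome accessions must be unique across groups, so
      # sequence ids are group-qualified (leaf labels repeat per family)
      cl <- new_cluster(gid, taxon = taxa,
                        seq_id = paste(gid, names(fam$seqs), sep = "."),
                        seqs = fam$seqs)
      profiles[[gid]] <- build_profile(cl, res$submat, ref_taxon)
      ref_leaf <- names(fam$seqs)[taxa == ref_taxon][1L]
      ref_proteome[paste(gid, ref_leaf, sep = ".")] <- fam$seqs[[ref_leaf]]
      for (leaf in names(fam$seqs)) {
        tx <- leaf_taxon(leaf)
        if (tx == ref_taxon) next
        qid <- sub("^.*@", "", leaf)          # copyN
        cds <- reverse_translate(fam$seqs[[leaf]], codon_table)
        cds_store[[gid]][leaf] <- cds
        queries[[tx]] <- c(queries[[tx]],
                           stats::setNames(cds, paste(gid, qid, sep = ".")))
      }
      cds_store[[gid]][ref_leaf] <- reverse_translate(fam$seqs[[ref_leaf]],
                                                      codon_table)
    }
    if (!length(profiles)) stop("assign: no family retained the reference taxon")
    groups <- assign_orthologs(
      queries, profiles, ref_proteome, res$submat,
      evalue_cutoff = config$evalue_cutoff,
      quartile_fraction = config$quartile_fraction,
      translate = TRUE,
      gap_open = config$gap_open, gap_extend = config$gap_extend,
      n_shuffles = config$n_shuffles, seed = seed)
    res$profiles <- profiles
    res$ref_proteome <- ref_proteome
    res$ref_taxon <- ref_taxon
    res$cds_store <- cds_store
    res$groups <- groups
    manifest$assign <- list(
      n_profiles = length(profiles),
      n_queries = sum(lengths(queries)),
      n_accepted = sum(vapply(groups, function(g) nrow(g$members),
                              integer(1))))
  }

  if ("prune" %in% config$stages) {
    need("groups", "prune"); need("families", "prune")
    pruned <- list()
    n_out <- 0L
    for (gid in names(res$groups)) {
      g <- res$groups[[gid]]
      fam <- res$families[[gid]]
      if (is.null(fam) || is.null(fam$gene_tree)) next
      # accepted members + the reference leaf, mapped to gene-tree leaves
      leaves <- vapply(seq_len(nrow(g$members)), function(r) {
        parts <- strsplit(g$members$seq_id[r], "|", fixed = TRUE)[[1]]
        paste0(parts[1L], "@", sub("^.*\\.", "", parts[2L]))
      }, character(1))
      ref_names <- names(res$ref_proteome)
      ref_leaf <- sub("^[^.]*\\.", "",
                      ref_names[startsWith(ref_names, paste0(gid, "."))])
      leaves <- intersect(unique(c(leaves, ref_leaf)),
                          fam$gene_tree$tip.label)
      if (length(leaves) < 2L) next
      sub_tree <- ape::keep.tip(fam$gene_tree, leaves)
      codon_rows <- backtranslate(
        stats::setNames(fam$seqs[leaves], leaves),
        res$cds_store[[gid]][leaves], id = gid)
      pg <- prune_group(sub_tree,
                        stats::setNames(as.character(codon_rows), leaves),
                        support_cutoff = config$support_cutoff,
                        type = "nucleotide")
      pg$id <- gid
      pruned[[gid]] <- pg
      if (pg$outparalogs) n_out <- n_out + 1L
    }
    kept <- occupancy_filter(pruned, total_taxa = config$n_taxa_seq,
                             min_fraction = config$min_occupancy)
    res$pruned <- pruned
    res$kept_groups <- kept
    manifest$prune <- list(
      groups_in = length(res$groups),
      groups_pruned = length(pruned),
      groups_with_outparalogs = n_out,
      groups_after_occupancy = length(kept))
  }

  if ("supermatrix" %in% config$stages) {
    need("kept_groups", "supermatrix")
    if (!length(res$kept_groups))
      stop("supermatrix: no groups survived the occupancy filter")
    alns <- lapply(res$kept_groups, function(pg) {
      w <- nchar(pg$seqs[[1L]])
      structure(pg$seqs, id = pg$id, width = w, class = "ppy_codon_aln")
    })
    sm <- concatenate_codon_alignments(alns, res$species_tree$tip.label)
    smf <- filter_codon_columns(sm, min_taxa = config$min_col_taxa)
    stats <- matrix_stats(smf)
    res$supermatrix <- smf
    res$matrix_stats <- stats
    manifest$supermatrix <- list(
      groups_in = length(res$kept_groups),
      n_sites_before = nchar(sm$seqs[[1L]]),
      n_sites = stats$n_sites,
      pct_complete = stats$pct_complete,
      pct_ambiguous = stats$pct_ambiguous)
  }

  if ("asr" %in% config$stages) {
    trait_tree <- with_seed(seed + 999L, {
      tr <- ape::rtree(config$n_taxa_trait)
      tr$tip.label <- paste0("sp", seq_len(config$n_taxa_trait))
      tr
    })
    sim <- simulate_binary_trait(trait_tree,
                                 rate_model("ER", q = config$trait_q),
                                 seed = seed + 1000L)
    traits <- apply_missingness(sim$tip_states, config$fraction_unknown,
                                seed = seed + 1001L)
    fit_er <- fit_mk(trait_tree, traits, "ER",
                     root_prior = config$root_prior)
    fit_ard <- fit_mk(trait_tree, traits, "ARD",
                      root_prior = config$root_prior)
    chosen <- model_select(list(fit_er, fit_ard))
    asr <- marginal_asr(trait_tree, traits, chosen,
                        sig_threshold = config$sig_threshold)
    res$trait_tree <- trait_tree
    res$trait_sim <- sim
    res$traits <- traits
    res$fits <- list(ER = fit_er, ARD = fit_ard)
    res$chosen_fit <- chosen
    res$asr <- asr
    manifest$asr <- list(
      n_tips = config$n_taxa_trait,
      n_unknown = sum(is.na(traits)),
      aicc_er = fit_er$AICc, aicc_ard = fit_ard$AICc,
      chosen = chosen$model$kind,
      n_nodes = nrow(asr),
      n_significant = sum(asr$significant))
  }

  manifest <- structure(manifest, class = "ppy_manifest")
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(res$submat))
      write_score_matrix(res$submat, file.path(config$out_dir, "submat.txt"))
    if (!is.null(res$supermatrix))
      export_supermatrix(res$supermatrix,
                         file.path(config$out_dir, "supermatrix"))
    if (!is.null(res$asr)) {
      utils::write.table(res$asr, file.path(config$out_dir, "asr_nodes.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      fits_tab <- attr(res$chosen_fit, "delta_table")
      utils::write.table(fits_tab, file.path(config$out_dir, "mk_fits.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    jsonlite::write_json(unclass(manifest),
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(manifest = manifest, results = res)
}

#' @export
print.ppy_manifest <- function(x, ...) {
  if (!length(x)) { cat("empty manifest (no stages run)\n"); return(invisible(x)) }
  for (stage in names(x)) {
    cat(stage, ":\n", sep = "")
    for (k in names(x[[stage]]))
      cat(sprintf("  %s: %s\n", k,
                  paste(format(x[[stage]][[k]], digits = 6), collapse = ", ")))
  }
  invisible(x)
}
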