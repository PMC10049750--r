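# Six-frame translation, PSSM profile scoring, hit filtering,
# Smith-Waterman alignment and the reciprocal-best-hit test.

test_that("six-frame translation matches independent recomputation", {
  expect_equal(translate_six_frames("ATGGCC")[["F1"]], "MA")
  fr <- translate_six_frames("ATG")
  expect_equal(unname(nchar(fr[c("F1", "F2", "F3")])), c(1L, 0L, 0L))
  expect_equal(unname(translate_six_frames("")), rep("", 6L))

  set.seed(8)
  nt <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  fr <- translate_six_frames(nt)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
  for (k in 0:2) {
    sub <- substr(rc, k + 1, k + ((300 - k) %/% 3) * 3)
    expect_equal(fr[[paste0("R", k + 1)]],
                 as.character(Biostrings::translate(Biostrings::DNAString(sub))))
  }
})

test_that("profile self-match dominates and shuffled queries get large E-values", {
  cl <- simulate_cluster(4, 80, 0.95, seed = 2)
  mat <- suppressWarnings(build_matrix_pipeline(list(cl), pseudocount = 1))
  prof <- build_profile(cl, mat, "tax1")
  self <- score_query(prof, prof$ref_seq, "self", n_shuffles = 200, seed = 1)
  expect_lt(self$evalue, 1e-5)
  set.seed(3)
  for (i in 1:5) {
    rnd <- paste(sample(strsplit(prof$ref_seq, "")[[1]]), collapse = "")
    h <- score_query(prof, rnd, "rnd", n_shuffles = 200, seed = 1)
    expect_lt(h$score, self$score)
  }
  shuf <- score_query(prof, paste(rev(strsplit(prof$ref_seq, "")[[1]]),
                                  collapse = ""),
                      "rev", n_shuffles = 200, seed = 1)
  expect_gt(shuf$evalue, 1e-5)
  expect_message(
    expect_null(score_query(prof, "MK", "short", n_shuffles = 10, seed = 1)),
    "short")
  empty_prof <- structure(list(pssm = matrix(0, 0, 2)),
                          class = "ppy_profile")
  expect_error(score_query(empty_prof, "MKLV"), "empty profile")
})

test_that("hit filtering enforces the E-value cutoff and ceiling quartile with ties", {
  h4 <- data.frame(query = paste0("q", 1:4), group = "g",
                   score = c(10, 9, 8, 7), evalue = 1e-9)
  expect_identical(filter_hits(h4)$query, "q1")

  h1 <- data.frame(query = "q1", group = "g", score = 5, evalue = 1e-9)
  expect_identical(filter_hits(h1)$query, "q1")

  h8 <- data.frame(query = paste0("q", 1:8), group = "g",
                   score = c(10, 9, 9, 8, 7, 6, 5, 4), evalue = 1e-9)
  expect_identical(sort(filter_hits(h8)$query), c("q1", "q2", "q3"))

  # E-value cutoff applies before the quartile
  mix <- data.frame(query = paste0("q", 1:4), group = "g",
                    score = c(10, 9, 8, 7),
                    evalue = c(1, 1e-9, 1e-9, 1e-9))
  expect_identical(filter_hits(mix)$query, "q2")

  # over random tables: output is a subset, never empties a group with a
  # passing hit, honors the ceiling count, and keeps all boundary ties
  for (s in 1:20) {
    set.seed(s)
    n <- sample(1:12, 1)
    tab <- data.frame(query = paste0("q", seq_len(n)),
                      group = sample(c("g1", "g2"), n, TRUE),
                      score = sample(1:6, n, TRUE),
                      evalue = 10^runif(n, -9, -6))
    once <- filter_hits(tab)
    expect_true(all(once$query %in% tab$query))
    for (g in unique(tab$group)) {
      kept <- once[once$group == g, ]
      n_pass <- sum(tab$group == g)
      expect_gte(nrow(kept), max(1L, ceiling(n_pass * 0.25)))
      boundary <- min(kept$score)
      in_g <- tab[tab$group == g, ]
      expect_equal(nrow(kept), sum(in_g$score >= boundary))
    }
  }
})

test_that("Smith-Waterman scores and alignments behave as a local aligner", {
  mat <- toy_submat(c("H", "E", "A", "G", "W"), match = 4, mismatch = -3)
  a <- "HEAGAWGHEE"
  r <- smith_waterman(a, a, mat)
  expect_equal(r$score, 4 * nchar(a))
  expect_equal(r$a_aln, a)
  expect_equal(r$a_range, c(0L, nchar(a)))

  neg <- toy_submat(c("A", "G"), match = 2, mismatch = -1)
  r2 <- smith_waterman("A", "G", neg)
  expect_equal(r2$score, 0)
  expect_equal(r2$a_aln, "")

  expect_equal(smith_waterman("", "AG", neg)$score, 0)

  # symmetry of the score in the two arguments
  set.seed(4)
  ab <- c("A", "C", "D", "E")
  m <- toy_submat(ab)
  for (i in 1:10) {
    x <- paste(sample(ab, 12, TRUE), collapse = "")
    y <- paste(sample(ab, 12, TRUE), collapse = "")
    expect_equal(smith_waterman(x, y, m)$score,
                 smith_waterman(y, x, m)$score)
    expect_gte(smith_waterman(x, x, m)$score,
               smith_waterman(x, y, m)$score)
  }
  expect_error(smith_waterman("AC", "AC", m, gap_open = 0), "penalties")
})

test_that("gapped alignments recover indels with the affine convention", {
  m <- toy_submat(c("A", "C", "D", "E", "G"), match = 5, mismatch = -4)
  r <- smith_waterman("ACDEG", "ACEG", m, gap_open = 2, gap_extend = 1)
  expect_equal(r$a_aln, "ACDEG")
  expect_equal(r$b_aln, "AC-EG")
  expect_equal(r$score, 4 * 5 - 2)
  # gap of length 2 costs open + extend
  r2 <- smith_waterman("ACDDEG", "ACEG", m, gap_open = 2, gap_extend = 1)
  expect_equal(r2$score, 4 * 5 - 3)
})

test_that("reciprocal best hit accepts true orthologs and rejects decoys", {
  cl <- simulate_cluster(4, 60, 0.9, seed = 12, id = "og1")
  mat <- suppressWarnings(build_matrix_pipeline(list(cl), pseudocount = 1))
  prof <- build_profile(cl, mat, "tax1")
  ref_prot <- c(og1_1 = prof$ref_seq,
                other = simulate_cluster(2, 60, 0.9, seed = 77)$seqs[[1]])

  exact <- stats::setNames(prof$ref_seq, "cand1")
  acc <- reciprocal_best_hit(exact, prof, ref_prot, exact, mat,
                             n_shuffles = 40, seed = 1)
  expect_true(acc$accept)

  # candidate that is a copy of a different reference protein
  wrong <- stats::setNames(ref_prot[["other"]], "cand2")
  rej <- reciprocal_best_hit(wrong, prof, ref_prot, wrong, mat,
                             n_shuffles = 40, seed = 1)
  expect_false(rej$accept)
  expect_match(rej$reason, "forward best-hit mismatch")

  # engineered out-paralog: closer to a second family; verified against
  # brute-force all-vs-all scores
  fam2 <- simulate_cluster(3, 60, 0.9, seed = 78, id = "og2")
  outpar <- stats::setNames(fam2$seqs[[2]], "cand3")
  scores <- vapply(ref_prot, function(rp)
    smith_waterman(outpar[[1]], rp, mat)$score, numeric(1))
  expect_error(reciprocal_best_hit(outpar, prof, character(0), outpar, mat),
               "empty reference proteome")
  ref_prot2 <- c(ref_prot, og2_ref = fam2$seqs[[1]])
  scores2 <- vapply(ref_prot2, function(rp)
    smith_waterman(outpar[[1]], rp, mat)$score, numeric(1))
  expect_identical(names(which.max(scores2)), "og2_ref")
  rej2 <- reciprocal_best_hit(outpar, prof, ref_prot2, outpar, mat,
                              n_shuffles = 40, seed = 1)
  expect_false(rej2$accept)
})

test_that("assignment recovers one-to-one families exactly and drops decoys", {
  cfg <- pipeline_config(seed = 3, stages = c("simulate", "build-matrix",
                                              "assign"),
                         n_taxa_seq = 4L, n_groups = 2L, seq_length = 50L,
                         dup_rate = 0, loss_rate = 0, subs_rate = 0.08,
                         n_shuffles = 30L,
                         n_clusters = 4L, cluster_length = 80L)
  out <- suppressWarnings(run_pipeline(cfg))
  groups <- out$results$groups
  fams <- out$results$families
  for (gid in names(groups)) {
    mem <- groups[[gid]]$members
    # reference taxon t1 anchors the group; every other taxon recovered once
    expect_setequal(mem$taxon, c("t2", "t3", "t4"))
    expect_false(anyDuplicated(mem$taxon) > 0)
    for (r in seq_len(nrow(mem))) {
      leaf <- paste0(mem$taxon[r], "@copy1")
      expect_identical(mem$sequence[r], unname(fams[[gid]]$seqs[leaf]))
    }
  }
  # decoy unrelated to any profile is never assigned
  decoy_prot <- simulate_cluster(2, 40, 0.9, seed = 99)$seqs[[1]]
  decoy_cds <- polyphylo:::reverse_translate(decoy_prot)
  queries <- list(t2 = c(decoy = decoy_cds))
  g2 <- assign_orthologs(queries, out$results$profiles,
                         out$results$ref_proteome, out$results$submat,
                         n_shuffles = 30L, seed = 5)
  expect_true(all(vapply(g2, function(g) nrow(g$members), integer(1)) == 0L))
  # empty query set -> all groups empty
  g3 <- assign_orthologs(list(), out$results$profiles,
                         out$results$ref_proteome, out$results$submat)
  expect_true(all(vapply(g3, function(g) nrow(g$members), integer(1)) == 0L))
})

test_that("external HMMER-style per-domain tables import and filter identically", {
  txt <- c(
    "#                                                               --- full sequence --- -------------- this domain -------------   hmm coord   ali coord   env coord",
    "# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
    "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------",
    "t2|q1|P              -            100 og001                -            120   1.2e-40  130.5   0.0   1   1   2.0e-42   1.1e-40  129.9   0.0     1   100     5    90     1   100 0.98 -",
    "t2|q2|P              -             80 og001                -            120   3.0e-03    9.1   0.0   1   1   4.0e-05   2.0e-03    8.8   0.0     1    60     1    60     1    70 0.80 -")
  f <- withr::local_tempfile(fileext = ".domtbl")
  writeLines(txt, f)
  hits <- read_hmmer_domtbl(f)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$group, c("og001", "og001"))
  expect_equal(hits$evalue, c(1.1e-40, 2.0e-03))
  expect_equal(hits$start, c(4L, 0L))
  expect_equal(hits$end, c(90L, 60L))
  kept <- filter_hits(hits)
  expect_identical(kept$query, "t2|q1|P")
})
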