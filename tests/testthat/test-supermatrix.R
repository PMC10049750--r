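# Back-translation, concatenation, codon-column filtering, statistics
# and export of the codon supermatrix.

test_that("back-translation replaces residues by source codons and gaps by ---", {
  ca <- backtranslate(c(A = "M-A"), c(A = "ATGGCC"), id = "g")
  expect_equal(unname(as.character(ca))[1], "ATG---GCC")

  ca2 <- backtranslate(c(A = "M-A", B = "---"), c(A = "ATGGCC"), id = "g")
  expect_equal(unname(ca2[["B"]]), "---------")

  # trailing stop codon trimmed
  ca3 <- backtranslate(c(A = "MA"), c(A = "ATGGCCTAA"), id = "g")
  expect_equal(unname(ca3[["A"]]), "ATGGCC")

  expect_error(backtranslate(c(A = "MA"), c(A = "ATGAAA")), "mismatch")
  expect_error(backtranslate(c(A = "MA"), c(A = "ATGGC")), "3x")

  # round trip: translating the gap-stripped codon row recovers the protein
  set.seed(6)
  for (i in 1:10) {
    prot <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                         20, TRUE), collapse = "")
    gapped <- paste(append(strsplit(prot, "")[[1]], "-",
                           after = sample(0:20, 1)), collapse = "")
    cds <- polyphylo:::reverse_translate(prot)
    row <- backtranslate(stats::setNames(gapped, "x"),
                         stats::setNames(cds, "x"))[["x"]]
    back <- as.character(Biostrings::translate(
      Biostrings::DNAString(gsub("-", "", row))))
    expect_identical(back, prot)
  }
})

test_that("concatenation is order-stable with gap fill and a tiling map", {
  g1 <- backtranslate(c(A = "MA", B = "MA"), c(A = "ATGGCT", B = "ATGGCA"),
                      id = "g1")
  g2 <- backtranslate(c(A = "MKA"), c(A = "ATGAAAGCC"), id = "g2")
  sm <- concatenate_codon_alignments(list(g2, g1), c("A", "B"))
  expect_equal(sm$map$group, c("g1", "g2"))
  expect_equal(sm$map$start, c(0L, 6L))
  expect_equal(sm$map$end, c(6L, 15L))
  expect_equal(unname(sm$seqs[["B"]]), "ATGGCA---------")
  # permuting the input order yields the identical matrix
  sm2 <- concatenate_codon_alignments(list(g1, g2), c("A", "B"))
  expect_identical(sm, sm2)
  dup <- g1; names(dup) <- c("A", "A")
  expect_error(concatenate_codon_alignments(list(dup), c("A", "B")),
               "duplicate taxon")
})

test_that("codon columns below the taxon threshold are removed exactly", {
  # 5 taxa, 2 codons: first codon has data in 4 taxa, second in 3
  rows <- c(t1 = "ATG---", t2 = "ATGATG", t3 = "ATG---",
            t4 = "ATGATG", t5 = "---ATG")
  sm <- structure(list(seqs = rows,
                       map = data.frame(group = "g", start = 0L, end = 6L)),
                  class = "ppy_supermatrix")
  f4 <- filter_codon_columns(sm, min_taxa = 4L)
  expect_equal(nchar(f4$seqs[["t1"]]), 3L)
  expect_equal(unname(f4$seqs[["t2"]]), "ATG")
  expect_equal(f4$map$end, 3L)
  # all-gap codon is removed at any threshold >= 1
  rows2 <- c(t1 = "---ATG", t2 = "---ATG")
  sm2 <- structure(list(seqs = rows2,
                        map = data.frame(group = "g", start = 0L, end = 6L)),
                   class = "ppy_supermatrix")
  f1 <- filter_codon_columns(sm2, min_taxa = 1L)
  expect_equal(unname(f1$seqs[["t1"]]), "ATG")
  # idempotence and monotonicity in min_taxa
  expect_identical(filter_codon_columns(f4, min_taxa = 4L), f4)
  f5 <- filter_codon_columns(sm, min_taxa = 5L)
  expect_lte(nchar(f5$seqs[[1]]), nchar(f4$seqs[[1]]))
})

test_that("matrix statistics count gaps and ambiguity as documented", {
  gapfree <- structure(list(seqs = c(a = "ATGATG", b = "ATGATG"),
                            map = data.frame(group = "g", start = 0L,
                                             end = 6L)),
                       class = "ppy_supermatrix")
  st <- matrix_stats(gapfree)
  expect_equal(st$pct_complete, 100)
  expect_equal(st$pct_ambiguous, 0)

  # 2 x 6 with 3 gap cells -> 75% complete
  sm <- structure(list(seqs = c(a = "ATG---", b = "ATGATG"),
                       map = data.frame(group = "g", start = 0L, end = 6L)),
                  class = "ppy_supermatrix")
  expect_equal(matrix_stats(sm)$pct_complete, 75)

  # one N among 12 cells -> 8.33%
  smn <- structure(list(seqs = c(a = "ATGATN", b = "ATGATG"),
                        map = data.frame(group = "g", start = 0L, end = 6L)),
                   class = "ppy_supermatrix")
  expect_equal(matrix_stats(smn)$pct_ambiguous, 100 / 12, tolerance = 1e-12)
  # N counts as present for completeness, '?' as a gap
  smq <- structure(list(seqs = c(a = "ATG?TG", b = "ATGATG"),
                        map = data.frame(group = "g", start = 0L, end = 6L)),
                   class = "ppy_supermatrix")
  expect_equal(matrix_stats(smq)$pct_complete, 100 * 11 / 12)
  expect_equal(matrix_stats(smq)$pct_ambiguous, 0)
  # per-taxon aligned bp
  pt <- matrix_stats(sm)$per_taxon
  expect_equal(pt$aligned_bp[pt$taxon == "a"], 3)
  expect_equal(pt$fraction_full[pt$taxon == "b"], 1)
})

test_that("export produces stride partitions that tile the matrix and round-trips", {
  g1 <- backtranslate(c(A = "MA", B = "MA"), c(A = "ATGGCT", B = "ATGGCA"),
                      id = "g1")
  g2 <- backtranslate(c(A = "MKA", B = "MKA"),
                      c(A = "ATGAAAGCC", B = "ATGAAAGCA"), id = "g2")
  sm <- concatenate_codon_alignments(list(g1, g2), c("A", "B"))
  base <- withr::local_tempfile()
  files <- export_supermatrix(sm, base)
  expect_true(all(file.exists(files)))

  expect_identical(read_phylip(files[["phylip"]]), sm$seqs)
  expect_identical(read_fasta(files[["fasta"]]), sm$seqs)

  # parse the partition file and check the three strides tile all columns
  lines <- readLines(files[["partitions"]])
  expect_length(lines, 3L)
  covered <- integer(0)
  for (ln in lines) {
    spec_part <- sub("^DNA, pos[0-9] = ", "", ln)
    for (rng in strsplit(spec_part, ", ")[[1]]) {
      m <- regmatches(rng, regexec("^([0-9]+)-([0-9]+)\\\\3$", rng))[[1]]
      expect_length(m, 3L)
      covered <- c(covered, seq(as.integer(m[2]), as.integer(m[3]), by = 3L))
    }
  }
  expect_identical(sort(covered), seq_len(nchar(sm$seqs[[1]])))

  # single-gene width 6: positions {1,4}, {2,5}, {3,6}
  smalone <- concatenate_codon_alignments(list(g1), c("A", "B"))
  f2 <- export_supermatrix(smalone, withr::local_tempfile())
  expect_identical(readLines(f2[["partitions"]]),
                   c("DNA, pos1 = 1-6\\3", "DNA, pos2 = 2-6\\3",
                     "DNA, pos3 = 3-6\\3"))
})

test_that("concatenation conserves non-gap cells before filtering", {
  g1 <- backtranslate(c(A = "MA", B = "M-"), c(A = "ATGGCT", B = "ATG"),
                      id = "g1")
  g2 <- backtranslate(c(A = "KV"), c(A = "AAAGTT"), id = "g2")
  sm <- concatenate_codon_alignments(list(g1, g2), c("A", "B"))
  cells_groups <- sum(vapply(list(g1, g2), function(g)
    sum(nchar(gsub("-", "", as.character(g)))), numeric(1)))
  cells_matrix <- sum(nchar(gsub("-", "", sm$seqs)))
  expect_equal(cells_matrix, cells_groups)
})
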