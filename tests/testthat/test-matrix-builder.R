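# Cluster curation and the log-odds substitution-matrix construction.

mkcluster <- function(id, ...) {
  seqs <- c(...)
  new_cluster(id, taxon = paste0("t", seq_along(seqs)),
              seq_id = paste0(id, "_", seq_along(seqs)), seqs = seqs)
}

test_that("percent identity averages pairwise identities over non-gap positions", {
  expect_equal(percent_identity(mkcluster("a", "ACDE", "ACDE")), 1.0)
  expect_equal(percent_identity(mkcluster("b", "ACDE", "ACDK")), 0.75)
  # pairwise identities {1.0, 0.5, 0.5} -> mean 2/3
  expect_equal(percent_identity(mkcluster("c", "AAAA", "AAAA", "AATT")),
               2 / 3)
  # gapped positions are excluded from the denominator
  expect_equal(percent_identity(mkcluster("d", "AC-E", "ACDE")), 1.0)
  expect_error(percent_identity(mkcluster("e", "ACDE")), "singleton")
})

test_that("cluster curation removes singletons then sub-threshold clusters", {
  single <- mkcluster("s", "ACDE")
  at70 <- mkcluster("keep", strrep("A", 10),
                    paste0(strrep("A", 7), strrep("C", 3)))
  below <- mkcluster("drop", strrep("A", 100),
                     paste0(strrep("A", 69), strrep("C", 31)))
  expect_equal(percent_identity(at70), 0.70)
  expect_equal(percent_identity(below), 0.69)
  out <- curate_clusters(list(single, at70, below))
  expect_identical(vapply(out, function(cl) cl$id, character(1)), "keep")
  expect_length(curate_clusters(list(single)), 0L)
  # order preserved
  out2 <- curate_clusters(list(at70, single, at70))
  expect_identical(vapply(out2, function(cl) cl$id, character(1)),
                   c("keep", "keep"))
})

test_that("reference-taxon selection counts clusters and breaks ties as documented", {
  clX <- function(id, taxa) new_cluster(id, taxon = taxa,
                                        seq_id = paste0(id, seq_along(taxa)),
                                        seqs = rep("AAAA", length(taxa)))
  cl <- list(clX("1", c("X", "Y")), clX("2", c("X", "Z")), clX("3", "X"))
  expect_equal(select_reference_taxon(cl), list(taxon = "X", count = 3L))
  tie <- list(clX("1", c("A", "B")), clX("2", c("A", "B")))
  expect_equal(select_reference_taxon(tie, priority = c("B", "A"))$taxon, "B")
  expect_equal(select_reference_taxon(list(clX("1", c("B", "A"))))$taxon, "A")
  expect_error(select_reference_taxon(list()), "empty")
})

test_that("blocks are maximal gap-free column runs", {
  full <- mkcluster("f", "ACDEFGHIKL", "ACDEFGHIKL")
  b <- extract_blocks(full)
  expect_length(b, 1L)
  expect_equal(c(b[[1]]$start, b[[1]]$end), c(0L, 10L))

  gapped <- mkcluster("g", "ACDE-GHIKL", "ACDEFGHIKL")
  b2 <- extract_blocks(gapped)
  expect_length(b2, 2L)
  expect_equal(c(b2[[1]]$start, b2[[1]]$end), c(0L, 4L))
  expect_equal(c(b2[[2]]$start, b2[[2]]$end), c(5L, 10L))

  # interleaved gaps, min_width filter
  inter <- mkcluster("i", "AA-AAAA-AA-AAA", "AAAAAAAAAAAAAA")
  b3 <- extract_blocks(inter, min_width = 3L)
  expect_equal(vapply(b3, function(x) x$end - x$start, integer(1)),
               c(4L, 3L))
  # column-identity threshold drops divergent columns
  div <- mkcluster("d", "AAAA", "AAAC", "AAAG")
  b4 <- extract_blocks(div, min_column_identity = 0.8)
  expect_equal(c(b4[[1]]$start, b4[[1]]$end), c(0L, 3L))
  expect_length(extract_blocks(mkcluster("e", "----", "----")), 0L)
})

test_that("sequence weights group by single linkage and sum to one per group", {
  blk <- extract_blocks(mkcluster("w", strrep("A", 20), strrep("A", 20),
                                  strrep("A", 20), strrep("A", 20)))[[1]]
  expect_equal(weight_sequences(blk, 0.9), rep(0.25, 4))
  expect_equal(weight_sequences(blk, 1.01), rep(1, 4))

  s1 <- strrep("A", 20)
  s2 <- paste0(strrep("A", 19), "C")          # 95% to s1
  s3 <- paste0(strrep("A", 10), strrep("D", 10))  # 50%
  blk2 <- extract_blocks(mkcluster("w2", s1, s2, s3))[[1]]
  expect_equal(weight_sequences(blk2, 0.9), c(0.5, 0.5, 1))
})

test_that("pair counting matches direct enumeration", {
  blkA <- extract_blocks(mkcluster("a", "A", "A", "A", "A"))[[1]]
  pc <- count_pairs(list(blkA), list(rep(1, 4)), alphabet = c("A", "B"))
  expect_equal(pc$counts["A", "A"], 6)
  expect_equal(pc$total, 6)

  blkB <- extract_blocks(mkcluster("b", "A", "A", "A", "B"))[[1]]
  pc2 <- count_pairs(list(blkB), list(rep(1, 4)), alphabet = c("A", "B"))
  expect_equal(pc2$counts["A", "A"], 3)
  expect_equal(pc2$counts["A", "B"], 3)
  expect_equal(pc2$total, 6)

  blkC <- extract_blocks(mkcluster("c", "A", "B"))[[1]]
  pc3 <- count_pairs(list(blkC), list(c(0.5, 1)), alphabet = c("A", "B"))
  expect_equal(pc3$counts["A", "B"], 0.5)

  # randomized toys against the enumeration oracle
  for (s in 1:20) {
    set.seed(s)
    alpha <- c("A", "C", "D")
    seqs <- vapply(1:4, function(i)
      paste(sample(alpha, 8, TRUE), collapse = ""), character(1))
    blocks <- extract_blocks(mkcluster(paste0("r", s), seqs))
    weights <- lapply(blocks, function(b) runif(length(b$seqs), 0.2, 1))
    got <- count_pairs(blocks, weights, alphabet = alpha)
    want <- pair_count_oracle(blocks, weights, alpha)
    expect_equal(got$counts, want, tolerance = 1e-12)
    expect_equal(got$total, sum(want[upper.tri(want, diag = TRUE)]),
                 tolerance = 1e-12)
  }
})

test_that("log-odds scores match the hand-computed construction", {
  # toy counts {AA:6, AB:2, BB:2}: q = (.6,.2,.2), p = (.7,.3),
  # e = (.49,.42,.09), s = round(2*log2(q/e)) = (1,-2,2)
  counts <- matrix(c(6, 2, 2, 2), 2, 2, dimnames = list(c("A", "B"),
                                                        c("A", "B")))
  pc <- structure(list(counts = counts, total = 10,
                       alphabet = c("A", "B")), class = "ppy_paircounts")
  so <- compute_log_odds(pc, scale = 2)
  expect_equal(so$bg, c(A = 0.7, B = 0.3))
  expect_equal(so$scores,
               matrix(c(1, -2, -2, 2), 2, 2,
                      dimnames = list(c("A", "B"), c("A", "B"))))
  # q == e everywhere -> all-zero matrix
  flat <- structure(list(counts = matrix(c(1, 2, 2, 1), 2, 2,
                                         dimnames = dimnames(counts)),
                         total = 4, alphabet = c("A", "B")),
                    class = "ppy_paircounts")
  expect_true(all(compute_log_odds(flat)$scores == 0))
  # identical-sequence blocks: positive diagonal, floored off-diagonal
  blk <- extract_blocks(mkcluster("i", "AB", "AB"))[[1]]
  pci <- count_pairs(list(blk), list(c(1, 1)), alphabet = c("A", "B"))
  expect_warning(soi <- compute_log_odds(pci), "floored")
  expect_true(all(diag(soi$scores) > 0))
  expect_lt(soi$scores["A", "B"], 0)
})

test_that("the matrix pipeline yields a symmetric negative-expectation matrix", {
  clusters <- lapply(1:4, function(k)
    simulate_cluster(4, 150, 0.95, seed = 20 + k, id = paste0("c", k)))
  mat <- suppressWarnings(build_matrix_pipeline(clusters, pseudocount = 1))
  expect_identical(mat$scores, t(mat$scores))
  expect_equal(sum(mat$bg), 1, tolerance = 1e-12)
  expected_score <- sum(outer(mat$bg, mat$bg) * mat$scores / mat$scale)
  expect_lt(expected_score, 0)
  # diagonal dominance for residues with decent support
  seen <- names(mat$bg)[mat$bg > 0.02]
  for (a in seen)
    expect_true(all(mat$scores[a, a] > mat$scores[a, setdiff(seen, a)]))
  # composition identity on a single gap-free cluster
  one <- simulate_cluster(2, 80, 0.98, seed = 31, id = "one")
  direct <- suppressWarnings(compute_log_odds(count_pairs(
    extract_blocks(one), list(weight_sequences(extract_blocks(one)[[1]])))))
  via <- suppressWarnings(build_matrix_pipeline(list(one)))
  expect_equal(via$scores, direct$scores)
  expect_error(build_matrix_pipeline(list()), "empty cluster list")
})

test_that("a clustering threshold above 1 reduces to unweighted counting", {
  cl <- simulate_cluster(4, 100, 0.92, seed = 41)
  blocks <- extract_blocks(cl)
  w_off <- lapply(blocks, weight_sequences, clustering_threshold = 1.01)
  w_unit <- lapply(blocks, function(b) rep(1, length(b$seqs)))
  expect_equal(count_pairs(blocks, w_off)$counts,
               count_pairs(blocks, w_unit)$counts)
})

test_that("scoring matrices survive the text-format round trip", {
  cl <- simulate_cluster(3, 60, 0.9, seed = 51)
  mat <- suppressWarnings(build_matrix_pipeline(list(cl), pseudocount = 1))
  f <- withr::local_tempfile(fileext = ".mat")
  write_score_matrix(mat, f)
  back <- read_score_matrix(f)
  expect_equal(back$scores, mat$scores)
  expect_identical(back$alphabet, mat$alphabet)
})
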