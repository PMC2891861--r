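test_that("FASTA reading upper-cases, names and validates records", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">g1 some description", "acgtACGT", ">g2", "GGGNCC"), tmp)
  p <- read_promoters(tmp)
  expect_length(p, 2)
  expect_identical(unname(p[["g1"]]), "ACGTACGT")
  writeLines(c(">a", "ACGT", ">a", "ACGT"), tmp)
  expect_error(read_promoters(tmp), "duplicate")
  expect_error(as_promoter_set(c(g1 = "ACGU")), "non-ACGTN")
  expect_error(as_promoter_set(c("ACGT")), "named")
})

test_that("scan results are case-invariant", {
  lower <- as_promoter_set(c(g = tolower("AAGTGAGAAAGCAAA")))
  upper <- as_promoter_set(c(g = "AAGTGAGAAAGCAAA"))
  expect_identical(consensus_scan(lower)$hits, consensus_scan(upper)$hits)
})

test_that("consensus scan expands degenerate letters literally", {
  s <- as_promoter_set(c(g = "TTGTGAGAAAGCATT"))
  got <- consensus_scan(s, "RTGABNNNGCA", alphabet = "are",
                        strands = "plus")
  expect_equal(unname(got$counts), 1L)
  expect_identical(got$hits$match, "GTGAGAAAGCA")
  # offsets: 15-mer, match starts at base 3 -> offset 3 - 15 - 1 = -13
  expect_equal(got$hits$start, -13)
  expect_equal(got$hits$end, -3)
})

test_that("the nonstandard R = G/C differs from standard IUPAC", {
  s <- as_promoter_set(c(g = "TTATGAGAAAGCATT"))
  expect_equal(unname(consensus_scan(s, "RTGABNNNGCA", "are",
                                     strands = "plus")$counts), 0L)
  expect_equal(unname(consensus_scan(s, "RTGABNNNGCA", "iupac",
                                     strands = "plus")$counts), 1L)
})

test_that("consensus presets expose the published variants", {
  expect_identical(are_consensus(), "RTGABNNNGCA")
  expect_identical(are_consensus("tca"), "RTGABNNNTCA")
  expect_identical(are_consensus("perfect"), "RTGABNNNGA")
})

test_that("consensus counts equal the brute-force oracle on random seqs", {
  seqs <- as_promoter_set(setNames(random_seqs(20, 500, seed = 61),
                                   paste0("g", 1:20)))
  for (strands in c("plus", "both")) {
    got <- consensus_scan(seqs, "RTGABNNNGCA", "are", strands = strands)
    want <- vapply(seqs, oracle_consensus_count, integer(1),
                   pattern = "RTGABNNNGCA", type = "are", strands = strands)
    expect_equal(unname(got$counts), unname(want))
  }
})

test_that("scanning is strand-symmetric", {
  seqs <- as_promoter_set(setNames(random_seqs(5, 300, seed = 62),
                                   paste0("g", 1:5)))
  rc <- as_promoter_set(vapply(seqs, oracle_revcomp, character(1)))
  a <- consensus_scan(seqs, strands = "both")
  b <- consensus_scan(rc, strands = "both")
  expect_equal(unname(a$counts), unname(b$counts))
  # mirrored coordinates: a plus-strand hit at [s, e] in seq appears at
  # [-e - 1 - L .. ] in the reverse complement; compare multisets of spans
  spans <- function(h, L) sort(h$end - h$start)
  expect_identical(spans(a$hits), spans(b$hits))
})

test_that("background frequencies are pooled and symmetrized", {
  expect_equal(background_frequencies(c(g = "AATT")),
               c(A = 0.5, C = 0, G = 0, T = 0.5))
  expect_equal(background_frequencies(c(g = "ACGT")),
               c(A = 0.25, C = 0.25, G = 0.25, T = 0.25))
  expect_error(background_frequencies(c(g = "NNNN")), "usable")
})

test_that("generator composition is recovered in the background", {
  p <- simulate_promoters(30, length = 2000, seed = 63)
  bg <- background_frequencies(p$sequences)
  expect_lt(abs(bg[["A"]] - 0.26), 0.01)
  expect_lt(abs(bg[["C"]] - 0.24), 0.01)
  expect_equal(sum(bg), 1)
})

test_that("log-odds weights are null for background-equal matrices", {
  m <- matrix(0.25, 4, 6, dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- build_pssm(m, pseudocount = 0)
  expect_true(all(p$weights == 0))
})

test_that("log-odds weights match hand computation", {
  m <- matrix(0.1, 4, 2, dimnames = list(c("A", "C", "G", "T"), NULL))
  m["A", 1] <- 0.7
  m["G", 2] <- 0.7
  p <- build_pssm(m, pseudocount = 0)
  expect_equal(unname(p$weights["A", 1]), log(0.7 / 0.25))
  expect_equal(unname(p$weights["C", 1]), log(0.1 / 0.25))
})

test_that("zero probabilities demand a pseudocount", {
  m <- matrix(c(1, 0, 0, 0), 4, 3, dimnames = list(c("A", "C", "G", "T"),
                                                   NULL))
  expect_error(build_pssm(m, pseudocount = 0), "pseudocount")
  expect_silent(build_pssm(m, pseudocount = 0.001))
})

test_that("expected score under the background is non-positive", {
  set.seed(64)
  for (i in 1:10) {
    W <- sample(4:12, 1)
    f <- matrix(rgamma(4 * W, 0.8), 4, W)
    f <- sweep(f, 2, colSums(f), "/")
    rownames(f) <- c("A", "C", "G", "T")
    bg <- rgamma(4, 2)
    bg <- setNames(bg / sum(bg), c("A", "C", "G", "T"))
    p <- build_pssm(f, background = bg, pseudocount = 0.001)
    exp_score <- sum(colSums(p$weights * matrix(bg, 4, W)))
    expect_lte(exp_score, 0)
  }
})

test_that("an all-zero-weight matrix yields no hits above threshold 1", {
  m <- matrix(0.25, 4, 5, dimnames = list(c("A", "C", "G", "T"), NULL))
  p <- build_pssm(m, pseudocount = 0)
  seqs <- as_promoter_set(setNames(random_seqs(3, 100, seed = 65),
                                   paste0("g", 1:3)))
  sc <- pssm_scan(seqs, p)
  expect_equal(nrow(sc$hits), 0)
  expect_true(all(sc$summary$n_matches == 0))
})

test_that("a strongly informative matrix peaks at its consensus word", {
  word <- "GTGACTCAGCA"
  f <- sapply(strsplit(word, "")[[1]], function(b) {
    col <- setNames(rep(0.02, 4), c("A", "C", "G", "T"))
    col[b] <- 0.94
    col
  })
  rownames(f) <- c("A", "C", "G", "T")
  p <- build_pssm(f, pseudocount = 0.001)
  truth <- data.frame(gene = "g1", motif = word, position = -150,
                      strand = "+")
  pr <- simulate_promoters(2, length = 400, planted = truth, seed = 66)
  sc <- pssm_scan(pr$sequences, p)
  best <- sc$summary[sc$summary$gene == "g1", ]
  expect_equal(best$best_start, -150)
  expect_identical(toupper(substr(best$best_seq, 5, 15)), word)
})

test_that("PSSM hits equal the brute-force oracle on random sequences", {
  m <- read_probability_matrix(
    system.file("extdata", "are_pssm_synthetic.tsv", package = "nrf2prot"))
  seqs <- as_promoter_set(setNames(random_seqs(15, 500, seed = 67,
                                               n_rate = 0.01),
                                   paste0("g", 1:15)))
  bg <- background_frequencies(seqs)
  p <- build_pssm(m, background = bg)
  sc <- suppressMessages(pssm_scan(seqs, p, threshold = 1,
                                   strands = "both"))
  for (g in names(seqs)) {
    want <- oracle_pssm_scores(seqs[[g]], p$weights, strands = "both")
    want_hits <- want[want > 1]
    got <- sc$hits$score[sc$hits$gene == g]
    expect_equal(sort(got), sort(want_hits), tolerance = 1e-12)
    srow <- sc$summary[sc$summary$gene == g, ]
    expect_equal(srow$n_matches, length(want_hits))
    if (length(want_hits))
      expect_equal(srow$highest_score, max(want_hits), tolerance = 1e-12)
  }
})

test_that("hits are unaffected by flanking sequence outside the window", {
  m <- read_probability_matrix(
    system.file("extdata", "are_pssm_synthetic.tsv", package = "nrf2prot"))
  p <- build_pssm(m)
  core <- "GTGAGAAAGCA"
  a <- as_promoter_set(c(g = paste0(strrep("T", 20), core, strrep("T", 20))))
  b <- as_promoter_set(c(g = paste0(strrep("C", 20), core, strrep("A", 20))))
  sa <- pssm_scan(a, p, strands = "plus")
  sb <- pssm_scan(b, p, strands = "plus")
  ha <- sa$hits[sa$hits$start == -31, ]
  hb <- sb$hits[sb$hits$start == -31, ]
  expect_equal(ha$score, hb$score)
})

test_that("promoters shorter than the matrix produce a warning, not hits", {
  m <- read_probability_matrix(
    system.file("extdata", "are_pssm_synthetic.tsv", package = "nrf2prot"))
  p <- build_pssm(m)
  expect_warning(sc <- pssm_scan(as_promoter_set(c(tiny = "ACGT")), p),
                 "tiny")
  expect_equal(sc$summary$n_matches, 0L)
})

test_that("panel summary averages per-gene statistics by group", {
  gs <- data.frame(gene = c("a", "b", "c"),
                   consensus_count = c(1, 3, 10),
                   highest_score = c(2, 4, 6))
  ps <- panel_summary(gs, list(two = c("a", "b"), one = "c"))
  expect_equal(ps$consensus_count[ps$group == "two"], 2)
  expect_equal(ps$highest_score[ps$group == "one"], 6)
  expect_warning(panel_summary(gs, list(none = "zz")), "omitted")
})
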