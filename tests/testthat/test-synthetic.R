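test_that("zero-noise, unit-fold simulation gives ratios of exactly 1", {
  tab <- simulate_itraq(5, cv = 0, fold_changes = 1, seed = 1)
  expect_true(all(tab$ratio == 1))
})

test_that("equal seeds give identical tables, different seeds differ", {
  a <- simulate_itraq(20, cv = 0.3, missing_run_rate = 0.2, seed = 7)
  b <- simulate_itraq(20, cv = 0.3, missing_run_rate = 0.2, seed = 7)
  d <- simulate_itraq(20, cv = 0.3, missing_run_rate = 0.2, seed = 8)
  expect_identical(a, b)
  expect_false(identical(a$ratio, d$ratio))

  s1 <- simulate_spot_table(10, noise = 0.2, seed = 3)
  s2 <- simulate_spot_table(10, noise = 0.2, seed = 3)
  expect_identical(s1, s2)

  p1 <- simulate_promoters(4, length = 100, seed = 5)
  p2 <- simulate_promoters(4, length = 100, seed = 5)
  expect_identical(p1, p2)
})

test_that("invalid generator arguments are rejected with the field named", {
  expect_error(simulate_itraq(0, seed = 1), "n_proteins")
  expect_error(simulate_itraq(5, cv = -1, seed = 1), "cv")
  expect_error(simulate_itraq(5, missing_run_rate = 2, seed = 1),
               "missing_run_rate")
  expect_error(simulate_itraq(5, fold_changes = c(p1 = -2), seed = 1),
               "fold_changes")
  expect_error(simulate_itraq(5, fold_changes = c(zz = 2), seed = 1), "zz")
  expect_error(simulate_itraq(5), "seed")
  expect_error(simulate_spot_table(3, noise = -0.1, seed = 1), "noise")
})

test_that("planted fold change is recovered by the geometric-mean estimate", {
  tab <- simulate_itraq(3, n_animals_per_group = 200, cv = 0.2,
                        fold_changes = c(p1 = 0.5), seed = 42)
  fit <- itraq_de(tab)
  expect_lt(abs(coef(fit)[["p1"]] - 0.5), 0.05)
  expect_lt(abs(coef(fit)[["p2"]] - 1.0), 0.05)
})

test_that("KO log-ratios centre on the planted log fold change (3 SE)", {
  fold <- 1.7
  cv <- 0.25
  tab <- simulate_itraq(2, n_animals_per_group = 150, n_runs = 2, cv = cv,
                        fold_changes = c(p1 = fold), seed = 11)
  lr <- log(tab$ratio[tab$accession == "p1" & tab$genotype == "KO"])
  se <- cv / sqrt(length(lr))
  expect_lt(abs(mean(lr) - log(fold)), 3 * se)
})

test_that("reference animal ratio is exactly 1 and all ratios positive", {
  tab <- simulate_itraq(10, cv = 0.5, seed = 2)
  expect_true(all(tab$ratio[tab$animal_id == "WT1"] == 1))
  expect_true(all(tab$ratio > 0))
})

test_that("noise-free spot tables normalize identically across gels", {
  s <- simulate_spot_table(6, noise = 0, effects = 1, seed = 1)
  ns <- normalize_spots(s)
  m <- tapply(ns$normalized_intensity, list(ns$spot_id, ns$gel_id), identity)
  expect_true(all(apply(m, 1, function(r) max(r) - min(r) < 1e-12)))
})

test_that("a planted absence makes the spot ineligible under 'both'", {
  s <- simulate_spot_table(4, seed = 9,
                           absent = data.frame(spot_id = "s2",
                                               gel_id = "KOgel1"))
  expect_false("s2" %in% spot_inclusion(s, require = "both"))
  expect_true("s2" %in% spot_inclusion(s, require = "any"))
})

test_that("planted spot effect is recovered from many gels", {
  s <- simulate_spot_table(5, n_gels_per_group = 200, noise = 0.1,
                           effects = c(s1 = 0.5), seed = 21)
  fit <- gel_de(s)
  f <- fit$results$fold_change[fit$results$spot_id == "s1"]
  expect_lt(abs(f - 0.5), 0.05)
})

test_that("degenerate composition yields a homogeneous sequence", {
  p <- simulate_promoters(1, length = 50,
                          base_composition = c(A = 1, C = 0, G = 0, T = 0),
                          seed = 1)
  expect_identical(unname(p$sequences[["g1"]]), strrep("A", 50))
})

test_that("planted motifs land at their stated offsets on both strands", {
  truth <- data.frame(gene = c("g1", "g2"), motif = "GTGAGAAAGCA",
                      position = c(-100, -250), strand = c("+", "-"))
  p <- simulate_promoters(3, length = 400, planted = truth, seed = 6)
  sc <- consensus_scan(p$sequences, "RTGABNNNGCA", strands = "both")
  h1 <- sc$hits[sc$hits$gene == "g1" & sc$hits$start == -100, ]
  expect_identical(h1$strand, "+")
  expect_identical(h1$match, "GTGAGAAAGCA")
  h2 <- sc$hits[sc$hits$gene == "g2" & sc$hits$start == -250, ]
  expect_identical(h2$strand, "-")
})

test_that("a motif that does not fit is rejected naming the gene", {
  truth <- data.frame(gene = "g1", motif = "GTGAGAAAGCA",
                      position = -5, strand = "+")
  expect_error(simulate_promoters(2, length = 100, planted = truth, seed = 1),
               "g1")
})

test_that("generated files round-trip through the package readers", {
  tmp <- withr::local_tempdir()
  tab <- simulate_itraq(6, cv = 0.2, missing_run_rate = 0.1, seed = 4)
  f <- file.path(tmp, "ratios.tsv")
  write_ratio_table(tab, f)
  back <- read_ratio_table(f, reference_animal = "WT1")
  expect_equal(back$ratio, tab$ratio, tolerance = 1e-12)
  expect_identical(back$accession, tab$accession)

  s <- simulate_spot_table(5, seed = 4)
  fs <- file.path(tmp, "spots.tsv")
  write_spot_table(s, fs)
  backs <- read_spot_table(fs)
  expect_equal(backs$intensity, s$intensity, tolerance = 1e-12)

  p <- simulate_promoters(3, length = 137, seed = 4)
  fp <- file.path(tmp, "prom.fa")
  write_promoters(p$sequences, fp)
  backp <- read_promoters(fp)
  expect_identical(as.character(backp), as.character(p$sequences))

  gs <- simulate_gene_sets(paste0("g", 1:50), 4, seed = 4)
  fg <- file.path(tmp, "sets.gmt")
  write_gmt(gs, fg)
  expect_identical(read_gmt(fg), gs)

  m <- read_probability_matrix(
    system.file("extdata", "are_pssm_synthetic.tsv", package = "nrf2prot"))
  fm <- file.path(tmp, "mat.tsv")
  write_probability_matrix(m, fm)
  expect_equal(read_probability_matrix(fm), m, tolerance = 1e-9)
})
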