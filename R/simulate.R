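#' Simulate an iTRAQ reporter-ratio table with known ground truth
#'
#' Emulates the structure of a multi-run iTRAQ experiment: each animal's
#' per-run ratio to a reference wild-type animal is the genotype's true
#' multiplicative effect times log-normal noise,
#' `ratio = fold * exp(N(0, cv^2))`, so the expected log ratio of a
#' knockout animal equals the log of its planted fold change and group
#' geometric means recover the planted effects.  The reference animal's own
#' ratio is exactly 1 in every run, as it is the denominator of the
#' labelling scheme.  Whole (protein, run) blocks can be dropped at random
#' to mimic run-to-run coverage differences, and individual (protein,
#' animal, run) cells can additionally be dropped to exercise the
#' complete-case rule downstream.
#'
#' @param n_proteins Number of proteins.
#' @param n_animals_per_group Animals per genotype; default 4.
#' @param n_runs Replicate runs; default 4.
#' @param fold_changes Planted KO/WT multiplicative effects: a single
#'   value, an unnamed vector of length `n_proteins`, or a named vector
#'   keyed by accession (`"p1"`, `"p2"`, ...) with unlisted proteins at 1.
#' @param cv Standard deviation of the multiplicative noise on the natural
#'   log scale; default 0.2.
#' @param missing_run_rate Probability that a (protein, run) block is
#'   dropped for all animals; default 0.
#' @param missing_cell_rate Probability that a single (protein, animal,
#'   run) cell is dropped; default 0.
#' @param seed Mandatory integer seed; identical seeds give identical
#'   tables.
#' @return A `ratio_table` (see [as_ratio_table()]) with attributes
#'   `reference_animal` (`"WT1"`) and `truth` (named vector of planted fold
#'   changes).
#' @examples
#' tab <- simulate_itraq(5, fold_changes = c(p1 = 0.5), cv = 0.1, seed = 1)
#' @export
simulate_itraq <- function(n_proteins, n_animals_per_group = 4, n_runs = 4,
                           fold_changes = 1, cv = 0.2,
                           missing_run_rate = 0, missing_cell_rate = 0,
                           seed) {
  n_proteins <- check_count(n_proteins, "n_proteins")
  n_animals_per_group <- check_count(n_animals_per_group,
                                     "n_animals_per_group")
  n_runs <- check_count(n_runs, "n_runs")
  cv <- check_nonneg(cv, "cv")
  missing_run_rate <- check_prob(missing_run_rate, "missing_run_rate")
  missing_cell_rate <- check_prob(missing_cell_rate, "missing_cell_rate")
  if (missing(seed)) stop_("'seed' is required")

  acc <- paste0("p", seq_len(n_proteins))
  fold <- setNames(rep(1, n_proteins), acc)
  if (!is.null(names(fold_changes))) {
    unknown <- setdiff(names(fold_changes), acc)
    if (length(unknown))
      stop_("'fold_changes' names not among proteins: ",
            paste(unknown, collapse = ", "))
    fold[names(fold_changes)] <- fold_changes
  } else if (length(fold_changes) == 1L) {
    fold[] <- fold_changes
  } else if (length(fold_changes) == n_proteins) {
    fold[] <- fold_changes
  } else {
    stop_("'fold_changes' must be length 1, n_proteins, or named")
  }
  if (any(!is.finite(fold)) || any(fold <= 0))
    stop_("'fold_changes' must be strictly positive")

  animals <- c(paste0("WT", seq_len(n_animals_per_group)),
               paste0("KO", seq_len(n_animals_per_group)))
  genotype <- rep(c("WT", "KO"), each = n_animals_per_group)
  runs <- paste0("run", seq_len(n_runs))

  with_seed(seed, {
    g <- expand.grid(accession = acc, animal_id = animals, run_id = runs,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    g$genotype <- genotype[match(g$animal_id, animals)]
    mu <- ifelse(g$genotype == "KO", log(fold[g$accession]), 0)
    g$ratio <- exp(mu + rnorm(nrow(g), 0, cv))
    g$ratio[g$animal_id == "WT1"] <- 1  # reference animal: denominator
    if (missing_run_rate > 0) {
      block <- expand.grid(accession = acc, run_id = runs,
                           stringsAsFactors = FALSE)
      drop <- block[runif(nrow(block)) < missing_run_rate, ]
      g <- g[!(paste(g$accession, g$run_id) %in%
                 paste(drop$accession, drop$run_id)), ]
    }
    if (missing_cell_rate > 0)
      g <- g[runif(nrow(g)) >= missing_cell_rate, ]
    g$protein_name <- paste("protein", sub("^p", "", g$accession))
    g <- g[order(g$accession, g$animal_id, g$run_id),
           c("accession", "protein_name", "genotype", "animal_id",
             "run_id", "ratio")]
    rownames(g) <- NULL
    out <- as_ratio_table(g, reference_animal = "WT1")
    attr(out, "truth") <- fold
    out
  })
}

#' Simulate a 2DE spot-intensity table
#'
#' Spot base abundances are log-normal across spots; knockout gels carry
#' the planted multiplicative effect, and every (gel, spot) intensity gets
#' independent log-normal noise.  Specific (spot, gel) observations can be
#' removed to exercise the inclusion rule.
#'
#' @param n_spots Number of spots.
#' @param n_gels_per_group Gels per group; default 4.
#' @param effects Planted KO/WT effects, as in [simulate_itraq()]'s
#'   `fold_changes` but keyed by spot id (`"s1"`, ...).
#' @param noise Log-scale noise SD (>= 0); default 0.1.
#' @param absent Optional data frame with columns `spot_id` and `gel_id`
#'   naming observations to delete.
#' @param seed Mandatory integer seed.
#' @return A spot table data frame with attribute `truth`.
#' @export
simulate_spot_table <- function(n_spots, n_gels_per_group = 4, effects = 1,
                                noise = 0.1, absent = NULL, seed) {
  n_spots <- check_count(n_spots, "n_spots")
  n_gels_per_group <- check_count(n_gels_per_group, "n_gels_per_group")
  noise <- check_nonneg(noise, "noise")
  if (missing(seed)) stop_("'seed' is required")

  spots <- paste0("s", seq_len(n_spots))
  eff <- setNames(rep(1, n_spots), spots)
  if (!is.null(names(effects))) {
    unknown <- setdiff(names(effects), spots)
    if (length(unknown))
      stop_("'effects' names not among spots: ", paste(unknown, collapse = ", "))
    eff[names(effects)] <- effects
  } else {
    eff[] <- effects
  }
  if (any(eff <= 0)) stop_("'effects' must be strictly positive")

  gels <- c(paste0("WTgel", seq_len(n_gels_per_group)),
            paste0("KOgel", seq_len(n_gels_per_group)))
  group <- rep(c("WT", "KO"), each = n_gels_per_group)

  with_seed(seed, {
    base <- setNames(exp(rnorm(n_spots, 0, 1)), spots)
    g <- expand.grid(spot_id = spots, gel_id = gels,
                     stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
    g$group <- group[match(g$gel_id, gels)]
    mult <- ifelse(g$group == "KO", eff[g$spot_id], 1)
    g$intensity <- base[g$spot_id] * mult * exp(rnorm(nrow(g), 0, noise))
    if (!is.null(absent)) {
      g <- g[!(paste(g$spot_id, g$gel_id) %in%
                 paste(absent$spot_id, absent$gel_id)), ]
    }
    g <- g[order(g$gel_id, g$spot_id),
           c("gel_id", "group", "spot_id", "intensity")]
    rownames(g) <- NULL
    attr(g, "truth") <- eff
    g
  })
}

#' Write a 2DE spot table
#'
#' @param x Spot table data frame.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_spot_table <- function(x, path) {
  write.table(x[c("gel_id", "group", "spot_id", "intensity")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Simulate promoter sequences with planted motifs
#'
#' Generates i.i.d. sequences from a base composition and overwrites the
#' requested windows with planted motifs (reverse-complemented for minus
#' strand plantings).  Positions follow the scanning convention: the base
#' immediately upstream of the start codon is -1 and the planted `position`
#' is the (negative) offset of the motif's first plus-strand base.
#'
#' @param n_genes Number of genes (ids `g1`, `g2`, ...).
#' @param length Promoter length in bp; default 2000.
#' @param base_composition Named A/C/G/T probabilities summing to 1;
#'   default the genome-like preset `A = T = 0.26`, `C = G = 0.24`.
#' @param planted Optional data frame with columns `gene`, `motif`,
#'   `position` (negative offset) and `strand` (`"+"`/`"-"`).
#' @param seed Mandatory integer seed.
#' @return List with `sequences` (a `promoter_set`) and `truth` (the
#'   planted data frame).
#' @export
simulate_promoters <- function(n_genes, length = 2000,
                               base_composition = c(A = 0.26, C = 0.24,
                                                    G = 0.24, T = 0.26),
                               planted = NULL, seed) {
  n_genes <- check_count(n_genes, "n_genes")
  length <- check_count(length, "length")
  if (missing(seed)) stop_("'seed' is required")
  bc <- base_composition[BASES]
  if (any(is.na(bc)) || any(bc < 0) || abs(sum(bc) - 1) > 1e-6)
    stop_("'base_composition' must be named A/C/G/T probabilities summing to 1")

  genes <- paste0("g", seq_len(n_genes))
  with_seed(seed, {
    seqs <- vapply(genes, function(g)
      paste(sample(BASES, length, replace = TRUE, prob = bc), collapse = ""),
      character(1L))
    if (!is.null(planted)) {
      need <- c("gene", "motif", "position", "strand")
      miss <- setdiff(need, names(planted))
      if (length(miss))
        stop_("'planted' is missing column(s): ", paste(miss, collapse = ", "))
      for (i in seq_len(nrow(planted))) {
        g <- planted$gene[i]
        if (!g %in% genes) stop_("planted gene '", g, "' does not exist")
        motif <- toupper(planted$motif[i])
        W <- nchar(motif)
        pos <- planted$position[i]
        start <- pos + length + 1L  # 1-based plus-strand start
        if (pos >= 0 || start < 1L || start + W - 1L > length)
          stop_("planted motif does not fit in promoter of gene '", g, "'")
        ins <- if (planted$strand[i] == "-") revcomp(motif) else motif
        seqs[[g]] <- paste0(substring(seqs[[g]], 1L, start - 1L), ins,
                            substring(seqs[[g]], start + W, length))
      }
    }
    list(sequences = as_promoter_set(seqs), truth = planted)
  })
}

#' Simulate gene sets over a universe
#'
#' Draws random member subsets for testing over-representation machinery.
#'
#' @param universe Character vector of gene identifiers.
#' @param n_sets Number of sets.
#' @param set_sizes Integer vector of candidate sizes; sampled per set.
#' @param seed Mandatory integer seed.
#' @return Named list of character vectors (`set1`, `set2`, ...).
#' @export
simulate_gene_sets <- function(universe, n_sets, set_sizes = 5:20, seed) {
  n_sets <- check_count(n_sets, "n_sets")
  if (missing(seed)) stop_("'seed' is required")
  with_seed(seed, {
    sets <- lapply(seq_len(n_sets), function(i) {
      size <- min(sample(set_sizes, 1L), length(universe))
      sample(universe, size)
    })
    setNames(sets, paste0("set", seq_len(n_sets)))
  })
}
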