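#' Run the iTRAQ differential-expression stage end to end
#'
#' Reads a reporter-ratio TSV, fits [itraq_de()], and writes the per-animal
#' summary, the per-protein results and a provenance block (configuration
#' echo, counts at each filtering stage, package version) to the output
#' directory.  Filtering counts (quantified, complete-case, significant)
#' are logged to standard error.
#'
#' @param input Path to a ratio table TSV (see [read_ratio_table()]).
#' @param output_dir Output directory; created if missing.
#' @param p_cut,bh_cut,z,log_scale,var_equal,run_average Passed to
#'   [itraq_de()].
#' @param reference_animal Optional reference animal id for validation.
#' @return The fitted `itraq_de` object, invisibly.
#' @export
run_itraq <- function(input, output_dir, p_cut = 0.05, bh_cut = 0.2,
                      z = 1.96, log_scale = TRUE, var_equal = TRUE,
                      run_average = "arithmetic",
                      reference_animal = NULL) {
  tab <- read_ratio_table(input, reference_animal = reference_animal)
  fit <- itraq_de(tab, p_cut = p_cut, bh_cut = bh_cut, z = z,
                  log_scale = log_scale, var_equal = var_equal,
                  run_average = run_average)
  message(sprintf("quantified: %d; complete-case: %d; significant: %d",
                  fit$n_quantified, fit$n_complete, fit$n_significant))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(fit$animal_values,
              file.path(output_dir, "animal_values.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_itraq_results(fit, file.path(output_dir, "itraq_results.tsv"))
  write_provenance(file.path(output_dir, "itraq_provenance.json"),
                   stage = "itraq",
                   config = c(list(input = input), fit$params),
                   counts = list(quantified = fit$n_quantified,
                                 complete_case = fit$n_complete,
                                 significant = fit$n_significant))
  invisible(fit)
}

#' Run the promoter-scanning stage end to end
#'
#' Reads promoters (FASTA) and a probability matrix, derives the background
#' from the promoter panel itself, performs both the degenerate consensus
#' search and the PSSM scan, and writes a per-gene report combining
#' consensus counts with matrix-match statistics plus a panel-mean footer
#' and a provenance block.
#'
#' @param fasta Promoter FASTA path.
#' @param matrix_file Probability-matrix path (see
#'   [read_probability_matrix()]).
#' @param output_dir Output directory; created if missing.
#' @param pattern Consensus pattern; default [are_consensus()].
#' @param alphabet `"are"` or `"iupac"`.
#' @param strands `"both"` or `"plus"`.
#' @param threshold PSSM score cut-off; default 1.
#' @param pseudocount Passed to [build_pssm()].
#' @param groups Optional named list of gene groups for [panel_summary()];
#'   a group `all` covering every gene is always added.
#' @return List with `consensus`, `pssm_scan`, `per_gene`, `panel`,
#'   invisibly.
#' @export
run_scan <- function(fasta, matrix_file, output_dir,
                     pattern = are_consensus(), alphabet = "are",
                     strands = "both", threshold = 1, pseudocount = 0.001,
                     groups = NULL) {
  seqs <- read_promoters(fasta)
  prob <- read_probability_matrix(matrix_file)
  bg <- background_frequencies(seqs)
  pssm <- build_pssm(prob, background = bg, pseudocount = pseudocount)
  cons <- consensus_scan(seqs, pattern = pattern, alphabet = alphabet,
                         strands = strands)
  scan <- pssm_scan(seqs, pssm, threshold = threshold, strands = strands)
  per_gene <- merge(data.frame(gene = names(cons$counts),
                               consensus_count = as.integer(cons$counts),
                               stringsAsFactors = FALSE),
                    scan$summary, by = "gene", sort = TRUE)
  groups <- c(list(all = names(seqs)), groups)
  panel <- panel_summary(
    per_gene[c("gene", "consensus_count", "n_matches", "highest_score",
               "mean_score")],
    groups)
  message(sprintf("genes scanned: %d; consensus hits: %d; matrix matches: %d",
                  length(seqs), nrow(cons$hits), nrow(scan$hits)))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(per_gene, file.path(output_dir, "promoter_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(panel, file.path(output_dir, "panel_means.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(file.path(output_dir, "scan_provenance.json"),
                   stage = "scan",
                   config = list(fasta = fasta, matrix_file = matrix_file,
                                 pattern = toupper(pattern),
                                 alphabet = if (is.character(alphabet))
                                   alphabet else "custom",
                                 strands = strands, threshold = threshold,
                                 pseudocount = pseudocount,
                                 background = as.list(bg)),
                   counts = list(genes = length(seqs),
                                 consensus_hits = nrow(cons$hits),
                                 matrix_matches = nrow(scan$hits)))
  invisible(list(consensus = cons, pssm_scan = scan, per_gene = per_gene,
                 panel = panel))
}

write_provenance <- function(path, stage, config, counts) {
  block <- list(stage = stage,
                package = "nrf2prot",
                version = as.character(packageVersion("nrf2prot")),
                r_version = as.character(getRversion()),
                config = config,
                counts = counts)
  jsonlite::write_json(block, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
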