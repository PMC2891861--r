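#' Packaged example data: constitutive Nrf2-null liver study
#'
#' Plain-text tables bundled with the package, drawn from a published
#' constitutive proteome comparison of Nrf2-knockout and wild-type mouse
#' liver:
#'
#' * `nrf2_itraq1()` — the training iTRAQ cohort (4 WT vs 4 KO mice, four
#'   replicate runs): per-animal run-averaged relative expression values
#'   against wild-type mouse 1, plus the reported geometric means,
#'   95% confidence bounds, fold changes and BH-adjusted p-values for the
#'   108 proteins accepted as differentially expressed.
#' * `nrf2_itraq2()` — the validation iTRAQ cohort (6 vs 6 mice): group
#'   summaries for its 38 significant proteins.
#' * `nrf2_gel2de()` — the 2DE gel study: normalized spot-intensity group
#'   means (+/- SD), fold changes and p-values for the 8 regulated spots.
#' * `nrf2_accession_aliases()` — the accession harmonization map used when
#'   intersecting the three lists (major urinary protein 6 is reported
#'   under two SwissProt accessions).
#'
#' @return A data frame (see above).
#' @name nrf2_data
NULL

extdata <- function(file) {
  system.file("extdata", file, package = "nrf2prot", mustWork = TRUE)
}

#' @rdname nrf2_data
#' @export
nrf2_itraq1 <- function() {
  read.delim(extdata("itraq1_relative_expression.tsv"),
             stringsAsFactors = FALSE)
}

#' @rdname nrf2_data
#' @export
nrf2_itraq2 <- function() {
  read.delim(extdata("itraq2_summary.tsv"), stringsAsFactors = FALSE)
}

#' @rdname nrf2_data
#' @export
nrf2_gel2de <- function() {
  read.delim(extdata("gel2de_spot_summary.tsv"), stringsAsFactors = FALSE)
}

#' @rdname nrf2_data
#' @export
nrf2_accession_aliases <- function() {
  read.delim(extdata("accession_aliases.tsv"), stringsAsFactors = FALSE)
}

#' Reshape a wide per-animal expression table to aggregated long form
#'
#' Turns a table with per-animal columns (`wt1`..`wt4`, `ko1`..`ko4`, as in
#' [nrf2_itraq1()]) into the long aggregated format consumed by
#' [itraq_de()] and [group_summary()], treating each per-animal value as an
#' already run-averaged expression.
#'
#' @param wide Data frame with columns `accession`, `protein_name`,
#'   optionally `n_runs`, and per-animal value columns matching
#'   `^(wt|ko)[0-9]+$`.
#' @return Long data frame with columns `accession`, `protein_name`,
#'   `animal_id`, `genotype`, `aggregated_ratio`, `n_runs`.
#' @export
animal_values_long <- function(wide) {
  cols <- grep("^(wt|ko)[0-9]+$", names(wide), value = TRUE)
  if (!length(cols)) stop_("no per-animal columns (wt1..., ko1...) found")
  rows <- lapply(cols, function(cl) {
    data.frame(accession = wide$accession,
               protein_name = wide$protein_name,
               animal_id = toupper(cl),
               genotype = toupper(sub("[0-9]+$", "", cl)),
               aggregated_ratio = wide[[cl]],
               n_runs = if ("n_runs" %in% names(wide)) wide$n_runs else 1L,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$accession, out$animal_id), ]
  rownames(out) <- NULL
  out
}
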