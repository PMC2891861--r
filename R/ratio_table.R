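#' Read an iTRAQ reporter-ratio table
#'
#' Reads the long-format tab-separated dialect used throughout the package:
#' one row per (protein, animal, run) with columns `accession`,
#' `protein_name`, `genotype` (`"WT"` or `"KO"`), `animal_id`, `run_id` and
#' `ratio`.  Ratios are relative expression values against a designated
#' reference wild-type animal (by convention the denominator sample of the
#' labelling scheme), so the reference animal's own ratio is 1 by
#' construction.
#'
#' @param path Path to a tab-separated file with a header line.
#' @param reference_animal Identifier of the reference (denominator) animal.
#'   Stored as an attribute; must be a wild-type animal present in the table.
#' @return A `data.frame` of class `ratio_table` with the columns above and
#'   attribute `reference_animal`.
#' @seealso [write_ratio_table()], [aggregate_runs()], [itraq_de()]
#' @export
read_ratio_table <- function(path, reference_animal = NULL) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  as_ratio_table(x, reference_animal = reference_animal)
}

#' Validate and classify a reporter-ratio data frame
#'
#' @param x A data frame with columns `accession`, `protein_name`,
#'   `genotype`, `animal_id`, `run_id`, `ratio`.
#' @inheritParams read_ratio_table
#' @return `x`, validated, with class `ratio_table` prepended.
#' @export
as_ratio_table <- function(x, reference_animal = NULL) {
  need <- c("accession", "protein_name", "genotype", "animal_id", "run_id",
            "ratio")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_("ratio table is missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(x)) {
    if (!is.numeric(x$ratio))
      stop_("column 'ratio' must be numeric")
    if (any(!is.finite(x$ratio)) || any(x$ratio <= 0))
      stop_("all ratios must be finite and strictly positive")
  }
  bad <- setdiff(unique(x$genotype), c("WT", "KO"))
  if (length(bad))
    stop_("genotype must be 'WT' or 'KO'; found: ", paste(bad, collapse = ", "))
  key <- paste(x$accession, x$animal_id, x$run_id, sep = "\r")
  if (anyDuplicated(key))
    stop_("duplicate (accession, animal_id, run_id) records present")
  if (!is.null(reference_animal)) {
    g <- unique(x$genotype[x$animal_id == reference_animal])
    if (!length(g))
      stop_("reference animal '", reference_animal, "' not present in table")
    if (!identical(g, "WT"))
      stop_("reference animal '", reference_animal, "' must be genotype WT")
  }
  attr(x, "reference_animal") <- reference_animal
  class(x) <- unique(c("ratio_table", class(x)))
  x
}

#' Write a reporter-ratio table
#'
#' @param x A `ratio_table` (or compatible data frame).
#' @param path Output path; tab-separated with header, no quoting.
#' @return `path`, invisibly.
#' @export
write_ratio_table <- function(x, path) {
  cols <- c("accession", "protein_name", "genotype", "animal_id", "run_id",
            "ratio")
  write.table(x[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Average replicate runs within each animal
#'
#' Collapses per-run ratios to one expression value per (protein, animal).
#' The default is the arithmetic mean of the run ratios; a geometric
#' alternative is available since group summaries downstream are geometric.
#' Proteins absent from every run of an animal are simply absent from the
#' result.
#'
#' @param x A `ratio_table` or compatible data frame.
#' @param method `"arithmetic"` (default) or `"geometric"` mean across runs.
#' @return A data frame with columns `accession`, `protein_name`,
#'   `animal_id`, `genotype`, `aggregated_ratio`, `n_runs`.
#' @export
aggregate_runs <- function(x, method = c("arithmetic", "geometric")) {
  method <- match.arg(method)
  if (!nrow(x)) stop_("ratio table is empty")
  f <- if (method == "arithmetic") mean else function(v) exp(mean(log(v)))
  agg <- aggregate(ratio ~ accession + protein_name + animal_id + genotype,
                   data = x, FUN = f)
  n <- aggregate(ratio ~ accession + protein_name + animal_id + genotype,
                 data = x, FUN = length)
  names(agg)[names(agg) == "ratio"] <- "aggregated_ratio"
  agg$n_runs <- n$ratio
  agg <- agg[order(agg$accession, agg$animal_id), ]
  rownames(agg) <- NULL
  agg[c("accession", "protein_name", "animal_id", "genotype",
        "aggregated_ratio", "n_runs")]
}

#' Retain proteins quantified in every required animal
#'
#' Mirrors the complete-data acceptance rule of the quantitative analysis: a
#' protein enters the statistical stage only when an aggregated expression
#' value exists for every animal in the design.
#'
#' @param agg Output of [aggregate_runs()].
#' @param required_animals Character vector of animal identifiers that must
#'   all be present.  Defaults to every animal occurring in `agg`.
#' @return The rows of `agg` belonging to complete-case proteins.
#' @export
complete_case_filter <- function(agg, required_animals = NULL) {
  if (is.null(required_animals))
    required_animals <- unique(agg$animal_id)
  if (!length(required_animals)) stop_("'required_animals' must be non-empty")
  have <- tapply(agg$animal_id, agg$accession,
                 function(a) all(required_animals %in% a))
  keep <- names(have)[have]
  out <- agg[agg$accession %in% keep, ]
  rownames(out) <- NULL
  out
}
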