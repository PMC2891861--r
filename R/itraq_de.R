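#' Differential expression analysis of an iTRAQ reporter-ratio table
#'
#' The central fitting routine.  Per-run ratios are averaged within each
#' animal, proteins quantified in every required animal are retained, each
#' genotype is summarized by its geometric mean with a log-normal confidence
#' interval, and the knockout/wild-type contrast is tested per protein with
#' a Shapiro-Wilk-gated choice between Student's t-test and the
#' Mann-Whitney test.  Raw p-values are Benjamini-Hochberg adjusted across
#' all quantified proteins and the dual acceptance rule
#' (`raw_p < p_cut` and `bh_p <= bh_cut`) flags significant proteins.
#'
#' @param x A `ratio_table` (see [read_ratio_table()]) or a pre-aggregated
#'   data frame from [aggregate_runs()].
#' @param p_cut,bh_cut Acceptance thresholds; defaults 0.05 and 0.2.
#' @param log_scale Run t-tests on log ratios (default `TRUE`).
#' @param var_equal Pooled-variance t-test (default `TRUE`).
#' @param normality_alpha Level for the Shapiro-Wilk gate; default 0.05.
#' @param z Normal quantile for group confidence intervals; default 1.96.
#' @param run_average Run-averaging method passed to [aggregate_runs()].
#' @param required_animals Animals that must all carry a value for a protein
#'   to be analysed; defaults to every animal present.
#' @return An object of class `itraq_de`: a list with `results` (one row per
#'   analysed protein: group geometric means, confidence bounds,
#'   `fold_change`, `test_used`, `raw_p`, `bh_p`, `significant`),
#'   `animal_values` (the aggregated per-animal matrix in long form),
#'   filtering counts and the call.  Methods: `print`, `summary`, `coef`
#'   (named fold changes), `plot` (volcano), `as.data.frame`.
#' @examples
#' tab <- simulate_itraq(n_proteins = 12, fold_changes = c(p1 = 2), seed = 1)
#' fit <- itraq_de(tab)
#' head(coef(fit))
#' @export
itraq_de <- function(x, p_cut = 0.05, bh_cut = 0.2, log_scale = TRUE,
                     var_equal = TRUE, normality_alpha = 0.05, z = 1.96,
                     run_average = c("arithmetic", "geometric"),
                     required_animals = NULL) {
  run_average <- match.arg(run_average)
  if (all(c("aggregated_ratio", "n_runs") %in% names(x))) {
    agg <- x
  } else {
    x <- as_ratio_table(x, reference_animal = attr(x, "reference_animal"))
    agg <- aggregate_runs(x, method = run_average)
  }
  n_quantified <- length(unique(agg$accession))
  agg <- complete_case_filter(agg, required_animals)
  n_complete <- length(unique(agg$accession))
  if (!n_complete) stop_("no protein passes the complete-case filter")

  sp <- split(agg, agg$accession)
  rows <- lapply(sp, function(d) {
    wt <- setNames(d$aggregated_ratio[d$genotype == "WT"],
                   d$animal_id[d$genotype == "WT"])
    ko <- setNames(d$aggregated_ratio[d$genotype == "KO"],
                   d$animal_id[d$genotype == "KO"])
    gm_wt <- geometric_mean(wt)
    gm_ko <- geometric_mean(ko)
    ci_wt <- suppressWarnings(lognormal_ci(wt, z = z))
    ci_ko <- suppressWarnings(lognormal_ci(ko, z = z))
    tw <- if (log_scale) list(wt = log(wt), ko = log(ko))
          else list(wt = wt, ko = ko)
    ch <- choose_test(tw$wt, tw$ko, alpha = normality_alpha)
    p <- suppressWarnings(
      raw_p(wt, ko, test = ch$test, log_scale = log_scale,
            var_equal = var_equal))
    data.frame(accession = d$accession[1L],
               protein_name = d$protein_name[1L],
               n_runs = max(d$n_runs),
               wt_geometric_mean = gm_wt,
               wt_ci_lower = unname(ci_wt[1L]),
               wt_ci_upper = unname(ci_wt[2L]),
               ko_geometric_mean = gm_ko,
               ko_ci_lower = unname(ci_ko[1L]),
               ko_ci_upper = unname(ci_ko[2L]),
               fold_change = fold_change(gm_ko, gm_wt),
               test_used = ch$test,
               shapiro_p_wt = unname(ch$shapiro_p["wt"]),
               shapiro_p_ko = unname(ch$shapiro_p["ko"]),
               f_test_p = ch$f_p,
               raw_p = p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$bh_p <- bh_adjust(res$raw_p)
  res <- select_significant(res, p_cut = p_cut, bh_cut = bh_cut)
  res <- res[order(res$fold_change), ]
  rownames(res) <- NULL

  structure(
    list(results = res,
         animal_values = agg,
         n_quantified = n_quantified,
         n_complete = n_complete,
         n_significant = sum(res$significant),
         params = list(p_cut = p_cut, bh_cut = bh_cut,
                       log_scale = log_scale, var_equal = var_equal,
                       normality_alpha = normality_alpha, z = z,
                       run_average = run_average),
         call = match.call()),
    class = "itraq_de")
}

#' @export
print.itraq_de <- function(x, ...) {
  cat("iTRAQ differential expression analysis\n")
  cat(sprintf("  proteins quantified:    %d\n", x$n_quantified))
  cat(sprintf("  complete cases:         %d\n", x$n_complete))
  cat(sprintf("  significant (p < %g & BH <= %g): %d\n",
              x$params$p_cut, x$params$bh_cut, x$n_significant))
  invisible(x)
}

#' @export
summary.itraq_de <- function(object, ...) {
  print(object)
  sig <- object$results[object$results$significant, ]
  if (nrow(sig)) {
    cat("\nSignificant proteins (ascending fold change):\n")
    print(sig[c("accession", "protein_name", "fold_change", "raw_p", "bh_p",
                "test_used")], digits = 3, row.names = FALSE)
  }
  invisible(object$results)
}

#' @export
coef.itraq_de <- function(object, ...) {
  setNames(object$results$fold_change, object$results$accession)
}

#' @export
as.data.frame.itraq_de <- function(x, ...) x$results

#' Volcano plot of an iTRAQ analysis
#'
#' @param x An `itraq_de` object.
#' @param ... Passed to [graphics::plot.default()].
#' @export
plot.itraq_de <- function(x, ...) {
  r <- x$results
  plot.default(log2(r$fold_change), -log10(r$raw_p),
               pch = ifelse(r$significant, 19, 1),
               xlab = "log2 fold change (KO/WT)",
               ylab = "-log10 raw p", ...)
  abline(h = -log10(x$params$p_cut), lty = 2)
  abline(v = log2(c(0.8, 1.25)), lty = 3)
  invisible(x)
}

#' Write the per-protein results of an iTRAQ analysis
#'
#' @param fit An `itraq_de` object.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_itraq_results <- function(fit, path) {
  write.table(fit$results, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
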