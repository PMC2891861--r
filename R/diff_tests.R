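#' Choose between t-test and Mann-Whitney for one protein
#'
#' Shapiro-Wilk normality is assessed in each group at level `alpha`; both
#' groups passing selects the unpaired Student t-test, either failing routes
#' to the Mann-Whitney rank test.  The variance-equality F-test p-value is
#' reported for the record (it does not influence the routing).  A group
#' whose values are all identical cannot be assessed for normality and is
#' treated as failing.
#'
#' @param values_wt,values_ko Numeric group values, at least 3 per group.
#' @param alpha Normality level; default 0.05.
#' @return A list with elements `test` (`"t_test"` or `"mann_whitney"`),
#'   `shapiro_p` (named vector, `NA` where undefined) and `f_p`.
#' @export
choose_test <- function(values_wt, values_ko, alpha = 0.05) {
  if (length(values_wt) < 3L || length(values_ko) < 3L)
    stop_("each group needs at least 3 values for the normality check")
  sw <- function(v) tryCatch(shapiro.test(v)$p.value,
                             error = function(e) NA_real_)
  p_wt <- sw(values_wt)
  p_ko <- sw(values_ko)
  fp <- tryCatch(var.test(values_wt, values_ko)$p.value,
                 error = function(e) NA_real_)
  normal <- !is.na(p_wt) && !is.na(p_ko) && p_wt > alpha && p_ko > alpha
  list(test = if (normal) "t_test" else "mann_whitney",
       shapiro_p = c(wt = p_wt, ko = p_ko),
       f_p = fp)
}

#' Two-sided group-comparison p-value
#'
#' @param values_wt,values_ko Numeric group values.
#' @param test `"t_test"` or `"mann_whitney"` (typically from
#'   [choose_test()]).
#' @param log_scale Log-transform values before a t-test (coherent with the
#'   geometric-mean effect scale; requires positive values).  The rank test
#'   is unaffected by monotone transforms and is run on the raw values.
#' @param var_equal Pooled-variance t-test when `TRUE` (default, matching
#'   the use of F-tests for variance equality); Welch otherwise.
#' @return Two-sided p-value.  Under a t-test with zero variance in both
#'   groups the comparison is degenerate and `1` is returned with a warning.
#' @export
raw_p <- function(values_wt, values_ko, test = c("t_test", "mann_whitney"),
                  log_scale = TRUE, var_equal = TRUE) {
  test <- match.arg(test)
  if (test == "t_test") {
    x <- values_wt
    y <- values_ko
    if (log_scale) {
      if (any(c(x, y) <= 0)) stop_("log_scale requires positive values")
      x <- log(x)
      y <- log(y)
    }
    if (sd(x) == 0 && sd(y) == 0) {
      warning("zero variance in both groups; p set to 1", call. = FALSE)
      return(1)
    }
    t.test(x, y, var.equal = var_equal)$p.value
  } else {
    n <- max(length(values_wt), length(values_ko))
    p <- suppressWarnings(
      wilcox.test(values_wt, values_ko, exact = n <= 8,
                  correct = TRUE)$p.value)
    if (is.na(p)) {
      # complete ties: the rank statistic is degenerate, no evidence at all
      warning("degenerate rank test (complete ties); p set to 1",
              call. = FALSE)
      p <- 1
    }
    p
  }
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up: sort ascending, take running minima of
#' `p * m / rank` from the largest rank down, cap at 1, restore input order.
#' Delegates to [stats::p.adjust()].
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  if (!all(ok)) stop_("p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Apply the dual significance rule
#'
#' A protein is accepted when its raw p-value is below `p_cut` *and* its
#' BH-adjusted value is at most `bh_cut`.  The permissive BH cut-off (0.2)
#' avoids discarding correlated regulated proteins through an overly
#' stringent multiplicity correction.
#'
#' @param results Data frame carrying columns `raw_p` and `bh_p`.
#' @param p_cut Raw p threshold (strict); default 0.05.
#' @param bh_cut BH threshold (non-strict); default 0.2.
#' @return `results` with a logical `significant` column (re)computed.
#' @export
select_significant <- function(results, p_cut = 0.05, bh_cut = 0.2) {
  if (!all(c("raw_p", "bh_p") %in% names(results)))
    stop_("'results' must have columns 'raw_p' and 'bh_p'")
  results$significant <- !is.na(results$raw_p) & !is.na(results$bh_p) &
    results$raw_p < p_cut & results$bh_p <= bh_cut
  results
}
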