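#' Geometric mean
#'
#' `exp(mean(log(x)))` for strictly positive values; the effect-size scale
#' used for all reporter-ratio summaries.
#'
#' @param x Numeric vector of positive values (length >= 1).  Names, when
#'   present, are used to identify offending entries in error messages.
#' @return The geometric mean, a positive scalar.
#' @examples
#' geometric_mean(c(0.47, 0.28, 0.48, 0.64))  # 0.45 to 2 dp
#' @export
geometric_mean <- function(x) {
  if (!length(x)) stop_("geometric_mean() needs at least one value")
  bad <- !is.finite(x) | x <= 0
  if (any(bad)) {
    who <- if (!is.null(names(x))) paste(names(x)[bad], collapse = ", ")
           else paste(which(bad), collapse = ", ")
    stop_("non-positive value(s) for: ", who)
  }
  exp(mean(log(x)))
}

#' Log-normal confidence interval for a geometric mean
#'
#' Normal-quantile interval on the natural-log scale,
#' `exp(mean(log x) +/- z * sd(log x) / sqrt(n))`, with the sample (n-1)
#' standard deviation.  With the default `z = 1.96` this is the 95% interval
#' reported alongside each group geometric mean.
#'
#' @param x Positive values (>= 2 for a proper interval).  A single value
#'   yields a degenerate interval at the value, with a warning.
#' @param z Normal quantile; default `1.96` (95%).
#' @return Named numeric vector `c(lower, upper)`.
#' @examples
#' lognormal_ci(c(1.00, 1.35, 1.29, 1.54))  # (1.07, 1.53) to 2 dp
#' @export
lognormal_ci <- function(x, z = 1.96) {
  if (any(!is.finite(x) | x <= 0)) stop_("all values must be positive")
  if (length(x) < 2L) {
    warning("confidence interval undefined for a single value; ",
            "returning a degenerate interval", call. = FALSE)
    return(c(lower = x, upper = x))
  }
  lx <- log(x)
  h <- z * sd(lx) / sqrt(length(x))
  c(lower = exp(mean(lx) - h), upper = exp(mean(lx) + h))
}

#' Fold change between group geometric means
#'
#' The knockout-to-wild-type ratio of (unrounded) geometric means.
#'
#' @param gm_ko,gm_wt Positive geometric means for the knockout and
#'   wild-type groups.
#' @return `gm_ko / gm_wt`.
#' @export
fold_change <- function(gm_ko, gm_wt) {
  if (any(!is.finite(c(gm_ko, gm_wt))) || any(c(gm_ko, gm_wt) <= 0))
    stop_("geometric means must be positive")
  gm_ko / gm_wt
}

#' Per-genotype geometric-mean summaries
#'
#' @param agg Output of [aggregate_runs()] (optionally filtered with
#'   [complete_case_filter()]).
#' @param z Normal quantile for the log-scale confidence interval.
#' @return A data frame with one row per (accession, genotype):
#'   `geometric_mean`, `ci_lower`, `ci_upper`, `n_animals`.
#' @export
group_summary <- function(agg, z = 1.96) {
  sp <- split(agg, list(agg$accession, agg$genotype), drop = TRUE)
  rows <- lapply(sp, function(d) {
    v <- setNames(d$aggregated_ratio, d$animal_id)
    ci <- if (length(v) >= 2L) lognormal_ci(v, z = z)
          else suppressWarnings(lognormal_ci(v, z = z))
    data.frame(accession = d$accession[1L],
               protein_name = d$protein_name[1L],
               genotype = d$genotype[1L],
               geometric_mean = geometric_mean(v),
               ci_lower = unname(ci[1L]),
               ci_upper = unname(ci[2L]),
               n_animals = length(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$accession, out$genotype), ]
  rownames(out) <- NULL
  out
}
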