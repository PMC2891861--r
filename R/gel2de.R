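#' Read a 2DE spot-intensity table
#'
#' Long-format tab-separated table with columns `gel_id`, `group` (`"WT"` or
#' `"KO"`), `spot_id` and `intensity` (background-corrected spot volume).
#' Absence of a (gel, spot) row means the spot was not matched on that gel.
#'
#' @param path Path to the TSV file.
#' @return A validated data frame.
#' @export
read_spot_table <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE)
  validate_spot_table(x)
}

validate_spot_table <- function(x) {
  need <- c("gel_id", "group", "spot_id", "intensity")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop_("spot table is missing column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(x$intensity)) || any(x$intensity < 0))
    stop_("intensities must be finite and non-negative")
  bad <- setdiff(unique(x$group), c("WT", "KO"))
  if (length(bad))
    stop_("group must be 'WT' or 'KO'; found: ", paste(bad, collapse = ", "))
  if (anyDuplicated(paste(x$gel_id, x$spot_id, sep = "\r")))
    stop_("duplicate (gel_id, spot_id) records present")
  x
}

#' Normalize spot intensities within each gel
#'
#' Each spot's intensity is expressed as a percentage of the summed
#' intensity of all matched spots on its gel, cancelling gel-to-gel loading
#' and staining differences.  Normalization is defined on the full matched
#' set of a gel only; re-normalizing a subset would break the conservation
#' property and is not offered.
#'
#' @param x A spot table (see [read_spot_table()]).
#' @return `x` with an added `normalized_intensity` column; per gel these
#'   sum to 100.
#' @export
normalize_spots <- function(x) {
  x <- validate_spot_table(x)
  tot <- tapply(x$intensity, x$gel_id, sum)
  zero <- names(tot)[tot <= 0]
  if (length(zero))
    stop_("gel(s) with zero total intensity: ", paste(zero, collapse = ", "))
  x$normalized_intensity <- 100 * x$intensity / as.numeric(tot[x$gel_id])
  x
}

#' Spots eligible for group comparison
#'
#' A spot qualifies for quantitative comparison only when it was matched on
#' every gel of at least one treatment group (`require = "any"`, the default
#' rule) or of both groups (`require = "both"`).
#'
#' @param x A spot table.
#' @param require `"any"` or `"both"`.
#' @return Sorted character vector of eligible spot identifiers.
#' @export
spot_inclusion <- function(x, require = c("any", "both")) {
  require <- match.arg(require)
  x <- validate_spot_table(x)
  gels <- tapply(x$gel_id, x$group, function(g) unique(g))
  present <- function(spot_rows, group) {
    if (is.null(gels[[group]])) return(FALSE)
    all(gels[[group]] %in% spot_rows$gel_id[spot_rows$group == group])
  }
  sp <- split(x, x$spot_id)
  ok <- vapply(sp, function(d) {
    in_wt <- present(d, "WT")
    in_ko <- present(d, "KO")
    if (require == "any") in_wt || in_ko else in_wt && in_ko
  }, logical(1L))
  sort(names(ok)[ok])
}

#' Group statistics for a single 2DE spot
#'
#' Group means of normalized intensities with SD and SEM, the KO/WT fold
#' change computed from unrounded means, and a two-sided p-value from the
#' Shapiro-Wilk-gated test choice.
#'
#' @param x A spot table (normalized internally if needed).
#' @param spot A spot identifier, eligible under [spot_inclusion()].
#' @param require Eligibility rule, passed to [spot_inclusion()].
#' @return One-row data frame: `spot_id`, per-group `mean`, `sd`, `sem`,
#'   `n`, `fold_change`, `test_used`, `raw_p`.
#' @export
spot_stats <- function(x, spot, require = c("any", "both")) {
  require <- match.arg(require)
  if (!"normalized_intensity" %in% names(x)) x <- normalize_spots(x)
  if (!spot %in% spot_inclusion(x, require = require))
    stop_("spot '", spot, "' is not eligible under the '", require,
          "' inclusion rule")
  d <- x[x$spot_id == spot, ]
  wt <- d$normalized_intensity[d$group == "WT"]
  ko <- d$normalized_intensity[d$group == "KO"]
  if (!length(wt) || !length(ko))
    stop_("spot '", spot, "' has an empty group")
  ch <- choose_test(wt, ko)
  p <- suppressWarnings(raw_p(wt, ko, test = ch$test, log_scale = FALSE))
  data.frame(spot_id = spot,
             wt_mean = mean(wt), wt_sd = sd(wt),
             wt_sem = sd(wt) / sqrt(length(wt)), wt_n = length(wt),
             ko_mean = mean(ko), ko_sd = sd(ko),
             ko_sem = sd(ko) / sqrt(length(ko)), ko_n = length(ko),
             fold_change = mean(ko) / mean(wt),
             test_used = ch$test,
             raw_p = p,
             stringsAsFactors = FALSE)
}

#' Differential analysis of a full 2DE spot table
#'
#' Normalizes, applies the inclusion rule, computes [spot_stats()] for every
#' eligible spot and Benjamini-Hochberg adjusts the p-values.
#'
#' @inheritParams spot_stats
#' @param p_cut,bh_cut Acceptance thresholds as in [itraq_de()].
#' @return An object of class `gel_de` with elements `results`, `n_spots`,
#'   `n_eligible`, `params`.
#' @export
gel_de <- function(x, require = c("any", "both"), p_cut = 0.05,
                   bh_cut = 0.2) {
  require <- match.arg(require)
  x <- normalize_spots(x)
  elig <- spot_inclusion(x, require = require)
  if (!length(elig)) stop_("no spot is eligible for comparison")
  res <- do.call(rbind, lapply(elig, function(s)
    spot_stats(x, s, require = require)))
  res$bh_p <- bh_adjust(res$raw_p)
  res <- select_significant(res, p_cut = p_cut, bh_cut = bh_cut)
  rownames(res) <- NULL
  structure(list(results = res,
                 n_spots = length(unique(x$spot_id)),
                 n_eligible = length(elig),
                 params = list(require = require, p_cut = p_cut,
                               bh_cut = bh_cut)),
            class = "gel_de")
}

#' @export
print.gel_de <- function(x, ...) {
  cat("2DE spot differential analysis\n")
  cat(sprintf("  spots observed: %d; eligible: %d; significant: %d\n",
              x$n_spots, x$n_eligible, sum(x$results$significant)))
  invisible(x)
}
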