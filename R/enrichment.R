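#' Read gene sets in GMT format
#'
#' One tab-separated line per set: name, description, then member gene
#' identifiers.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop_("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1L), 1L)
  if (anyDuplicated(names(sets))) stop_("duplicate gene-set names in GMT")
  sets
}

#' Write gene sets in GMT format
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Optional per-set description column; recycled.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "na") {
  description <- rep_len(description, length(sets))
  lines <- mapply(function(nm, d, members)
    paste(c(nm, d, members), collapse = "\t"),
    names(sets), description, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set over-representation
#'
#' For each gene set, the probability that at least the observed number of
#' significant genes would fall in the set by chance, given the number of
#' significant genes and the size of the quantified universe: the
#' upper-tail hypergeometric probability `P(X >= k)` with `N` universe
#' genes, `K` of them in the set and `n` significant.  Set members outside
#' the universe are dropped (with a message); raw p-values are reported
#' without multiplicity correction, [bh_adjust()] being available
#' separately.
#'
#' @param significant Character vector of significant gene identifiers;
#'   must be a subset of `universe`.
#' @param universe Character vector: all quantified genes (the background).
#' @param genesets Named list of character vectors (see [read_gmt()]).
#' @return Data frame sorted by `p`: `set`, `N`, `K`, `n`, `k`, `p`,
#'   `neg_log10_p`.
#' @examples
#' hypergeom_enrich(c("g1", "g2"), paste0("g", 1:10),
#'                  list(s = paste0("g", 1:5)))
#' @export
hypergeom_enrich <- function(significant, universe, genesets) {
  universe <- unique(universe)
  significant <- unique(significant)
  outside <- setdiff(significant, universe)
  if (length(outside))
    stop_("significant gene(s) absent from the universe: ",
          paste(outside, collapse = ", "))
  if (is.null(names(genesets))) stop_("'genesets' must be named")
  N <- length(universe)
  n <- length(significant)
  dropped <- 0L
  rows <- lapply(names(genesets), function(nm) {
    members <- unique(genesets[[nm]])
    inU <- intersect(members, universe)
    dropped <<- dropped + (length(members) - length(inU))
    K <- length(inU)
    k <- length(intersect(inU, significant))
    p <- if (k == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, N = N, K = K, n = n, k = k, p = p,
               neg_log10_p = -log10(p), stringsAsFactors = FALSE)
  })
  if (dropped)
    message(dropped, " gene-set member(s) outside the universe dropped")
  out <- do.call(rbind, rows)
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out
}
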