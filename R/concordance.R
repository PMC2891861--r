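#' Cross-analysis concordance of significant protein lists
#'
#' Given named lists of protein identifiers from independent analyses (for
#' example two iTRAQ cohorts and a 2DE gel study), harmonizes identifiers
#' through an explicit alias map and reports the proteins present in at
#' least `k` lists together with the counts of every Venn region.  The alias
#' map is an auditable table, not fuzzy matching: the same protein can carry
#' different database accessions across analyses (e.g. the two major urinary
#' protein 6 accessions) and such pairs must be declared.
#'
#' @param lists Named list of character vectors of protein identifiers.
#' @param name_map Optional data frame with columns `alias` and `canonical`;
#'   every occurrence of an alias is replaced by its canonical identifier
#'   before comparison.  See [nrf2_accession_aliases()] for the packaged map.
#' @param k Minimum number of lists a protein must appear in; default 2.
#' @return An object of class `concordance`: list with `members` (sorted
#'   identifiers in >= k lists), `membership` (logical matrix, protein x
#'   analysis), `venn` (named counts per exclusive region, names like
#'   `"A&B"`), `k` and `name_map`.
#' @examples
#' concordance(list(a = c("A", "B"), b = c("B", "C"), c = "C"))$members
#' @export
concordance <- function(lists, name_map = NULL, k = 2) {
  if (is.null(names(lists)) || any(!nzchar(names(lists))))
    stop_("'lists' must be a named list")
  k <- check_count(k, "k")
  harmon <- function(ids, listname) {
    if (!is.null(name_map)) {
      if (!all(c("alias", "canonical") %in% names(name_map)))
        stop_("'name_map' needs columns 'alias' and 'canonical'")
      i <- match(ids, name_map$alias)
      ids[!is.na(i)] <- name_map$canonical[i[!is.na(i)]]
    }
    dup <- unique(ids[duplicated(ids)])
    if (length(dup))
      stop_("duplicate identifiers in list '", listname, "' after ",
            "harmonization: ", paste(dup, collapse = ", "))
    ids
  }
  lists <- mapply(harmon, lists, names(lists), SIMPLIFY = FALSE)
  all_ids <- sort(unique(unlist(lists)))
  membership <- vapply(lists, function(l) all_ids %in% l,
                       logical(length(all_ids)))
  if (is.null(dim(membership)))
    membership <- matrix(membership, nrow = length(all_ids),
                         dimnames = list(all_ids, names(lists)))
  rownames(membership) <- all_ids
  counts <- rowSums(membership)
  region <- apply(membership, 1L, function(m)
    paste(colnames(membership)[m], collapse = "&"))
  venn <- table(region)
  structure(
    list(members = all_ids[counts >= k],
         membership = membership,
         venn = setNames(as.integer(venn), names(venn)),
         k = k,
         name_map = name_map),
    class = "concordance")
}

#' @export
print.concordance <- function(x, ...) {
  cat(sprintf("Concordance across %d analyses (k >= %d): %d protein(s)\n",
              ncol(x$membership), x$k, length(x$members)))
  cat("Venn region counts:\n")
  print(x$venn)
  invisible(x)
}
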