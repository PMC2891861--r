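#' Read promoter sequences from FASTA
#'
#' Reads a FASTA file of upstream (5'-flanking) sequences, one record per
#' gene, upper-casing on the way in.  Only A/C/G/T/N are accepted; `N` never
#' matches any pattern letter or matrix column during scanning.
#'
#' Coordinate convention used throughout the scanners: the base immediately
#' 5' of the start codon is position -1 and the first base of an L-base
#' promoter is -L, so a W-base match starting i bases into the sequence
#' spans offsets `i - L - 1` to `i + W - L - 2` (inclusive, both negative).
#'
#' @param path FASTA file path.
#' @return Named character vector of upper-case sequences (class
#'   `promoter_set`).
#' @export
read_promoters <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  as_promoter_set(seqs)
}

#' Validate a named vector of promoter sequences
#'
#' @param seqs Named character vector of A/C/G/T/N sequences (mixed case
#'   accepted).
#' @return The upper-cased, validated vector.
#' @export
as_promoter_set <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop_("promoter sequences must be named by gene")
  dup <- unique(names(seqs)[duplicated(names(seqs))])
  if (length(dup))
    stop_("duplicate gene identifiers: ", paste(dup, collapse = ", "))
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) {
    stop_("empty sequence(s) for: ",
          paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop_("non-ACGTN characters in: ", paste(names(seqs)[bad], collapse = ", "))
  class(seqs) <- c("promoter_set", "character")
  seqs
}

#' Write promoter sequences as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width; default 60.
#' @return `path`, invisibly.
#' @export
write_promoters <- function(seqs, path, width = 60) {
  con <- file(path, "w")
  on.exit(close(con))
  for (g in names(seqs)) {
    writeLines(paste0(">", g), con)
    s <- seqs[[g]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(s)))
}

#' Background base frequencies of a promoter panel
#'
#' Pools base counts across all sequences and symmetrizes strand-wise:
#' `p(A) = p(T) =` mean A/T frequency and `p(C) = p(G) =` mean C/G
#' frequency, as appropriate for double-stranded scanning.  `N` bases are
#' ignored.
#'
#' @param seqs A `promoter_set` (or named character vector).
#' @return Named numeric vector `c(A, C, G, T)` summing to 1.
#' @export
background_frequencies <- function(seqs) {
  seqs <- as_promoter_set(seqs)
  chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1L]]
  n <- c(A = sum(chars == "A"), C = sum(chars == "C"),
         G = sum(chars == "G"), T = sum(chars == "T"))
  tot <- sum(n)
  if (tot == 0) stop_("no usable (non-N) bases in the sequence set")
  at <- (n[["A"]] + n[["T"]]) / (2 * tot)
  cg <- (n[["C"]] + n[["G"]]) / (2 * tot)
  c(A = at, C = cg, G = cg, T = at)
}
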