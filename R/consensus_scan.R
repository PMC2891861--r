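#' Degenerate-letter alphabets for consensus search
#'
#' Two conventions are provided.  `"are"` follows the definitions used with
#' the classical ARE consensus `RTGABNNNGCA`: R = G/C, B = G/C/T, N = any
#' base (note R here is *not* the standard purine code).  `"iupac"` is the
#' standard IUPAC degenerate code (R = A/G, B = C/G/T, ...).
#'
#' @param type `"are"` or `"iupac"`.
#' @return Named list mapping each pattern letter to its allowed bases.
#' @export
motif_alphabet <- function(type = c("are", "iupac")) {
  type <- match.arg(type)
  iupac <- list(
    A = "A", C = "C", G = "G", T = "T",
    R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
    K = c("G", "T"), M = c("A", "C"),
    B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
    V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  if (type == "are") {
    iupac$R <- c("G", "C")
    iupac$B <- c("G", "C", "T")
  }
  iupac
}

#' ARE consensus presets
#'
#' Three published variants of the antioxidant-response-element consensus
#' string circulate: the canonical `RTGABNNNGCA`, the `RTGABNNNTCA`
#' variant, and the shorter `RTGABNNNGA` "perfect ARE".  The default is the
#' canonical form.
#'
#' @param variant `"gca"` (default), `"tca"` or `"perfect"`.
#' @return The consensus pattern string.
#' @export
are_consensus <- function(variant = c("gca", "tca", "perfect")) {
  switch(match.arg(variant),
         gca = "RTGABNNNGCA",
         tca = "RTGABNNNTCA",
         perfect = "RTGABNNNGA")
}

pattern_sets <- function(pattern, alphabet) {
  if (is.character(alphabet) && length(alphabet) == 1L)
    alphabet <- motif_alphabet(alphabet)
  letters_ <- strsplit(toupper(pattern), "", fixed = TRUE)[[1L]]
  unknown <- setdiff(letters_, names(alphabet))
  if (length(unknown))
    stop_("pattern letter(s) without an alphabet entry: ",
          paste(unique(unknown), collapse = ", "))
  sets <- alphabet[letters_]
  if (any(!lengths(sets))) stop_("alphabet contains an empty base set")
  sets
}

# Start positions (1-based) of windows of `sets` matching in `chars`.
match_positions <- function(chars, sets) {
  L <- length(chars)
  W <- length(sets)
  if (W > L) return(integer(0))
  ok <- rep(TRUE, L - W + 1L)
  for (i in seq_len(W)) {
    ok <- ok & chars[i:(L - W + i)] %in% sets[[i]]
  }
  which(ok)
}

#' Scan promoters for a degenerate consensus pattern
#'
#' Every window (overlapping matches allowed) whose bases all belong to the
#' per-position allowed sets is a hit.  With `strands = "both"` the reverse
#' complement of each promoter is scanned as well and minus-strand hits are
#' reported in plus-strand coordinates with the plus-strand sequence.
#'
#' @param seqs A `promoter_set` (see [read_promoters()]).
#' @param pattern Degenerate pattern string, e.g. [are_consensus()].
#' @param alphabet `"are"` (default), `"iupac"`, or a list from
#'   [motif_alphabet()].
#' @param strands `"both"` (default) or `"plus"`.
#' @return Object of class `motif_scan`: list with `hits` (data frame:
#'   `gene`, `strand`, `start`, `end` as negative offsets from the start
#'   codon, `match`) and `counts` (named integer per gene, zeros included).
#' @examples
#' seqs <- as_promoter_set(c(g1 = "AAGTGAGAAAGCAAA"))
#' consensus_scan(seqs, "RTGABNNNGCA", strands = "plus")$counts
#' @export
consensus_scan <- function(seqs, pattern = are_consensus(),
                           alphabet = "are",
                           strands = c("both", "plus")) {
  strands <- match.arg(strands)
  seqs <- as_promoter_set(seqs)
  sets <- pattern_sets(pattern, alphabet)
  W <- length(sets)
  rows <- list()
  counts <- setNames(integer(length(seqs)), names(seqs))
  for (g in names(seqs)) {
    s <- seqs[[g]]
    L <- nchar(s)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    pos_rc <- integer(0)
    pos <- match_positions(chars, sets)
    if (length(pos)) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, strand = "+",
        start = pos - L - 1L, end = pos + W - L - 2L,
        match = substring(s, pos, pos + W - 1L),
        stringsAsFactors = FALSE)
    }
    if (strands == "both") {
      rc <- strsplit(revcomp(s), "", fixed = TRUE)[[1L]]
      pos_rc <- match_positions(rc, sets)
      if (length(pos_rc)) {
        ps <- L - (pos_rc + W - 1L) + 1L  # plus-strand start
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, strand = "-",
          start = ps - L - 1L, end = ps + W - L - 2L,
          match = substring(s, ps, ps + W - 1L),
          stringsAsFactors = FALSE)
      }
    }
    counts[[g]] <- length(pos) + length(pos_rc)
  }
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), strand = character(),
               start = integer(), end = integer(), match = character(),
               stringsAsFactors = FALSE)
  hits <- hits[order(hits$gene, hits$start, hits$strand), ]
  rownames(hits) <- NULL
  structure(list(hits = hits, counts = counts, pattern = toupper(pattern),
                 strands = strands),
            class = "motif_scan")
}

#' @export
print.motif_scan <- function(x, ...) {
  cat(sprintf("Consensus scan ('%s', strands = %s): %d hit(s) in %d gene(s)\n",
              x$pattern, x$strands, nrow(x$hits), sum(x$counts > 0)))
  invisible(x)
}
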