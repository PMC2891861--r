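BASES <- c("A", "C", "G", "T")

#' Read a position-specific probability matrix
#'
#' Simple whitespace-delimited dialect: four rows (bases A, C, G, T, in
#' that order or labelled in a leading column) by W position columns, with
#' an optional header line.  Each column must sum to 1 (tolerance 1e-6).
#'
#' @param path Path to the matrix file.
#' @return A 4 x W numeric matrix with rownames A/C/G/T.
#' @export
read_probability_matrix <- function(path) {
  raw <- read.table(path, header = FALSE, stringsAsFactors = FALSE,
                    fill = TRUE)
  # drop a header line (any row that is entirely non-numeric after col 1)
  num_like <- apply(raw, 1L, function(r)
    all(!is.na(suppressWarnings(as.numeric(r[-1L])))))
  raw <- raw[num_like, , drop = FALSE]
  labelled <- all(toupper(raw[[1L]]) %in% BASES)
  if (labelled) {
    rn <- toupper(raw[[1L]])
    m <- as.matrix(raw[-1L])
    rownames(m) <- rn
    m <- m[BASES, , drop = FALSE]
  } else {
    m <- suppressWarnings(apply(raw, 2L, as.numeric))
    m <- m[, colSums(is.na(m)) == 0, drop = FALSE]
    if (nrow(m) != 4L) stop_("expected 4 base rows (A, C, G, T)")
    rownames(m) <- BASES
  }
  mode(m) <- "numeric"
  colnames(m) <- NULL
  validate_probability_matrix(m)
}

#' Write a probability matrix in the package's tabular dialect
#'
#' @param m 4 x W probability matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_probability_matrix <- function(m, path) {
  m <- validate_probability_matrix(m)
  lines <- vapply(BASES, function(b)
    paste(c(b, format(m[b, ], digits = 10)), collapse = "\t"), character(1L))
  writeLines(lines, path)
  invisible(path)
}

validate_probability_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != 4L)
    stop_("probability matrix must be 4 x W with rows A, C, G, T")
  if (is.null(rownames(m))) rownames(m) <- BASES
  m <- m[BASES, , drop = FALSE]
  if (any(m < 0)) stop_("probabilities must be non-negative")
  cs <- colSums(m)
  if (any(abs(cs - 1) > 1e-6))
    stop_("each matrix column must sum to 1 (tolerance 1e-6)")
  m
}

#' Build a log-odds scoring matrix (PSSM)
#'
#' patser-style natural-log weights
#' `w(b, i) = ln((f(b, i) + eps) / ((1 + 4 eps) * p(b)))`, i.e. the
#' pseudocount-regularized probabilities (renormalized to a proper
#' distribution) against the background `p`.  A pseudocount is required
#' whenever the matrix contains zeros, otherwise weights would be infinite.
#'
#' @param prob 4 x W probability matrix (see [read_probability_matrix()]).
#' @param background Named base probabilities, e.g. from
#'   [background_frequencies()]; defaults to uniform.
#' @param pseudocount Regularization `eps`; default 0.001.
#' @return Object of class `pssm`: list with `weights` (4 x W), `prob`,
#'   `background`, `pseudocount`, `width`.
#' @export
build_pssm <- function(prob, background = c(A = 0.25, C = 0.25, G = 0.25,
                                            T = 0.25),
                       pseudocount = 0.001) {
  prob <- validate_probability_matrix(prob)
  eps <- check_nonneg(pseudocount, "pseudocount")
  background <- background[BASES]
  if (any(is.na(background)) || any(background < 0) ||
      abs(sum(background) - 1) > 1e-6)
    stop_("background must be named A/C/G/T probabilities summing to 1")
  if (eps == 0 && any(prob == 0))
    stop_("pseudocount = 0 with zero probabilities gives infinite weights; ",
          "use a positive pseudocount")
  if (eps == 0 && any(background == 0))
    stop_("zero background frequency requires a positive pseudocount")
  w <- log((prob + eps) / ((1 + 4 * eps) * matrix(background, 4L, ncol(prob))))
  structure(list(weights = w, prob = prob,
                 background = background, pseudocount = eps,
                 width = ncol(prob)),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("PSSM: width %d, pseudocount %g\n", x$width, x$pseudocount))
  cat("background:", paste(sprintf("%s=%.3f", BASES, x$background),
                           collapse = " "), "\n")
  print(round(x$weights, 3))
  invisible(x)
}

# Window scores for one sequence; NA where the window overlaps an N.
window_scores <- function(chars, w) {
  L <- length(chars)
  W <- ncol(w)
  if (W > L) return(numeric(0))
  idx <- match(chars, BASES)  # N -> NA
  s <- numeric(L - W + 1L)
  for (i in seq_len(W)) {
    s <- s + w[, i][idx[i:(L - W + i)]]
  }
  s
}

#' Scan promoters with a PSSM
#'
#' Scores every window as the sum of per-position log-odds weights; windows
#' with score strictly above `threshold` are reported as matrix matches
#' (the conventional cut-off is a score of 1, in natural-log units).
#' Windows overlapping an `N` are skipped.  Minus-strand hits are reported
#' in plus-strand coordinates; their `match` column shows the plus-strand
#' sequence.
#'
#' @param seqs A `promoter_set`.
#' @param pssm A `pssm` object from [build_pssm()].
#' @param threshold Score cut-off (exclusive); default 1.
#' @param strands `"both"` (default) or `"plus"`.
#' @return Object of class `pssm_scan`: list with `hits` (data frame:
#'   `gene`, `strand`, `start`, `end`, `match`, `score`) and `summary` (one
#'   row per gene: `n_matches`, `highest_score`, `mean_score`, `sd_score`,
#'   best-hit `best_start`, `best_end`, `best_strand`, and `best_seq`
#'   rendered with the matched core upper-case between lower-case flanks).
#'   Genes shorter than the matrix width are reported with zero windows and
#'   a warning.
#' @export
pssm_scan <- function(seqs, pssm, threshold = 1,
                      strands = c("both", "plus")) {
  strands <- match.arg(strands)
  if (!inherits(pssm, "pssm")) stop_("'pssm' must come from build_pssm()")
  seqs <- as_promoter_set(seqs)
  W <- pssm$width
  rows <- list()
  summ <- list()
  n_skipped <- 0L
  for (g in names(seqs)) {
    s <- seqs[[g]]
    L <- nchar(s)
    if (L < W)
      warning("promoter '", g, "' is shorter than the matrix width; ",
              "no window scored", call. = FALSE)
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    sc_p <- window_scores(chars, pssm$weights)
    n_skipped <- n_skipped + sum(is.na(sc_p))
    hit_df <- NULL
    ip <- which(!is.na(sc_p) & sc_p > threshold)
    if (length(ip)) {
      hit_df <- data.frame(gene = g, strand = "+",
                           start = ip - L - 1L, end = ip + W - L - 2L,
                           match = substring(s, ip, ip + W - 1L),
                           score = sc_p[ip], stringsAsFactors = FALSE)
    }
    if (strands == "both") {
      rc <- strsplit(revcomp(s), "", fixed = TRUE)[[1L]]
      sc_m <- window_scores(rc, pssm$weights)
      n_skipped <- n_skipped + sum(is.na(sc_m))
      im <- which(!is.na(sc_m) & sc_m > threshold)
      if (length(im)) {
        ps <- L - (im + W - 1L) + 1L
        hit_df <- rbind(hit_df, data.frame(
          gene = g, strand = "-",
          start = ps - L - 1L, end = ps + W - L - 2L,
          match = substring(s, ps, ps + W - 1L),
          score = sc_m[im], stringsAsFactors = FALSE))
      }
    }
    if (!is.null(hit_df)) rows[[length(rows) + 1L]] <- hit_df
    summ[[g]] <- summarize_gene_hits(g, hit_df, s, L, W)
  }
  if (n_skipped)
    message(n_skipped, " window(s) containing N skipped")
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene = character(), strand = character(), start = integer(),
               end = integer(), match = character(), score = numeric(),
               stringsAsFactors = FALSE)
  hits <- hits[order(hits$gene, hits$start, hits$strand), ]
  rownames(hits) <- NULL
  summary <- do.call(rbind, summ)
  rownames(summary) <- NULL
  structure(list(hits = hits, summary = summary, threshold = threshold,
                 strands = strands, width = W),
            class = "pssm_scan")
}

summarize_gene_hits <- function(g, hit_df, s, L, W, flank = 4L) {
  if (is.null(hit_df) || !nrow(hit_df)) {
    return(data.frame(gene = g, n_matches = 0L, highest_score = NA_real_,
                      mean_score = NA_real_, sd_score = NA_real_,
                      best_start = NA_integer_, best_end = NA_integer_,
                      best_strand = NA_character_, best_seq = NA_character_,
                      stringsAsFactors = FALSE))
  }
  b <- hit_df[which.max(hit_df$score), ]
  pos <- b$start + L + 1L  # back to 1-based
  left <- substring(s, max(1L, pos - flank), pos - 1L)
  right <- substring(s, pos + W, min(L, pos + W + flank - 1L))
  data.frame(gene = g, n_matches = nrow(hit_df),
             highest_score = max(hit_df$score),
             mean_score = mean(hit_df$score),
             sd_score = if (nrow(hit_df) > 1L) sd(hit_df$score) else NA_real_,
             best_start = b$start, best_end = b$end,
             best_strand = b$strand,
             best_seq = paste0(tolower(left), toupper(b$match),
                               tolower(right)),
             stringsAsFactors = FALSE)
}

#' @export
print.pssm_scan <- function(x, ...) {
  cat(sprintf("PSSM scan (width %d, score > %g, strands = %s): %d hit(s) in %d gene(s)\n",
              x$width, x$threshold, x$strands, nrow(x$hits),
              sum(x$summary$n_matches > 0)))
  invisible(x)
}

#' Panel-level means of per-gene scan statistics
#'
#' Arithmetic means of per-gene consensus counts and matrix-match
#' statistics over declared gene groups (e.g. all genes, up-regulated,
#' down-regulated, significant), mirroring the footer rows of a promoter
#' analysis report.
#'
#' @param gene_stats Data frame with a `gene` column plus numeric columns
#'   to average — typically the `summary` of [pssm_scan()] merged with the
#'   `counts` of [consensus_scan()].
#' @param groups Named list of gene-identifier vectors.
#' @return Data frame, one row per group, with the group name, size and
#'   the mean of every numeric column.  Empty groups are dropped with a
#'   warning.
#' @export
panel_summary <- function(gene_stats, groups) {
  if (!"gene" %in% names(gene_stats)) stop_("'gene_stats' needs a 'gene' column")
  if (is.null(names(groups))) stop_("'groups' must be a named list")
  num <- names(gene_stats)[vapply(gene_stats, is.numeric, logical(1L))]
  rows <- list()
  for (nm in names(groups)) {
    d <- gene_stats[gene_stats$gene %in% groups[[nm]], , drop = FALSE]
    if (!nrow(d)) {
      warning("group '", nm, "' matches no gene; omitted", call. = FALSE)
      next
    }
    means <- lapply(d[num], function(v) mean(v, na.rm = TRUE))
    rows[[nm]] <- data.frame(group = nm, n_genes = nrow(d),
                             as.data.frame(means),
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
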