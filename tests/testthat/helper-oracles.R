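# Brute-force oracles, deliberately naive and independent of the package's
# scanning/adjustment code paths.

oracle_alphabet <- function(type = "are") {
  a <- list(A = "A", C = "C", G = "G", T = "T",
            R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
            W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
            B = c("C", "G", "T"), D = c("A", "G", "T"),
            H = c("A", "C", "T"), V = c("A", "C", "G"),
            N = c("A", "C", "G", "T"))
  if (type == "are") {
    a$R <- c("G", "C")
    a$B <- c("G", "C", "T")
  }
  a
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]), collapse = "")
}

# count of degenerate-pattern matches, window by window
oracle_consensus_count <- function(seq, pattern, type = "are",
                                   strands = "both") {
  alpha <- oracle_alphabet(type)
  count_one <- function(s) {
    sc <- strsplit(s, "")[[1]]
    pc <- strsplit(pattern, "")[[1]]
    W <- length(pc)
    L <- length(sc)
    if (W > L) return(0L)
    n <- 0L
    for (start in 1:(L - W + 1)) {
      ok <- TRUE
      for (j in 1:W) {
        if (!sc[start + j - 1] %in% alpha[[pc[j]]]) { ok <- FALSE; break }
      }
      if (ok) n <- n + 1L
    }
    n
  }
  n <- count_one(seq)
  if (strands == "both") n <- n + count_one(oracle_revcomp(seq))
  n
}

# per-window PSSM scores; windows overlapping N dropped
oracle_pssm_scores <- function(seq, weights, strands = "both") {
  score_one <- function(s) {
    sc <- strsplit(s, "")[[1]]
    W <- ncol(weights)
    L <- length(sc)
    if (W > L) return(numeric(0))
    out <- numeric(0)
    for (start in 1:(L - W + 1)) {
      win <- sc[start:(start + W - 1)]
      if (any(!win %in% rownames(weights))) next
      v <- 0
      for (j in 1:W) v <- v + unname(weights[win[j], j])
      out <- c(out, v)
    }
    out
  }
  s <- score_one(seq)
  if (strands == "both") s <- c(s, score_one(oracle_revcomp(seq)))
  s
}

# literal step-up definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- sapply(i:m, function(j) min(1, p[o[j]] * m / j))
    q[o[i]] <- min(cand)
  }
  q
}

# upper-tail hypergeometric by exhaustive enumeration of draws
oracle_hyper_upper <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  inset <- seq_len(K)
  mean(apply(draws, 2, function(d) sum(d %in% inset) >= k))
}

random_seqs <- function(n, len, seed, n_rate = 0) {
  set.seed(seed)
  sapply(seq_len(n), function(i) {
    b <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
    if (n_rate > 0) b[runif(len) < n_rate] <- "N"
    paste(b, collapse = "")
  })
}
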