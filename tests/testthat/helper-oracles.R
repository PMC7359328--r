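# Independent oracles used across the suite. Each is a deliberately naive
# implementation kept separate from the package code paths it checks.

# Brute-force one-sample KS statistic: sup over the empirical CDF step points.
bruteKsD <- function(values, cdf) {
  x <- sort(values)
  n <- length(x)
  F <- cdf(x)
  max(pmax(seq_len(n) / n - F, F - (seq_len(n) - 1) / n))
}

# Reference Benjamini-Hochberg step-up: q_i = min over j >= i (by sorted p)
# of p_(j) * m / j, mapped back to input order.
bruteBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Regex-based TTTV PAM scanner oracle: overlapping matches on both strands,
# reported as (strand, 0-based forward PAM start, spacer) keys.
regexPamOracle <- function(seq) {
  seq <- as.character(seq)
  len <- nchar(seq)
  scan1 <- function(s) {
    hits <- gregexpr("(?=TTT[ACG][ACGT]{23})", s, perl = TRUE)[[1]]
    if (hits[1] == -1) integer(0) else as.integer(hits)
  }
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  fwd <- scan1(seq)
  rev <- scan1(rc)
  keys <- c(
    sprintf("+:%d:%s", fwd - 1L, substring(seq, fwd + 4L, fwd + 26L)),
    sprintf("-:%d:%s", len - (rev - 1L) - 4L, substring(rc, rev + 4L, rev + 26L)))
  sort(keys)
}

# Quadratic DP Levenshtein distance (substitutions, indels, tails all 1).
bruteEditDistance <- function(a, b) {
  a <- strsplit(a, "")[[1]]
  b <- strsplit(b, "")[[1]]
  D <- matrix(0L, length(a) + 1L, length(b) + 1L)
  D[, 1] <- 0:length(a)
  D[1, ] <- 0:length(b)
  for (i in seq_along(a))
    for (j in seq_along(b))
      D[i + 1, j + 1] <- min(D[i, j + 1] + 1L, D[i + 1, j] + 1L,
                             D[i, j] + (a[i] != b[j]))
  D[length(a) + 1L, length(b) + 1L]
}

# Brute-force read assignment under the mapping rules.
bruteMapRead <- function(read, refSeqs, ids, minLen = 60, maxMM = 2) {
  if (nchar(read) < minLen) return("discarded")
  d <- vapply(refSeqs, bruteEditDistance, integer(1), a = read)
  m <- min(d)
  if (m > maxMM || sum(d == m) > 1L) return("unmapped")
  ids[which.min(d)]
}

# Exact two-sided Mann-Whitney p by complete enumeration of rank splits.
bruteMannWhitneyP <- function(x, y) {
  all <- c(x, y)
  n <- length(x)
  U <- function(ix) {
    xs <- all[ix]
    ys <- all[-ix]
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  obs <- U(seq_len(n))
  us <- combn(length(all), n, U)
  mu <- length(x) * length(y) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

randomSeq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
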