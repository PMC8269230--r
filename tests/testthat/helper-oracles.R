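# Independent oracles, deliberately written with plain string operations and
# naive loops so they share no code path with the package implementation.

# All k-words of a string, in order.
oracle_words <- function(s, k) {
  n <- nchar(s) - k + 1
  substring(s, 1:n, k:(n + k - 1))
}

oracle_count <- function(s, k) {
  words <- oracle_words(s, k)
  all_words <- sort(apply(expand.grid(rep(list(c("A", "C", "G", "T")), k)),
                          1, paste, collapse = ""))
  tab <- table(factor(words, levels = all_words))
  setNames(as.numeric(tab), all_words)
}

# Brute-force d2*: direct evaluation of the centered, Markov-normalized
# k-mer correlation formula.
oracle_d2star <- function(s1, s2, k, order = 0) {
  prof <- function(s) {
    L <- nchar(s)
    N <- oracle_count(s, k)
    words <- names(N)
    p_word <- vapply(words, function(w) {
      if (order == 0) {
        chars <- strsplit(w, "")[[1]]
        base_n <- vapply(c("A", "C", "G", "T"), function(b)
          sum(strsplit(s, "")[[1]] == b), numeric(1))
        prod(base_n[chars] / L)
      } else {
        rc <- oracle_count(s, order)
        r1c <- oracle_count(s, order + 1)
        p <- rc[substr(w, 1, order)] / sum(rc)
        for (i in (order + 1):k) {
          ctx <- substr(w, i - order, i - 1)
          tot <- sum(r1c[paste0(ctx, c("A", "C", "G", "T"))])
          p <- p * if (tot > 0) r1c[paste0(ctx, substr(w, i, i))] / tot else 0
        }
        unname(p)
      }
    }, numeric(1))
    E <- (L - k + 1) * p_word
    list(X = N - E, E = E)
  }
  p1 <- prof(s1); p2 <- prof(s2)
  ok <- p1$E > 0 & p2$E > 0
  X <- p1$X[ok]; Y <- p2$X[ok]; EX <- p1$E[ok]; EY <- p2$E[ok]
  D <- sum(X * Y / sqrt(EX * EY))
  0.5 * (1 - D / (sqrt(sum(X^2 / EX)) * sqrt(sum(Y^2 / EY))))
}

# Exhaustive affine-gap (Gotoh) local alignment score, one strand.
oracle_sw_score <- function(q, s, match = 1, mismatch = -3, gap_open = 5,
                            gap_ext = 2) {
  qc <- strsplit(q, "")[[1]]; sc <- strsplit(s, "")[[1]]
  n <- length(qc); m <- length(sc)
  M <- matrix(-Inf, n + 1, m + 1); E <- M; F_ <- M
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(M[i, j - 1] - gap_open - gap_ext,
                     E[i, j - 1] - gap_ext)
      F_[i, j] <- max(M[i - 1, j] - gap_open - gap_ext,
                      F_[i - 1, j] - gap_ext)
      sub <- if (qc[i - 1] == sc[j - 1]) match else mismatch
      M[i, j] <- sub + max(0, M[i - 1, j - 1], E[i - 1, j - 1],
                           F_[i - 1, j - 1])
      best <- max(best, M[i, j], E[i, j], F_[i, j])
    }
  }
  best
}

# Best local score over both strands of the query.
oracle_sw_both <- function(q, s, ...) {
  rc <- paste(rev(chartr("ACGT", "TGCA", strsplit(q, "")[[1]])),
              collapse = "")
  max(oracle_sw_score(q, s, ...), oracle_sw_score(rc, s, ...))
}

# Sliding Hamming-distance scan for a pattern on one strand.
oracle_hamming_hits <- function(read, pat, max_mm) {
  n <- nchar(read) - nchar(pat) + 1
  if (n < 1) return(integer(0))
  which(vapply(1:n, function(i) {
    sum(strsplit(substr(read, i, i + nchar(pat) - 1), "")[[1]] !=
          strsplit(pat, "")[[1]]) <= max_mm
  }, logical(1))) - 1L
}

oracle_revcomp <- function(x) {
  vapply(x, function(s) paste(rev(chartr("ACGT", "TGCA",
                                         strsplit(s, "")[[1]])),
                              collapse = ""), character(1), USE.NAMES = FALSE)
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
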