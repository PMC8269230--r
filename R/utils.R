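#' @importFrom methods is
#' @importFrom stats rbinom rnorm rpois runif t.test cor cmdscale dist sd setNames
#' @importFrom utils combn read.delim write.table packageVersion head
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream, so every generator is a pure function of (arguments, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific seed from a master seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 2147480000 + offset * 97003 + 11) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

as_dna <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "DNAString")) return(Biostrings::DNAStringSet(x))
  out <- Biostrings::DNAStringSet(toupper(as.character(x)))
  names(out) <- names(x)
  out
}

as_seq_chr <- function(x) {
  if (is(x, "DNAStringSet") || is(x, "DNAString")) {
    out <- as.character(x)
  } else {
    out <- toupper(as.character(x))
    names(out) <- names(x)
  }
  out
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Random DNA string(s), uniform base composition unless probs given.
random_dna <- function(n, length, probs = rep(0.25, 4)) {
  vapply(seq_len(n), function(i) {
    paste(sample(DNA_BASES, length, replace = TRUE, prob = probs), collapse = "")
  }, character(1))
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

check_prob <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
    stop(sprintf("`%s` must be a number in [%g, %g]", name, lo, hi), call. = FALSE)
  invisible(x)
}
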