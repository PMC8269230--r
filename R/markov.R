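#' Markov models of nucleotide composition
#'
#' A `markov_model` holds the transition structure of an order-`r` Markov
#' chain over the alphabet \{A, C, G, T\}: a `4^r x 4` matrix of transition
#' probabilities (rows are the `r`-mer contexts in lexicographic order,
#' columns the next base) and an initial distribution over contexts.  Models
#' drive the synthetic genome generator and supply the expected k-mer counts
#' used by the d2* dissimilarity.
#'
#' @param transition numeric matrix, `4^order` rows (contexts, lexicographic)
#'   by 4 columns (A, C, G, T); each row must sum to 1.
#' @param order non-negative integer, the chain order `r`. Order 0 means
#'   i.i.d. bases; `transition` is then a single row of base probabilities.
#' @param init optional probability vector of length `4^order` over starting
#'   contexts; defaults to uniform.
#' @return An object of class `markov_model`.
#' @examples
#' m <- markov_model(matrix(c(0, 0.5, 0.5, 0), nrow = 1), order = 0)
#' s <- generate_genome(m, 1000, seed = 1)
#' @export
markov_model <- function(transition, order, init = NULL) {
  order <- as.integer(order)
  if (order < 0) stop("`order` must be >= 0", call. = FALSE)
  transition <- as.matrix(transition)
  nctx <- 4L^order
  if (nrow(transition) != nctx || ncol(transition) != 4L)
    stop(sprintf("`transition` must be %d x 4 for order %d", nctx, order),
         call. = FALSE)
  if (any(transition < 0))
    stop("transition probabilities must be >= 0", call. = FALSE)
  if (any(abs(rowSums(transition) - 1) > 1e-12))
    stop("each transition row must sum to 1 (within 1e-12)", call. = FALSE)
  if (is.null(init)) init <- rep(1 / nctx, nctx)
  if (length(init) != nctx || any(init < 0) || abs(sum(init) - 1) > 1e-12)
    stop("`init` must be a probability vector of length 4^order", call. = FALSE)
  structure(list(order = order, transition = transition, init = as.numeric(init)),
            class = "markov_model")
}

#' @export
print.markov_model <- function(x, ...) {
  cat(sprintf("Markov model of order %d (%d contexts)\n", x$order,
              nrow(x$transition)))
  invisible(x)
}

#' Estimate a Markov model from a sequence
#'
#' Maximum-likelihood transition estimates from the `(order+1)`-mer counts of
#' `sequence`; contexts never observed fall back to a uniform row so the
#' model remains generative. The initial context distribution is the
#' empirical `order`-mer frequency.
#'
#' @param sequence a DNA string (character or `DNAString(Set)`), A/C/G/T only.
#' @param order chain order `r >= 0`.
#' @return A `markov_model`.
#' @export
train_markov <- function(sequence, order) {
  order <- as.integer(order)
  seqs <- as_dna(sequence)
  if (length(seqs) != 1L) stop("train on a single sequence", call. = FALSE)
  L <- Biostrings::width(seqs)
  if (L < order + 1L) stop("sequence shorter than order + 1", call. = FALSE)
  kc <- Biostrings::oligonucleotideFrequency(seqs[[1]], width = order + 1L)
  mat <- matrix(as.numeric(kc), ncol = 4L, byrow = TRUE)
  tot <- rowSums(mat)
  trans <- mat / ifelse(tot > 0, tot, 1)
  trans[tot == 0, ] <- 0.25
  if (order == 0L) {
    init <- rep(1, 1)
  } else {
    rc <- Biostrings::oligonucleotideFrequency(seqs[[1]], width = order)
    init <- as.numeric(rc) / sum(rc)
  }
  markov_model(trans, order, init = init)
}

#' Draw a random Markov model
#'
#' Transition rows are independent symmetric Dirichlet draws; lower
#' `concentration` gives more idiosyncratic (easier to tell apart)
#' compositional signatures.
#'
#' @param order chain order.
#' @param concentration Dirichlet concentration parameter (> 0).
#' @param seed integer seed.
#' @return A `markov_model`.
#' @export
random_markov <- function(order, concentration = 5, seed = 1) {
  with_seed(seed, {
    nctx <- 4L^as.integer(order)
    g <- matrix(stats::rgamma(nctx * 4L, shape = concentration), nrow = nctx)
    markov_model(g / rowSums(g), order)
  })
}

#' Generate a genome from a Markov model
#'
#' Simulates a nucleotide sequence of exactly `length` bases from `model`.
#' Deterministic for fixed `(model, length, seed)`.
#'
#' @param model a [markov_model()].
#' @param length sequence length in nt; must be `>= order + 1`.
#' @param seed integer seed.
#' @return A single character string over A/C/G/T.
#' @export
generate_genome <- function(model, length, seed) {
  stopifnot(inherits(model, "markov_model"))
  length <- as.integer(length)
  r <- model$order
  if (length < r + 1L)
    stop("`length` must be >= order + 1", call. = FALSE)
  with_seed(seed, {
    if (r == 0L) {
      return(paste(sample(DNA_BASES, length, replace = TRUE,
                          prob = model$transition[1, ]), collapse = ""))
    }
    nctx <- 4L^r
    ctx0 <- sample.int(nctx, 1L, prob = model$init) - 1L
    # decode starting context into its r bases (most-significant first)
    out <- integer(length)
    tmp <- ctx0
    for (i in r:1) { out[i] <- tmp %% 4L; tmp <- tmp %/% 4L }
    cum <- t(apply(model$transition, 1L, cumsum))
    u <- runif(length - r)
    ctx <- ctx0
    mod <- 4L^(r - 1L)
    for (i in (r + 1L):length) {
      row <- cum[ctx + 1L, ]
      ui <- u[i - r]
      b <- (ui > row[1L]) + (ui > row[2L]) + (ui > row[3L])
      out[i] <- b
      ctx <- (ctx %% mod) * 4L + b
    }
    paste(DNA_BASES[out + 1L], collapse = "")
  })
}
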