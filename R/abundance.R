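#' Filter alignment records by percent identity
#'
#' Keeps records whose identity (`n_matches / aligned_length`) is at least
#' `min_identity` (inclusive).  Records with `aligned_length == 0` are
#' dropped with a warning.
#'
#' @param records data frame with at least `aligned_length` and `n_matches`.
#' @param min_identity minimum identity in `[0, 1]` (default 0.90).
#' @return The filtered data frame.
#' @export
filter_alignments_by_identity <- function(records, min_identity = 0.90) {
  check_prob(min_identity, "min_identity")
  zero <- records$aligned_length == 0
  if (any(zero)) {
    warning(sum(zero), " record(s) with zero aligned length dropped")
    records <- records[!zero, , drop = FALSE]
  }
  records[records$n_matches / records$aligned_length >= min_identity, ,
          drop = FALSE]
}

#' Breadth-filtered coverage of one target in one sample
#'
#' Per-base depth is computed by interval stacking of the aligned target
#' spans.  Breadth is the fraction of positions with depth >= 1; mean depth
#' is averaged over all positions of the target.  The target is retained only
#' when breadth reaches `breadth_threshold` (the guard against spurious
#' coverage); the normalized abundance
#' `mean_depth * scale / library_read_count` is reported only for retained
#' targets (`NA` otherwise).
#'
#' @param records alignment records for one (target, sample): data frame with
#'   `target_start`, `target_end` (0-based half-open).
#' @param target_length target length, nt (> 0).
#' @param library_read_count total reads in the sample's library.
#' @param scale normalization constant (depth per `scale` library reads);
#'   default 1e8.
#' @param breadth_threshold retention threshold on breadth (default 0.75,
#'   inclusive).
#' @return One-row data frame: `breadth`, `mean_depth`, `retained`,
#'   `normalized_abundance`.
#' @export
compute_coverage <- function(records, target_length, library_read_count,
                             scale = 1e8, breadth_threshold = 0.75) {
  if (target_length <= 0) stop("target_length must be > 0", call. = FALSE)
  if (nrow(records) == 0) {
    breadth <- 0; mean_depth <- 0
  } else {
    s <- pmax(records$target_start, 0L)
    e <- pmin(records$target_end, target_length)
    ir <- IRanges::IRanges(start = s + 1L, end = e)
    cov <- IRanges::coverage(ir, width = target_length)
    breadth <- sum(S4Vectors::runLength(cov)[S4Vectors::runValue(cov) >= 1]) /
      target_length
    mean_depth <- sum(as.numeric(S4Vectors::runLength(cov)) *
                        S4Vectors::runValue(cov)) / target_length
  }
  retained <- breadth >= breadth_threshold
  data.frame(breadth = breadth, mean_depth = mean_depth, retained = retained,
             normalized_abundance = if (retained)
               mean_depth * scale / library_read_count else NA_real_)
}

#' Long-format abundance table across samples and targets
#'
#' Applies identity filtering and [compute_coverage()] to every
#' (sample, target) combination present in `records`.
#'
#' @param records data frame with `sample_id`, `target_id`, `target_start`,
#'   `target_end`, `aligned_length`, `n_matches`.
#' @param target_lengths named vector of target lengths.
#' @param library_sizes named vector of per-sample library read counts.
#' @param min_identity,breadth_threshold,scale see
#'   [filter_alignments_by_identity()] and [compute_coverage()].
#' @return Data frame `sample`, `target`, `breadth`, `mean_depth`,
#'   `retained`, `normalized_abundance` (all targets x all samples).
#' @export
abundance_table <- function(records, target_lengths, library_sizes,
                            min_identity = 0.90, breadth_threshold = 0.75,
                            scale = 1e8) {
  records <- filter_alignments_by_identity(records, min_identity)
  samples <- names(library_sizes)
  targets <- names(target_lengths)
  grid <- expand.grid(sample = samples, target = targets,
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    rec <- records[records$sample_id == grid$sample[i] &
                     records$target_id == grid$target[i], , drop = FALSE]
    cbind(grid[i, , drop = FALSE],
          compute_coverage(rec, target_lengths[[grid$target[i]]],
                           library_sizes[[grid$sample[i]]], scale = scale,
                           breadth_threshold = breadth_threshold))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pivot a long abundance table into a samples x targets matrix
#'
#' Non-retained combinations contribute 0.
#'
#' @param tab output of [abundance_table()].
#' @return Numeric matrix, samples in rows.
#' @export
abundance_matrix <- function(tab) {
  samples <- unique(tab$sample); targets <- unique(tab$target)
  m <- matrix(0, length(samples), length(targets),
              dimnames = list(samples, targets))
  keep <- tab$retained & !is.na(tab$normalized_abundance)
  m[cbind(tab$sample[keep], tab$target[keep])] <-
    tab$normalized_abundance[keep]
  m
}

#' Welch's unequal-variance t test between two abundance groups
#'
#' Two-sided, with Welch–Satterthwaite degrees of freedom.  If both groups
#' are constant with identical means the statistic is defined as 0 with
#' p = 1.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return List `t`, `df`, `p`.
#' @export
welch_compare <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stop("each group needs >= 2 values", call. = FALSE)
  if (sd(x) == 0 && sd(y) == 0) {
    if (isTRUE(all.equal(mean(x), mean(y))))
      return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = NA_real_, p = 0))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Row-normalize an abundance matrix to relative abundances
#'
#' Each sample row is divided by its total; all-zero rows are left at zero
#' and recorded in the `zero_rows` attribute.
#'
#' @param m non-negative numeric matrix, samples in rows.
#' @return Matrix of the same shape with rows summing to 1 (or 0).
#' @export
relative_abundance <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative entries", call. = FALSE)
  tot <- rowSums(m)
  out <- m / ifelse(tot > 0, tot, 1)
  attr(out, "zero_rows") <- rownames(m)[tot == 0] %||%
    which(tot == 0)
  out
}
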