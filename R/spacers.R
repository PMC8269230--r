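#' Find direct-repeat hits on a read
#'
#' Scans the read and its reverse complement for occurrences of the DR with
#' at most `max_mismatch` substitutions (Hamming distance; no indels).
#' Overlapping hits are reported.  Positions are 0-based on the forward
#' orientation of the read; a `-` strand hit means the DR matches the
#' read's reverse complement at that forward-coordinate window.
#'
#' @param read read sequence (character).
#' @param dr direct repeat sequence.
#' @param max_mismatch maximum substitutions (default 3).
#' @return Data frame `position`, `strand`, sorted by position.
#' @export
find_dr_hits <- function(read, dr, max_mismatch = 3) {
  read <- toupper(as_seq_chr(read)); dr <- toupper(as_seq_chr(dr))
  if (nchar(dr) > nchar(read))
    return(data.frame(position = integer(0), strand = character(0)))
  rd <- Biostrings::DNAString(read)
  hit_pos <- function(pattern) {
    m <- Biostrings::matchPattern(pattern, rd, max.mismatch = max_mismatch,
                                  with.indels = FALSE)
    Biostrings::start(m) - 1L
  }
  fwd <- hit_pos(dr)
  rev <- hit_pos(revcomp_chr(dr))
  out <- data.frame(position = c(fwd, rev),
                    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
                    stringsAsFactors = FALSE)
  out[order(out$position), , drop = FALSE]
}

#' Extract spacers between consecutive direct-repeat hits
#'
#' For each pair of consecutive same-strand DR hits on a read, the
#' intervening sequence is emitted if its length is within
#' `[min_spacer, max_spacer]`.  Spacers between `-` strand hits are reported
#' as their reverse complement, i.e. on the forward orientation of the
#' CRISPR array.
#'
#' @param read read sequence.
#' @param hits data frame from [find_dr_hits()].
#' @param dr the direct repeat (its length delimits the spacer windows).
#' @param max_spacer,min_spacer spacer length bounds, nt (defaults 60 / 15).
#' @return Data frame `spacer`, `strand`, `start` (0-based, forward read
#'   coordinates).
#' @export
extract_spacers <- function(read, hits, dr, max_spacer = 60,
                            min_spacer = 15) {
  read <- toupper(as_seq_chr(read))
  drlen <- nchar(dr)
  out <- list()
  for (st in c("+", "-")) {
    pos <- sort(hits$position[hits$strand == st])
    if (length(pos) < 2) next
    for (i in seq_len(length(pos) - 1L)) {
      s0 <- pos[i] + drlen          # spacer start (0-based)
      s1 <- pos[i + 1L]             # spacer end (half-open)
      len <- s1 - s0
      if (len < min_spacer || len > max_spacer) next
      sp <- substr(read, s0 + 1L, s1)
      if (st == "-") sp <- revcomp_chr(sp)
      out[[length(out) + 1L]] <- data.frame(spacer = sp, strand = st,
                                            start = s0,
                                            stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(spacer = character(0), strand = character(0),
                      start = integer(0)))
  do.call(rbind, out)
}

#' Recover spacers from a read pool given per-MAG direct repeats
#'
#' Vectorized read-level spacer extraction: for every DR, all reads are
#' scanned on both strands with at most `max_mismatch` substitutions
#' (overlaps allowed) and spacers are taken between consecutive same-strand
#' hits.
#'
#' @param reads character vector of read sequences (named by read id) or a
#'   data frame with `read_id` and `sequence`.
#' @param drs data frame `mag_id`, `dr_sequence`.
#' @param max_mismatch maximum DR substitutions (default 3).
#' @param max_spacer,min_spacer spacer length bounds.
#' @return Data frame `mag_id`, `read_id`, `strand`, `spacer`.
#' @export
extract_spacers_from_reads <- function(reads, drs, max_mismatch = 3,
                                       max_spacer = 60, min_spacer = 15) {
  if (is.data.frame(reads)) {
    rs <- setNames(reads$sequence, reads$read_id)
  } else {
    rs <- as_seq_chr(reads)
    if (is.null(names(rs))) names(rs) <- sprintf("read%07d", seq_along(rs))
  }
  pool <- Biostrings::DNAStringSet(rs)
  out <- list()
  for (d in seq_len(nrow(drs))) {
    dr <- toupper(drs$dr_sequence[d])
    drlen <- nchar(dr)
    for (st in c("+", "-")) {
      pat <- if (st == "+") dr else revcomp_chr(dr)
      mi <- Biostrings::vmatchPattern(pat, pool, max.mismatch = max_mismatch,
                                      with.indels = FALSE)
      n_hits <- lengths(mi)
      for (ri in which(n_hits >= 2L)) {
        pos <- sort(Biostrings::start(mi[[ri]])) - 1L
        gaps <- pos[-1L] - (pos[-length(pos)] + drlen)
        keep <- gaps >= min_spacer & gaps <= max_spacer
        if (!any(keep)) next
        s0 <- (pos[-length(pos)] + drlen)[keep]
        s1 <- pos[-1L][keep]
        sp <- substring(rs[[ri]], s0 + 1L, s1)
        if (st == "-") sp <- revcomp_chr(sp)
        out[[length(out) + 1L]] <- data.frame(
          mag_id = drs$mag_id[d], read_id = names(rs)[ri], strand = st,
          spacer = sp, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out))
    return(data.frame(mag_id = character(0), read_id = character(0),
                      strand = character(0), spacer = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

canonical_spacer <- function(x) {
  rc <- revcomp_chr(x)
  ifelse(x <= rc, x, rc)
}

#' Dereplicate spacers at 100% identity
#'
#' Exact-string deduplication after canonical orientation (the
#' lexicographically smaller of a spacer and its reverse complement), so a
#' spacer recovered from either strand counts once.  Counts are reported
#' overall and per MAG.
#'
#' @param records data frame with `spacer` and optionally `mag_id`.
#' @param canonical orient spacers canonically before deduplication
#'   (default TRUE).
#' @return List: `spacers` (unique spacer strings), `n_unique`, and
#'   `per_mag` (data frame `mag_id`, `n_unique`) when `mag_id` is present.
#' @export
dereplicate_spacers <- function(records, canonical = TRUE) {
  if (nrow(records) == 0)
    return(list(spacers = character(0), n_unique = 0L, per_mag = NULL))
  sp <- if (canonical) canonical_spacer(records$spacer) else records$spacer
  uni <- unique(sp)
  per_mag <- NULL
  if (!is.null(records$mag_id)) {
    per_mag <- stats::aggregate(
      list(n_unique = sp), list(mag_id = records$mag_id),
      function(v) length(unique(v)))
  }
  list(spacers = uni, n_unique = length(uni), per_mag = per_mag)
}
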