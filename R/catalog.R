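#' Filter viral scaffolds by length
#'
#' @param scaffolds named character vector or `DNAStringSet` of scaffold
#'   sequences.
#' @param min_length minimum retained length in nt (inclusive). Default
#'   10000, the smallest viral genome size the catalogue is built for.
#' @return The retained scaffolds, same type as the input.
#' @export
filter_by_length <- function(scaffolds, min_length = 10000) {
  if (min_length <= 0) stop("min_length must be > 0", call. = FALSE)
  if (is(scaffolds, "DNAStringSet"))
    return(scaffolds[Biostrings::width(scaffolds) >= min_length])
  scaffolds[nchar(scaffolds) >= min_length]
}

#' Merge upstream predictor flags per scaffold
#'
#' A scaffold is lysogenic if at least one upstream tool called it lysogenic,
#' and complete if at least one tool called it circular or complete (logical
#' OR across tools, per flag).
#'
#' @param tool_flags data frame with columns `scaffold_id`, `tool`,
#'   `lysogenic`, `circular` (logical).
#' @param known_tools allowed tool names; any other name is an error.
#' @return Data frame `scaffold_id`, `lysogenic`, `complete` (one row per
#'   scaffold).
#' @export
merge_tool_flags <- function(tool_flags,
                             known_tools = c("virsorter", "vibrant",
                                             "checkv")) {
  need <- c("scaffold_id", "tool", "lysogenic", "circular")
  if (!all(need %in% names(tool_flags)))
    stop("tool_flags needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- setdiff(unique(tool_flags$tool), known_tools)
  if (length(bad))
    stop("unknown tool name(s): ", paste(bad, collapse = ", "), call. = FALSE)
  ids <- unique(tool_flags$scaffold_id)
  lys <- tapply(as.logical(tool_flags$lysogenic), tool_flags$scaffold_id, any)
  com <- tapply(as.logical(tool_flags$circular), tool_flags$scaffold_id, any)
  data.frame(scaffold_id = ids, lysogenic = unname(lys[ids]),
             complete = unname(com[ids]), stringsAsFactors = FALSE)
}

#' Length and G+C content of sequences
#'
#' G+C fraction is (#G + #C) / (#A + #C + #G + #T); `N` bases are excluded
#' from both numerator and denominator.
#'
#' @param sequences named character vector or `DNAStringSet`.
#' @return Data frame `id`, `length`, `gc`.
#' @export
sequence_stats <- function(sequences) {
  dna <- as_dna(sequences)
  if (is.null(names(dna))) names(dna) <- sprintf("seq%d", seq_along(dna))
  af <- Biostrings::alphabetFrequency(dna)
  acgt <- af[, c("A", "C", "G", "T"), drop = FALSE]
  denom <- rowSums(acgt)
  if (any(denom == 0))
    stop("sequence with zero non-N bases: ",
         paste(names(dna)[denom == 0], collapse = ", "), call. = FALSE)
  data.frame(id = names(dna), length = Biostrings::width(dna),
             gc = unname((acgt[, "C"] + acgt[, "G"]) / denom),
             stringsAsFactors = FALSE)
}

# Global identity of the shorter sequence aligned onto the longer one:
# matches / alignment length of a global(shorter)-local(longer) alignment.
pair_identity <- function(short, long) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(short), Biostrings::DNAString(long),
    type = "global-local",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = TRUE),
    gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(aln, type = "PID1") / 100
}

# Fraction of the shorter sequence's k-mers present in the longer; cheap
# screen so full alignments are only computed for plausible near-duplicates.
kmer_containment <- function(short, long, k = 15) {
  n <- nchar(short) - k + 1
  if (n < 1) return(1)
  km <- unique(substring(short, 1:n, k:(n + k - 1)))
  lk <- unique(substring(long, 1:(nchar(long) - k + 1), k:nchar(long)))
  mean(km %in% lk)
}

#' Dereplicate viral scaffolds into populations
#'
#' Greedy longest-first clustering: scaffolds are visited in order of
#' decreasing length (ties broken by id); each joins the first existing
#' representative to which its global identity — matches over the alignment
#' length of a global alignment of the shorter sequence onto the longer —
#' reaches `identity_threshold`, otherwise it founds a new population.  A
#' k-mer containment screen (`prefilter_min` fraction of shared 15-mers)
#' skips alignments that cannot reach the threshold.
#'
#' @param scaffolds named character vector or `DNAStringSet` (length-filtered).
#' @param identity_threshold minimum identity to join a population
#'   (default 0.99).
#' @param prefilter_min k-mer containment below which a pair is not aligned.
#' @return Object of class `viral_populations`: a list with `table`
#'   (`population_id`, `representative_id`, `n_members`, `length`, `gc`),
#'   `members` (list of member id vectors) and `representatives` (named
#'   character vector of representative sequences).
#' @export
dereplicate <- function(scaffolds, identity_threshold = 0.99,
                        prefilter_min = 0.5) {
  seqs <- as_seq_chr(scaffolds)
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("scaffolds must carry unique names", call. = FALSE)
  if (length(seqs) == 0) {
    return(structure(list(table = data.frame(), members = list(),
                          representatives = character(0)),
                     class = "viral_populations"))
  }
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  rep_ids <- character(0)
  members <- list()
  for (i in seq_along(seqs)) {
    id <- names(seqs)[i]
    placed <- FALSE
    for (p in seq_along(rep_ids)) {
      rs <- seqs[[rep_ids[p]]]
      if (kmer_containment(seqs[[i]], rs) < prefilter_min) next
      if (pair_identity(seqs[[i]], rs) >= identity_threshold) {
        members[[p]] <- c(members[[p]], id)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      rep_ids <- c(rep_ids, id)
      members[[length(rep_ids)]] <- id
    }
  }
  reps <- seqs[rep_ids]
  st <- sequence_stats(reps)
  tab <- data.frame(population_id = sprintf("vpop%03d", seq_along(rep_ids)),
                    representative_id = rep_ids,
                    n_members = lengths(members),
                    length = st$length, gc = st$gc, stringsAsFactors = FALSE)
  names(members) <- tab$population_id
  structure(list(table = tab, members = members, representatives = reps),
            class = "viral_populations")
}

#' @export
print.viral_populations <- function(x, ...) {
  cat(sprintf("%d viral population(s) from %d scaffold(s)\n",
              nrow(x$table), sum(x$table$n_members)))
  print(head(x$table, 10))
  invisible(x)
}

#' Build the viral population catalogue
#'
#' Length filtering, dereplication, flag merging and per-population summary
#' statistics in one step.  A population is lysogenic/complete if any member
#' scaffold is.
#'
#' @param scaffolds named scaffold sequences.
#' @param tool_flags per-tool flag table (see [merge_tool_flags()]), or NULL.
#' @param min_length length filter threshold, nt.
#' @param identity_threshold dereplication identity.
#' @return A `viral_populations` object whose `table` gains `lysogenic` and
#'   `complete` columns when flags are supplied.
#' @export
build_catalog <- function(scaffolds, tool_flags = NULL, min_length = 10000,
                          identity_threshold = 0.99) {
  kept <- filter_by_length(scaffolds, min_length)
  pops <- dereplicate(kept, identity_threshold)
  if (!is.null(tool_flags) && nrow(pops$table)) {
    fl <- merge_tool_flags(tool_flags)
    idx <- function(ids, col) {
      v <- fl[[col]][match(ids, fl$scaffold_id)]
      v[is.na(v)] <- FALSE
      any(v)
    }
    pops$table$lysogenic <- vapply(pops$members, idx, logical(1),
                                   col = "lysogenic")
    pops$table$complete <- vapply(pops$members, idx, logical(1),
                                  col = "complete")
  }
  pops
}
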