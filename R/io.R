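#' Read sequences from FASTA or FASTQ
#'
#' Ids and order are preserved, sequences are uppercased, `N` and IUPAC
#' ambiguity codes are accepted, and any other character raises a parse
#' error naming the file.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return A named `DNAStringSet`.
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  tryCatch({
    # Biostrings only warns on invalid letters; treat them as parse errors
    out <- withCallingHandlers(
      Biostrings::readDNAStringSet(path, format = format),
      warning = function(w) {
        if (grepl("invalid", conditionMessage(w)))
          stop(conditionMessage(w), call. = FALSE)
      })
    # uppercase via round-trip through character; re-validates the alphabet
    up <- Biostrings::DNAStringSet(toupper(as.character(out)))
    names(up) <- names(out)
    up
  }, error = function(e)
    stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE))
}

#' Write sequences as FASTA or FASTQ
#'
#' FASTA is wrapped at 80 columns; FASTQ uses a constant quality of `I`.
#'
#' @param seqs named character vector or `DNAStringSet`.
#' @param path output file.
#' @param format `"fasta"` (default) or `"fastq"`.
#' @export
write_sequences <- function(seqs, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  dna <- as_dna(seqs)
  if (is.null(names(dna))) names(dna) <- sprintf("seq%d", seq_along(dna))
  if (format == "fasta") {
    Biostrings::writeXStringSet(dna, path, width = 80)
  } else {
    q <- Biostrings::BStringSet(vapply(Biostrings::width(dna), function(w)
      strrep("I", w), character(1)))
    Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = q)
  }
  invisible(path)
}

#' Read alignment records from TSV or SAM/BAM
#'
#' Tabular records need columns `read_id`, `target_id`, `sample_id`,
#' `target_start`, `target_end` (0-based half-open), `aligned_length`,
#' `n_matches`.  For SAM/BAM, the aligned length is the number of alignment
#' columns (M/I/D, soft clips excluded) and
#' `n_matches = aligned_length - NM` using the standard edit-distance tag.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"tsv"`, `"sam"` or `"bam"`.
#' @param sample_id sample label attached to SAM/BAM records.
#' @return Data frame of alignment records.
#' @export
read_alignment_records <- function(path, format = c("auto", "tsv", "sam",
                                                    "bam"),
                                   sample_id = "sample1") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("sam", "bam")) ext else "tsv"
  }
  if (format == "tsv") {
    rec <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    need <- c("read_id", "target_id", "sample_id", "target_start",
              "target_end", "aligned_length", "n_matches")
    if (!all(need %in% names(rec)))
      stop("alignment TSV needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    return(rec)
  }
  bam <- if (format == "sam") {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  } else path
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "cigar"), tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  if (length(x$qname) == 0)
    return(data.frame(read_id = character(0), target_id = character(0),
                      sample_id = character(0), target_start = integer(0),
                      target_end = integer(0), aligned_length = integer(0),
                      n_matches = integer(0)))
  ops <- GenomicAlignments::cigarOpTable(x$cigar)
  aligned_len <- ops[, "M"] + ops[, "I"] + ops[, "D"]
  ref_width <- GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar)
  nm <- x$tag$NM %||% rep(0L, length(x$qname))
  nm[is.na(nm)] <- 0L
  data.frame(read_id = x$qname, target_id = as.character(x$rname),
             sample_id = sample_id, target_start = x$pos - 1L,
             target_end = x$pos - 1L + ref_width,
             aligned_length = as.integer(aligned_len),
             n_matches = as.integer(aligned_len - nm),
             stringsAsFactors = FALSE)
}

#' Write a table as TSV with a provenance header
#'
#' Tab-separated, `.` decimal mark, preceded by a comment line naming the
#' generating configuration hash.
#'
#' @param x data frame.
#' @param path output file.
#' @param config_hash hash string recorded in the header comment.
#' @export
write_tsv <- function(x, path, config_hash = "unconfigured") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# virolink config=%s", config_hash), con)
  write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (or any plain TSV)
#'
#' @param path input file.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
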