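#' Align a short query (spacer) against a viral genome
#'
#' Optimal local alignment under the short-query nucleotide scoring scheme
#' (match +1, mismatch -3, gap opening 5, gap extension 2), computed over
#' both strands of the subject.  A shared-word gate mirrors seeded search:
#' when query and subject share no `word_size`-mer on either strand, no
#' alignment is reported.  Ties between strands or positions are broken by
#' lowest subject coordinate, then the + strand.
#'
#' @param query short query sequence (15–60 nt for spacers).
#' @param subject subject sequence (e.g. a viral genome).
#' @param word_size seed word length gate (default 7).
#' @param match,mismatch,gap_opening,gap_extension scoring parameters.
#' @return `NULL` when no alignment qualifies, else a list:
#'   `alignment_length` (columns, incl. gaps), `n_matches`, `identity`,
#'   `query_length`, `subject_start`, `subject_end` (0-based half-open,
#'   forward subject coordinates), `strand`, `score`.
#' @export
align_short <- function(query, subject, word_size = 7, match = 1,
                        mismatch = -3, gap_opening = 5, gap_extension = 2) {
  query <- toupper(as_seq_chr(query)); subject <- toupper(as_seq_chr(subject))
  slen <- nchar(subject)
  submat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = TRUE)
  has_word <- function(q) {
    n <- nchar(q) - word_size + 1L
    if (n < 1L) return(FALSE)
    any(vapply(substring(q, 1:n, word_size:(n + word_size - 1L)),
               function(w) grepl(w, subject, fixed = TRUE), logical(1)))
  }
  best <- NULL
  for (st in c("+", "-")) {
    q <- if (st == "+") query else revcomp_chr(query)
    if (!has_word(q)) next
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(q), Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = submat,
      gapOpening = gap_opening, gapExtension = gap_extension)
    sc <- Biostrings::score(aln)
    if (sc <= 0) next
    s_start <- Biostrings::start(Biostrings::subject(aln)) - 1L
    s_end <- Biostrings::end(Biostrings::subject(aln))
    cand <- list(
      alignment_length = Biostrings::nchar(aln),
      n_matches = Biostrings::nmatch(aln),
      identity = Biostrings::nmatch(aln) / Biostrings::nchar(aln),
      query_length = nchar(query),
      subject_start = s_start, subject_end = s_end,
      strand = st, score = sc)
    if (is.null(best) || sc > best$score ||
        (sc == best$score && (cand$subject_start < best$subject_start ||
                              (cand$subject_start == best$subject_start &&
                               st == "+" && best$strand == "-"))))
      best <- cand
  }
  best
}

#' Protospacer similarity filter
#'
#' Similarity = alignment length x identity / query length; link evidence is
#' emitted when similarity reaches `threshold` (inclusive, default 0.80).
#'
#' @param aln an alignment summary as returned by [align_short()] (needs
#'   `alignment_length`, `identity`, `query_length`).
#' @param threshold minimum similarity (default 0.80).
#' @return `NULL`, or a list with `similarity` and the alignment fields.
#' @export
protospacer_link <- function(aln, threshold = 0.80) {
  if (is.null(aln)) return(NULL)
  if (aln$query_length == 0) stop("query_length is 0", call. = FALSE)
  similarity <- aln$alignment_length * aln$identity / aln$query_length
  if (similarity >= threshold) c(aln, list(similarity = similarity)) else NULL
}

#' CRISPR spacer-to-protospacer linkage
#'
#' Aligns every (deduplicated) spacer of every MAG against every viral
#' genome with [align_short()] and applies the protospacer similarity filter.
#' Evidence is reported per (host, virus) pair with the best similarity.
#'
#' @param spacer_records data frame `mag_id`, `spacer`.
#' @param viruses named character vector of viral genomes.
#' @param threshold similarity threshold (default 0.80).
#' @return Link evidence data frame `host_id`, `virus_id`, `method`
#'   (`"crispr"`), `score`, `detail`.
#' @export
crispr_links <- function(spacer_records, viruses, threshold = 0.80) {
  viruses <- as_seq_chr(viruses)
  uni <- unique(spacer_records[c("mag_id", "spacer")])
  out <- list()
  for (i in seq_len(nrow(uni))) {
    for (v in names(viruses)) {
      hit <- protospacer_link(align_short(uni$spacer[i], viruses[[v]]),
                              threshold)
      if (!is.null(hit))
        out[[length(out) + 1L]] <- data.frame(
          host_id = uni$mag_id[i], virus_id = v, method = "crispr",
          score = hit$similarity,
          detail = sprintf("spacer=%s;alen=%d;identity=%.4f",
                           uni$spacer[i], hit$alignment_length,
                           hit$identity),
          stringsAsFactors = FALSE)
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else empty_evidence()
  best_per_pair(ev)
}

empty_evidence <- function() {
  data.frame(host_id = character(0), virus_id = character(0),
             method = character(0), score = numeric(0),
             detail = character(0), stringsAsFactors = FALSE)
}

best_per_pair <- function(ev, decreasing = TRUE) {
  if (!nrow(ev)) return(ev)
  ev <- ev[order(ev$host_id, ev$virus_id,
                 if (decreasing) -ev$score else ev$score), , drop = FALSE]
  ev <- ev[!duplicated(ev[c("host_id", "virus_id", "method")]), ,
           drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' k-mer profile with Markov-expected counts
#'
#' Counts all `4^k` words of length `k` on the forward strand and computes
#' the expected count of each word under a Markov model of the given order
#' estimated from the same sequence:
#' `E_w = (L - k + 1) * p(w)` with `p(w)` chained from the maximum-likelihood
#' transition estimates (order 0: product of base frequencies).
#'
#' @param sequence DNA sequence (character or `DNAString(Set)`).
#' @param k word length (default 6).
#' @param order Markov order, `0 <= order <= k - 2` (default 2).
#' @return Object of class `kmer_profile`: list with `k`, `order`, `counts`
#'   (`N_w`), `expected` (`E_w`), `centered` (`N_w - E_w`) and `length`.
#' @export
kmer_profile <- function(sequence, k = 6, order = 2) {
  k <- as.integer(k); order <- as.integer(order)
  dna <- as_dna(sequence)
  if (length(dna) != 1L) stop("profile one sequence at a time", call. = FALSE)
  L <- Biostrings::width(dna)
  if (L < k) stop("sequence shorter than k", call. = FALSE)
  if (order < 0 || order > k - 2L)
    stop("order must be in [0, k - 2]", call. = FALSE)
  counts <- as.numeric(Biostrings::oligonucleotideFrequency(dna[[1]],
                                                            width = k))
  n_words <- 4L^k
  idx <- seq_len(n_words) - 1L
  if (order == 0L) {
    basef <- as.numeric(Biostrings::oligonucleotideFrequency(dna[[1]],
                                                             width = 1L))
    p1 <- basef / L
    p <- rep(1, n_words)
    for (i in seq_len(k)) {
      d <- (idx %/% 4L^(k - i)) %% 4L
      p <- p * p1[d + 1L]
    }
  } else {
    rmer <- as.numeric(Biostrings::oligonucleotideFrequency(dna[[1]],
                                                            width = order))
    r1mer <- as.numeric(Biostrings::oligonucleotideFrequency(
      dna[[1]], width = order + 1L))
    ctx_tot <- rowSums(matrix(r1mer, ncol = 4L, byrow = TRUE))
    trans <- matrix(r1mer, ncol = 4L, byrow = TRUE) /
      ifelse(ctx_tot > 0, ctx_tot, 1)
    p_ctx <- rmer / sum(rmer)
    first_ctx <- idx %/% 4L^(k - order)
    p <- p_ctx[first_ctx + 1L]
    for (i in (order + 1L):k) {
      ctx <- (idx %/% 4L^(k - i + 1L)) %% 4L^order
      d <- (idx %/% 4L^(k - i)) %% 4L
      p <- p * trans[cbind(ctx + 1L, d + 1L)]
    }
  }
  expected <- (L - k + 1L) * p
  words <- Biostrings::mkAllStrings(DNA_BASES, k)
  structure(list(k = k, order = order,
                 counts = setNames(counts, words),
                 expected = setNames(expected, words),
                 centered = setNames(counts - expected, words),
                 length = L),
            class = "kmer_profile")
}

#' @export
print.kmer_profile <- function(x, ...) {
  cat(sprintf("k-mer profile: k=%d, order=%d, L=%d\n", x$k, x$order,
              x$length))
  invisible(x)
}

#' d2* oligonucleotide dissimilarity
#'
#' The centered, Markov-normalized k-mer correlation statistic mapped to a
#' dissimilarity in `[0, 1]`:
#' `D = sum_w X_w Y_w / sqrt(EX_w EY_w)` over words with positive expected
#' count in both profiles (`X`, `Y` centered counts), and
#' `d2* = (1 - D / (sqrt(sum X^2/EX) sqrt(sum Y^2/EY))) / 2`.
#' Low values indicate shared oligonucleotide composition, a signal of host
#' association.
#'
#' @param p,q [kmer_profile()] objects sharing `k` and `order`.
#' @return The dissimilarity, or `NA` (with a warning) when either centered
#'   profile is all zero.
#' @export
d2star <- function(p, q) {
  stopifnot(inherits(p, "kmer_profile"), inherits(q, "kmer_profile"))
  if (p$k != q$k || p$order != q$order)
    stop("profiles must share k and order", call. = FALSE)
  ok <- p$expected > 0 & q$expected > 0
  X <- p$centered[ok]; Y <- q$centered[ok]
  EX <- p$expected[ok]; EY <- q$expected[ok]
  nx <- sum(X^2 / EX); ny <- sum(Y^2 / EY)
  if (nx == 0 || ny == 0) {
    warning("all-zero centered profile; d2* undefined")
    return(NA_real_)
  }
  D <- sum(X * Y / sqrt(EX * EY))
  0.5 * (1 - D / (sqrt(nx) * sqrt(ny)))
}

#' Oligonucleotide-frequency linkage between viruses and hosts
#'
#' Computes d2* for every (host, virus) pair and emits evidence for all
#' pairs strictly below `threshold` (default 0.2) — every qualifying pair,
#' not only the best host per virus.
#'
#' @param viruses,hosts named character vectors of genome sequences.
#' @param k,order d2* word length and Markov order (defaults 6 and 2).
#' @param threshold strict upper bound on d2* (default 0.2).
#' @param best_only report only the minimum-d2* host per virus
#'   (default FALSE).
#' @return Evidence data frame `host_id`, `virus_id`, `method` (`"onf"`),
#'   `score` (d2*), `detail`.
#' @export
onf_links <- function(viruses, hosts, k = 6, order = 2, threshold = 0.2,
                      best_only = FALSE) {
  viruses <- as_seq_chr(viruses); hosts <- as_seq_chr(hosts)
  if (!length(hosts) || !length(viruses)) return(empty_evidence())
  vp <- lapply(viruses, kmer_profile, k = k, order = order)
  hp <- lapply(hosts, kmer_profile, k = k, order = order)
  out <- list()
  for (v in names(viruses)) {
    d <- vapply(hp, function(h) d2star(vp[[v]], h), numeric(1))
    keep <- which(!is.na(d) & d < threshold)
    if (best_only && length(keep))
      keep <- keep[which.min(d[keep])]
    for (i in keep)
      out[[length(out) + 1L]] <- data.frame(
        host_id = names(hosts)[i], virus_id = v, method = "onf",
        score = d[i], detail = sprintf("k=%d;order=%d", k, order),
        stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else empty_evidence()
}

#' tRNA identity linkage
#'
#' Evidence for every (host, virus) pair sharing a tRNA that is exactly
#' identical over its full length on either strand (complete, 100% identity
#' matches only).
#'
#' @param virus_trnas data frame `virus_id`, `sequence`.
#' @param host_trnas data frame `mag_id`, `sequence`.
#' @return Evidence data frame (`method = "trna"`, `score = 1`).
#' @export
trna_links <- function(virus_trnas, host_trnas) {
  if (!nrow(virus_trnas) || !nrow(host_trnas)) return(empty_evidence())
  vseq <- toupper(virus_trnas$sequence)
  hseq <- toupper(host_trnas$sequence)
  hrc <- revcomp_chr(hseq)
  out <- list()
  for (i in seq_along(vseq)) {
    hits <- which(hseq == vseq[i] | hrc == vseq[i])
    for (j in hits)
      out[[length(out) + 1L]] <- data.frame(
        host_id = host_trnas$mag_id[j], virus_id = virus_trnas$virus_id[i],
        method = "trna", score = 1,
        detail = sprintf("trna_length=%d", nchar(vseq[i])),
        stringsAsFactors = FALSE)
  }
  ev <- if (length(out)) do.call(rbind, out) else empty_evidence()
  best_per_pair(ev)
}

# Run command-line BLAST+ (blastn) of viruses against host contigs and
# return tabular HSPs. Requires makeblastdb/blastn on PATH.
run_blastn <- function(viruses, contigs, task = "blastn",
                       evalue = 10) {
  if (Sys.which("blastn") == "" || Sys.which("makeblastdb") == "")
    stop("BLAST+ (makeblastdb/blastn) not found on PATH", call. = FALSE)
  td <- tempfile("blast"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  qf <- file.path(td, "query.fasta"); sf <- file.path(td, "subject.fasta")
  write_sequences(viruses, qf)
  write_sequences(contigs, sf)
  db <- file.path(td, "hostdb")
  system2("makeblastdb", c("-in", sf, "-dbtype", "nucl", "-out", db),
          stdout = FALSE, stderr = FALSE)
  outf <- file.path(td, "hits.tsv")
  system2("blastn", c("-task", task, "-query", qf, "-db", db,
                      "-evalue", format(evalue), "-outfmt",
                      shQuote(paste("6 qseqid sseqid pident length qstart",
                                    "qend sstart send evalue bitscore")),
                      "-out", outf), stdout = FALSE, stderr = FALSE)
  cols <- c("qseqid", "sseqid", "pident", "length", "qstart", "qend",
            "sstart", "send", "evalue", "bitscore")
  if (!file.exists(outf) || file.info(outf)$size == 0)
    return(setNames(data.frame(character(0), character(0), numeric(0),
                               integer(0), integer(0), integer(0),
                               integer(0), integer(0), numeric(0),
                               numeric(0)), cols))
  setNames(read.delim(outf, header = FALSE, stringsAsFactors = FALSE), cols)
}

#' Nucleotide homology linkage (prophage detection)
#'
#' BLASTs viral genomes against MAG contigs and aggregates local alignments
#' per (virus, MAG): overlapping query blocks are merged before computing
#' viral-contig coverage; identity is matches over aligned columns pooled
#' across blocks.  Evidence requires coverage >= `min_coverage`, pooled
#' identity >= `min_identity`, best bit score >= `min_bitscore` and best
#' E-value <= `max_evalue`.  Pairs where the viral scaffold is itself a
#' member contig of the MAG are excluded as potential binning errors, unless
#' the virus is flagged as a defined prophage region.
#'
#' @param viruses named character vector of viral genomes.
#' @param contigs named character vector of MAG contigs.
#' @param bins data frame `contig_id`, `mag_id` mapping contigs to MAGs.
#' @param provirus_ids virus ids flagged upstream as defined prophage
#'   regions (exempt from the binning-error exclusion).
#' @param min_coverage,min_identity,min_bitscore,max_evalue cutoffs
#'   (defaults 0.75, 0.70, 50, 0.001).
#' @return Evidence data frame (`method = "homology"`, `score` = best bit
#'   score).
#' @export
homology_links <- function(viruses, contigs, bins,
                           provirus_ids = character(0),
                           min_coverage = 0.75, min_identity = 0.70,
                           min_bitscore = 50, max_evalue = 0.001) {
  viruses <- as_seq_chr(viruses); contigs <- as_seq_chr(contigs)
  hits <- run_blastn(viruses, contigs)
  if (!nrow(hits)) return(empty_evidence())
  hits$mag_id <- bins$mag_id[match(hits$sseqid, bins$contig_id)]
  hits <- hits[!is.na(hits$mag_id), , drop = FALSE]
  out <- list()
  for (key in unique(paste(hits$qseqid, hits$mag_id))) {
    h <- hits[paste(hits$qseqid, hits$mag_id) == key, , drop = FALSE]
    v <- h$qseqid[1]; mag <- h$mag_id[1]
    qr <- IRanges::reduce(IRanges::IRanges(pmin(h$qstart, h$qend),
                                           pmax(h$qstart, h$qend)))
    coverage <- sum(IRanges::width(qr)) / nchar(viruses[[v]])
    identity <- sum(h$pident / 100 * h$length) / sum(h$length)
    bit <- max(h$bitscore); ev <- min(h$evalue)
    if (coverage < min_coverage || identity < min_identity ||
        bit < min_bitscore || ev > max_evalue) next
    binned <- v %in% bins$contig_id[bins$mag_id == mag]
    if (binned && !(v %in% provirus_ids)) next
    out[[length(out) + 1L]] <- data.frame(
      host_id = mag, virus_id = v, method = "homology", score = bit,
      detail = sprintf("coverage=%.3f;identity=%.3f;evalue=%.3g",
                       coverage, identity, ev),
      stringsAsFactors = FALSE)
  }
  if (length(out)) do.call(rbind, out) else empty_evidence()
}

#' Integrate link evidence into a host-virus interaction network
#'
#' Interactions are unique at (host, virus, method) granularity, so the same
#' pair supported by two channels contributes two interactions (per-method
#' counting).  Per-virus host counts are the number of unique (host, method)
#' edges of the virus.
#'
#' @param evidence evidence data frame (rbind of the channel outputs).
#' @param host_meta optional data frame with `mag_id` plus attribute columns
#'   (taxonomy, site) attached to host nodes.
#' @param virus_meta optional data frame with `virus_id` plus attribute
#'   columns (site, lifestyle) attached to virus nodes.
#' @return Object of class `virolink_network`: list with `edges` (unique
#'   evidence), `n_interactions`, `per_virus` (host-interaction counts),
#'   `per_method` (interaction totals per channel) and `graph` (a bipartite
#'   `igraph` object).
#' @export
integrate_network <- function(evidence, host_meta = NULL,
                              virus_meta = NULL) {
  if (!nrow(evidence)) {
    edges <- empty_evidence()
  } else {
    edges <- evidence[!duplicated(evidence[c("host_id", "virus_id",
                                             "method")]), , drop = FALSE]
  }
  if (!is.null(host_meta) &&
      !all(edges$host_id %in% host_meta$mag_id))
    stop("evidence references unknown host id(s)", call. = FALSE)
  if (!is.null(virus_meta) &&
      !all(edges$virus_id %in% virus_meta$virus_id))
    stop("evidence references unknown virus id(s)", call. = FALSE)
  per_method <- as.data.frame(table(method = edges$method),
                              stringsAsFactors = FALSE)
  names(per_method)[2] <- "n"
  per_virus <- as.data.frame(table(virus_id = edges$virus_id),
                             stringsAsFactors = FALSE)
  names(per_virus)[2] <- "n_host_interactions"
  hosts <- unique(edges$host_id); vir <- unique(edges$virus_id)
  g <- igraph::make_empty_graph(directed = FALSE)
  if (length(hosts) + length(vir) > 0) {
    g <- igraph::add_vertices(g, length(hosts) + length(vir),
                              name = c(hosts, vir),
                              type = c(rep(FALSE, length(hosts)),
                                       rep(TRUE, length(vir))))
    if (nrow(edges))
      g <- igraph::add_edges(g, rbind(match(edges$host_id, c(hosts, vir)),
                                      match(edges$virus_id, c(hosts, vir))),
                             method = edges$method, score = edges$score)
    if (!is.null(host_meta)) {
      for (cl in setdiff(names(host_meta), "mag_id")) {
        vals <- rep(NA_character_, length(hosts) + length(vir))
        vals[seq_along(hosts)] <-
          as.character(host_meta[[cl]][match(hosts, host_meta$mag_id)])
        g <- igraph::set_vertex_attr(g, cl, value = vals)
      }
    }
    if (!is.null(virus_meta)) {
      for (cl in setdiff(names(virus_meta), "virus_id")) {
        vals <- igraph::vertex_attr(g, cl) %||%
          rep(NA_character_, length(hosts) + length(vir))
        vals[length(hosts) + seq_along(vir)] <-
          as.character(virus_meta[[cl]][match(vir, virus_meta$virus_id)])
        g <- igraph::set_vertex_attr(g, cl, value = vals)
      }
    }
  }
  structure(list(edges = edges, n_interactions = nrow(edges),
                 per_virus = per_virus, per_method = per_method, graph = g),
            class = "virolink_network")
}

#' @export
print.virolink_network <- function(x, ...) {
  cat(sprintf("Host-virus network: %d unique interaction(s) between %d MAG(s) and %d virus(es)\n",
              x$n_interactions, length(unique(x$edges$host_id)),
              length(unique(x$edges$virus_id))))
  if (nrow(x$per_method))
    cat("  per method:",
        paste(sprintf("%s=%d", x$per_method$method, x$per_method$n),
              collapse = ", "), "\n")
  invisible(x)
}

#' Write a network as GraphML
#'
#' @param network a `virolink_network`.
#' @param path output file path.
#' @export
write_network_graphml <- function(network, path) {
  igraph::write_graph(network$graph, path, format = "graphml")
  invisible(path)
}
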