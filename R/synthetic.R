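#' Specify a CRISPR array for planting
#'
#' Describes a CRISPR locus — one direct repeat (DR) interleaved with an
#' ordered list of spacers — to be spliced into a host genome.  The
#' serialized locus is `DR, S1, DR, S2, ..., DR`: `n` spacers imply `n + 1`
#' DR copies.
#'
#' @param dr_sequence direct repeat, 20–50 nt.
#' @param spacers character vector of spacers, each 15–60 nt.
#' @param host_id host identifier the array belongs to.
#' @param insertion_position 0-based offset into the host genome at which the
#'   locus is spliced in.
#' @return An object of class `crispr_array_spec`.
#' @export
crispr_array_spec <- function(dr_sequence, spacers, host_id,
                              insertion_position) {
  dr_sequence <- toupper(dr_sequence)
  spacers <- toupper(spacers)
  if (nchar(dr_sequence) < 20 || nchar(dr_sequence) > 50)
    stop("DR length must be in [20, 50] nt", call. = FALSE)
  sl <- nchar(spacers)
  if (length(spacers) < 1L || any(sl < 15 | sl > 60))
    stop("spacer lengths must be in [15, 60] nt", call. = FALSE)
  structure(list(dr_sequence = dr_sequence, spacers = spacers,
                 host_id = host_id,
                 insertion_position = as.integer(insertion_position)),
            class = "crispr_array_spec")
}

serialize_array <- function(spec) {
  paste0(spec$dr_sequence,
         paste0(vapply(spec$spacers, function(s) paste0(s, spec$dr_sequence),
                       character(1)), collapse = ""))
}

#' Plant a CRISPR array into a host genome
#'
#' Splices the serialized locus of `spec` into `host_sequence` at the
#' declared insertion position (the host grows by the locus length).
#'
#' @param host_sequence host genome (character string).
#' @param spec a [crispr_array_spec()].
#' @return A list with `sequence` (modified host), `locus_start`,
#'   `locus_end` (0-based half-open on the modified sequence) and `locus`.
#' @export
plant_crispr_array <- function(host_sequence, spec) {
  stopifnot(inherits(spec, "crispr_array_spec"))
  host_sequence <- as_seq_chr(host_sequence)
  L <- nchar(host_sequence)
  pos <- spec$insertion_position
  if (pos < 0 || pos > L)
    stop("insertion_position outside host sequence", call. = FALSE)
  locus <- serialize_array(spec)
  seq2 <- paste0(substr(host_sequence, 1, pos), locus,
                 substr(host_sequence, pos + 1, L))
  list(sequence = seq2, locus_start = pos, locus_end = pos + nchar(locus),
       locus = locus)
}

# Substitute exactly n positions of `segment`, each to a different base.
mutate_exact <- function(segment, n_mutations) {
  if (n_mutations == 0) return(segment)
  ch <- strsplit(segment, "")[[1]]
  if (n_mutations > length(ch))
    stop("more mutations than positions", call. = FALSE)
  idx <- sample.int(length(ch), n_mutations)
  for (i in idx) ch[i] <- sample(setdiff(DNA_BASES, ch[i]), 1L)
  paste(ch, collapse = "")
}

# Pick non-overlapping [start, start+w) windows inside [0, L) by rejection.
pick_windows <- function(L, widths) {
  taken <- matrix(numeric(0), ncol = 2)
  starts <- integer(length(widths))
  for (i in seq_along(widths)) {
    w <- widths[i]
    for (try in 1:2000) {
      s <- sample.int(L - w + 1L, 1L) - 1L
      if (nrow(taken) == 0 ||
          all(s + w <= taken[, 1] | s >= taken[, 2])) {
        taken <- rbind(taken, c(s, s + w))
        starts[i] <- s
        break
      }
      if (try == 2000) stop("could not place non-overlapping windows")
    }
  }
  starts
}

#' Generate a viral genome with planted features
#'
#' Simulates a viral genome from a compositional Markov model (optionally one
#' trained on a host genome, creating an oligonucleotide-frequency-linkable
#' pair), then overwrites non-overlapping windows with protospacers (each
#' carrying an exact, seeded number of substitutions relative to its spacer)
#' and tRNA genes.  Window placement keeps the genome length fixed.
#'
#' @param length viral genome length, nt.
#' @param model a [markov_model()] driving the backbone composition.
#' @param protospacers list of `list(sequence=, n_mutations=, revcomp=)`
#'   entries; `revcomp = TRUE` plants the reverse complement.
#' @param trna_inserts character vector of tRNA sequences to plant verbatim.
#' @param seed integer seed.
#' @return A list with `sequence` and `placements`, a data frame with one row
#'   per planted feature (`type`, `source`, `planted`, `start`, `end`,
#'   `n_mutations`, `strand`; coordinates 0-based half-open).
#' @export
generate_virus <- function(length, model, protospacers = list(),
                           trna_inserts = character(0), seed = 1) {
  length <- as.integer(length)
  widths <- c(vapply(protospacers, function(p) nchar(p$sequence), integer(1)),
              nchar(trna_inserts))
  if (any(widths > length))
    stop("planted feature longer than genome", call. = FALSE)
  backbone <- generate_genome(model, length, seed = derive_seed(seed, 1))
  with_seed(derive_seed(seed, 2), {
    n_ps <- length(protospacers)
    placements <- data.frame(type = character(0), source = character(0),
                             planted = character(0), start = integer(0),
                             end = integer(0), n_mutations = integer(0),
                             strand = character(0), stringsAsFactors = FALSE)
    if (length(widths) > 0) {
      starts <- pick_windows(length, widths)
      planted <- character(length(widths))
      types <- c(rep("protospacer", n_ps), rep("trna", length(trna_inserts)))
      sources <- c(vapply(protospacers, function(p) p$sequence, character(1)),
                   trna_inserts)
      strands <- character(length(widths))
      nmut <- integer(length(widths))
      for (i in seq_along(widths)) {
        if (i <= n_ps) {
          p <- protospacers[[i]]
          rc <- isTRUE(p$revcomp)
          seg <- mutate_exact(toupper(p$sequence), p$n_mutations %||% 0L)
          if (rc) seg <- revcomp_chr(seg)
          planted[i] <- seg
          strands[i] <- if (rc) "-" else "+"
          nmut[i] <- as.integer(p$n_mutations %||% 0L)
        } else {
          planted[i] <- toupper(sources[i])
          strands[i] <- "+"
          nmut[i] <- 0L
        }
        substr(backbone, starts[i] + 1L, starts[i] + widths[i]) <- planted[i]
      }
      placements <- data.frame(type = types, source = toupper(sources),
                               planted = planted, start = starts,
                               end = starts + widths, n_mutations = nmut,
                               strand = strands, stringsAsFactors = FALSE)
    }
    list(sequence = backbone, placements = placements)
  })
}

#' Insert a prophage into a host genome
#'
#' Splices the full viral sequence verbatim into the host at `position`
#' (0-based); no attachment-site duplication is modelled, since downstream
#' homology linkage only needs sequence identity.
#'
#' @param host_sequence host genome (character).
#' @param viral_sequence viral genome (character).
#' @param position 0-based insertion offset.
#' @return List with `sequence` and `start`, `end` (0-based half-open
#'   provirus coordinates on the modified host).
#' @export
insert_prophage <- function(host_sequence, viral_sequence, position) {
  host_sequence <- as_seq_chr(host_sequence)
  viral_sequence <- as_seq_chr(viral_sequence)
  L <- nchar(host_sequence)
  position <- as.integer(position)
  if (position < 0 || position > L)
    stop("insertion position out of range", call. = FALSE)
  seq2 <- paste0(substr(host_sequence, 1, position), viral_sequence,
                 substr(host_sequence, position + 1, L))
  list(sequence = seq2, start = position,
       end = position + nchar(viral_sequence))
}

#' Read simulation configuration
#'
#' @param read_length read length, nt (default 200, e.g. merged short-read
#'   pairs; long enough to span a full DR–spacer–DR unit).
#' @param error_rate per-base substitution probability in `[0, 0.5)`.
#' @param depth target fold-coverage of a genome at relative abundance 1.
#' @param seed integer seed.
#' @return A list of class `read_sim_config`.
#' @export
read_sim_config <- function(read_length = 200L, error_rate = 0,
                            depth = 20, seed = 1L) {
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must be in [0, 0.5)", call. = FALSE)
  if (depth <= 0) stop("depth must be > 0", call. = FALSE)
  structure(list(read_length = as.integer(read_length),
                 error_rate = error_rate, depth = depth,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

#' Simulate shotgun reads from a set of genomes
#'
#' Single-end reads with uniform start positions, random strand, and i.i.d.
#' substitution errors.  The expected read count of genome *i* is
#' `abundance_i * depth * length_i / read_length` (Poisson), so counts are
#' proportional to abundance times genome length.
#'
#' @param genomes named character vector of genome sequences.
#' @param abundances non-negative relative abundances (recycled to 1).
#' @param config a [read_sim_config()].
#' @return Data frame: `read_id`, `origin`, `start` (0-based on origin),
#'   `strand`, `sequence`.
#' @export
simulate_reads <- function(genomes, abundances = NULL,
                           config = read_sim_config()) {
  genomes <- as_seq_chr(genomes)
  if (length(genomes) == 0) stop("empty genome set", call. = FALSE)
  if (is.null(names(genomes)))
    names(genomes) <- sprintf("genome%02d", seq_along(genomes))
  if (is.null(abundances)) abundances <- rep(1, length(genomes))
  if (any(abundances < 0)) stop("abundances must be >= 0", call. = FALSE)
  rl <- config$read_length
  lens <- nchar(genomes)
  if (any(lens < rl & abundances > 0))
    stop("genome shorter than read length", call. = FALSE)
  with_seed(config$seed, {
    n_reads <- rpois(length(genomes), abundances * config$depth * lens / rl)
    pieces <- vector("list", length(genomes))
    for (g in seq_along(genomes)) {
      n <- n_reads[g]
      if (n == 0) next
      starts <- sample.int(lens[g] - rl + 1L, n, replace = TRUE) - 1L
      seqs <- substring(genomes[g], starts + 1L, starts + rl)
      minus <- runif(n) < 0.5
      if (any(minus)) seqs[minus] <- revcomp_chr(seqs[minus])
      if (config$error_rate > 0) {
        nerr <- rbinom(n, rl, config$error_rate)
        for (i in which(nerr > 0)) seqs[i] <- mutate_exact(seqs[i], nerr[i])
      }
      pieces[[g]] <- data.frame(
        origin = names(genomes)[g], start = starts,
        strand = ifelse(minus, "-", "+"), sequence = seqs,
        stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, pieces)
    if (is.null(out))
      out <- data.frame(origin = character(0), start = integer(0),
                        strand = character(0), sequence = character(0))
    out$read_id <- sprintf("read%07d", seq_len(nrow(out)))
    out[c("read_id", "origin", "start", "strand", "sequence")]
  })
}

#' Simulate paired microbial/viral abundance matrices with site structure
#'
#' Samples are grouped into sites; each site has its own log-scale population
#' profile (between-site spread `site_sd`), samples vary around it by
#' `sample_sd`, and the viral matrix is a linear map (`coupling`) of the
#' microbial matrix with optional multiplicative log-normal noise.
#' Environmental covariates: `temperature` and `sodium` track the site means
#' (plus jitter), `ph` and `moisture` are pure noise.
#'
#' @param n_samples number of samples (>= 2).
#' @param n_populations number of populations per community.
#' @param n_sites number of sites samples are spread over.
#' @param coupling `"identity"`, `"permutation"`, `"none"`, or a
#'   `n_populations x n_populations` matrix mapping microbial to viral
#'   abundances. `"none"` draws an independent viral community.
#' @param noise_sd sd of log-normal noise applied to the coupled viral
#'   matrix (0 = exact linear image).
#' @param site_sd between-site log-abundance sd.
#' @param sample_sd within-site (replicate) log-abundance sd.
#' @param seed integer seed.
#' @return List with `microbial`, `viral` (samples x populations matrices),
#'   `env` (data frame), `sites` (factor) and `coupling` record.
#' @export
simulate_abundance_matrix <- function(n_samples, n_populations, n_sites = 3,
                                      coupling = "identity", noise_sd = 0,
                                      site_sd = 1.5, sample_sd = 0.1,
                                      seed = 1L) {
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  with_seed(seed, {
    sites <- factor(rep_len(paste0("site", seq_len(n_sites)), n_samples))
    site_mu <- matrix(rnorm(n_sites * n_populations, 0, site_sd),
                      nrow = n_sites)
    micro <- exp(site_mu[as.integer(sites), , drop = FALSE] +
                   matrix(rnorm(n_samples * n_populations, 0, sample_sd),
                          nrow = n_samples))
    dimnames(micro) <- list(sprintf("S%02d", seq_len(n_samples)),
                            sprintf("pop%03d", seq_len(n_populations)))
    if (is.matrix(coupling)) {
      C <- coupling
      viral <- micro %*% C
      ctype <- "matrix"
    } else if (identical(coupling, "identity")) {
      C <- diag(n_populations)
      viral <- micro
      ctype <- "identity"
    } else if (identical(coupling, "permutation")) {
      perm <- sample.int(n_populations)
      C <- diag(n_populations)[, perm]
      viral <- micro[, perm, drop = FALSE]
      ctype <- "permutation"
    } else if (identical(coupling, "none")) {
      site_mu_v <- matrix(rnorm(n_sites * n_populations, 0, site_sd),
                          nrow = n_sites)
      viral <- exp(site_mu_v[as.integer(sites), , drop = FALSE] +
                     matrix(rnorm(n_samples * n_populations, 0, sample_sd),
                            nrow = n_samples))
      C <- NULL
      ctype <- "none"
    } else stop("unknown coupling", call. = FALSE)
    if (noise_sd > 0)
      viral <- viral * exp(matrix(rnorm(length(viral), 0, noise_sd),
                                  nrow = n_samples))
    viral[viral < 0] <- 0
    dimnames(viral) <- list(rownames(micro),
                            sprintf("vpop%03d", seq_len(n_populations)))
    site_temp <- seq(18, 30, length.out = n_sites)
    site_na <- seq(2, 12, length.out = n_sites)
    env <- data.frame(
      sample = rownames(micro), site = as.character(sites),
      temperature = site_temp[as.integer(sites)] + rnorm(n_samples, 0, 0.5),
      sodium = site_na[as.integer(sites)] + rnorm(n_samples, 0, 0.3),
      ph = rnorm(n_samples, 7.5, 0.4),
      moisture = rnorm(n_samples, 1.0, 0.2),
      stringsAsFactors = FALSE)
    list(microbial = micro, viral = viral, env = env, sites = sites,
         coupling = list(type = ctype, map = C))
  })
}
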