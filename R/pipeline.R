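#' Pipeline configuration
#'
#' Collects every stage threshold with its default and validates domains.
#' The configuration round-trips losslessly through JSON.
#'
#' @param min_scaffold_length catalogue length filter, nt.
#' @param derep_identity dereplication identity threshold.
#' @param map_identity read-mapping identity filter.
#' @param breadth_threshold coverage breadth retention threshold.
#' @param abundance_scale normalization constant (reads per library).
#' @param dr_max_mismatch maximum DR substitutions in spacer extraction.
#' @param spacer_max,spacer_min spacer length bounds, nt.
#' @param protospacer_threshold protospacer similarity threshold.
#' @param d2star_k,d2star_order,d2star_threshold ONF channel settings.
#' @param homology_min_coverage,homology_min_identity,homology_min_bitscore,homology_max_evalue
#'   homology channel cutoffs.
#' @param n_perm permutations for all permutation-based tests.
#' @param seed global RNG seed.
#' @return A list of class `pipeline_config` with a `hash` attribute.
#' @export
pipeline_config <- function(min_scaffold_length = 10000,
                            derep_identity = 0.99,
                            map_identity = 0.90,
                            breadth_threshold = 0.75,
                            abundance_scale = 1e8,
                            dr_max_mismatch = 3,
                            spacer_max = 60, spacer_min = 15,
                            protospacer_threshold = 0.80,
                            d2star_k = 6, d2star_order = 2,
                            d2star_threshold = 0.2,
                            homology_min_coverage = 0.75,
                            homology_min_identity = 0.70,
                            homology_min_bitscore = 50,
                            homology_max_evalue = 0.001,
                            n_perm = 999, seed = 1L) {
  cfg <- list(min_scaffold_length = min_scaffold_length,
              derep_identity = derep_identity,
              map_identity = map_identity,
              breadth_threshold = breadth_threshold,
              abundance_scale = abundance_scale,
              dr_max_mismatch = dr_max_mismatch,
              spacer_max = spacer_max, spacer_min = spacer_min,
              protospacer_threshold = protospacer_threshold,
              d2star_k = d2star_k, d2star_order = d2star_order,
              d2star_threshold = d2star_threshold,
              homology_min_coverage = homology_min_coverage,
              homology_min_identity = homology_min_identity,
              homology_min_bitscore = homology_min_bitscore,
              homology_max_evalue = homology_max_evalue,
              n_perm = n_perm, seed = as.integer(seed))
  check_prob(cfg$derep_identity, "derep_identity")
  check_prob(cfg$map_identity, "map_identity")
  check_prob(cfg$breadth_threshold, "breadth_threshold")
  check_prob(cfg$protospacer_threshold, "protospacer_threshold")
  check_prob(cfg$homology_min_coverage, "homology_min_coverage")
  check_prob(cfg$homology_min_identity, "homology_min_identity")
  if (cfg$min_scaffold_length <= 0 || cfg$spacer_min < 1 ||
      cfg$spacer_max < cfg$spacer_min || cfg$n_perm < 1 ||
      cfg$d2star_order > cfg$d2star_k - 2)
    stop("invalid pipeline configuration", call. = FALSE)
  attr(cfg, "hash") <- config_hash(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(cfg) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA),
             tf)
  unname(tools::md5sum(tf))
}

# Perfect-alignment records for simulated reads mapped back to their origin.
reads_to_records <- function(reads, sample_id) {
  rl <- nchar(reads$sequence)
  data.frame(read_id = reads$read_id, target_id = reads$origin,
             sample_id = sample_id, target_start = reads$start,
             target_end = reads$start + rl, aligned_length = rl,
             n_matches = rl, stringsAsFactors = FALSE)
}

#' Run the full analysis pipeline on a synthetic world
#'
#' Chains every stage on a [simulate_world()] object: viral population
#' cataloguing; per-sample viral read simulation, mapping-equivalent
#' alignment records, breadth-filtered normalized abundances; read-level
#' spacer extraction; the four linkage channels and network integration;
#' and paired community statistics (diversity, Bray-Curtis, PCoA, PERMANOVA
#' by site, BioENV, symmetric CoCA).  Microbial abundances come from the
#' world's marker-scaffold (rpS3-style) coverages.
#'
#' @param world a `virolink_world`.
#' @param config a [pipeline_config()].
#' @param n_samples number of samples for the abundance stage.
#' @param reads_per_sample viral reads simulated per sample.
#' @param outdir optional directory; when given, stage tables are written as
#'   TSV (plus the network as GraphML and the manifest as JSON).
#' @return A list of class `virolink_run` with per-stage results and a
#'   provenance `manifest`.
#' @export
run_pipeline <- function(world, config = pipeline_config(),
                         n_samples = 12, reads_per_sample = 3000,
                         outdir = NULL) {
  stopifnot(inherits(world, "virolink_world"),
            inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  seed <- config$seed
  log_lines <- character(0)
  note <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time()), msg))
  }

  # --- catalog ---
  catalog <- build_catalog(world$viruses, world$virus_flags,
                           min_length = config$min_scaffold_length,
                           identity_threshold = config$derep_identity)
  note("catalog: %d populations from %d scaffolds", nrow(catalog$table),
       length(world$viruses))

  # --- abundance ---
  ab <- simulate_abundance_matrix(n_samples, nrow(catalog$table),
                                  coupling = "identity",
                                  seed = derive_seed(seed, 21))
  rel <- ab$viral / rowSums(ab$viral)
  reps <- catalog$representatives
  rec_list <- lapply(seq_len(n_samples), function(s) {
    rd <- simulate_reads(reps, abundances = rel[s, ] * ncol(rel),
                         config = read_sim_config(
                           read_length = 200, error_rate = 0,
                           depth = reads_per_sample * 200 / sum(nchar(reps)),
                           seed = derive_seed(seed, 22 + s)))
    reads_to_records(rd, rownames(rel)[s])
  })
  records <- do.call(rbind, rec_list)
  lib_sizes <- setNames(as.numeric(table(records$sample_id)[rownames(rel)]),
                        rownames(rel))
  viral_tab <- abundance_table(records,
                               setNames(nchar(reps), names(reps)),
                               lib_sizes,
                               min_identity = config$map_identity,
                               breadth_threshold = config$breadth_threshold,
                               scale = config$abundance_scale)
  viral_mat <- abundance_matrix(viral_tab)
  colnames(viral_mat) <-
    catalog$table$population_id[match(colnames(viral_mat),
                                      catalog$table$representative_id)]
  micro_mat <- ab$microbial  # marker-scaffold coverages supplied as input
  note("abundance: %d/%d retained combinations", sum(viral_tab$retained),
       nrow(viral_tab))

  # --- spacers ---
  spacers <- extract_spacers_from_reads(world$reads, world$drs,
                                        max_mismatch = config$dr_max_mismatch,
                                        max_spacer = config$spacer_max,
                                        min_spacer = config$spacer_min)
  derep_sp <- dereplicate_spacers(spacers)
  note("spacers: %d records, %d unique", nrow(spacers), derep_sp$n_unique)

  # --- linkage ---
  ev <- rbind(
    crispr_links(spacers, catalog$representatives,
                 threshold = config$protospacer_threshold),
    onf_links(catalog$representatives, world$hosts, k = config$d2star_k,
              order = config$d2star_order,
              threshold = config$d2star_threshold),
    trna_links(world$virus_trnas, world$host_trnas),
    homology_links(catalog$representatives, world$hosts, world$bins,
                   provirus_ids = world$provirus$virus_id,
                   min_coverage = config$homology_min_coverage,
                   min_identity = config$homology_min_identity,
                   min_bitscore = config$homology_min_bitscore,
                   max_evalue = config$homology_max_evalue))
  # evidence is keyed by MAG ids; ONF links carry contig ids — map them
  idx <- match(ev$host_id, world$bins$contig_id)
  ev$host_id[!is.na(idx)] <- world$bins$mag_id[idx[!is.na(idx)]]
  network <- integrate_network(ev, host_meta = world$bins[-1],
                               virus_meta = world$virus_meta)
  truth_eval <- evaluate_links(network$edges, world$truth)
  note("linkage: %d unique interactions", network$n_interactions)

  # --- community stats ---
  nz <- rowSums(viral_mat) > 0
  vm <- viral_mat[nz, colSums(viral_mat) > 0, drop = FALSE]
  sites <- ab$sites[nz]
  div <- shannon_evenness(vm)
  bc <- bray_curtis(vm)
  ord <- pcoa(bc)
  perm <- permanova(bc, sites, n_perm = config$n_perm,
                    seed = derive_seed(seed, 31))
  be <- bioenv(bc, ab$env[nz, c("temperature", "sodium", "ph", "moisture")],
               n_perm = config$n_perm, seed = derive_seed(seed, 32))
  coca <- coca_symmetric(relative_abundance(vm),
                         relative_abundance(micro_mat[nz, , drop = FALSE]),
                         n_axes = 3, n_perm = config$n_perm,
                         seed = derive_seed(seed, 33))
  # per-sample viral vs microbial abundance contrast (log10 scale)
  welch <- do.call(rbind, lapply(rownames(vm), function(s) {
    va <- vm[s, vm[s, ] > 0]
    ma <- micro_mat[s, micro_mat[s, ] > 0]
    if (length(va) < 2 || length(ma) < 2) return(NULL)
    wc <- welch_compare(log10(va), log10(ma))
    data.frame(sample = s, t = wc$t, p = wc$p, stringsAsFactors = FALSE)
  }))
  note("community: PERMANOVA R2=%.3f p=%.4g; CoCA p=%.4g", perm$R2, perm$p,
       coca$p)

  manifest <- list(
    package_version = as.character(packageVersion("virolink")),
    r_version = R.version.string,
    config = unclass(config), config_hash = attr(config, "hash"),
    seed = seed,
    stage_counts = list(
      scaffolds = length(world$viruses),
      populations = nrow(catalog$table),
      alignment_records = nrow(records),
      spacer_records = nrow(spacers),
      unique_spacers = derep_sp$n_unique,
      interactions = network$n_interactions),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    log = log_lines)

  res <- structure(list(
    catalog = catalog, viral_abundance = viral_tab,
    viral_matrix = viral_mat, microbial_matrix = micro_mat,
    spacers = spacers, unique_spacers = derep_sp,
    evidence = ev, network = network, truth_eval = truth_eval,
    diversity = div, welch = welch, bray_curtis = bc, pcoa = ord,
    permanova = perm,
    bioenv = be, coca = coca, env = ab$env, sites = ab$sites,
    manifest = manifest), class = "virolink_run")

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    h <- attr(config, "hash")
    write_tsv(catalog$table, file.path(outdir, "populations.tsv"), h)
    write_sequences(catalog$representatives,
                    file.path(outdir, "representatives.fasta"))
    write_tsv(viral_tab, file.path(outdir, "viral_abundance.tsv"), h)
    write_tsv(spacers, file.path(outdir, "spacers.tsv"), h)
    write_tsv(ev, file.path(outdir, "link_evidence.tsv"), h)
    write_tsv(network$per_virus, file.path(outdir, "per_virus_counts.tsv"),
              h)
    write_network_graphml(network, file.path(outdir, "network.graphml"))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                                pretty = TRUE),
               file.path(outdir, "manifest.json"))
  }
  res
}

#' @export
print.virolink_run <- function(x, ...) {
  cat("virolink pipeline run\n")
  cat(sprintf("  populations: %d   unique spacers: %d   interactions: %d\n",
              nrow(x$catalog$table), x$unique_spacers$n_unique,
              x$network$n_interactions))
  print(x$permanova)
  print(x$coca)
  invisible(x)
}
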