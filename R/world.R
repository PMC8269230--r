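#' Simulate a complete synthetic soil community with planted ground truth
#'
#' Builds a deterministic miniature of a desert-soil metagenome study: host
#' genomes (MAG contigs) drawn from per-host random Markov models, CRISPR
#' arrays spliced into a subset of hosts, viral genomes carrying the matching
#' protospacers, virus–host pairs sharing exact tRNA genes, prophages
#' embedded verbatim in host contigs, composition-coupled viruses generated
#' from host-trained order-2 models, error-bearing shotgun reads, and a
#' machine-readable truth table keyed by linkage mechanism.
#'
#' @param n_hosts number of host MAGs (one contig each).
#' @param n_viruses number of viral scaffolds.
#' @param n_crispr,n_trna,n_prophage,n_onf number of planted links per
#'   mechanism; mechanisms use disjoint virus sets in the order crispr,
#'   trna, prophage, onf; remaining viruses are unlinked.
#' @param host_length,virus_length genome lengths in nt (viruses vary
#'   +/- 20% around `virus_length`; all stay >= 10 kb).
#' @param spacers_per_array spacers per planted CRISPR array.
#' @param spacer_mutations substitutions applied to each planted protospacer.
#' @param dr_length direct-repeat length, nt.
#' @param read_depth,read_length,read_error read simulation settings for the
#'   host-derived read pool used in spacer extraction.
#' @param seed master integer seed; every sub-generator derives its own
#'   stream from it.
#' @return A list of class `virolink_world`; see Details.
#' @details Components: `hosts`/`viruses` (named sequences), `bins`
#'   (contig-to-MAG table with taxonomy and site), `virus_meta` (site,
#'   lifestyle), `virus_flags` (per-tool lysogeny/completeness calls),
#'   `drs` (direct repeats per MAG), `planted_spacers`, `host_trnas`,
#'   `virus_trnas`, `provirus` (defined prophage regions), `reads`
#'   (host-derived read pool), and `truth`
#'   (`host_id`, `virus_id`, `mechanism`, `params_json`).
#' @export
simulate_world <- function(n_hosts = 20, n_viruses = 30, n_crispr = 10,
                           n_trna = 5, n_prophage = 3, n_onf = 6,
                           host_length = 20000, virus_length = 12000,
                           spacers_per_array = 3, spacer_mutations = 0,
                           dr_length = 29, read_depth = 20,
                           read_length = 200, read_error = 0, seed = 1L) {
  if (n_crispr + n_trna + n_prophage + n_onf > n_viruses)
    stop("more planted links than viruses", call. = FALSE)
  if (n_crispr + n_trna + n_prophage > n_hosts)
    stop("mechanism host sets exceed n_hosts", call. = FALSE)
  host_ids <- sprintf("H%02d", seq_len(n_hosts))
  virus_ids <- sprintf("V%02d", seq_len(n_viruses))

  # per-host compositional signatures (order-1 chains)
  host_models <- lapply(seq_len(n_hosts), function(i)
    random_markov(1, concentration = 5, seed = derive_seed(seed, 100 + i)))
  hosts <- vapply(seq_len(n_hosts), function(i)
    generate_genome(host_models[[i]], host_length,
                    seed = derive_seed(seed, 200 + i)), character(1))
  names(hosts) <- host_ids

  crispr_hosts <- seq_len(n_crispr)
  trna_hosts <- n_crispr + seq_len(n_trna)
  proph_hosts <- n_crispr + n_trna + seq_len(n_prophage)
  crispr_vir <- seq_len(n_crispr)
  trna_vir <- n_crispr + seq_len(n_trna)
  proph_vir <- n_crispr + n_trna + seq_len(n_prophage)
  onf_vir <- n_crispr + n_trna + n_prophage + seq_len(n_onf)

  # CRISPR arrays: one DR per host, spacers free of the DR on either strand
  drs <- character(0); planted_spacers <- list(); truth <- list()
  arrays <- list()
  for (j in seq_along(crispr_hosts)) {
    h <- crispr_hosts[j]
    w <- with_seed(derive_seed(seed, 300 + j), {
      dr <- random_dna(1, dr_length)
      sp <- character(spacers_per_array)
      for (s in seq_len(spacers_per_array)) {
        repeat {
          cand <- random_dna(1, sample(25:45, 1))
          if (!grepl(dr, cand, fixed = TRUE) &&
              !grepl(revcomp_chr(dr), cand, fixed = TRUE) &&
              !grepl(cand, dr, fixed = TRUE)) break
        }
        sp[s] <- cand
      }
      pos <- sample.int(nchar(hosts[h]) - 1L, 1L)
      list(dr = dr, sp = sp, pos = pos)
    })
    spec <- crispr_array_spec(w$dr, w$sp, host_ids[h], w$pos)
    res <- plant_crispr_array(hosts[h], spec)
    hosts[h] <- res$sequence
    drs[host_ids[h]] <- w$dr
    planted_spacers[[host_ids[h]]] <- w$sp
    arrays[[host_ids[h]]] <- spec
  }

  # tRNA complements: every host carries two; linked viruses copy one exactly
  host_trnas <- do.call(rbind, lapply(seq_len(n_hosts), function(i) {
    tr <- with_seed(derive_seed(seed, 400 + i), random_dna(2, 75))
    data.frame(mag_id = host_ids[i],
               trna_id = sprintf("%s_trna%d", host_ids[i], 1:2),
               sequence = tr, stringsAsFactors = FALSE)
  }))

  # viral genomes
  viruses <- character(n_viruses)
  virus_trnas <- list()
  vlen <- with_seed(derive_seed(seed, 500), {
    pmax(10000L, as.integer(round(virus_length *
                                    runif(n_viruses, 0.9, 1.25))))
  })
  for (v in seq_len(n_viruses)) {
    vseed <- derive_seed(seed, 600 + v)
    protos <- list(); trnas <- character(0)
    model <- random_markov(1, concentration = 5,
                           seed = derive_seed(seed, 700 + v))
    if (v %in% crispr_vir) {
      h <- host_ids[crispr_hosts[match(v, crispr_vir)]]
      protos <- lapply(planted_spacers[[h]], function(s)
        list(sequence = s, n_mutations = spacer_mutations))
      truth[[length(truth) + 1L]] <- data.frame(
        host_id = h, virus_id = virus_ids[v], mechanism = "crispr",
        params_json = jsonlite::toJSON(list(n_spacers = length(protos),
                                            n_mutations = spacer_mutations),
                                       auto_unbox = TRUE),
        stringsAsFactors = FALSE)
    } else if (v %in% trna_vir) {
      h <- host_ids[trna_hosts[match(v, trna_vir)]]
      shared <- host_trnas$sequence[host_trnas$mag_id == h][1]
      trnas <- shared
      truth[[length(truth) + 1L]] <- data.frame(
        host_id = h, virus_id = virus_ids[v], mechanism = "trna",
        params_json = jsonlite::toJSON(list(trna_length = nchar(shared)),
                                       auto_unbox = TRUE),
        stringsAsFactors = FALSE)
    } else if (v %in% onf_vir) {
      h_idx <- with_seed(derive_seed(seed, 800 + v),
                         sample.int(n_hosts, 1))
      model <- train_markov(hosts[h_idx], order = 2)
      truth[[length(truth) + 1L]] <- data.frame(
        host_id = host_ids[h_idx], virus_id = virus_ids[v],
        mechanism = "onf",
        params_json = jsonlite::toJSON(list(order = 2), auto_unbox = TRUE),
        stringsAsFactors = FALSE)
    }
    gv <- generate_virus(vlen[v], model, protospacers = protos,
                         trna_inserts = trnas, seed = vseed)
    viruses[v] <- gv$sequence
    decoy <- with_seed(derive_seed(seed, 900 + v), random_dna(1, 75))
    vt <- data.frame(virus_id = virus_ids[v],
                     trna_id = sprintf("%s_trna%d", virus_ids[v],
                                       seq_len(length(trnas) + 1)),
                     sequence = c(trnas, decoy), stringsAsFactors = FALSE)
    virus_trnas[[v]] <- vt
  }
  names(viruses) <- virus_ids
  virus_trnas <- do.call(rbind, virus_trnas)

  # prophages: viral genome embedded verbatim in the host contig
  provirus <- list()
  for (j in seq_along(proph_hosts)) {
    h <- proph_hosts[j]; v <- proph_vir[j]
    pos <- with_seed(derive_seed(seed, 1000 + j),
                     sample.int(nchar(hosts[h]) - 1L, 1L))
    ins <- insert_prophage(hosts[h], viruses[v], pos)
    hosts[h] <- ins$sequence
    provirus[[j]] <- data.frame(virus_id = virus_ids[v],
                                host_contig = paste0(host_ids[h], "_c1"),
                                start = ins$start, end = ins$end,
                                stringsAsFactors = FALSE)
    truth[[length(truth) + 1L]] <- data.frame(
      host_id = host_ids[h], virus_id = virus_ids[v],
      mechanism = "prophage",
      params_json = jsonlite::toJSON(list(start = ins$start, end = ins$end),
                                     auto_unbox = TRUE),
      stringsAsFactors = FALSE)
  }
  provirus <- if (length(provirus)) do.call(rbind, provirus) else
    data.frame(virus_id = character(0), host_contig = character(0),
               start = integer(0), end = integer(0))

  # metadata: taxonomy, site, upstream tool calls
  taxa <- c("Actinobacteria", "Chloroflexi", "Thaumarchaeota", "Firmicutes")
  sites <- c("L", "M", "Y")
  meta <- with_seed(derive_seed(seed, 1100), list(
    htax = sample(taxa, n_hosts, replace = TRUE, prob = c(.45, .4, .1, .05)),
    hsite = sample(sites, n_hosts, replace = TRUE),
    vsite = sample(sites, n_viruses, replace = TRUE),
    circ = runif(n_viruses) < 0.15))
  bins <- data.frame(contig_id = paste0(host_ids, "_c1"), mag_id = host_ids,
                     taxonomy = meta$htax, site = meta$hsite,
                     stringsAsFactors = FALSE)
  names(hosts) <- bins$contig_id
  lys <- virus_ids %in% virus_ids[proph_vir]
  virus_flags <- do.call(rbind, lapply(c("virsorter", "vibrant", "checkv"),
    function(tool) data.frame(scaffold_id = virus_ids, tool = tool,
                              lysogenic = lys & tool == "virsorter",
                              circular = meta$circ & tool == "checkv",
                              stringsAsFactors = FALSE)))
  virus_meta <- data.frame(virus_id = virus_ids, site = meta$vsite,
                           lifestyle = ifelse(lys, "lysogenic", "lytic"),
                           stringsAsFactors = FALSE)

  reads <- simulate_reads(hosts, config = read_sim_config(
    read_length = read_length, error_rate = read_error, depth = read_depth,
    seed = derive_seed(seed, 1200)))

  truth <- do.call(rbind, truth)
  rownames(truth) <- NULL
  structure(list(
    hosts = hosts, viruses = viruses, bins = bins, virus_meta = virus_meta,
    virus_flags = virus_flags,
    drs = data.frame(mag_id = names(drs), dr_sequence = unname(drs),
                     stringsAsFactors = FALSE),
    planted_spacers = planted_spacers, arrays = arrays,
    host_trnas = host_trnas, virus_trnas = virus_trnas,
    provirus = provirus, reads = reads, truth = truth,
    seed = seed), class = "virolink_world")
}

#' @export
print.virolink_world <- function(x, ...) {
  cat(sprintf(paste0("Synthetic community: %d hosts, %d viruses, %d reads\n",
                     "planted links: %s\n"),
              length(x$hosts), length(x$viruses), nrow(x$reads),
              paste(sprintf("%s=%d", names(table(x$truth$mechanism)),
                            table(x$truth$mechanism)), collapse = ", ")))
  invisible(x)
}

#' Score predicted links against the planted truth
#'
#' Compares the unique (host, virus) pairs of each evidence channel with the
#' planted links of the corresponding mechanism (`homology` evidence is
#' scored against `prophage` truth).
#'
#' @param evidence data frame of link evidence
#'   (`host_id`, `virus_id`, `method`).
#' @param truth truth table from [simulate_world()].
#' @return Data frame with one row per mechanism: `n_truth`, `n_predicted`,
#'   `precision`, `recall`.
#' @export
evaluate_links <- function(evidence, truth) {
  mechmap <- c(crispr = "crispr", trna = "trna", prophage = "homology",
               onf = "onf")
  out <- lapply(names(mechmap), function(mech) {
    tr <- truth[truth$mechanism == mech, , drop = FALSE]
    ev <- evidence[evidence$method == mechmap[[mech]], , drop = FALSE]
    tp_set <- paste(tr$host_id, tr$virus_id)
    pred <- unique(paste(ev$host_id, ev$virus_id))
    tp <- sum(pred %in% tp_set)
    data.frame(mechanism = mech, n_truth = nrow(tr),
               n_predicted = length(pred),
               precision = if (length(pred)) tp / length(pred) else NA_real_,
               recall = if (nrow(tr)) tp / length(tp_set) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
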