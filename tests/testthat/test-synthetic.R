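test_that("generate_genome honors the model composition and the seed", {
  gc_only <- markov_model(matrix(c(0, 0.5, 0.5, 0), nrow = 1), order = 0)
  s <- generate_genome(gc_only, 10000, seed = 1)
  expect_equal(nchar(s), 10000)
  expect_true(grepl("^[GC]+$", s))

  expect_identical(generate_genome(gc_only, 5000, seed = 7),
                   generate_genome(gc_only, 5000, seed = 7))

  uniform <- markov_model(matrix(rep(0.25, 4), nrow = 1), order = 0)
  u <- generate_genome(uniform, 100000, seed = 2)
  gc <- sum(strsplit(u, "")[[1]] %in% c("G", "C")) / 100000
  # binomial(1e5, .5): |gc - .5| < 0.01 is a > 6 sigma band
  expect_lt(abs(gc - 0.5), 0.01)

  expect_error(generate_genome(uniform, 0, seed = 1), "length")
  m1 <- random_markov(1, seed = 1)
  expect_error(generate_genome(m1, 1, seed = 1), "length")
})

test_that("order-r genomes reproduce the model's (r+1)-mer frequencies", {
  m <- random_markov(1, concentration = 5, seed = 11)
  g <- generate_genome(m, 100000, seed = 12)
  # stationary distribution of the order-1 chain
  ev <- eigen(t(m$transition))
  pi_ <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  pi_ <- pi_ / sum(pi_)
  # empirical dinucleotide frequencies vs stationary * transition
  emp <- matrix(oracle_count(g, 2), ncol = 4, byrow = TRUE) / (100000 - 1)
  expect_true(all(abs(as.numeric(emp) - as.numeric(m$transition * pi_)) <
                    0.01))
})

test_that("markov_model validates its arguments", {
  expect_error(markov_model(matrix(c(0.5, 0.5, 0.1, 0), nrow = 1), 0),
               "sum to 1")
  expect_error(markov_model(matrix(rep(0.25, 4), nrow = 1), 1), "4 x 4")
  expect_error(markov_model(matrix(c(-0.1, 0.6, 0.25, 0.25), nrow = 1), 0),
               ">= 0")
})

test_that("plant_crispr_array serializes DR,S1,DR,...,DR and validates", {
  host <- strrep("A", 200)
  spec <- crispr_array_spec("GTTTCCGTTTCCGTTTCCGT", strrep("ACGT", 8),
                            "h1", 0)
  res <- plant_crispr_array(host, spec)
  expect_equal(substr(res$sequence, 1, 20 + 32 + 20),
               paste0("GTTTCCGTTTCCGTTTCCGT", strrep("ACGT", 8),
                      "GTTTCCGTTTCCGTTTCCGT"))
  expect_equal(res$locus_start, 0)

  sp3 <- crispr_array_spec(strrep("GT", 12), rep(strrep("CA", 14), 3),
                           "h1", 10)
  res3 <- plant_crispr_array(host, sp3)
  n_dr <- lengths(regmatches(res3$locus,
                             gregexpr(strrep("GT", 12), res3$locus,
                                      fixed = TRUE)))
  expect_equal(n_dr, 4)  # n spacers => n + 1 DR copies
  expect_equal(nchar(res3$sequence), 200 + nchar(res3$locus))
  expect_equal(res3$locus_end - res3$locus_start, nchar(res3$locus))

  expect_error(plant_crispr_array(host,
                                  crispr_array_spec(strrep("GT", 12),
                                                    strrep("CA", 14), "h",
                                                    500)),
               "insertion_position")
})

test_that("generate_virus plants protospacers with exact mutation counts", {
  m <- markov_model(matrix(rep(0.25, 4), nrow = 1), 0)
  spacer <- random_seq(32, seed = 5)
  v0 <- generate_virus(5000, m,
                       protospacers = list(list(sequence = spacer,
                                                n_mutations = 0)),
                       seed = 3)
  expect_true(grepl(spacer, v0$sequence, fixed = TRUE))
  pl <- v0$placements
  expect_equal(substr(v0$sequence, pl$start + 1, pl$end), spacer)

  v2 <- generate_virus(5000, m,
                       protospacers = list(list(sequence = spacer,
                                                n_mutations = 2)),
                       seed = 3)
  region <- substr(v2$sequence, v2$placements$start + 1, v2$placements$end)
  expect_equal(sum(strsplit(region, "")[[1]] != strsplit(spacer, "")[[1]]),
               2)

  rc <- generate_virus(5000, m,
                       protospacers = list(list(sequence = spacer,
                                                n_mutations = 0,
                                                revcomp = TRUE)),
                       seed = 4)
  expect_true(grepl(oracle_revcomp(spacer), rc$sequence, fixed = TRUE))

  expect_error(generate_virus(20, m,
                              protospacers = list(list(sequence = spacer,
                                                       n_mutations = 0))),
               "longer than genome")
})

test_that("insert_prophage embeds the virus verbatim at the coordinates", {
  host <- random_seq(10000, seed = 21)
  virus <- random_seq(1200, seed = 22)
  res <- insert_prophage(host, virus, 5000)
  expect_equal(substr(res$sequence, res$start + 1, res$end), virus)
  expect_equal(res$start, 5000)
  expect_equal(res$end, 6200)
  expect_equal(nchar(res$sequence), 11200)

  at0 <- insert_prophage(host, virus, 0)
  expect_equal(substr(at0$sequence, 1, 1200), virus)

  expect_error(insert_prophage(host, virus, 10001), "out of range")
})

test_that("simulate_reads: exact substrings, Poisson counts, abundances", {
  g <- c(g1 = random_seq(50000, seed = 31), g2 = random_seq(20000, seed = 32))
  cfg <- read_sim_config(read_length = 100, error_rate = 0, depth = 20,
                         seed = 33)
  reads <- simulate_reads(g, config = cfg)
  # error-free reads are exact substrings of their origin (either strand)
  idx <- sample(nrow(reads), 50)
  for (i in idx) {
    r <- reads[i, ]
    sq <- if (r$strand == "-") oracle_revcomp(r$sequence) else r$sequence
    expect_equal(substr(g[[r$origin]], r$start + 1, r$start + 100), sq)
  }
  n1 <- sum(reads$origin == "g1")
  expect_lt(abs(n1 - 10000), 0.05 * 10000)  # ~5 sd of Poisson(1e4)

  only1 <- simulate_reads(g, abundances = c(1, 0), config = cfg)
  expect_true(all(only1$origin == "g1"))

  expect_error(simulate_reads(character(0)), "empty genome set")

  err <- simulate_reads(g["g2"],
                        config = read_sim_config(read_length = 100,
                                                 error_rate = 0.1,
                                                 depth = 2, seed = 9))
  mm <- vapply(seq_len(50), function(i) {
    r <- err[i, ]
    sq <- if (r$strand == "-") oracle_revcomp(r$sequence) else r$sequence
    sum(strsplit(sq, "")[[1]] !=
          strsplit(substr(g[["g2"]], r$start + 1, r$start + 100), "")[[1]])
  }, numeric(1))
  expect_gt(mean(mm), 5)   # ~10 errors per 100 nt expected
  expect_lt(mean(mm), 15)
})

test_that("simulate_abundance_matrix couples communities as declared", {
  a <- simulate_abundance_matrix(12, 20, coupling = "identity",
                                 noise_sd = 0, seed = 41)
  expect_equal(unname(a$viral), unname(a$microbial))
  expect_true(all(a$viral >= 0))
  expect_equal(nrow(a$env), 12)

  b1 <- simulate_abundance_matrix(10, 15, coupling = "permutation", seed = 5)
  b2 <- simulate_abundance_matrix(10, 15, coupling = "permutation", seed = 5)
  expect_identical(b1, b2)
  # permutation coupling: viral columns are a reordering of microbial ones
  expect_equal(unname(sort(colSums(b1$viral))),
               unname(sort(colSums(b1$microbial))))

  expect_error(simulate_abundance_matrix(1, 5), "n_samples")
})

test_that("the synthetic world is internally consistent", {
  w <- simulate_world(n_hosts = 6, n_viruses = 8, n_crispr = 2, n_trna = 2,
                      n_prophage = 1, n_onf = 1, host_length = 12000,
                      virus_length = 11000, read_depth = 5, seed = 99)
  expect_s3_class(w, "virolink_world")
  # truth references only generated entities
  expect_true(all(w$truth$host_id %in% w$bins$mag_id))
  expect_true(all(w$truth$virus_id %in% names(w$viruses)))
  expect_equal(as.vector(table(w$truth$mechanism)[c("crispr", "onf",
                                                    "prophage", "trna")]),
               c(2, 1, 1, 2))
  # prophage region is the viral genome verbatim
  pv <- w$provirus[1, ]
  expect_equal(substr(w$hosts[[pv$host_contig]], pv$start + 1, pv$end),
               w$viruses[[pv$virus_id]])
  # planted spacers appear verbatim in the linked virus
  tr <- w$truth[w$truth$mechanism == "crispr", ][1, ]
  for (sp in w$planted_spacers[[tr$host_id]])
    expect_true(grepl(sp, w$viruses[[tr$virus_id]], fixed = TRUE))
  # determinism
  w2 <- simulate_world(n_hosts = 6, n_viruses = 8, n_crispr = 2, n_trna = 2,
                       n_prophage = 1, n_onf = 1, host_length = 12000,
                       virus_length = 11000, read_depth = 5, seed = 99)
  expect_identical(w$hosts, w2$hosts)
  expect_identical(w$reads, w2$reads)
})
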