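test_that("align_short finds planted protospacers with exact statistics", {
  genome <- random_seq(2000, 101)
  q <- random_seq(30, 102)
  g <- paste0(substr(genome, 1, 1000), q, substr(genome, 1001, 2000))
  aln <- align_short(q, g)
  expect_equal(aln$alignment_length, 30)
  expect_equal(aln$identity, 1)
  expect_equal(aln$subject_start, 1000)
  expect_equal(aln$subject_end, 1030)
  expect_equal(aln$strand, "+")

  # two substitutions: full-length ungapped alignment, identity 28/30
  ch <- strsplit(q, "")[[1]]
  ch[10] <- setdiff(c("A", "C", "G", "T"), ch[10])[1]
  ch[20] <- setdiff(c("A", "C", "G", "T"), ch[20])[1]
  q2 <- paste(ch, collapse = "")
  g2 <- paste0(substr(genome, 1, 1000), q2, substr(genome, 1001, 2000))
  aln2 <- align_short(q, g2)
  expect_equal(aln2$alignment_length, 30)
  expect_equal(aln2$identity, 28 / 30)

  # reverse-complement planting is found on the minus strand
  g3 <- paste0(substr(genome, 1, 500), oracle_revcomp(q),
               substr(genome, 501, 2000))
  aln3 <- align_short(q, g3)
  expect_equal(aln3$strand, "-")
  expect_equal(aln3$identity, 1)

  # no shared 7-mer: no alignment
  expect_null(align_short(strrep("A", 20), strrep("C", 200)))
})

test_that("align_short agrees with exhaustive local alignment", {
  set.seed(111)
  for (i in 1:10) {
    q <- random_seq(sample(15:40, 1), 200 + i)
    s <- random_seq(200, 300 + i)
    # embed a mutated copy half the time so scores are non-trivial
    if (i %% 2 == 0) {
      ch <- strsplit(q, "")[[1]]
      for (p in sample(length(ch), 3))
        ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1]
      pos <- sample(200 - length(ch), 1)
      substr(s, pos, pos + length(ch) - 1) <- paste(ch, collapse = "")
    }
    has_word <- function(q, s) {
      n <- nchar(q) - 6
      any(vapply(substring(q, 1:n, 7:(n + 6)), grepl, logical(1), x = s,
                 fixed = TRUE))
    }
    got <- align_short(q, s)
    # exhaustive optimum over the strands that pass the seed-word gate
    cand <- c(if (has_word(q, s)) oracle_sw_score(q, s),
              if (has_word(oracle_revcomp(q), s))
                oracle_sw_score(oracle_revcomp(q), s))
    if (length(cand)) {
      expect_false(is.null(got))
      expect_equal(got$score, max(cand))
      expect_equal(got$identity, got$n_matches / got$alignment_length)
    } else {
      # no seed word on either strand: the gate must refuse
      expect_null(got)
    }
  }
})

test_that("protospacer similarity formula and threshold are exact", {
  mk <- function(alen, id, qlen) list(alignment_length = alen, identity = id,
                                      query_length = qlen)
  expect_equal(protospacer_link(mk(30, 1, 30))$similarity, 1)
  expect_equal(protospacer_link(mk(24, 1, 30))$similarity, 0.8)  # boundary in
  expect_equal(protospacer_link(mk(27, 25 / 27, 30))$similarity, 25 / 30)
  expect_null(protospacer_link(mk(27, 23 / 27, 30)))  # 0.767 below cutoff
  expect_null(protospacer_link(NULL))
  expect_error(protospacer_link(mk(10, 1, 0)), "query_length")
})

test_that("kmer_profile counts words and expected counts correctly", {
  p <- kmer_profile("AAAA", k = 2, order = 0)
  expect_equal(unname(p$counts["AA"]), 3)
  expect_equal(sum(p$counts), 3)
  expect_true(all(p$counts[names(p$counts) != "AA"] == 0))

  s <- random_seq(20, 121)
  p0 <- kmer_profile(s, k = 3, order = 0)
  expect_equal(sum(p0$counts), 20 - 3 + 1)
  # order-0 closed form: E_w = (L - k + 1) * prod p(base)
  basef <- vapply(c("A", "C", "G", "T"),
                  function(b) sum(strsplit(s, "")[[1]] == b) / 20, numeric(1))
  w <- "ACG"
  expect_equal(unname(p0$expected[w]),
               18 * basef["A"] * basef["C"] * basef["G"],
               ignore_attr = TRUE)

  expect_error(kmer_profile("ACG", k = 6), "shorter than k")
  expect_error(kmer_profile(random_seq(100, 1), k = 4, order = 3), "order")
})

test_that("d2star matches brute-force evaluation and is a semimetric", {
  s <- random_seq(30, 131)
  t_ <- random_seq(30, 132)
  got <- d2star(kmer_profile(s, 2, 0), kmer_profile(t_, 2, 0))
  expect_equal(got, oracle_d2star(s, t_, 2, 0), tolerance = 1e-12)

  # order-1 normalization, longer pair
  s2 <- random_seq(500, 133); t2 <- random_seq(500, 134)
  expect_equal(d2star(kmer_profile(s2, 3, 1), kmer_profile(t2, 3, 1)),
               oracle_d2star(s2, t2, 3, 1), tolerance = 1e-12)

  # self-dissimilarity is zero; symmetry to 1e-12
  p <- kmer_profile(s2, 4, 1); q <- kmer_profile(t2, 4, 1)
  expect_equal(d2star(p, p), 0)
  expect_equal(d2star(p, q), d2star(q, p), tolerance = 1e-12)
  expect_gte(d2star(p, q), 0)
  expect_lte(d2star(p, q), 1)

  # independent uniform sequences decorrelate around 0.5
  u1 <- random_seq(100000, 135); u2 <- random_seq(100000, 136)
  d <- d2star(kmer_profile(u1, 6, 0), kmer_profile(u2, 6, 0))
  expect_lt(abs(d - 0.5), 0.05)

  expect_error(d2star(kmer_profile(s, 2, 0), kmer_profile(s, 3, 0)),
               "share k and order")
})

test_that("onf_links applies a strict threshold to all qualifying pairs", {
  h1 <- generate_genome(random_markov(1, 5, seed = 141), 50000, seed = 142)
  h2 <- generate_genome(random_markov(1, 5, seed = 143), 50000, seed = 144)
  v <- generate_genome(train_markov(h1, 2), 30000, seed = 145)
  d_true <- d2star(kmer_profile(v, 6, 0), kmer_profile(h1, 6, 0))
  d_far <- d2star(kmer_profile(v, 6, 0), kmer_profile(h2, 6, 0))
  expect_lt(d_true, d_far)

  # strictness: a pair exactly at the threshold is not linked
  at <- onf_links(c(v = v), c(h1 = h1, h2 = h2), k = 6, order = 0,
                  threshold = d_true)
  expect_false("h1" %in% at$host_id)
  above <- onf_links(c(v = v), c(h1 = h1, h2 = h2), k = 6, order = 0,
                     threshold = d_true + 1e-9)
  expect_true("h1" %in% above$host_id)

  expect_equal(nrow(onf_links(c(v = v), character(0))), 0)
})

test_that("trna_links demands complete identity and reports all pairs", {
  trna <- random_seq(75, 151)
  vt <- data.frame(virus_id = "v1", sequence = trna)
  ht <- data.frame(mag_id = c("m1", "m2", "m3"),
                   sequence = c(trna, trna, random_seq(75, 152)))
  ev <- trna_links(vt, ht)
  expect_setequal(ev$host_id, c("m1", "m2"))  # all-pairs semantics

  sub <- trna
  substr(sub, 10, 10) <- setdiff(c("A", "C", "G", "T"),
                                 substr(trna, 10, 10))[1]
  expect_equal(nrow(trna_links(data.frame(virus_id = "v1", sequence = sub),
                               ht[3, ])), 0)

  # reverse-complement copies still count as complete matches
  rc <- trna_links(data.frame(virus_id = "v1",
                              sequence = oracle_revcomp(trna)), ht[1, ])
  expect_equal(nrow(rc), 1)
})

test_that("homology_links enforces cutoffs and the binning exclusion", {
  host_bg <- random_seq(30000, 161)
  virus <- random_seq(12000, 162)
  with_pp <- insert_prophage(host_bg, virus, 9000)
  contigs <- c(hostA_c1 = with_pp$sequence, hostB_c1 = random_seq(30000, 163))
  bins <- data.frame(contig_id = names(contigs),
                     mag_id = c("hostA", "hostB"))
  ev <- homology_links(c(V1 = virus), contigs, bins)
  expect_equal(ev$host_id, "hostA")
  expect_equal(ev$method, "homology")
  expect_match(ev$detail, "identity=1.000")

  # 60% of the virus present: below the 75% coverage cutoff
  part <- insert_prophage(host_bg, substr(virus, 1, 7200), 9000)
  ev60 <- homology_links(c(V1 = virus),
                         c(hostA_c1 = part$sequence), bins[1, ])
  expect_equal(nrow(ev60), 0)

  # virus binned inside the MAG: excluded unless flagged as provirus
  bins2 <- rbind(bins, data.frame(contig_id = "V1", mag_id = "hostA"))
  ev_ex <- homology_links(c(V1 = virus), contigs, bins2)
  expect_equal(nrow(ev_ex), 0)
  ev_pv <- homology_links(c(V1 = virus), contigs, bins2,
                          provirus_ids = "V1")
  expect_equal(ev_pv$host_id, "hostA")

  # monotonicity: raising any cutoff never adds links
  n0 <- nrow(homology_links(c(V1 = virus), contigs, bins))
  expect_lte(nrow(homology_links(c(V1 = virus), contigs, bins,
                                 min_coverage = 0.9)), n0)
  expect_lte(nrow(homology_links(c(V1 = virus), contigs, bins,
                                 min_bitscore = 1e5)), n0)
})

test_that("integrate_network counts per-method unique interactions", {
  ev <- data.frame(
    host_id = c("m1", "m1", "m1", "m2"),
    virus_id = c("v1", "v1", "v1", "v1"),
    method = c("trna", "onf", "trna", "crispr"),
    score = c(1, 0.1, 1, 0.9),
    detail = "")
  net <- integrate_network(ev)
  # same pair supported by trna and onf -> 2 interactions; duplicate trna
  # evidence collapses
  expect_equal(net$n_interactions, 3)
  expect_equal(net$per_virus$n_host_interactions[
    net$per_virus$virus_id == "v1"], 3)
  expect_setequal(net$per_method$method, c("trna", "onf", "crispr"))

  expect_error(integrate_network(ev, host_meta = data.frame(mag_id = "m1")),
               "unknown host")
  g <- net$graph
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 3)
})
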