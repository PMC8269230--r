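test_that("length filter keeps scaffolds at or above the threshold", {
  sc <- c(a = random_seq(9999, 1), b = random_seq(10000, 2),
          c = random_seq(17700, 3))
  expect_equal(names(filter_by_length(sc, 10000)), c("b", "c"))
  expect_equal(names(filter_by_length(sc, 1)), c("a", "b", "c"))
  expect_length(filter_by_length(character(0), 10000), 0)
  expect_error(filter_by_length(sc, 0), "min_length")
})

test_that("tool flags merge by logical OR and reject unknown tools", {
  fl <- data.frame(scaffold_id = rep("s1", 3),
                   tool = c("virsorter", "vibrant", "checkv"),
                   lysogenic = c(FALSE, TRUE, FALSE),
                   circular = c(FALSE, FALSE, FALSE))
  m <- merge_tool_flags(fl)
  expect_true(m$lysogenic)
  expect_false(m$complete)

  fl$lysogenic <- FALSE
  expect_false(merge_tool_flags(fl)$lysogenic)
  fl$lysogenic <- TRUE; fl$circular <- TRUE
  m2 <- merge_tool_flags(fl)
  expect_true(m2$lysogenic && m2$complete)

  fl$tool[1] <- "mystery"
  expect_error(merge_tool_flags(fl), "unknown tool")
})

test_that("sequence_stats computes GC excluding N", {
  st <- sequence_stats(c(x = "GCGC", y = "ATAT", z = "GCATN"))
  expect_equal(st$gc, c(1, 0, 0.5))
  expect_equal(st$length, c(4, 4, 5))
  expect_error(sequence_stats(c(bad = "NNNN")), "zero non-N")
})

test_that("dereplication clusters near-identical scaffolds greedily", {
  base <- random_seq(20000, seed = 51)
  twin <- base
  # 0.5% substitutions: identity ~99.5% > 0.99 threshold
  set.seed(52)
  pos <- sample(20000, 100)
  ch <- strsplit(twin, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  twin <- paste(ch, collapse = "")
  far <- random_seq(20000, seed = 53)

  pops <- dereplicate(c(s1 = base, s2 = twin, s3 = far))
  expect_equal(nrow(pops$table), 2)
  joint <- pops$members[[which(vapply(pops$members, length,
                                      integer(1)) == 2)]]
  expect_setequal(joint, c("s1", "s2"))

  # identical pair -> one population of two members
  same <- dereplicate(c(a = base, b = base))
  expect_equal(nrow(same$table), 1)
  expect_equal(same$table$n_members, 2)
  # tie in length: representative is the lexicographically smaller id
  expect_equal(same$table$representative_id, "a")

  # 95% identity (5% substitutions) stays below a 99% threshold
  set.seed(54)
  div <- strsplit(base, "")[[1]]
  for (p in sample(20000, 1000)) div[p] <- sample(setdiff(c("A", "C", "G",
                                                            "T"), div[p]), 1)
  two <- dereplicate(c(a = base, b = paste(div, collapse = "")))
  expect_equal(nrow(two$table), 2)
})

test_that("populations partition the input and are idempotent", {
  set.seed(61)
  scaff <- setNames(vapply(1:8, function(i) random_seq(11000, 60 + i),
                           character(1)), sprintf("c%02d", 1:8))
  # add two near-duplicates
  scaff["c09"] <- scaff[["c01"]]
  scaff["c10"] <- scaff[["c03"]]
  pops <- dereplicate(scaff)
  all_members <- unlist(pops$members)
  expect_setequal(all_members, names(scaff))
  expect_equal(anyDuplicated(all_members), 0)
  # representative maximality
  for (p in seq_len(nrow(pops$table))) {
    rep_len <- pops$table$length[p]
    expect_true(all(nchar(scaff[pops$members[[p]]]) <= rep_len))
  }
  # idempotence on representatives
  again <- dereplicate(pops$representatives)
  expect_equal(sort(again$table$representative_id),
               sort(pops$table$representative_id))
  expect_true(all(again$table$n_members == 1))
})

test_that("build_catalog merges flags onto populations", {
  sc <- c(v1 = random_seq(12000, 71), v2 = random_seq(12500, 72))
  fl <- data.frame(scaffold_id = c("v1", "v1", "v2"),
                   tool = c("virsorter", "checkv", "vibrant"),
                   lysogenic = c(TRUE, FALSE, FALSE),
                   circular = c(FALSE, TRUE, FALSE))
  cat_ <- build_catalog(sc, fl)
  tab <- cat_$table[match(c("v1", "v2"), cat_$table$representative_id), ]
  expect_equal(tab$lysogenic, c(TRUE, FALSE))
  expect_equal(tab$complete, c(TRUE, FALSE))
})
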