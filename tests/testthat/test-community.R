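test_that("Shannon diversity and Pielou evenness closed forms", {
  u <- rep(1, 10)
  d <- shannon_evenness(u)
  expect_equal(d$H, log(10))
  expect_equal(d$J, 1)
  expect_equal(d$S, 10L)

  one <- shannon_evenness(c(5, 0, 0))
  expect_equal(one$H, 0)
  expect_true(is.na(one$J))  # evenness undefined for S = 1

  mix <- shannon_evenness(c(0.5, 0.25, 0.25))
  expect_equal(mix$H, 1.5 * log(2), tolerance = 1e-12)

  expect_error(shannon_evenness(c(0, 0)), "all-zero")
  expect_error(shannon_evenness(c(-1, 2)), "negative")
})

test_that("Bray-Curtis distances match the formula", {
  m <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(1, 1, 0),
             d = c(0, 0, 2))
  d <- as.matrix(bray_curtis(m))
  expect_equal(d["a", "b"], 0.5)
  expect_equal(d["a", "c"], 0)
  expect_equal(d["a", "d"], 1)  # disjoint supports
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))

  withzero <- rbind(a = c(1, 2), z = c(0, 0))
  expect_warning(dz <- bray_curtis(withzero), "all-zero")
  expect_true(is.na(as.matrix(dz)["a", "z"]))
})

test_that("PCoA reconstructs Euclidean configurations", {
  set.seed(171)
  pts <- cbind(rnorm(8), rnorm(8))
  d <- dist(pts)
  ord <- pcoa(d)
  rec <- dist(ord$coordinates[, 1:2])
  expect_equal(as.numeric(rec), as.numeric(d), tolerance = 1e-9)

  two <- pcoa(matrix(c(0, 3, 3, 0), 2))
  expect_equal(ncol(two$coordinates), 1)
  expect_equal(abs(diff(two$coordinates[, 1])), 3)

  # three equidistant samples: the two positive eigenvalues are equal
  eq <- pcoa(matrix(1, 3, 3) - diag(3))
  pos <- eq$eigenvalues[eq$eigenvalues > 1e-9]
  expect_equal(pos[1], pos[2], tolerance = 1e-9)

  asym <- matrix(c(0, 1, 2, 0), 2)
  expect_error(pcoa(asym), "symmetric")
})

test_that("PERMANOVA partitions variance and saturates under separation", {
  set.seed(181)
  base <- matrix(rexp(8 * 10), 8)
  far <- rbind(base, base + 100)
  g <- factor(rep(c("a", "b"), each = 8))
  res <- permanova(dist(far), g, n_perm = 999, seed = 1)
  expect_equal(res$p, 0.001)  # minimum attainable at 999 permutations
  expect_gt(res$R2, 0.9)
  r2s <- res$table$R2
  expect_equal(sum(r2s[1:2]), 1, tolerance = 1e-12)

  expect_error(permanova(dist(base), factor(rep("a", 8))), ">= 2 groups")
  # seeded: reproducible p
  res2 <- permanova(dist(far), g, n_perm = 999, seed = 1)
  expect_identical(res$p, res2$p)
})

test_that("BioENV recovers a constructed driver variable", {
  set.seed(191)
  n <- 14
  env <- data.frame(driver = rnorm(n), noise1 = rnorm(n), noise2 = rnorm(n))
  comm_d <- dist(scale(env$driver))
  be <- bioenv(comm_d, env, n_perm = 99, seed = 2)
  expect_equal(be$best_subset, "driver")
  expect_equal(be$rho, 1, tolerance = 1e-9)
  expect_lte(be$p, 0.05)

  # adding irrelevant variables never raises the best correlation
  be2 <- bioenv(comm_d, env["driver"], n_perm = 99, seed = 2)
  expect_lte(be$rho, be2$rho + 1e-12)

  wide <- as.data.frame(matrix(rnorm(n * 16), n))
  expect_error(bioenv(comm_d, wide), "exhaustive")
})

test_that("symmetric CoCA: identical and permuted communities", {
  ab <- simulate_abundance_matrix(12, 20, coupling = "identity", seed = 7)
  y <- ab$microbial
  self <- coca_symmetric(y, y, n_axes = 3, n_perm = 99, seed = 3)
  expect_true(all(self$axis_correlations >= 1 - 1e-9))
  expect_true(all(diff(self$eigenvalues) <= 1e-12))
  expect_true(all(self$eigenvalues >= -1e-12))

  perm <- simulate_abundance_matrix(12, 20, coupling = "permutation",
                                    noise_sd = 0, seed = 8)
  cc <- coca_symmetric(perm$viral, perm$microbial, n_axes = 3, n_perm = 199,
                       seed = 4)
  expect_gte(sum(cc$pct_common_variance[1:3]), 95)
  expect_true(all(cc$axis_correlations >= 0.99))
  expect_lte(cc$p, 0.005)

  # independent unstructured communities: mostly non-significant
  ps <- vapply(1:10, function(r) {
    set.seed(900 + r)
    y1 <- matrix(rexp(12 * 20), 12)
    y2 <- matrix(rexp(12 * 20), 12)
    coca_symmetric(y1, y2, n_axes = 3, n_perm = 99, seed = r)$p
  }, numeric(1))
  expect_gte(sum(ps > 0.05), 7)

  expect_error(coca_symmetric(y[1:5, ], y), "share samples")
  y0 <- y; y0[1, ] <- 0
  expect_error(coca_symmetric(y0, y), "zero-sum")
})
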