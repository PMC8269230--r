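#' Shannon-Wiener diversity and Pielou evenness
#'
#' `H = -sum p_i ln p_i` over the nonzero relative abundances of each sample
#' row (natural log), observed richness `S`, and evenness `J = H / ln S`
#' (`NA` when `S = 1`).
#'
#' @param x numeric vector (one sample) or samples x populations matrix.
#' @return Data frame `H`, `S`, `J`, one row per sample.
#' @export
shannon_evenness <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (any(x < 0)) stop("negative abundances", call. = FALSE)
  if (any(rowSums(x) == 0)) stop("all-zero sample row", call. = FALSE)
  H <- vegan::diversity(x, index = "shannon")
  S <- rowSums(x > 0)
  J <- ifelse(S > 1, H / log(S), NA_real_)
  data.frame(H = as.numeric(H), S = as.integer(S), J = as.numeric(J),
             row.names = rownames(x))
}

#' Bray-Curtis distance matrix
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`.  Pairs involving an
#' all-zero sample are undefined and reported as `NA` with a warning.
#'
#' @param m non-negative samples x populations matrix.
#' @return A `dist` object.
#' @export
bray_curtis <- function(m) {
  m <- as.matrix(m)
  if (any(m < 0)) stop("negative abundances", call. = FALSE)
  zero <- rowSums(m) == 0
  d <- suppressWarnings(vegan::vegdist(m, method = "bray"))
  if (any(zero)) {
    warning("all-zero sample row(s): distances reported as NA")
    dm <- as.matrix(d)
    dm[zero, ] <- NA; dm[, zero] <- NA
    diag(dm) <- 0
    d <- stats::as.dist(dm)
  }
  d
}

#' Principal-coordinate analysis
#'
#' Metric embedding via eigendecomposition of the double-centered Gower
#' matrix of squared distances.  All eigenvalues (including negative ones)
#' are reported; coordinate axes are returned only for positive eigenvalues,
#' ordered by decreasing eigenvalue.
#'
#' @param d a `dist` object or symmetric distance matrix.
#' @return Object of class `virolink_pcoa`: list with `coordinates`,
#'   `eigenvalues`, `var_explained` (fractions over positive eigenvalues).
#' @export
pcoa <- function(d) {
  dm <- as.matrix(d)
  if (!isSymmetric(unname(dm), tol = 1e-8))
    stop("distance matrix must be symmetric", call. = FALSE)
  n <- nrow(dm)
  # cmdscale warns when fewer than k eigenvalues are positive; expected here
  fit <- suppressWarnings(cmdscale(stats::as.dist(dm), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  coords <- fit$points[, seq_along(pos), drop = FALSE]
  colnames(coords) <- sprintf("PCo%d", seq_along(pos))
  structure(list(coordinates = coords, eigenvalues = eig,
                 var_explained = eig[pos] / sum(eig[pos])),
            class = "virolink_pcoa")
}

#' @export
print.virolink_pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d sample(s), %d positive axis/axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  cat("  leading var explained:",
      paste(sprintf("%.1f%%", 100 * head(x$var_explained, 3)),
            collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.virolink_pcoa <- function(x, axes = c(1, 2), groups = NULL, ...) {
  xy <- x$coordinates[, axes, drop = FALSE]
  col <- if (is.null(groups)) 1 else as.integer(factor(groups))
  graphics::plot(xy, col = col, pch = 19,
                 xlab = sprintf("PCo%d (%.1f%%)", axes[1],
                                100 * x$var_explained[axes[1]]),
                 ylab = sprintf("PCo%d (%.1f%%)", axes[2],
                                100 * x$var_explained[axes[2]]), ...)
  invisible(x)
}

#' One-way PERMANOVA
#'
#' Permutational partitioning of the squared distances among and within the
#' levels of `groups`, with pseudo-F statistic and permutation p-value
#' `(1 + #{F_perm >= F_obs}) / (1 + n_perm)`.
#'
#' @param d `dist` object or symmetric matrix of distances.
#' @param groups grouping factor (>= 2 levels, every group non-empty).
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutation stream.
#' @return Object of class `virolink_permanova`: list `pseudo_F`, `R2`
#'   (among-group), `p`, `n_permutations`, `table`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1L) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 1)) stop("empty group", call. = FALSE)
  d <- stats::as.dist(as.matrix(d))
  dat <- data.frame(groups = groups)
  fit <- with_seed(seed,
                   vegan::adonis2(d ~ groups, data = dat,
                                  permutations = n_perm))
  structure(list(pseudo_F = fit$F[1], R2 = fit$R2[1],
                 p = fit$`Pr(>F)`[1], n_permutations = n_perm,
                 table = as.data.frame(fit)),
            class = "virolink_permanova")
}

#' @export
print.virolink_permanova <- function(x, ...) {
  cat(sprintf("PERMANOVA (one-way, %d permutations): pseudo-F = %.3f, R2 = %.3f, P = %.4g\n",
              x$n_permutations, x$pseudo_F, x$R2, x$p))
  invisible(x)
}

#' BioENV: best environmental-variable subset
#'
#' Exhaustive search over all non-empty subsets of the (z-scored)
#' environmental variables for the subset whose Euclidean inter-sample
#' distances have maximum Spearman rank correlation with the community
#' distances.  The permutation p-value of the best subset comes from a
#' Mantel test (Spearman, `n_perm` permutations of sample identities).
#'
#' @param comm_dist community distance `dist` object.
#' @param env data frame of numeric environmental variables.
#' @param n_perm Mantel permutations (default 999).
#' @param seed integer seed.
#' @param max_vars refuse exhaustive search above this many variables
#'   unless raised explicitly (default 15).
#' @return Object of class `virolink_bioenv`: list `best_subset`, `rho`,
#'   `p`, `search` (per-size best models).
#' @export
bioenv <- function(comm_dist, env, n_perm = 999, seed = 1L, max_vars = 15) {
  env <- as.data.frame(env)
  num <- vapply(env, is.numeric, logical(1))
  env <- env[num]
  if (ncol(env) > max_vars)
    stop("more than ", max_vars,
         " variables: exhaustive search refused (raise max_vars to override)",
         call. = FALSE)
  fit <- with_seed(seed, vegan::bioenv(comm_dist, env,
                                       index = "euclidean", upto = ncol(env)))
  sm <- summary(fit)
  best <- which.max(sm$correlation)
  vars <- strsplit(sm$variables[best], " ")[[1]]
  mant <- with_seed(derive_seed(seed, 1), vegan::mantel(
    comm_dist, dist(scale(env[vars])), method = "spearman",
    permutations = n_perm))
  structure(list(best_subset = vars, rho = unname(sm$correlation[best]),
                 p = mant$signif, n_permutations = n_perm,
                 search = data.frame(size = sm$size,
                                     correlation = sm$correlation,
                                     variables = sm$variables)),
            class = "virolink_bioenv")
}

#' @export
print.virolink_bioenv <- function(x, ...) {
  cat(sprintf("BioENV: best subset {%s}, rho = %.4f, P = %.4g (%d permutations)\n",
              paste(x$best_subset, collapse = ", "), x$rho, x$p,
              x$n_permutations))
  invisible(x)
}

# chi-square transform of a non-negative matrix under common row weights r:
# Q = D_r^{-1/2} (P - r c') D_c^{-1/2}, P = Y / sum(Y), c = colSums(P).
chisq_transform <- function(Y, r) {
  P <- Y / sum(Y)
  cc <- colSums(P)
  keep <- cc > 0
  P <- P[, keep, drop = FALSE]; cc <- cc[keep]
  Q <- (P - outer(r, cc)) / sqrt(outer(r, cc))
  list(Q = Q, c = cc, keep = keep)
}

coca_stat <- function(Y1, Y2, n_axes) {
  r <- (rowSums(Y1) / sum(Y1) + rowSums(Y2) / sum(Y2)) / 2
  t1 <- chisq_transform(Y1, r); t2 <- chisq_transform(Y2, r)
  sv <- svd(crossprod(t1$Q, t2$Q))
  lambda <- sv$d^2
  list(lambda = lambda, u = sv$u, v = sv$v, t1 = t1, t2 = t2, r = r,
       stat = sum(lambda[seq_len(min(n_axes, length(lambda)))]))
}

#' Symmetric co-correspondence analysis
#'
#' Ordination maximizing the covariance between the site scores of two
#' community matrices observed on the same samples.  Both matrices are
#' chi-square-transformed as in correspondence analysis under common site
#' weights (the mean of the two matrices' relative row totals); the weighted
#' singular value decomposition of their cross-product yields paired axes.
#' Axis eigenvalues are squared singular values; significance is assessed by
#' permuting the rows of the second matrix and recomputing the sum of the
#' leading `n_axes` eigenvalues (`p = (1 + #{stat_perm >= stat_obs}) /
#' (1 + n_perm)`).
#'
#' @param y_viral,y_microbial non-negative samples x populations matrices
#'   with identical sample sets in identical order.
#' @param n_axes number of axes reported (default 3).
#' @param n_perm row permutations for the significance test (default 999).
#' @param seed integer seed.
#' @return Object of class `virolink_coca`: `eigenvalues`,
#'   `pct_common_variance` (per axis, of total common variance),
#'   `pct_total_variance` (share of each community's total inertia explained
#'   by the reported axes), `site_scores` (list of two matrices),
#'   `axis_correlations` (Pearson, per axis), `p`, `n_permutations`.
#' @export
coca_symmetric <- function(y_viral, y_microbial, n_axes = 3, n_perm = 999,
                           seed = 1L) {
  Y1 <- as.matrix(y_viral); Y2 <- as.matrix(y_microbial)
  if (nrow(Y1) != nrow(Y2))
    stop("matrices must share samples (rows)", call. = FALSE)
  if (!is.null(rownames(Y1)) && !is.null(rownames(Y2)) &&
      !identical(rownames(Y1), rownames(Y2)))
    stop("sample names/order differ between matrices", call. = FALSE)
  if (any(Y1 < 0) || any(Y2 < 0)) stop("negative entries", call. = FALSE)
  if (any(rowSums(Y1) == 0) || any(rowSums(Y2) == 0))
    stop("zero-sum sample row", call. = FALSE)
  obs <- coca_stat(Y1, Y2, n_axes)
  n_axes <- min(n_axes, length(obs$lambda))
  ax <- seq_len(n_axes)
  dr <- 1 / sqrt(obs$r)
  scores1 <- dr * (obs$t1$Q %*% obs$u[, ax, drop = FALSE])
  scores2 <- dr * (obs$t2$Q %*% obs$v[, ax, drop = FALSE])
  dimnames(scores1) <- list(rownames(Y1), sprintf("CoCA%d", ax))
  dimnames(scores2) <- dimnames(scores1)
  axis_cor <- vapply(ax, function(i)
    abs(cor(scores1[, i], scores2[, i])), numeric(1))
  tot1 <- sum(obs$t1$Q^2); tot2 <- sum(obs$t2$Q^2)
  expl1 <- sum(colSums((obs$t1$Q %*% obs$u[, ax, drop = FALSE])^2)) / tot1
  expl2 <- sum(colSums((obs$t2$Q %*% obs$v[, ax, drop = FALSE])^2)) / tot2
  perm_ge <- 0L
  if (n_perm > 0) {
    perm_ge <- with_seed(seed, {
      cnt <- 0L
      for (b in seq_len(n_perm)) {
        idx <- sample.int(nrow(Y2))
        if (coca_stat(Y1, Y2[idx, , drop = FALSE], n_axes)$stat >=
            obs$stat - 1e-12) cnt <- cnt + 1L
      }
      cnt
    })
  }
  structure(list(
    eigenvalues = obs$lambda,
    pct_common_variance = 100 * obs$lambda / sum(obs$lambda),
    pct_total_variance = c(viral = 100 * expl1, microbial = 100 * expl2),
    site_scores = list(viral = scores1, microbial = scores2),
    axis_correlations = axis_cor,
    n_axes = n_axes, p = (1 + perm_ge) / (1 + n_perm),
    n_permutations = n_perm), class = "virolink_coca")
}

#' @export
print.virolink_coca <- function(x, ...) {
  ax <- seq_len(x$n_axes)
  cat(sprintf("Symmetric CoCA (%d axes): common variance %s (sum %.1f%%)\n",
              x$n_axes,
              paste(sprintf("%.1f%%", x$pct_common_variance[ax]),
                    collapse = " + "),
              sum(x$pct_common_variance[ax])))
  cat(sprintf("  explains %.1f%% of viral and %.1f%% of microbial total variance; P = %.4g\n",
              x$pct_total_variance[["viral"]],
              x$pct_total_variance[["microbial"]], x$p))
  invisible(x)
}

#' @export
summary.virolink_coca <- function(object, ...) {
  ax <- seq_len(object$n_axes)
  data.frame(axis = ax, eigenvalue = object$eigenvalues[ax],
             pct_common_variance = object$pct_common_variance[ax],
             axis_correlation = object$axis_correlations[ax])
}
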