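# Group-level inference: point-wise one-sample t statistics, cluster-mass
# sign-flip permutation tests against chance (1D time axis or 2D
# train x test lattice, 4-connectivity), windowed FDR-corrected t tests,
# and JZS Bayes factors.

#' Cluster-permutation test configuration
#'
#' @param alpha_forming two-tailed point-wise threshold for cluster forming
#'   (default 0.05).
#' @param n_permutations Monte-Carlo permutations B (default 1024). Whenever
#'   `B >= 2^n - 1` for n subjects the test switches to exhaustive
#'   enumeration of all sign patterns.
#' @param seed RNG seed for the random sign flips.
#' @return a `cluster_config` list.
#' @export
cluster_config <- function(alpha_forming = 0.05, n_permutations = 1024,
                           seed = 1) {
  .assert(alpha_forming > 0 && alpha_forming < 1, "alpha_forming must be in (0, 1)")
  .assert(n_permutations >= 1, "n_permutations must be >= 1")
  structure(as.list(environment()), class = "cluster_config")
}

#' Two-tailed one-sample t test
#'
#' `t = (mean(x) - mu) / (sd(x)/sqrt(n))` with the n-1 SD; two-tailed p from
#' the t distribution. Zero variance yields t = +-Inf with p = 0 and a
#' warning.
#'
#' @param values numeric vector, length >= 2.
#' @param mu null value (default 0).
#' @return list with `t`, `df`, `p`.
#' @export
one_sample_t <- function(values, mu = 0) {
  n <- length(values)
  .assert(n >= 2, "need at least two values")
  s <- stats::sd(values)
  if (s == 0) {
    warning("zero variance in one_sample_t; returning t = +-Inf")
    tv <- sign(mean(values) - mu) * Inf
    return(list(t = tv, df = n - 1, p = if (tv == 0) 1 else 0))
  }
  tv <- (mean(values) - mu) / (s / sqrt(n))
  list(t = tv, df = n - 1, p = 2 * stats::pt(-abs(tv), n - 1))
}

# column-wise one-sample t statistics of an n x p matrix against 0,
# optionally under a set of sign-flip rows F (B x n). Uses the fact that
# flipping signs leaves column sums of squares unchanged.
.colwise_t <- function(X, flips = NULL) {
  n <- nrow(X)
  ss <- colSums(X^2)
  if (is.null(flips)) {
    m <- colMeans(X)
    v <- (ss - n * m^2) / (n - 1)
    v[v < 0] <- 0
    return(m / sqrt(v / n))
  }
  M <- flips %*% X / n                       # B x p means
  V <- sweep(-n * M^2, 2, ss, `+`) / (n - 1) # B x p variances
  V[V < 0] <- 0
  M / sqrt(V / n)
}

# runs of supra-threshold t values of one sign -> list of (members, mass)
.clusters_1d <- function(tvec, tcrit) {
  out <- list()
  for (sgn in c(1, -1)) {
    supra <- (sgn * tvec) > tcrit
    supra[is.na(supra)] <- FALSE
    r <- rle(supra)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      mem <- starts[j]:ends[j]
      out[[length(out) + 1L]] <- list(members = mem,
                                      mass = sum(tvec[mem]), sign = sgn)
    }
  }
  out
}

# 4-connected components of a logical matrix (BFS on the lattice)
.label4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    frontier <- s
    lab[s] <- cur
    while (length(frontier)) {
      i <- (frontier - 1L) %% nr + 1L
      j <- (frontier - 1L) %/% nr + 1L
      nb <- c(frontier[i > 1] - 1L, frontier[i < nr] + 1L,
              frontier[j > 1] - nr, frontier[j < nc] + nr)
      nb <- unique(nb[mask[nb] & lab[nb] == 0L])
      lab[nb] <- cur
      frontier <- nb
    }
  }
  lab
}

.clusters_2d <- function(tmat, tcrit) {
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- (sgn * tmat) > tcrit
    mask[is.na(mask)] <- FALSE
    if (!any(mask)) next
    lab <- .label4(mask)
    for (cl in seq_len(max(lab))) {
      mem <- which(lab == cl)
      out[[length(out) + 1L]] <- list(members = mem,
                                      mass = sum(tmat[mem]), sign = sgn)
    }
  }
  out
}

.max_abs_mass <- function(clusters) {
  if (!length(clusters)) 0 else max(abs(vapply(clusters, `[[`, 0, "mass")))
}

# sign-flip matrix: exhaustive (2^n x n, identity included) when
# B >= 2^n - 1, otherwise B random +-1 rows
.sign_flips <- function(n, B, seed) {
  if (n <= 30 && B >= 2^n - 1) {
    f <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    dimnames(f) <- NULL
    attr(f, "exhaustive") <- TRUE
    f
  } else {
    f <- with_seed(seed, matrix(sample(c(1, -1), B * n, replace = TRUE), B, n))
    attr(f, "exhaustive") <- FALSE
    f
  }
}

.cluster_perm <- function(X, dims, config) {
  n <- nrow(X)
  .assert(n >= 2, "need at least two subjects")
  tcrit <- stats::qt(1 - config$alpha_forming / 2, n - 1)
  find <- if (is.null(dims)) {
    function(tv) .clusters_1d(tv, tcrit)
  } else {
    function(tv) .clusters_2d(matrix(tv, dims[1], dims[2]), tcrit)
  }
  t_obs <- .colwise_t(X)
  obs <- find(t_obs)
  flips <- .sign_flips(n, config$n_permutations, config$seed)
  Tn <- .colwise_t(X, flips)
  null <- vapply(seq_len(nrow(flips)), function(b) .max_abs_mass(find(Tn[b, ])), 0)
  exhaustive <- isTRUE(attr(flips, "exhaustive"))
  pval <- function(mass) {
    if (exhaustive) mean(null >= abs(mass)) else {
      (1 + sum(null >= abs(mass))) / (length(null) + 1)
    }
  }
  clusters <- lapply(obs, function(cl) {
    c(cl, list(p = pval(cl$mass)))
  })
  structure(list(clusters = clusters, t = t_obs, t_crit = tcrit,
                 null_distribution = null, exhaustive = exhaustive,
                 dims = dims, config = config),
            class = "cluster_result")
}

#' Cluster-mass permutation test on time courses
#'
#' Point-wise two-tailed one-sample t tests of subject values against
#' `chance`; supra-threshold points are grouped by temporal adjacency
#' separately by sign, cluster mass is the summed t, and significance comes
#' from the permutation null of the maximum absolute cluster mass under
#' sign-flipping of subject-level deviations. Monte-Carlo p-values use the
#' (k+1)/(B+1) convention; with `B >= 2^n - 1` all sign patterns are
#' enumerated instead.
#'
#' @param subject_by_time subjects x time matrix (e.g. AUC).
#' @param chance null value (default 0.5).
#' @param config a [cluster_config()].
#' @return a `cluster_result`: `clusters` (members, mass, sign, p), the
#'   point-wise `t`, and the null distribution.
#' @export
cluster_permutation_1d <- function(subject_by_time, chance = 0.5,
                                   config = cluster_config()) {
  .cluster_perm(as.matrix(subject_by_time) - chance, dims = NULL, config)
}

#' Cluster-mass permutation test on a train x test lattice
#'
#' As [cluster_permutation_1d()], with clusters formed under 4-connectivity
#' on the 2D lattice (cells touching only diagonally belong to different
#' clusters).
#'
#' @param subject_by_traintest subjects x train x test array.
#' @inheritParams cluster_permutation_1d
#' @return a `cluster_result`; cluster members index the flattened lattice.
#' @export
cluster_permutation_2d <- function(subject_by_traintest, chance = 0.5,
                                   config = cluster_config()) {
  d <- dim(subject_by_traintest)
  .assert(length(d) == 3, "need a subjects x train x test array")
  X <- matrix(subject_by_traintest, d[1], d[2] * d[3]) - chance
  .cluster_perm(X, dims = d[2:3], config)
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("<cluster_result> %d cluster(s), %s null (%d draws)\n",
              length(x$clusters),
              if (x$exhaustive) "exhaustive" else "Monte-Carlo",
              length(x$null_distribution)))
  for (cl in x$clusters) {
    cat(sprintf("  sign %+d extent %d mass %.2f p %.4f\n",
                cl$sign, length(cl$members), cl$mass, cl$p))
  }
  invisible(x)
}

#' Benjamini-Hochberg FDR
#'
#' Step-up FDR control at level `q`; adjusted p-values via
#' `p.adjust(..., "BH")`.
#'
#' @param p_values vector of p-values in [0, 1].
#' @param q FDR level (default 0.05).
#' @return list with logical `reject` and numeric `p_adjusted`.
#' @export
fdr_bh <- function(p_values, q = 0.05) {
  if (!length(p_values)) {
    return(list(reject = logical(0), p_adjusted = numeric(0)))
  }
  .assert(all(p_values >= 0 & p_values <= 1), "p-values must lie in [0, 1]")
  adj <- stats::p.adjust(p_values, method = "BH")
  list(reject = adj <= q, p_adjusted = adj)
}

#' JZS Bayes factor for a one-sample t statistic
#'
#' BF10 with a Cauchy prior of scale `r` on the standardized effect size,
#' computed by adaptive numerical quadrature of the Zellner-Siow marginal
#' likelihood. Values above 1 favor the alternative.
#'
#' @param t observed t statistic.
#' @param n sample size (>= 2).
#' @param r Cauchy prior scale (default sqrt(2)/2).
#' @param rel_tol quadrature relative tolerance.
#' @return the Bayes factor BF10.
#' @export
bf10_jzs <- function(t, n, r = sqrt(2) / 2, rel_tol = 1e-8) {
  .assert(is.finite(t), "t must be finite")
  .assert(n >= 2, "n must be >= 2")
  nu <- n - 1
  like_null <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  integrand <- function(g) {
    (1 + n * g * r^2)^(-1 / 2) *
      (1 + t^2 / ((1 + n * g * r^2) * nu))^(-(nu + 1) / 2) *
      (2 * pi)^(-1 / 2) * g^(-3 / 2) * exp(-1 / (2 * g))
  }
  alt <- stats::integrate(integrand, 0, Inf, rel.tol = rel_tol,
                          subdivisions = 500L)$value
  alt / like_null
}

#' Windowed one-sample t tests with FDR correction and Bayes factors
#'
#' Subject curves are averaged over closed time windows
#' `[center - half_width, center + half_width]`, tested against `chance`
#' with two-tailed one-sample t tests, BH-FDR corrected across all windows
#' (and curve directions) tested in the call, and accompanied by JZS BF10.
#'
#' @param curves subjects x time matrix, or a named list of such matrices
#'   (e.g. both directions of a lag curve) sharing one time axis.
#' @param times time axis in seconds.
#' @param centers window centers (s).
#' @param half_width window half-width (s; default 0.025 for 50 ms windows).
#' @param chance null value (default 0.5).
#' @param q FDR level (default 0.05).
#' @param bf_scale Cauchy prior scale for BF10.
#' @return a data.frame with one row per window x curve: `curve`, `center`,
#'   `half_width`, `n_samples`, `mean`, `t`, `df`, `p`, `p_fdr`, `bf10`,
#'   `significant`.
#' @export
windowed_tests <- function(curves, times, centers, half_width = 0.025,
                           chance = 0.5, q = 0.05, bf_scale = sqrt(2) / 2) {
  if (is.matrix(curves)) curves <- list(curve = curves)
  .assert(is.list(curves) && length(curves) >= 1, "curves must be a matrix or list")
  tol <- 1e-9
  rows <- list()
  for (nm in names(curves)) {
    m <- as.matrix(curves[[nm]])
    .assert(ncol(m) == length(times), "curve width must match the time axis")
    for (ct in centers) {
      sel <- which(times >= ct - half_width - tol & times <= ct + half_width + tol)
      .assert(length(sel) > 0, sprintf("window at %g s selects no samples", ct))
      vals <- rowMeans(m[, sel, drop = FALSE])
      tt <- one_sample_t(vals, chance)
      rows[[length(rows) + 1L]] <- data.frame(
        curve = nm, center = ct, half_width = half_width,
        n_samples = length(sel), mean = mean(vals),
        t = tt$t, df = tt$df, p = tt$p,
        bf10 = if (is.finite(tt$t)) bf10_jzs(tt$t, length(vals), bf_scale) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  fdr <- fdr_bh(out$p, q)
  out$p_fdr <- fdr$p_adjusted
  out$significant <- fdr$reject
  out
}
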