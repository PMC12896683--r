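test_that("one-sample t statistic matches the closed form and t.test", {
  r <- one_sample_t(c(1, 2, 3), 0)
  expect_equal(r$t, 2 / (1 / sqrt(3)), tolerance = 1e-12) # = 3.4641
  expect_equal(r$df, 2)
  # mu at the sample mean: t = 0, p = 1
  r0 <- one_sample_t(c(1, 2, 3), 2)
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 1)
  # agreement with t.test on random data
  set.seed(1)
  x <- rnorm(15, 0.3)
  tt <- t.test(x, mu = 0.1)
  r2 <- one_sample_t(x, 0.1)
  expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-12)
  expect_warning(z <- one_sample_t(rep(1, 4), 0), "zero variance")
  expect_equal(z$p, 0)
})

test_that("1D cluster permutation equals the exhaustive sign-flip oracle", {
  # independent oracle: enumerate all 2^n sign patterns by brute force
  oracle_1d <- function(X, alpha = 0.05) {
    n <- nrow(X)
    tcrit <- qt(1 - alpha / 2, n - 1)
    tvec <- function(M) apply(M, 2, function(v) mean(v) / (sd(v) / sqrt(n)))
    masses <- function(tv) {
      out <- numeric(0)
      for (sgn in c(1, -1)) {
        r <- rle((sgn * tv) > tcrit)
        e <- cumsum(r$lengths); s <- e - r$lengths + 1
        for (j in which(r$values)) out <- c(out, sum(tv[s[j]:e[j]]))
      }
      out
    }
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    null <- apply(signs, 1, function(f) {
      mm <- masses(tvec(X * f))
      if (length(mm)) max(abs(mm)) else 0
    })
    obs <- masses(tvec(X))
    list(mass = obs,
         p = vapply(obs, function(m) mean(null >= abs(m)), numeric(1)))
  }
  for (s in 1:4) {
    set.seed(s)
    X <- matrix(rnorm(5 * 12, mean = 0.4), 5, 12)
    got <- cluster_permutation_1d(X, chance = 0,
                                  config = cluster_config(n_permutations = 31,
                                                          seed = s))
    expect_true(got$exhaustive)
    want <- oracle_1d(X)
    expect_equal(vapply(got$clusters, `[[`, 0, "mass"), want$mass,
                 tolerance = 1e-10)
    expect_equal(vapply(got$clusters, `[[`, 0, "p"), want$p,
                 tolerance = 1e-12)
  }
  # all subjects exactly at chance everywhere: no clusters
  flat <- matrix(0.5, 6, 20)
  expect_warning(none <- cluster_permutation_1d(flat, 0.5,
                                                cluster_config(n_permutations = 63)),
                 NA)
  expect_equal(length(none$clusters), 0)
})

test_that("a strong planted boxcar is detected as one dominant cluster", {
  set.seed(7)
  n <- 20
  X <- matrix(rnorm(n * 120, 0, 0.05), n, 120) + 0.5
  X[, 31:80] <- X[, 31:80] + 0.1 # d = 2 over 50 contiguous points
  res <- cluster_permutation_1d(X, 0.5,
                                cluster_config(n_permutations = 255, seed = 1))
  ps <- vapply(res$clusters, `[[`, 0, "p")
  main <- res$clusters[[which.min(ps)]]
  expect_gte(length(intersect(main$members, 31:80)), 45)
  expect_equal(min(ps), 1 / 256) # minimal attainable Monte-Carlo p
  # monotonicity: scaling deviations up never increases the cluster p
  X2 <- 0.5 + (X - 0.5) * 2
  res2 <- cluster_permutation_1d(X2, 0.5,
                                 cluster_config(n_permutations = 255, seed = 1))
  expect_lte(min(vapply(res2$clusters, `[[`, 0, "p")), min(ps))
  # p-values are never exactly zero
  expect_true(all(ps > 0))
})

test_that("2D clustering uses 4-connectivity and matches its oracle", {
  # two supra-threshold cells touching only diagonally are two clusters
  n <- 6
  X <- array(0, c(n, 4, 4))
  X[, 2, 2] <- 1 + 0.01 * seq_len(n) # strong positive cells with tiny spread
  X[, 3, 3] <- 1 + 0.01 * seq_len(n)
  res <- cluster_permutation_2d(X, 0, cluster_config(n_permutations = 63))
  expect_equal(length(res$clusters), 2)
  expect_equal(sort(vapply(res$clusters, function(cl) length(cl$members), 1L)),
               c(1L, 1L))
  # exhaustive equivalence at n = 5: the full max-mass null matches a brute
  # force built on an independent component labeller (igraph on the lattice)
  oracle_null_2d <- function(Y, alpha = 0.05) {
    n <- dim(Y)[1]; d1 <- dim(Y)[2]; d2 <- dim(Y)[3]
    tcrit <- qt(1 - alpha / 2, n - 1)
    lattice <- igraph::make_lattice(c(d1, d2))
    signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
    apply(signs, 1, function(f) {
      Yf <- sweep(Y, 1, f, `*`)
      tv <- apply(Yf, c(2, 3), function(v) mean(v) / (sd(v) / sqrt(n)))
      best <- 0
      for (sgn in c(1, -1)) {
        mask <- as.vector((sgn * tv) > tcrit)
        if (!any(mask)) next
        sub <- igraph::induced_subgraph(lattice, which(mask))
        comp <- igraph::components(sub)$membership
        mass <- tapply(as.vector(tv)[which(mask)], comp, sum)
        best <- max(best, max(abs(mass)))
      }
      best
    })
  }
  set.seed(3)
  Y <- array(rnorm(5 * 3 * 3, 0.5), c(5, 3, 3))
  got <- cluster_permutation_2d(Y, 0, cluster_config(n_permutations = 31))
  expect_true(got$exhaustive)
  expect_equal(length(got$null_distribution), 32)
  expect_equal(sort(got$null_distribution), sort(oracle_null_2d(Y)),
               tolerance = 1e-10)
  # planted block generalization is detected
  set.seed(9)
  Z <- array(rnorm(12 * 10 * 10, 0, 0.05), c(12, 10, 10)) + 0.5
  Z[, 3:6, 3:6] <- Z[, 3:6, 3:6] + 0.08
  zres <- cluster_permutation_2d(Z, 0.5,
                                 cluster_config(n_permutations = 255, seed = 2))
  ps <- vapply(zres$clusters, `[[`, 0, "p")
  block <- zres$clusters[[which.min(ps)]]
  planted_cells <- as.vector(outer(3:6, (3:6 - 1) * 10, `+`))
  expect_gt(length(intersect(block$members, planted_cells)), 10)
  expect_lt(min(ps), 0.05)
})

test_that("windowed tests average inclusively, FDR-correct and attach BF10", {
  times <- seq(0, 0.5, by = 0.005)
  set.seed(4)
  n <- 20
  m <- matrix(rnorm(n * length(times), 0, 0.04), n) + 0.5
  on <- times >= 0.175 & times <= 0.225
  m[, on] <- m[, on] + 0.05
  res <- windowed_tests(m, times, centers = c(0.1, 0.2), half_width = 0.025)
  # 175-225 ms at 5 ms sampling: 11 samples averaged
  expect_equal(res$n_samples, c(11, 11))
  expect_equal(res$df, c(19, 19))
  # t on pre-averaged values equals the windowed t
  sel <- which(times >= 0.175 - 1e-9 & times <= 0.225 + 1e-9)
  expect_equal(res$t[2], one_sample_t(rowMeans(m[, sel]), 0.5)$t,
               tolerance = 1e-12)
  expect_true(res$significant[2])
  expect_false(res$significant[1])
  expect_gt(res$bf10[2], 3)
  # single window: FDR leaves p unchanged
  one <- windowed_tests(m, times, centers = 0.2)
  expect_equal(one$p_fdr, one$p)
  # list input spans the FDR family over directions
  both <- windowed_tests(list(a = m, b = m), times, centers = c(0.1, 0.2))
  expect_equal(nrow(both), 4)
  expect_equal(both$p_fdr, p.adjust(both$p, "BH"))
  expect_error(windowed_tests(m, times, centers = 5), "no samples")
})

test_that("Benjamini-Hochberg step-up behaves on the worked examples", {
  r1 <- fdr_bh(c(0.01, 0.02, 0.04), 0.05)
  expect_true(all(r1$reject)) # p_(3) = 0.04 <= 3 * 0.05 / 3
  r2 <- fdr_bh(c(0.04, 0.5), 0.05)
  expect_false(any(r2$reject))
  expect_equal(fdr_bh(numeric(0))$reject, logical(0))
  # against the independent step-up walk
  set.seed(2)
  p <- runif(20)^2
  adj <- fdr_bh(p)$p_adjusted
  expect_equal(adj, p.adjust(p, "BH"))
})

test_that("JZS Bayes factor is calibrated and numerically stable", {
  # a null-ish t favors the null
  expect_lt(bf10_jzs(0, 20), 1)
  # larger |t| gives more evidence for the alternative
  bfs <- sapply(c(0, 1, 2, 3, 4), function(t) bf10_jzs(t, 20))
  expect_true(all(diff(bfs) > 0))
  # quadrature self-convergence: tightening the tolerance changes nothing
  b1 <- bf10_jzs(2.08, 20, rel_tol = 1e-6)
  b2 <- bf10_jzs(2.08, 20, rel_tol = 1e-12)
  expect_lt(abs(b1 - b2) / b2, 1e-6)
  expect_error(bf10_jzs(Inf, 20), "finite")
  # wider prior scale shrinks evidence for small effects (sanity)
  expect_lt(bf10_jzs(1, 20, r = 1), bf10_jzs(1, 20, r = 0.5))
})

test_that("1D cluster test controls the family-wise error rate on null data", {
  # modest-size calibration run; the full-size one lives in the acceptance
  # suite
  set.seed(11)
  n_sim <- 60
  hits <- sapply(seq_len(n_sim), function(s) {
    X <- matrix(rnorm(10 * 40), 10, 40) * 0.03 + 0.5
    res <- cluster_permutation_1d(X, 0.5,
                                  cluster_config(n_permutations = 128,
                                                 seed = s))
    any(vapply(res$clusters, `[[`, 0, "p") < 0.05)
  })
  # 95% binomial band around 0.05 for 60 draws: at most ~8 hits
  expect_lte(sum(hits), qbinom(0.975, n_sim, 0.05) + 1)
})
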