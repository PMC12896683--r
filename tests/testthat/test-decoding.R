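test_that("sliding-window features concatenate sensors over the window", {
  ep <- tiny_epochs(n_trials = 6, n_sensors = 3, n_samples = 10, seed = 1)
  # 306 sensors x 5 samples would give 1530 features; here 3 x 5 = 15
  x <- extract_features(ep, ep$times[5], window_samples = 5)
  expect_equal(dim(x), c(6, 15))
  expect_equal(x[2, ], as.vector(ep$data[2, , 3:7]))
  # window 1 returns the single-sample sensor vector
  x1 <- extract_features(ep, ep$times[5], window_samples = 1)
  expect_equal(x1[3, ], ep$data[3, , 5])
  # with 10 samples and window 5, only centers 3..8 are valid
  expect_error(extract_features(ep, ep$times[2], 5), "edge")
  expect_error(extract_features(ep, ep$times[9], 5), "edge")
  expect_silent(extract_features(ep, ep$times[3], 5))
  expect_silent(extract_features(ep, ep$times[8], 5))
})

test_that("class balancing subsamples the majority to the minority count", {
  labs <- c(rep("left", 300), rep("right", 100))
  keep <- balance_classes(labs, seed = 4)
  expect_equal(sum(labs[keep] == "left"), 100)
  expect_equal(sum(labs[keep] == "right"), 100)
  expect_true(all(which(labs == "right") %in% keep))
  # equal counts: everything retained
  expect_equal(balance_classes(rep(c("a", "b"), 5)), 1:10)
  # a single class errors
  expect_error(balance_classes(rep("left", 5)), "two")
})

test_that("pseudotrials partition each class into groups of m", {
  set.seed(2)
  x <- matrix(rnorm(40 * 3), 40)
  y <- rep(c("left", "right"), each = 20)
  pt <- make_pseudotrials(x, y, m = 5, seed = 9)
  expect_equal(nrow(pt$features), 8) # floor(20/5) per class
  expect_equal(table(pt$labels)[["left"]], 4)
  # m = 1 returns the original trials (up to order)
  pt1 <- make_pseudotrials(x, y, m = 1, seed = 1)
  expect_equal(nrow(pt1$features), 40)
  expect_equal(sort(pt1$features[, 1]), sort(x[, 1]))
  # 13 trials with m = 5 -> 2 pseudotrials, 3 dropped
  pt2 <- make_pseudotrials(x[1:13, ], y[1:13], m = 5, seed = 1)
  expect_equal(nrow(pt2$features), 2)
  # each pseudotrial is a mean of m distinct trials: column means preserved
  expect_equal(colMeans(pt$features[pt$labels == "left", ]),
               colMeans(x[1:20, ]), tolerance = 1e-12)
  # fewer than m trials in every class errors
  expect_error(make_pseudotrials(x[1:3, ], y[1:3], m = 5), "at least m")
})

test_that("standardization is fit on train only, with the zero-SD rule", {
  tr <- matrix(c(1, 3, 10, 10), 2) # second feature constant
  te <- matrix(c(0, 2, 11, 12), 2)
  st <- standardize_features(tr, te)
  expect_equal(st$train[, 1], c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(st$train[, 2], c(0, 0))
  expect_equal(st$test[, 2], c(0, 0))
  # test = train maps to the same z-scores
  st2 <- standardize_features(tr, tr)
  expect_equal(st2$test, st2$train)
  # train columns have mean 0, sd 1 after transform
  set.seed(1)
  z <- standardize_features(matrix(rnorm(50), 10))$train
  expect_lt(max(abs(colMeans(z))), 1e-12)
  expect_equal(apply(z, 2, sd), rep(1, 5), tolerance = 1e-12)
})

test_that("univariate F selection ranks by the one-way ANOVA statistic", {
  # classes A = {0, 2}, B = {4, 6}: SSB = 16, SSW = 4 -> F = 8
  tr <- cbind(c(0, 2, 4, 6), c(1, -1, 1, -1))
  f_oracle <- summary(aov(tr[, 1] ~ factor(c("a", "a", "b", "b"))))[[1]]$`F value`[1]
  expect_equal(f_oracle, 8, tolerance = 1e-12)
  expect_equal(select_features_f(tr, c("a", "a", "b", "b"), 1), 1L)
  # k = n_features is the identity selection
  expect_setequal(select_features_f(tr, c("a", "a", "b", "b"), 2), 1:2)
  expect_warning(sel <- select_features_f(tr, c("a", "a", "b", "b"), 5),
                 "exceeds")
  expect_equal(length(sel), 2)
  # planted informative features are found at high SNR
  hits <- sapply(1:5, function(s) {
    set.seed(s)
    y <- rep(c("a", "b"), each = 30)
    x <- matrix(rnorm(60 * 100), 60)
    x[y == "b", 1:10] <- x[y == "b", 1:10] + 2.5
    sum(select_features_f(x, y, 10) <= 10)
  })
  expect_true(all(hits >= 9))
})

test_that("linear classifiers recover separating directions and AUC oracle holds", {
  # two separable points: training AUC 1
  X <- rbind(c(-1, 0), c(1, 0))
  m <- train_linear_classifier(X, c("left", "right"), decoding_config())
  expect_equal(auc_score(predict(m, X), c("left", "right")), 1)
  # label flip negates scores up to solver tolerance
  m2 <- train_linear_classifier(X, c("right", "left"), decoding_config())
  expect_equal(predict(m2, X), -predict(m, X), tolerance = 1e-6)
  # Gaussian classes: weight vector aligns with the mean difference
  for (clf in c("linear_svm", "logistic")) {
    set.seed(3)
    n <- 250
    mu <- c(1, -0.5, 0.25, 0, 0)
    Xg <- rbind(matrix(rnorm(n * 5), n, 5) + rep(mu, each = n),
                matrix(rnorm(n * 5), n, 5) - rep(mu, each = n))
    yg <- rep(c("b", "a"), each = n)
    mg <- train_linear_classifier(Xg, yg, decoding_config(classifier = clf))
    expect_gt(abs(cor(mg$w, mu)), 0.9)
    # orientation: larger scores for the positive (second sorted) class
    sc <- predict(mg, Xg)
    expect_gt(mean(sc[yg == "b"]), mean(sc[yg == "a"]))
  }
  expect_error(train_linear_classifier(X, c("left", "left"), decoding_config()),
               "two classes")
})

test_that("auc_score equals exhaustive pair counting and is equivariant", {
  pair_auc <- function(s, y, pos) {
    sp <- s[y == pos]; sn <- s[y != pos]
    cmp <- outer(sp, sn, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  expect_equal(auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc_score(c(3, 2, 1), c(1, 0, 0)), 1)
  expect_equal(auc_score(rep(1, 6), rep(c(0, 1), 3)), 0.5)
  # oracle equivalence on random instances with <= 12 trials, incl. ties
  for (s in 1:50) {
    set.seed(s)
    n <- sample(4:12, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    sc <- sample(seq(0, 1, 0.1), n, replace = TRUE)
    expect_equal(auc_score(sc, y), pair_auc(sc, y, 1))
    # label-flip equivariance and monotone invariance
    expect_equal(auc_score(sc, 1 - y), 1 - auc_score(sc, y))
    expect_equal(auc_score(exp(3 * sc), y), auc_score(sc, y))
  }
  # independent cross-check against pROC
  set.seed(99)
  sc <- rnorm(40); y <- sample(0:1, 40, replace = TRUE)
  expect_equal(auc_score(sc, y),
               as.numeric(pROC::auc(pROC::roc(y, sc, quiet = TRUE,
                                              direction = "<"))))
})

test_that("Haufe transform maps weights through the covariance", {
  # identity covariance: pattern proportional to the weights
  set.seed(5)
  X <- matrix(rnorm(4000), 1000, 4)
  X <- scale(X, scale = FALSE) %*% solve(chol(cov(X))) # exact identity cov
  m <- structure(list(w = c(1, 2, 0, -1), b = 0, classes = c("a", "b")),
                 class = "linear_model")
  a <- haufe_patterns(X, m)
  expect_equal(a, m$w / sqrt(sum(m$w^2)), tolerance = 1e-6)
  # cov [[2,1],[1,1]] with w = (1, 0) gives pattern prop. to (2, 1)
  S <- matrix(c(2, 1, 1, 1), 2)
  X2 <- matrix(rnorm(4000), 2000, 2)
  X2 <- scale(X2, scale = FALSE) %*% solve(chol(cov(X2))) %*% chol(S)
  m2 <- structure(list(w = c(1, 0), b = 0, classes = c("a", "b")),
                  class = "linear_model")
  a2 <- haufe_patterns(X2, m2)
  expect_equal(a2, c(2, 1) / sqrt(5), tolerance = 1e-6)
  expect_gte(sum(a2 * m2$w), 0)
})

test_that("decoder weights recover the planted sensor pattern", {
  # high-SNR planted pattern; sensor-averaged Haufe pattern matches it
  tab <- generate_design(design_config(n_sessions = 1, blocks_per_session = 1,
                                       trials_per_block = 200, seed = 8))
  pat <- make_effect_patterns(12, seed = 9)
  eff <- effects_only(presearch = list(amplitude = 1.5, window = c(0.1, 0.4),
                                       ramp = 0.025))
  ep <- simulate_epochs(tab, pat, eff, noise_spec(seed = 10),
                        epoch_span = c(0, 0.5))
  keep <- which(ep$trial_table$distractor_hemifield %in% c("left", "right"))
  x <- extract_features(ep, 0.25, 5)[keep, ]
  y <- ep$trial_table$distractor_hemifield[keep]
  st <- standardize_features(x)
  m <- train_linear_classifier(st$train, y, decoding_config())
  a <- haufe_patterns(st$train, m)
  a_sensor <- rowMeans(matrix(a, nrow = 12))
  expect_gt(abs(cor(a_sensor, pat$p_pre)), 0.9)
})

test_that("decode_timecourse separates planted from empty windows and does not leak", {
  eff <- effects_only(presearch = list(amplitude = 0.4, window = c(0.1, 0.7),
                                       ramp = 0.025))
  group <- lapply(1:6, function(s) sim_subject(s, n_sensors = 16,
                                               trials_per_block = 120,
                                               n_sessions = 1, effects = eff,
                                               epoch_span = c(0, 1.5)))
  cfg <- decoding_config(time_step = 25, seed = 2)
  res <- decode_timecourse(group, "distractor_hemifield", cfg)
  expect_equal(dim(res$auc), c(6, length(res$times)))
  planted <- res$times >= 0.15 & res$times <= 0.65
  empty <- res$times >= 1.0 & res$times <= 1.4
  expect_gt(mean(res$auc[, planted]), 0.75)
  expect_lt(abs(mean(res$auc[, empty]) - 0.5), 0.06)
  # shuffled labels: full pipeline at chance (no leakage through
  # balancing, standardization or selection)
  null_mean <- sapply(1:6, function(s) {
    ep <- sim_subject(50 + s, n_sensors = 16, trials_per_block = 120,
                      n_sessions = 1, effects = effects_only(),
                      epoch_span = c(0, 0.4))
    cfgs <- decoding_config(time_step = 20, feature_select_k = 20, seed = s)
    mean(decode_timecourse(ep, "distractor_hemifield", cfgs)$auc)
  })
  expect_lt(abs(mean(null_mean) - 0.5), 0.05)
})
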