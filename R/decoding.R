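# Decoding primitives: sliding-window features, class balancing, pseudotrial
# averaging, train-fitted z-scoring, univariate F feature selection, linear
# classifiers with extractable weights, ROC AUC, Haufe activation patterns.

#' Decoding configuration
#'
#' @param window_samples odd number of samples in the sliding feature window
#'   (default 5, i.e. 25 ms at 200 Hz; the window is centered, so edge
#'   centers that do not fit are excluded rather than padded).
#' @param pseudotrial_size trials averaged per pseudotrial (default 5).
#' @param n_folds cross-validation folds (default 5).
#' @param classifier "linear_svm" (hinge-loss max-margin) or "logistic"
#'   (ridge-penalized logistic regression).
#' @param regularization inverse penalty strength; cost `C` for the SVM,
#'   `1/lambda` for the logistic ridge (default 1).
#' @param feature_select_k keep the k largest univariate F statistics
#'   (NULL = no selection).
#' @param balance subsample the majority class to the minority count before
#'   splitting (default TRUE; skipped automatically when classes are equal).
#' @param n_repeats repeated pseudotrial/subsampling draws averaged per fold.
#' @param time_step stride, in samples, between evaluated time centers.
#' @param seed RNG seed; per-session/fold seeds are derived from it.
#' @return a `decoding_config` list.
#' @export
decoding_config <- function(window_samples = 5, pseudotrial_size = 5,
                            n_folds = 5, classifier = c("linear_svm", "logistic"),
                            regularization = 1, feature_select_k = NULL,
                            balance = TRUE, n_repeats = 1, time_step = 1,
                            seed = 1) {
  classifier <- match.arg(classifier)
  .assert(window_samples >= 1 && window_samples %% 2 == 1,
          "window_samples must be odd and >= 1")
  .assert(pseudotrial_size >= 1, "pseudotrial_size must be >= 1")
  .assert(n_folds >= 2, "n_folds must be >= 2")
  .assert(regularization > 0, "regularization must be > 0")
  structure(as.list(environment()), class = "decoding_config")
}

#' Extract sliding-window features at a time center
#'
#' Concatenates, per trial, the sensor values over `window_samples` samples
#' centered at `t_center` (sensor index varying fastest). With 306 sensors
#' and a 5-sample window the feature vector has 306 x 5 = 1530 elements.
#'
#' @param epochs an `epoch_set`.
#' @param t_center window center (s); must coincide with a sample and leave
#'   `(window_samples - 1)/2` samples on each side.
#' @param window_samples odd window length in samples.
#' @return a trials x (sensors * window_samples) matrix.
#' @export
extract_features <- function(epochs, t_center, window_samples = 5) {
  .assert(window_samples >= 1 && window_samples %% 2 == 1,
          "window_samples must be odd")
  i <- which.min(abs(epochs$times - t_center))
  .assert(abs(epochs$times[i] - t_center) <= 0.5 / epochs$sfreq + 1e-9,
          "t_center does not coincide with a sample")
  half <- (window_samples - 1) / 2
  .assert(i - half >= 1 && i + half <= length(epochs$times),
          "window around t_center extends past the epoch edge")
  x <- epochs$data[, , (i - half):(i + half), drop = FALSE]
  dim(x) <- c(dim(x)[1], dim(x)[2] * dim(x)[3])
  x
}

# valid center indices for a window, honoring the stride
.valid_centers <- function(n_samples, window_samples, time_step = 1) {
  half <- (window_samples - 1) / 2
  seq(half + 1, n_samples - half, by = time_step)
}

#' Balance two classes by subsampling the majority
#'
#' Randomly subsamples the majority class without replacement down to the
#' minority count; the minority class is retained in full.
#'
#' @param labels two-class label vector.
#' @param seed RNG seed.
#' @return sorted indices of retained elements.
#' @export
balance_classes <- function(labels, seed = 1) {
  cls <- sort(unique(as.character(labels)))
  .assert(length(cls) == 2, "labels must contain exactly two non-empty classes")
  i1 <- which(labels == cls[1]); i2 <- which(labels == cls[2])
  .assert(length(i1) > 0 && length(i2) > 0, "a class has zero members")
  k <- min(length(i1), length(i2))
  with_seed(seed, {
    keep <- c(if (length(i1) > k) sample(i1, k) else i1,
              if (length(i2) > k) sample(i2, k) else i2)
    sort(keep)
  })
}

#' Average trials into pseudotrials
#'
#' Within each class, randomly partitions the trials into groups of exactly
#' `m` (any remainder is dropped) and averages each group; each original
#' trial contributes to at most one pseudotrial. Raises an error only if no
#' class yields at least one pseudotrial.
#'
#' @param features trials x features matrix.
#' @param labels label vector, one per row.
#' @param m trials per pseudotrial.
#' @param seed RNG seed for the random partition.
#' @return list with `features` (pseudotrials x features) and `labels`.
#' @export
make_pseudotrials <- function(features, labels, m = 5, seed = 1) {
  .assert(m >= 1, "m must be >= 1")
  labels <- as.character(labels)
  with_seed(seed, {
    out_x <- list(); out_y <- character(0)
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      k <- floor(length(idx) / m)
      if (k == 0) next
      perm <- if (length(idx) > 1) sample(idx) else idx
      grp <- rep(seq_len(k), each = m)
      xg <- rowsum(features[perm[seq_len(k * m)], , drop = FALSE], grp) / m
      out_x[[cl]] <- xg
      out_y <- c(out_y, rep(cl, k))
    }
    .assert(length(out_y) > 0, "no class has at least m trials")
    feat <- do.call(rbind, out_x)
    dimnames(feat) <- NULL
    list(features = feat, labels = out_y)
  })
}

#' Z-score features with train-estimated parameters
#'
#' Per-feature mean and SD (n-1 denominator) are estimated on the training
#' set only and applied to both sets. Features with (near-)zero training SD
#' are mapped to zero in both sets.
#'
#' @param train,test feature matrices with matching columns.
#' @return list with `train`, `test`, and the `center`/`scale` used.
#' @export
standardize_features <- function(train, test = NULL) {
  .assert(nrow(train) >= 1, "empty training set")
  mu <- colMeans(train)
  sdv <- if (nrow(train) > 1) {
    sqrt(colSums(sweep(train, 2, mu)^2) / (nrow(train) - 1))
  } else rep(0, ncol(train))
  dead <- !is.finite(sdv) | sdv < 1e-12
  sdv[dead] <- 1
  tr <- sweep(sweep(train, 2, mu), 2, sdv, "/")
  tr[, dead] <- 0
  te <- NULL
  if (!is.null(test)) {
    te <- sweep(sweep(test, 2, mu), 2, sdv, "/")
    te[, dead] <- 0
  }
  list(train = tr, test = te, center = mu, scale = sdv, dead = dead)
}

#' Univariate F-test feature selection
#'
#' Ranks features by the one-way ANOVA F statistic computed on the training
#' set only and returns the indices of the k largest.
#'
#' @param train trials x features training matrix.
#' @param labels class labels.
#' @param k number of features to keep (clamped to the feature count with a
#'   warning if larger).
#' @return integer vector of selected column indices.
#' @export
select_features_f <- function(train, labels, k) {
  .assert(k >= 1, "k must be >= 1")
  labels <- as.character(labels)
  cls <- unique(labels)
  .assert(length(cls) >= 2, "need at least two classes")
  if (k > ncol(train)) {
    warning("k exceeds the number of features; keeping all")
    k <- ncol(train)
  }
  n <- nrow(train)
  gm <- colMeans(train)
  ssb <- 0; ssw <- 0
  for (cl in cls) {
    xg <- train[labels == cl, , drop = FALSE]
    mg <- colMeans(xg)
    ssb <- ssb + nrow(xg) * (mg - gm)^2
    ssw <- ssw + colSums(sweep(xg, 2, mg)^2)
  }
  fstat <- (ssb / (length(cls) - 1)) / (ssw / (n - length(cls)))
  fstat[!is.finite(fstat)] <- Inf # zero within-class variance: maximal evidence
  order(fstat, decreasing = TRUE)[seq_len(k)]
}

#' Fit a linear two-class classifier
#'
#' Either a linear support vector machine (via libsvm) or ridge-penalized
#' logistic regression (via glmnet). The fitted rule is reduced to explicit
#' weights: `score(x) = <w, x> + b`, oriented so that larger scores favor the
#' second of the (alphabetically sorted) class labels — the same orientation
#' [auc_score()] treats as positive.
#'
#' @param X trials x features matrix.
#' @param y two-class label vector.
#' @param config a [decoding_config()] (classifier and regularization used).
#' @return a `linear_model` with elements `w`, `b`, `classes`.
#' @export
train_linear_classifier <- function(X, y, config = decoding_config()) {
  y <- as.character(y)
  cls <- sort(unique(y))
  .assert(length(cls) == 2, "need exactly two classes")
  .assert(all(is.finite(X)), "non-finite features")
  if (config$classifier == "linear_svm") {
    fit <- e1071::svm(x = X, y = factor(y, levels = cls), kernel = "linear",
                      cost = config$regularization, scale = FALSE)
    w <- drop(crossprod(fit$coefs, fit$SV))
    b <- -fit$rho
  } else {
    y01 <- as.integer(y == cls[2])
    lam <- 1 / (config$regularization * nrow(X))
    # glmnet warns about class counts below 8; expected with pseudotrials
    fit <- withCallingHandlers(
      glmnet::glmnet(X, y01, family = "binomial", alpha = 0,
                     lambda = lam, standardize = FALSE),
      warning = function(w) {
        if (grepl("fewer than 8|one multinomial", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    cf <- as.numeric(stats::coef(fit, s = lam))
    w <- cf[-1]
    b <- cf[1]
  }
  # orient scores toward the positive (second) class
  s <- drop(X %*% w) + b
  if (mean(s[y == cls[2]]) < mean(s[y == cls[1]])) {
    w <- -w; b <- -b
  }
  structure(list(w = w, b = b, classes = cls), class = "linear_model")
}

#' @export
predict.linear_model <- function(object, newdata, ...) {
  drop(newdata %*% object$w) + object$b
}

#' Area under the ROC curve
#'
#' The Mann-Whitney statistic: the fraction of (positive, negative) pairs in
#' which the positive score exceeds the negative one, ties counted one half.
#' The positive class is the larger of the two sorted labels (so label 1 for
#' 0/1 labels, "right" for left/right), overridable via `positive`.
#'
#' @param scores numeric decision scores.
#' @param labels two-class labels.
#' @param positive label treated as positive (default: last sorted label).
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels, positive = NULL) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  .assert(length(cls) == 2, "labels must contain exactly two classes")
  positive <- positive %||% cls[2]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  .assert(n1 > 0 && n0 > 0, "both classes must be non-empty")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Haufe activation-pattern transform
#'
#' Converts linear decoder weights into an encoding (activation) pattern
#' `A = Cov(X) w`, normalized to unit norm with the sign fixed so that
#' `<A, w> >= 0`. A small ridge proportional to the mean feature variance is
#' added to the covariance diagonal to handle degeneracy.
#'
#' @param X the (standardized) data the model was fit on.
#' @param model a `linear_model`.
#' @return unit-norm activation pattern in feature space.
#' @export
haufe_patterns <- function(X, model) {
  .assert(inherits(model, "linear_model"), "model must be a linear_model")
  cv <- stats::cov(X)
  eps <- 1e-10 * mean(diag(cv))
  if (!is.finite(eps) || eps <= 0) eps <- 1e-12
  a <- drop((cv + diag(eps, ncol(X))) %*% model$w)
  nrm <- sqrt(sum(a^2))
  if (nrm > 0) a <- a / nrm
  if (sum(a * model$w) < 0) a <- -a
  a
}
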