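# Subject/group-level analyses built on the session decoding engine.

# sample indices of valid strided centers, optionally restricted to a
# half-open time window
.centers_in <- function(epochs, config, t_window = NULL) {
  idx <- .valid_centers(n_samples(epochs), config$window_samples,
                        config$time_step)
  if (!is.null(t_window)) {
    tol <- 1e-6 / epochs$sfreq
    tt <- epochs$times[idx]
    idx <- idx[tt >= t_window[1] - tol & tt < t_window[2] - tol]
  }
  .assert(length(idx) > 0, "no valid time centers in the requested window")
  idx
}

#' Time-resolved decoding of a condition label
#'
#' For each valid time center, classifies the two-class label from
#' sliding-window sensor features with the full cross-validation discipline
#' (balancing, pseudotrials formed separately in train and test folds,
#' train-fitted z-scoring, optional F selection). Sessions are decoded
#' independently and averaged within subject; trials whose label is NA or
#' "absent" are dropped.
#'
#' @param epochs an `epoch_set` (one subject) or a list of them (a group).
#' @param label_column trial-table column to decode (e.g.
#'   "distractor_hemifield").
#' @param config a [decoding_config()].
#' @param t_window optional half-open `c(t0, t1)` restriction of the time
#'   centers (s).
#' @return a `decoding_result`: `times`, `auc` (subjects x times matrix),
#'   `chance = 0.5`, `config`.
#' @export
decode_timecourse <- function(epochs, label_column,
                              config = decoding_config(), t_window = NULL) {
  label_transfer(epochs, label_column, label_column, config, t_window)
}

#' Train on one label, test on another
#'
#' Per time point, fits the classifier in cross-validation on `train_label`
#' and scores held-out pseudotrials against `test_label` (e.g. train on the
#' previous trial's distractor hemifield, test on the current one). Trials
#' are restricted to those where both labels are defined; pseudotrials are
#' grouped within joint label cells so every pseudotrial has a pure label on
#' both columns. With `train_label == test_label` this reduces exactly to
#' [decode_timecourse()].
#'
#' @inheritParams decode_timecourse
#' @param train_label,test_label trial-table columns.
#' @return a `decoding_result` (see [decode_timecourse()]).
#' @export
label_transfer <- function(epochs, train_label, test_label,
                           config = decoding_config(), t_window = NULL) {
  subjects <- .as_subject_list(epochs)
  centers <- .centers_in(subjects[[1]], config, t_window)
  auc <- t(vapply(seq_along(subjects), function(i) {
    .subject_decode(subjects[[i]], train_label, test_label, config,
                    centers, mode = "diag", test_centers = NULL,
                    seed = derive_seed(config$seed, paste0("subj", i)))
  }, numeric(length(centers))))
  structure(list(times = subjects[[1]]$times[centers], auc = auc,
                 chance = 0.5, config = config,
                 train_label = train_label, test_label = test_label),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s -> %s: %d subject(s) x %d times, mean peak AUC %.3f at %.3f s\n",
              x$train_label, x$test_label, nrow(x$auc), ncol(x$auc),
              max(colMeans(x$auc), na.rm = TRUE),
              x$times[which.max(colMeans(x$auc))]))
  invisible(x)
}

#' Temporal generalization matrix
#'
#' Trains at each time center and tests the fitted decoder at every other
#' center on the same fold's held-out pseudotrials; z-scoring parameters are
#' estimated on the training pseudotrials at the train time and applied to
#' test features at every test time. The classifier defaults to logistic
#' regression for generalization analyses.
#'
#' @inheritParams decode_timecourse
#' @return a `tg_matrix`: `train_times`, `test_times`, `auc` (subjects x
#'   train x test array), `config`.
#' @export
temporal_generalization <- function(epochs, label_column,
                                    config = decoding_config(classifier = "logistic"),
                                    t_window = NULL) {
  subjects <- .as_subject_list(epochs)
  centers <- .centers_in(subjects[[1]], config, t_window)
  n_c <- length(centers)
  auc <- array(NA_real_, c(length(subjects), n_c, n_c))
  for (i in seq_along(subjects)) {
    auc[i, , ] <- .subject_decode(subjects[[i]], label_column, label_column,
                                  config, centers, mode = "full",
                                  test_centers = NULL,
                                  seed = derive_seed(config$seed, paste0("subj", i)))
  }
  tt <- subjects[[1]]$times[centers]
  structure(list(train_times = tt, test_times = tt, auc = auc,
                 config = config, label_column = label_column),
            class = "tg_matrix")
}

#' Cross-epoch lag-aligned generalization curves
#'
#' For each lag tau, trains at `pre_start + tau` and tests the held-out
#' pseudotrials at `post_start + tau` (direction pre->post), and vice versa
#' (post->pre). Lags advance in steps of `lag_step` samples from the
#' interval onsets; lags whose feature window would cross an epoch edge are
#' dropped. The two directions share one lag grid because the intervals have
#' equal length.
#'
#' @inheritParams decode_timecourse
#' @param pre_interval,post_interval half-open `c(start, end)` training/test
#'   intervals of equal length (defaults `c(0, 1)` and `c(1.5, 2.5)` s).
#' @param lag_step lag grid step in samples (default 1, i.e. 5 ms at 200 Hz).
#' @return a `lag_curve`: `lags` (s), `auc_pre2post` and `auc_post2pre`
#'   (subjects x lags matrices), the intervals and config.
#' @export
cross_epoch_curves <- function(epochs, label_column,
                               pre_interval = c(0, 1), post_interval = c(1.5, 2.5),
                               config = decoding_config(classifier = "logistic"),
                               lag_step = 1) {
  .assert(abs(diff(pre_interval) - diff(post_interval)) < 1e-9,
          "pre and post intervals must have equal length")
  subjects <- .as_subject_list(epochs)
  ep1 <- subjects[[1]]
  dt <- 1 / ep1$sfreq
  tol <- 1e-6 * dt
  half <- (config$window_samples - 1) / 2
  nearest <- function(t) which.min(abs(ep1$times - t))
  i_pre0 <- nearest(pre_interval[1]); i_post0 <- nearest(post_interval[1])
  n_lag_full <- floor(diff(pre_interval) / dt / lag_step)
  lag_idx <- (seq_len(n_lag_full) - 1) * lag_step
  pre_c <- i_pre0 + lag_idx
  post_c <- i_post0 + lag_idx
  ok <- pre_c - half >= 1 & post_c - half >= 1 &
    pre_c + half <= n_samples(ep1) & post_c + half <= n_samples(ep1) &
    ep1$times[pre_c] < pre_interval[2] - tol &
    ep1$times[post_c] < post_interval[2] - tol
  .assert(any(ok), "no valid lags: intervals incompatible with the epoch span")
  pre_c <- pre_c[ok]; post_c <- post_c[ok]
  lags <- ep1$times[pre_c] - ep1$times[i_pre0]

  run_dir <- function(train_c, test_c, tag) {
    t(vapply(seq_along(subjects), function(i) {
      .subject_decode(subjects[[i]], label_column, label_column, config,
                      centers = train_c, mode = "pairs", test_centers = test_c,
                      seed = derive_seed(config$seed, paste0(tag, "/subj", i)))
    }, numeric(length(train_c))))
  }
  structure(list(lags = lags,
                 auc_pre2post = run_dir(pre_c, post_c, "pre2post"),
                 auc_post2pre = run_dir(post_c, pre_c, "post2pre"),
                 pre_interval = pre_interval, post_interval = post_interval,
                 config = config, label_column = label_column),
            class = "lag_curve")
}
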