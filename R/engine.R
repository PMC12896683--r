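# Session-level cross-validated decoding engine shared by the time-course,
# temporal-generalization, cross-epoch and label-transfer analyses.
#
# Discipline per session: filter trials with defined labels -> optional
# majority-class subsampling -> stratified K-fold split of raw trials ->
# per fold, pseudotrials formed separately within train and test ->
# z-scoring fit on training pseudotrials at the train time -> optional
# univariate F feature selection -> linear fit -> held-out AUC. Pseudotrial
# averaging commutes with time-window extraction, so group-averaged trials
# are computed once per fold and features are sliced from them per center.

.defined_two_class <- function(x) !is.na(x) & x %in% c("left", "right")

# stratified fold assignment: within each class, shuffled round-robin
.stratified_folds <- function(labels, k, seed) {
  fold <- integer(length(labels))
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- if (length(idx) > 1) sample(idx) else idx
      fold[idx] <- rep(seq_len(k), length.out = length(idx))
    }
  })
  fold
}

# random partition of idx into groups of exactly m within each cell
.pseudo_assign <- function(idx, cells, m, seed) {
  groups <- list()
  with_seed(seed, {
    for (cl in sort(unique(cells))) {
      ci <- idx[cells == cl]
      kk <- floor(length(ci) / m)
      if (kk == 0) next
      perm <- if (length(ci) > 1) sample(ci) else ci
      for (g in seq_len(kk)) {
        groups[[length(groups) + 1L]] <- perm[((g - 1) * m + 1):(g * m)]
      }
    }
  })
  groups
}

# average flat (trials x features) rows over a list of index groups
.group_means <- function(flat, groups) {
  g <- rep(seq_along(groups), lengths(groups))
  rowsum(flat[unlist(groups), , drop = FALSE], g) / lengths(groups)
}

# feature column indices of a window centered at sample index i
.window_cols <- function(i, half, n_sensors) {
  smp <- (i - half):(i + half)
  as.vector(outer(seq_len(n_sensors), (smp - 1) * n_sensors, "+"))
}

# Decode one session. centers/test_centers are sample indices; mode is
# "diag" (test where you train), "full" (every train x test pair) or
# "pairs" (test_centers[j] paired with centers[j]). Returns an AUC array:
# vector (diag/pairs) or train x test matrix (full).
.session_decode <- function(epochs, train_label, test_label, config,
                            centers, mode = "diag", test_centers = NULL,
                            seed = 1) {
  tab <- epochs$trial_table
  .assert(train_label %in% names(tab), paste("no label column", train_label))
  .assert(test_label %in% names(tab), paste("no label column", test_label))
  keep <- which(.defined_two_class(tab[[train_label]]) &
                  .defined_two_class(tab[[test_label]]))
  .assert(length(keep) > 0, "no trials with both labels defined")
  y_tr <- tab[[train_label]][keep]
  y_te <- tab[[test_label]][keep]
  .assert(length(unique(y_tr)) == 2, "train label must have two classes")

  if (isTRUE(config$balance) && length(unique(table(y_tr))) > 1) {
    b <- balance_classes(y_tr, seed = derive_seed(seed, "balance"))
    keep <- keep[b]; y_tr <- y_tr[b]; y_te <- y_te[b]
  }
  need <- config$n_folds * config$pseudotrial_size
  .assert(min(table(y_tr)) >= need,
          sprintf("fewer than n_folds x pseudotrial_size = %d trials per class after balancing", need))

  flat <- matrix(epochs$data[keep, , , drop = FALSE], nrow = length(keep))
  n_se <- n_sensors(epochs)
  half <- (config$window_samples - 1) / 2
  m <- config$pseudotrial_size

  n_test <- switch(mode, diag = 1L, pairs = 1L, full = length(centers))
  acc <- array(0, c(length(centers), n_test))
  cnt <- array(0, c(length(centers), n_test))

  folds <- .stratified_folds(y_tr, config$n_folds, derive_seed(seed, "folds"))
  for (rep_i in seq_len(config$n_repeats)) {
    for (k in seq_len(config$n_folds)) {
      tr <- which(folds != k); te <- which(folds == k)
      # train pseudotrials are pure in the train label, test pseudotrials in
      # the test label (identical partitions when the labels coincide)
      g_tr <- .pseudo_assign(tr, y_tr[tr], m,
                             derive_seed(seed, sprintf("pt/%d/%d/train", rep_i, k)))
      g_te <- .pseudo_assign(te, y_te[te], m,
                             derive_seed(seed, sprintf("pt/%d/%d/test", rep_i, k)))
      if (!length(g_tr) || !length(g_te)) next
      ptr <- .group_means(flat, g_tr)
      pte <- .group_means(flat, g_te)
      ytr_p <- y_tr[vapply(g_tr, `[`, integer(1), 1)]
      yte_p <- y_te[vapply(g_te, `[`, integer(1), 1)]
      if (length(unique(ytr_p)) < 2) next

      for (ci in seq_along(centers)) {
        cols <- .window_cols(centers[ci], half, n_se)
        std <- standardize_features(ptr[, cols, drop = FALSE])
        xtr <- std$train
        sel <- NULL
        if (!is.null(config$feature_select_k)) {
          sel <- select_features_f(xtr, ytr_p, config$feature_select_k)
          xtr <- xtr[, sel, drop = FALSE]
        }
        model <- train_linear_classifier(xtr, ytr_p, config)

        t2set <- switch(mode,
                        diag = centers[ci],
                        pairs = test_centers[ci],
                        full = centers)
        for (tj in seq_along(t2set)) {
          cols2 <- .window_cols(t2set[tj], half, n_se)
          xte <- sweep(sweep(pte[, cols2, drop = FALSE], 2, std$center),
                       2, std$scale, "/")
          if (any(std$dead)) xte[, std$dead] <- 0
          if (!is.null(sel)) xte <- xte[, sel, drop = FALSE]
          if (length(unique(yte_p)) == 2) {
            a <- auc_score(predict(model, xte), yte_p)
            acc[ci, tj] <- acc[ci, tj] + a
            cnt[ci, tj] <- cnt[ci, tj] + 1
          }
        }
      }
    }
  }
  .assert(any(cnt > 0), "no fold produced test pseudotrials for both classes")
  out <- acc / pmax(cnt, 1)
  out[cnt == 0] <- NA_real_
  if (mode == "full") out else drop(out)
}

# split an epoch_set by session, decode each, average within subject
.subject_decode <- function(epochs, train_label, test_label, config,
                            centers, mode, test_centers, seed) {
  sess <- unique(epochs$trial_table$session)
  res <- lapply(seq_along(sess), function(si) {
    idx <- which(epochs$trial_table$session == sess[si])
    .session_decode(subset_trials(epochs, idx), train_label, test_label,
                    config, centers, mode, test_centers,
                    seed = derive_seed(seed, paste0("sess", sess[si])))
  })
  # session average, ignoring cells a session could not score
  arr <- simplify2array(res)
  nd <- length(dim(arr))
  if (nd <= 1) mean(unlist(res), na.rm = TRUE)
  else apply(arr, seq_len(nd - 1), mean, na.rm = TRUE)
}

.as_subject_list <- function(epochs) {
  if (inherits(epochs, "epoch_set")) list(epochs) else {
    .assert(is.list(epochs) && all(vapply(epochs, inherits, TRUE, "epoch_set")),
            "epochs must be an epoch_set or a list of them")
    epochs
  }
}
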