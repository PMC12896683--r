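# Pipeline: simulate a group of subjects, run the requested analyses,
# apply group statistics, and write a reproducible result bundle.

.analysis_labels <- list(
  distractor      = list(train = "distractor_hemifield",      test = "distractor_hemifield"),
  target          = list(train = "target_hemifield",          test = "target_hemifield"),
  prev_distractor = list(train = "prev_distractor_hemifield", test = "prev_distractor_hemifield"),
  prev_target     = list(train = "prev_target_hemifield",     test = "prev_target_hemifield"),
  transfer        = list(train = "prev_distractor_hemifield", test = "distractor_hemifield")
)
.all_analyses <- c(names(.analysis_labels), "tgm", "crossgen")

#' Pipeline configuration
#'
#' Bundles every stage's configuration plus a master seed from which all
#' per-stage, per-subject seeds are derived deterministically. The defaults
#' emulate the study design at the package's scaled working size (64
#' sensors, 240 trials per session, 20 subjects) with a strided time grid.
#'
#' @param n_subjects simulated subjects (default 20).
#' @param n_sensors sensors per subject (default 64).
#' @param design a [design_config()] (default: 240 trials/session).
#' @param effects a [planted_effects()].
#' @param noise a [noise_spec()].
#' @param rho_pre_late,rho_pre_early,rho_pre_carryover requested pattern
#'   correlations.
#' @param decoding a [decoding_config()].
#' @param cluster a [cluster_config()].
#' @param analyses which analyses to run; any of "distractor", "target",
#'   "prev_distractor", "prev_target", "transfer", "tgm", "crossgen".
#' @param tgm_time_step time-grid stride (samples) for the generalization
#'   matrix (default 8, i.e. 40 ms at 200 Hz).
#' @param crossgen_lag_step lag stride (samples) for cross-epoch curves.
#' @param pre_interval,post_interval cross-epoch intervals (s).
#' @param seed master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_subjects = 20, n_sensors = 64,
                            design = design_config(trials_per_block = 40),
                            effects = planted_effects(),
                            noise = noise_spec(),
                            rho_pre_late = 0.8, rho_pre_early = 0,
                            rho_pre_carryover = 0.8,
                            decoding = decoding_config(time_step = 4),
                            cluster = cluster_config(),
                            analyses = .all_analyses,
                            tgm_time_step = 8, crossgen_lag_step = 4,
                            pre_interval = c(0, 1), post_interval = c(1.5, 2.5),
                            seed = 1) {
  .assert(n_subjects >= 1, "n_subjects must be >= 1")
  unknown <- setdiff(analyses, .all_analyses)
  .assert(length(unknown) == 0,
          paste("unknown analysis key(s):", paste(unknown, collapse = ", ")))
  structure(as.list(environment()), class = "pipeline_config")
}

# simulate the whole group from the master seed
.simulate_group <- function(config) {
  lapply(seq_len(config$n_subjects), function(i) {
    des <- config$design
    des$seed <- derive_seed(config$seed, paste0("design/subj", i))
    tab <- generate_design(des)
    pat <- make_effect_patterns(config$n_sensors, config$rho_pre_late,
                                config$rho_pre_early,
                                config$rho_pre_carryover,
                                seed = derive_seed(config$seed, paste0("patterns/subj", i)))
    nz <- config$noise
    nz$seed <- derive_seed(config$seed, paste0("noise/subj", i))
    simulate_epochs(tab, pat, config$effects, nz)
  })
}

.write_auc_csv <- function(times, auc, path) {
  df <- data.frame(time = times, t(auc))
  names(df)[-1] <- paste0("subj", seq_len(nrow(auc)))
  utils::write.csv(df, path, row.names = FALSE)
}

.clusters_to_table <- function(cres, times = NULL) {
  if (!length(cres$clusters)) {
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      extent = integer(0), mass = numeric(0),
                      sign = integer(0), p = numeric(0)))
  }
  do.call(rbind, lapply(cres$clusters, function(cl) {
    data.frame(
      onset = if (is.null(times)) min(cl$members) else times[min(cl$members)],
      offset = if (is.null(times)) max(cl$members) else times[max(cl$members)],
      extent = length(cl$members), mass = cl$mass, sign = cl$sign, p = cl$p)
  }))
}

#' Run the full simulate - decode - generalize - stats pipeline
#'
#' Simulates `n_subjects` epoch sets from the design, runs each requested
#' analysis at group level, applies the cluster-permutation and windowed
#' tests, and writes result CSV/JSON files plus a machine-readable manifest
#' (config, derived seeds, file checksums) into `out_dir`. Reruns with the
#' same config and seed produce bit-identical result files.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param verbose print progress lines.
#' @return a result bundle (invisibly): per-analysis results, cluster
#'   tables, manifest, and file paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, verbose = TRUE) {
  .assert(inherits(config, "pipeline_config"), "config must be a pipeline_config")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulating %d subject(s)", config$n_subjects)
  group <- .simulate_group(config)
  bundle <- list(config = config, results = list(), clusters = list(),
                 windows = NULL, files = character(0))
  dcfg <- config$decoding
  ccfg <- config$cluster
  ccfg$seed <- derive_seed(config$seed, "cluster")

  for (an in intersect(names(.analysis_labels), config$analyses)) {
    say("analysis: %s", an)
    lab <- .analysis_labels[[an]]
    cfg <- dcfg
    cfg$seed <- derive_seed(config$seed, paste0("decode/", an))
    res <- label_transfer(group, lab$train, lab$test, cfg)
    cres <- cluster_permutation_1d(res$auc, res$chance, ccfg)
    bundle$results[[an]] <- res
    bundle$clusters[[an]] <- cres
    f1 <- file.path(out_dir, paste0(an, "_auc.csv"))
    .write_auc_csv(res$times, res$auc, f1)
    f2 <- file.path(out_dir, paste0(an, "_clusters.json"))
    jsonlite::write_json(.clusters_to_table(cres, res$times), f2,
                         digits = NA, auto_unbox = TRUE)
    bundle$files <- c(bundle$files, f1, f2)
  }

  if ("tgm" %in% config$analyses) {
    say("analysis: tgm")
    cfg <- dcfg
    cfg$classifier <- "logistic"
    cfg$time_step <- config$tgm_time_step
    cfg$seed <- derive_seed(config$seed, "decode/tgm")
    tg <- temporal_generalization(group, "distractor_hemifield", cfg)
    cres <- cluster_permutation_2d(tg$auc, 0.5, ccfg)
    bundle$results$tgm <- tg
    bundle$clusters$tgm <- cres
    f1 <- file.path(out_dir, "tgm_auc.csv")
    mean_tgm <- apply(tg$auc, c(2, 3), mean)
    df <- data.frame(train_time = rep(tg$train_times, times = length(tg$test_times)),
                     test_time = rep(tg$test_times, each = length(tg$train_times)),
                     auc = as.vector(mean_tgm))
    utils::write.csv(df, f1, row.names = FALSE)
    f2 <- file.path(out_dir, "tgm_clusters.json")
    jsonlite::write_json(.clusters_to_table(cres), f2, digits = NA,
                         auto_unbox = TRUE)
    bundle$files <- c(bundle$files, f1, f2)
  }

  if ("crossgen" %in% config$analyses) {
    say("analysis: crossgen")
    cfg <- dcfg
    cfg$classifier <- "logistic"
    cfg$seed <- derive_seed(config$seed, "decode/crossgen")
    lc <- cross_epoch_curves(group, "distractor_hemifield",
                             config$pre_interval, config$post_interval,
                             cfg, lag_step = config$crossgen_lag_step)
    win <- windowed_tests(list(pre2post = lc$auc_pre2post,
                               post2pre = lc$auc_post2pre),
                          lc$lags, centers = c(0.1, 0.2))
    bundle$results$crossgen <- lc
    bundle$windows <- win
    f1 <- file.path(out_dir, "crossgen_auc.csv")
    df <- data.frame(lag = lc$lags,
                     pre2post = colMeans(lc$auc_pre2post),
                     post2pre = colMeans(lc$auc_post2pre))
    utils::write.csv(df, f1, row.names = FALSE)
    f2 <- file.path(out_dir, "crossgen_windows.csv")
    utils::write.csv(win, f2, row.names = FALSE)
    bundle$files <- c(bundle$files, f1, f2)
  }

  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                               force = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(cfg_json, cfg_path)
  manifest <- list(
    package = "megmvpa",
    version = as.character(utils::packageVersion("megmvpa")),
    seed = config$seed,
    analyses = config$analyses,
    config_md5 = unname(tools::md5sum(cfg_path)),
    files = lapply(basename(bundle$files), identity),
    checksums = as.list(stats::setNames(unname(tools::md5sum(bundle$files)),
                                        basename(bundle$files)))
  )
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  bundle$manifest <- manifest
  bundle$files <- c(bundle$files, cfg_path, man_path)
  bundle$out_dir <- out_dir
  say("wrote %d files to %s", length(bundle$files), out_dir)
  invisible(bundle)
}

#' Summarize a pipeline result bundle
#'
#' Tabulates, per analysis, the peak group-mean AUC and its latency, the
#' number of significant clusters (p < 0.05) and the smallest cluster
#' p-value, and flags which planted effects were recovered. Accepts the
#' bundle returned by [run_pipeline()] or the path of its output directory.
#'
#' @param bundle a pipeline bundle or an output directory path.
#' @return a data.frame summary (also printed as text).
#' @export
make_report <- function(bundle) {
  if (is.character(bundle)) {
    dirp <- bundle
    man_path <- file.path(dirp, "manifest.json")
    .assert(file.exists(man_path), paste("missing manifest:", man_path))
    man <- jsonlite::fromJSON(man_path)
    missing <- setdiff(unlist(man$files), list.files(dirp))
    .assert(length(missing) == 0,
            paste("bundle incomplete; missing:", paste(missing, collapse = ", ")))
    analyses <- intersect(man$analyses, names(.analysis_labels))
    rows <- lapply(analyses, function(an) {
      auc <- utils::read.csv(file.path(dirp, paste0(an, "_auc.csv")))
      cl <- jsonlite::fromJSON(file.path(dirp, paste0(an, "_clusters.json")))
      gm <- rowMeans(auc[, -1, drop = FALSE])
      nsig <- if (length(cl)) sum(cl$p < 0.05) else 0L
      data.frame(analysis = an, peak_auc = max(gm),
                 peak_time = auc$time[which.max(gm)],
                 n_clusters_sig = nsig,
                 min_p = if (length(cl) && nrow(cl)) min(cl$p) else NA_real_,
                 recovered = nsig > 0)
    })
    out <- do.call(rbind, rows)
  } else {
    .assert(is.list(bundle) && !is.null(bundle$results), "not a pipeline bundle")
    rows <- lapply(names(bundle$results), function(an) {
      res <- bundle$results[[an]]
      if (an == "tgm") {
        gm <- apply(res$auc, c(2, 3), mean)
        cres <- bundle$clusters$tgm
        nsig <- sum(vapply(cres$clusters, `[[`, 0, "p") < 0.05)
        return(data.frame(analysis = an, peak_auc = max(gm),
                          peak_time = res$train_times[which(gm == max(gm), arr.ind = TRUE)[1]],
                          n_clusters_sig = nsig,
                          min_p = if (length(cres$clusters)) min(vapply(cres$clusters, `[[`, 0, "p")) else NA_real_,
                          recovered = nsig > 0))
      }
      if (an == "crossgen") {
        win <- bundle$windows
        return(data.frame(analysis = "crossgen",
                          peak_auc = max(colMeans(res$auc_pre2post)),
                          peak_time = res$lags[which.max(colMeans(res$auc_pre2post))],
                          n_clusters_sig = sum(win$significant),
                          min_p = min(win$p_fdr),
                          recovered = any(win$significant)))
      }
      gm <- colMeans(res$auc)
      cres <- bundle$clusters[[an]]
      ps <- vapply(cres$clusters, `[[`, 0, "p")
      data.frame(analysis = an, peak_auc = max(gm),
                 peak_time = res$times[which.max(gm)],
                 n_clusters_sig = sum(ps < 0.05),
                 min_p = if (length(ps)) min(ps) else NA_real_,
                 recovered = sum(ps < 0.05) > 0)
    })
    out <- do.call(rbind, rows)
  }
  for (i in seq_len(nrow(out))) {
    cat(sprintf("%-16s peak AUC %.3f at %+.3f s | %d significant cluster(s)%s | %s\n",
                out$analysis[i], out$peak_auc[i], out$peak_time[i],
                out$n_clusters_sig[i],
                ifelse(is.na(out$min_p[i]), "", sprintf(" (min p = %.4f)", out$min_p[i])),
                ifelse(out$recovered[i], "effect recovered", "nothing recovered")))
  }
  invisible(out)
}
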