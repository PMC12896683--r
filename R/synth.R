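# Synthetic epochs emulating a statistical-learning visual-search design:
# two sessions of blocked trials, a color-singleton distractor on 66% of
# trials appearing in one hemifield on 75% of distractor trials (roles
# swapped across sessions), targets balanced 50/50, and planted spatial
# activity patterns time-locked to placeholder/search onsets.

#' Design configuration for the synthetic experiment
#'
#' Probabilities are realized as exact per-session counts (round-half-up,
#' then a seeded shuffle), not Bernoulli draws, so the design statistics of a
#' generated session are exact by construction.
#'
#' @param n_sessions number of sessions per subject (default 2).
#' @param blocks_per_session blocks per session (default 6).
#' @param trials_per_block trials per block (default 120; the defaults give
#'   720 trials per session).
#' @param p_distractor_present fraction of trials with a distractor (0.66).
#' @param p_high_hemifield fraction of distractor-present trials in the
#'   high-probability hemifield (0.75).
#' @param high_prob_hemifield_session1 which hemifield is high-probability in
#'   session 1 ("left" or "right").
#' @param swap_between_sessions swap the hemifield roles in even sessions
#'   (default TRUE).
#' @param seed RNG seed for the trial-order shuffle.
#' @return a `design_config` list.
#' @export
design_config <- function(n_sessions = 2, blocks_per_session = 6,
                          trials_per_block = 120,
                          p_distractor_present = 0.66,
                          p_high_hemifield = 0.75,
                          high_prob_hemifield_session1 = "left",
                          swap_between_sessions = TRUE, seed = 1) {
  .assert(n_sessions >= 1 && blocks_per_session >= 1, "counts must be >= 1")
  .assert(trials_per_block >= 2, "trials_per_block must be >= 2 for exact balancing")
  .assert(p_distractor_present >= 0 && p_distractor_present <= 1 &&
            p_high_hemifield >= 0 && p_high_hemifield <= 1,
          "probabilities must lie in [0, 1]")
  .assert(high_prob_hemifield_session1 %in% c("left", "right"),
          "high_prob_hemifield_session1 must be 'left' or 'right'")
  structure(as.list(environment()), class = "design_config")
}

# split n into (upper, lower) as evenly as integers allow, extra to upper
.split_even <- function(n) c(ceiling(n / 2), floor(n / 2))

.other_hemifield <- function(h) c(left = "right", right = "left")[[h]]

#' Generate a trial table from a design configuration
#'
#' Realizes the design with exact counts per session: with the defaults, 720
#' trials of which round(0.66 x 720) = 475 are distractor-present,
#' round(0.75 x 475) = 356 of those in the high-probability hemifield,
#' targets exactly 360/360 across hemifields, and positions within hemifield
#' as even as integer counts allow. The trial order is shuffled by the seed;
#' hemifield roles swap in even sessions when configured. Previous-trial
#' labels are attached (NA at block starts).
#'
#' @param config a [design_config()].
#' @return a trial table (see [validate_trial_table()]).
#' @export
generate_design <- function(config = design_config()) {
  .assert(inherits(config, "design_config"), "config must be a design_config")
  with_seed(config$seed, {
    sessions <- lapply(seq_len(config$n_sessions), function(s) {
      n <- config$blocks_per_session * config$trials_per_block
      high <- if (s %% 2 == 1 || !config$swap_between_sessions) {
        config$high_prob_hemifield_session1
      } else .other_hemifield(config$high_prob_hemifield_session1)
      low <- .other_hemifield(high)

      n_present <- round_half_up(config$p_distractor_present * n)
      n_high <- round_half_up(config$p_high_hemifield * n_present)
      n_low <- n_present - n_high

      hi_pos <- .split_even(n_high)
      lo_pos <- .split_even(n_low)
      d_hemi <- c(rep(high, n_high), rep(low, n_low), rep("absent", n - n_present))
      d_pos <- c(rep(c("upper", "lower"), hi_pos),
                 rep(c("upper", "lower"), lo_pos),
                 rep("absent", n - n_present))
      ord_d <- sample.int(n)

      n_left <- .split_even(n)[1]
      t_hemi <- c(rep("left", n_left), rep("right", n - n_left))
      t_pos <- c(rep(c("upper", "lower"), .split_even(n_left)),
                 rep(c("upper", "lower"), .split_even(n - n_left)))
      ord_t <- sample.int(n)

      data.frame(
        session = s,
        block = rep(seq_len(config$blocks_per_session),
                    each = config$trials_per_block),
        trial = seq_len(n),
        distractor_present = d_hemi[ord_d] != "absent",
        distractor_hemifield = d_hemi[ord_d],
        distractor_position = d_pos[ord_d],
        target_hemifield = t_hemi[ord_t],
        target_position = t_pos[ord_t],
        high_prob_hemifield = high,
        stringsAsFactors = FALSE
      )
    })
    attach_previous_labels(do.call(rbind, sessions))
  })
}

#' Construct correlated spatial effect patterns
#'
#' Builds five unit-norm, zero-mean sensor patterns by Gram-Schmidt from
#' seeded random vectors: a presearch pattern; early and late post-search
#' patterns whose correlations with the presearch pattern equal
#' `rho_pre_early` and `rho_pre_late` exactly (constructed, not sampled); a
#' target pattern orthogonal to the presearch pattern; and a carryover
#' pattern (the trace of the previous trial's distractor location) whose
#' correlation with the presearch pattern is `rho_pre_carryover` — high by
#' default, expressing that the lingering previous-location code and the
#' anticipatory current-location code share one spatial mechanism, which is
#' what lets a decoder trained on the previous location transfer to the
#' current one. Because all patterns have zero mean, Pearson correlation
#' coincides with the inner product.
#'
#' @param n_sensors number of sensors (>= 6: five orthogonal zero-mean
#'   directions are needed).
#' @param rho_pre_late correlation between presearch and late post-search
#'   patterns (default 0.8).
#' @param rho_pre_early correlation between presearch and early post-search
#'   patterns (default 0).
#' @param rho_pre_carryover correlation between presearch and carryover
#'   patterns (default 0.8).
#' @param seed RNG seed.
#' @return a `pattern_set` with elements `p_pre`, `p_early`, `p_late`,
#'   `p_target`, `p_carryover`.
#' @export
make_effect_patterns <- function(n_sensors, rho_pre_late = 0.8,
                                 rho_pre_early = 0, rho_pre_carryover = 0.8,
                                 seed = 1) {
  .assert(abs(rho_pre_late) <= 1 && abs(rho_pre_early) <= 1 &&
            abs(rho_pre_carryover) <= 1, "|rho| must be <= 1")
  .assert(n_sensors >= 6,
          "n_sensors too small for the requested orthogonal set (need >= 6)")
  with_seed(seed, {
    # orthonormal zero-mean basis u1..u5 by Gram-Schmidt
    u <- matrix(0, n_sensors, 5)
    k <- 0
    while (k < 5) {
      v <- stats::rnorm(n_sensors)
      v <- v - mean(v)
      if (k > 0) v <- v - u[, seq_len(k), drop = FALSE] %*%
          crossprod(u[, seq_len(k), drop = FALSE], v)
      nv <- sqrt(sum(v^2))
      if (nv > 1e-8) {
        k <- k + 1
        u[, k] <- v / nv
      }
    }
    mix <- function(rho, uo) rho * u[, 1] + sqrt(1 - rho^2) * uo
    structure(list(
      p_pre = u[, 1],
      p_early = mix(rho_pre_early, u[, 2]),
      p_late = mix(rho_pre_late, u[, 3]),
      p_target = u[, 4],
      p_carryover = mix(rho_pre_carryover, u[, 5]),
      rho_pre_late = rho_pre_late, rho_pre_early = rho_pre_early,
      rho_pre_carryover = rho_pre_carryover,
      n_sensors = n_sensors, seed = seed
    ), class = "pattern_set")
  })
}

#' Planted-effect specification
#'
#' Each effect has an amplitude (in noise-SD units), a time window in seconds
#' and a half-Gaussian onset/offset ramp width. Defaults plant a sustained
#' presearch distractor-location code at 0.1-0.7 s after placeholder onset,
#' brief early (~100 ms) and late (~200 ms) post-search distractor codes, a
#' post-search target code, and a carryover code signed by the previous
#' trial's distractor hemifield.
#'
#' @param presearch,early_reactive,late_reactive,target_post,carryover each a
#'   list with `amplitude`, `window` (c(on, off) in s) and `ramp` (s).
#' @return a `planted_effects` list.
#' @export
planted_effects <- function(
    presearch      = list(amplitude = 0.4, window = c(0.1, 0.7),     ramp = 0.025),
    early_reactive = list(amplitude = 0.4, window = c(1.575, 1.625), ramp = 0.025),
    late_reactive  = list(amplitude = 0.4, window = c(1.675, 1.725), ramp = 0.025),
    target_post    = list(amplitude = 0.4, window = c(1.675, 1.725), ramp = 0.025),
    carryover      = list(amplitude = 0.4, window = c(0.1, 0.7),     ramp = 0.025)) {
  eff <- list(presearch = presearch, early_reactive = early_reactive,
              late_reactive = late_reactive, target_post = target_post,
              carryover = carryover)
  for (nm in names(eff)) {
    e <- eff[[nm]]
    .assert(e$amplitude >= 0, paste(nm, "amplitude must be >= 0"))
    .assert(length(e$window) == 2 && e$window[1] < e$window[2],
            paste(nm, "window must be c(on, off) with on < off"))
  }
  structure(eff, class = "planted_effects")
}

#' Noise specification
#'
#' Gaussian sensor noise with a random spatial covariance mixed with the
#' identity and optional moving-average temporal smoothing.
#'
#' @param sensor_sd marginal noise SD per sensor (> 0).
#' @param spatial_correlation mixing weight in [0, 1) of a seeded random
#'   correlation matrix with the identity.
#' @param temporal_smoothing_ms moving-average kernel width (ms; 0 = none).
#' @param seed RNG seed for the covariance and the draws.
#' @return a `noise_spec` list.
#' @export
noise_spec <- function(sensor_sd = 1, spatial_correlation = 0.2,
                       temporal_smoothing_ms = 10, seed = 1) {
  .assert(sensor_sd > 0, "sensor_sd must be > 0")
  .assert(spatial_correlation >= 0 && spatial_correlation < 1,
          "spatial_correlation must lie in [0, 1)")
  structure(as.list(environment()), class = "noise_spec")
}

# boxcar on [t_on, t_off] with half-Gaussian ramps of width sigma outside
.effect_envelope <- function(times, window, ramp) {
  env <- numeric(length(times))
  inside <- times >= window[1] & times <= window[2]
  env[inside] <- 1
  if (ramp > 0) {
    pre <- times < window[1]
    env[pre] <- exp(-(window[1] - times[pre])^2 / (2 * ramp^2))
    post <- times > window[2]
    env[post] <- exp(-(times[post] - window[2])^2 / (2 * ramp^2))
  }
  env
}

# +1 for left, -1 for right, 0 for absent/NA
.hemifield_sign <- function(labels) {
  s <- numeric(length(labels))
  s[!is.na(labels) & labels == "left"] <- 1
  s[!is.na(labels) & labels == "right"] <- -1
  s
}

.effect_label_column <- c(
  presearch = "distractor_hemifield",
  early_reactive = "distractor_hemifield",
  late_reactive = "distractor_hemifield",
  target_post = "target_hemifield",
  carryover = "prev_distractor_hemifield"
)
.effect_pattern <- c(
  presearch = "p_pre", early_reactive = "p_early", late_reactive = "p_late",
  target_post = "p_target", carryover = "p_carryover"
)

#' Simulate an epoch set with planted effects
#'
#' Builds `data[trial] = sum_e sign_e(trial) * amplitude_e * envelope_e(t) *
#' pattern_e + noise`, where the sign is +1/-1 for a left/right label of the
#' effect's condition column and 0 for absent/NA trials. Distractor-absent
#' trials carry no distractor signal but full noise and are retained (they
#' are filtered at decoding time).
#'
#' @param table a trial table.
#' @param patterns a [make_effect_patterns()] pattern set.
#' @param effects a [planted_effects()] specification.
#' @param noise a [noise_spec()].
#' @param epoch_span c(start, end) in seconds (default c(-0.5, 2.5); the time
#'   grid is half-open, so the default yields 600 samples at 200 Hz).
#' @param sfreq sampling rate in Hz.
#' @return an `epoch_set`.
#' @export
simulate_epochs <- function(table, patterns, effects = planted_effects(),
                            noise = noise_spec(), epoch_span = c(-0.5, 2.5),
                            sfreq = 200) {
  validate_trial_table(table)
  .assert(inherits(patterns, "pattern_set"), "patterns must be a pattern_set")
  n_tr <- nrow(table)
  n_se <- patterns$n_sensors
  n_sa <- round((epoch_span[2] - epoch_span[1]) * sfreq)
  times <- epoch_span[1] + (seq_len(n_sa) - 1) / sfreq

  # planted signal assembled as one (trial*sensor) x sample product:
  # columns of TP hold vec(sign_e x pattern_e), rows of ENV the envelopes
  tp_cols <- list(); env_rows <- list()
  for (nm in names(effects)) {
    e <- effects[[nm]]
    if (e$amplitude == 0) next
    col <- .effect_label_column[[nm]]
    .assert(col %in% names(table),
            paste("active effect", nm, "needs missing label column", col))
    .assert(e$window[1] >= epoch_span[1] && e$window[2] <= epoch_span[2],
            paste(nm, "window outside epoch span"))
    s <- .hemifield_sign(table[[col]])
    if (all(s == 0)) next
    tp_cols[[nm]] <- as.vector(outer(s * e$amplitude,
                                     patterns[[.effect_pattern[[nm]]]]))
    env_rows[[nm]] <- .effect_envelope(times, e$window, e$ramp)
  }

  out <- with_seed(noise$seed, {
    if (noise$spatial_correlation > 0) {
      a <- matrix(stats::rnorm(n_se * n_se), n_se)
      c0 <- tcrossprod(a) / n_se
      d <- sqrt(diag(c0))
      c0 <- c0 / outer(d, d)
      sig <- (1 - noise$spatial_correlation) * diag(n_se) +
        noise$spatial_correlation * c0
      cr <- chol(sig)
    } else cr <- NULL
    z <- array(stats::rnorm(n_tr * n_se * n_sa), c(n_tr, n_se, n_sa))
    if (!is.null(cr)) {
      for (sa in seq_len(n_sa)) z[, , sa] <- z[, , sa] %*% cr
    }
    w <- max(1L, round(noise$temporal_smoothing_ms / 1000 * sfreq))
    if (w > 1) {
      # circular moving average along the sample axis via index shifts
      acc <- z
      off <- setdiff(seq_len(w) - ceiling(w / 2), 0L)
      for (o in off) {
        idx <- ((seq_len(n_sa) - 1 + o) %% n_sa) + 1
        acc <- acc + z[, , idx]
      }
      z <- acc / w
    }
    z * noise$sensor_sd
  })
  if (length(tp_cols)) {
    sigflat <- do.call(cbind, tp_cols) %*%
      do.call(rbind, env_rows)
    out <- out + array(sigflat, c(n_tr, n_se, n_sa))
  }

  epoch_set(out, times, sfreq, table)
}
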