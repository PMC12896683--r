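# Small programmatic fixtures shared across test files.

# a minimal hand-built trial table (2 sessions x 1 block)
tiny_table <- function() {
  tab <- data.frame(
    session = rep(1:2, each = 4),
    block = 1,
    trial = rep(1:4, 2),
    distractor_present = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE),
    distractor_hemifield = c("left", "right", "absent", "left",
                             "right", "absent", "left", "right"),
    distractor_position = c("upper", "lower", "absent", "upper",
                            "lower", "absent", "upper", "lower"),
    target_hemifield = rep(c("left", "right"), 4),
    target_position = rep(c("upper", "lower"), 4),
    high_prob_hemifield = rep(c("left", "right"), each = 4),
    stringsAsFactors = FALSE
  )
  attach_previous_labels(tab)
}

# random epochs with a matching generated design
tiny_epochs <- function(n_trials = 20, n_sensors = 4, n_samples = 30,
                        sfreq = 200, seed = 1) {
  set.seed(seed)
  tab <- generate_design(design_config(
    n_sessions = 1, blocks_per_session = 1, trials_per_block = n_trials,
    seed = seed))
  times <- (seq_len(n_samples) - 1) / sfreq
  epoch_set(array(rnorm(n_trials * n_sensors * n_samples),
                  c(n_trials, n_sensors, n_samples)),
            times, sfreq, tab)
}

# planted-effect list with every effect off except the named ones
effects_only <- function(..., span_guard = TRUE) {
  on <- list(...)
  eff <- planted_effects()
  for (nm in names(eff)) {
    if (nm %in% names(on)) eff[[nm]] <- on[[nm]] else eff[[nm]]$amplitude <- 0
  }
  eff
}

# simulate one subject at the scaled working size used throughout the tests
sim_subject <- function(seed, n_sensors = 64, trials_per_block = 40,
                        n_sessions = 2, effects = planted_effects(),
                        rho_pre_late = 0.8, rho_pre_early = 0,
                        epoch_span = c(-0.5, 2.5)) {
  tab <- generate_design(design_config(
    n_sessions = n_sessions, trials_per_block = trials_per_block,
    seed = derive_seed(seed, "design")))
  pat <- make_effect_patterns(n_sensors, rho_pre_late, rho_pre_early,
                              seed = derive_seed(seed, "patterns"))
  simulate_epochs(tab, pat, effects,
                  noise_spec(seed = derive_seed(seed, "noise")),
                  epoch_span = epoch_span)
}
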