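# lazily computed, memoized fixtures shared across test files
.cc_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .cc_cache)) {
    assign(name, force(expr), envir = .cc_cache)
  }
  get(name, envir = .cc_cache)
}

# the 11 built-in trials, built at the canonical 100 Hz
get_design_trials <- function() {
  cached("design_trials", {
    lapply(builtin_design(), function(spec) {
      suppressWarnings(build_trial(round_section_durations(spec)))
    })
  })
}

# one analyzed 18-participant cohort under default generative settings
get_cohort_analysis <- function() {
  cached("cohort_analysis", {
    analyze_cohort(simulate_cohort(n_participants = 18, master_seed = 1))
  })
}

# a single-section stimulus trial (durations pre-assigned, no joins)
single_section_trial <- function(frequency, peak_velocity, duration,
                                 sample_rate = 100) {
  sec <- stimulus_section(frequency, peak_velocity, duration = duration,
                          start_time = 0)
  suppressWarnings(build_trial(trial_spec(1L, list(sec),
                                          total_duration = duration),
                               sample_rate = sample_rate))
}
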