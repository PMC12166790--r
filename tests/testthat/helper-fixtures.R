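# Shared fixtures, built in code at test time.

# Constant-acceleration recording (vec in g), default 10 min at 30 Hz.
const_recording <- function(vec, secs = 600, fs = 30) {
  raw_recording(matrix(rep(vec, each = fs * secs), ncol = 3), fs)
}

# Reduced outcome set for model-fitting tests (keeps cohorts cheap).
quick_outcomes <- function(names = c("alsfrs_total", "peak6_counts")) {
  oc <- default_outcomes()
  oc[oc$outcome %in% names, ]
}

quick_cohort <- function(n = 60, seed = 1L, ...) {
  simulate_cohort(cohort_params(n_participants = n,
                                outcomes = quick_outcomes(), ...), seed = seed)
}

# One day of synthetic wrist signal at 30 Hz, cached per activity level.
day_recording <- local({
  cache <- list()
  function(activity = 0.5, seed = 3L) {
    key <- sprintf("%s_%d", activity, seed)
    if (is.null(cache[[key]]))
      cache[[key]] <<- simulate_raw_recording(
        signal_params(duration_days = 1, activity_level = activity),
        seed = seed)
    cache[[key]]
  }
})

# Exhaustive sliding-window enumeration oracles (independent of the
# cumulative-sum implementations in the package).
brute_force_window_means <- function(v, k) {
  vapply(seq_len(length(v) - k + 1), function(i) mean(v[i:(i + k - 1)]),
         numeric(1))
}
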