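# shared fixtures, built once per test run

# small mixed cohort reused across test files
quick_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(n_ingroup = 3,
                                                  n_equality = 1,
                                                  master_seed = 3)
    cache
  }
})

quick_kept <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- suppressWarnings(preprocess_trials(quick_cohort()$trials)$trials)
    cache
  }
})

# hand-built single-subject trial frame on real stimuli
tiny_trials <- function(rt, boundary, stim_type = NULL, subject = 1L) {
  stim <- generate_stimuli()
  n <- length(rt)
  rows <- if (is.null(stim_type)) seq_len(n) else
    vapply(stim_type, function(tp) which(stim$stim_type == tp)[1], 1L)
  out <- cbind(subject = subject, stim[rows, , drop = FALSE],
               boundary = boundary, rt = rt, censored = FALSE)
  rownames(out) <- NULL
  out
}

# closed-form lower-boundary absorption probability (independent oracle)
p_lower_oracle <- function(v, a, z) {
  if (abs(v) < 1e-12) return(1 - z)
  (exp(-2 * v * a) - exp(-2 * v * z * a)) / (exp(-2 * v * a) - 1)
}
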