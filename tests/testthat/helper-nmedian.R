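# shared fixtures: streams are generated in code, never stored

# drive an nm_state through a vector with the single-step R updater
nm_run_r <- function(state, x) {
  est <- numeric(length(x))
  for (i in seq_along(x)) {
    state <- nm_update(state, x[i])
    est[i] <- nm_estimate(state)
  }
  list(state = state, estimates = est)
}

# drive a cmm_state through a vector with the single-step R updater
cmm_run_r <- function(state, x) {
  est <- numeric(length(x))
  for (i in seq_along(x)) {
    state <- cmm_update(state, x[i])
    est[i] <- cmm_estimate(state)
  }
  list(state = state, estimates = est)
}

expect_sorted <- function(v) expect_false(is.unsorted(v))
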