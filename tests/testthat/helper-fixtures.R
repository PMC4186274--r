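# Shared fixtures for the test suite.

# A reduced-size configuration for tests that only need structure, not
# statistical power.
tiny_config <- function(...) {
  simulation_config(n_observers = 2, n_blocks = 4,
                    n_control_observers = 3, n_control_blocks = 1, ...)
}

# Deterministic Bernoulli psychometric data from a cumulative normal.
make_binomial_proportions <- function(levels, mu, sigma, n_per_level) {
  k <- stats::rbinom(length(levels), n_per_level,
                     stats::pnorm((levels - mu) / sigma))
  list(p = k / n_per_level, n = rep(n_per_level, length(levels)))
}

# Hand-built trial table: one response per (block, level), single stimulus.
make_manual_trials <- function(responses_by_block, levels = 1:9, f = 36,
                               dtheta = 0.5, dalpha = 4.95,
                               condition_id = "condA", observer_id = "obs01") {
  n_blocks <- length(responses_by_block)
  rows <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    data.frame(observer_id = observer_id, condition_id = condition_id,
               f_cm = f, dtheta_deg_s = dtheta, dalpha_deg_s = dalpha,
               head_state = "stationary",
               direction = rep(c("left", "right"), length.out = length(levels)),
               head_speed_cm_s = NA_real_,
               disparity_pixels = seq_along(levels),
               disparity_arcmin = levels,
               response_stereo_deeper = responses_by_block[[b]],
               block = b)
  }))
  rownames(rows) <- NULL
  rows
}
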