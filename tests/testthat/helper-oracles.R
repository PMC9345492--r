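# Brute-force oracles, kept independent of the implementation paths they
# check.

# direct truncated-window running median (O(n * w))
oracle_running_median <- function(x, hw) {
  n <- length(x)
  vapply(seq_len(n), function(i)
    median(x[max(1, i - hw):min(n, i + hw)]), numeric(1))
}

# direct sliding-window spike count at one time point
oracle_window_count <- function(times, t, window) {
  sum(times >= t - window / 2 & times < t + window / 2)
}

# classify a noiseless (beta, theta_E) point by simulating from a
# Down-like and an Up-like initial condition and matching the endpoints
# against the analytic fixed points
oracle_classify <- function(beta, theta_E, params, duration = 20000) {
  p <- params
  p$beta <- beta
  p$theta_E <- theta_E
  p$sigma <- 0
  up <- up_fixed_point(p)
  down <- down_fixed_point(p)
  endpoint <- function(init) {
    tr <- simulate_rate(p, duration, dt = 0.1, init = init,
                        record_every = 1000)
    unlist(tail(tr$states, 1)[c("r_E", "r_I", "r_A", "a")])
  }
  matches <- function(st, fp) {
    fp$exists && max(abs(st - c(fp$r_E0, fp$r_I0, fp$r_A0, fp$a0))) < 1e-3
  }
  e_down <- endpoint(c(0, 0, down$r_A0, 0))
  up_init <- if (up$exists)
    c(up$r_E0, up$r_I0, up$r_A0, up$a0) * 1.001
  else c(10, 30, 5, beta * 5)
  e_up <- endpoint(up_init)
  if (matches(e_down, down) && matches(e_up, up)) "Bist"
  else if (matches(e_down, down) && matches(e_up, down)) "D"
  else if (matches(e_down, up) && matches(e_up, up)) "U"
  else "Osc"
}

# pooled Up/Down statistics over several spiking runs
pooled_updown_stats <- function(params, n_runs, duration, seed0) {
  segs <- lapply(seq_len(n_runs), function(k) {
    sim <- simulate_spiking(params, duration, seed = seed0 + k)
    segment_phases(median_smooth(spiking_rate_series(sim)))
  })
  list(stats = phase_statistics(segs),
       up_counts = vapply(segs, function(s)
         sum(s$retained & s$label == "Up"), numeric(1)))
}

# deterministic right-hand side of the rate dynamics (internal helper)
rate_rhs_for_test <- function(state, params)
  astroud:::rate_rhs(state, params)
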