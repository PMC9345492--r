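test_that("rectified-linear transfer matches hand evaluation", {
  expect_equal(transfer(30, gain = 4, theta = 25), 20)   # I-population values
  expect_equal(transfer(25, gain = 4, theta = 25), 0)    # boundary
  expect_equal(transfer(17, gain = 0.3, theta = 17), 0)
  expect_equal(transfer(-5, gain = 1, theta = -3.5), 0)  # below threshold
  expect_equal(transfer(-3, gain = 1, theta = -3.5), 0.5)
  expect_error(transfer(NaN, 1, 0), "non-finite")
  expect_error(transfer(1, gain = -1, theta = 0), "gain")
})

test_that("recurrent inputs follow the coupling matrix", {
  J <- rate_params()$J
  I <- recurrent_inputs(c(1, 1, 1), J)
  expect_equal(unname(I["I_E"]), 5 - 1 + 1)
  expect_equal(unname(I["I_I"]), 10 - 0.5 + 0.5)
  expect_equal(unname(I["I_A"]), 0.5 + 0.5 + 0.1)
  expect_equal(unname(recurrent_inputs(c(0, 0, 0), J)), c(0, 0, 0))
  expect_error(recurrent_inputs(c(1, NA, 1), J), "non-finite")
})

test_that("OU updates are exact: noiseless decay, stationarity, white limit", {
  # sigma = 0: pure exponential decay
  expect_equal(ou_step(2, tau_ou = 5, sigma = 0, dt = 1), 2 * exp(-1 / 5))
  expect_error(ou_step(0, tau_ou = 5, sigma = -1, dt = 1), "sigma")

  # stationarity of a long chain at the reference noise amplitude
  set.seed(42)
  n <- 1e5
  xi <- numeric(n)
  for (k in 2:n) xi[k] <- ou_step(xi[k - 1], tau_ou = 1, sigma = 3.52,
                                  dt = 1)
  rho <- exp(-1)
  n_eff <- n * (1 - rho) / (1 + rho)
  expect_lt(abs(mean(xi)), 3 * 3.52 / sqrt(n_eff))
  expect_lt(abs(sd(xi) - 3.52), 3 * 3.52 / sqrt(2 * n_eff))

  # tau_ou << dt: consecutive samples uncorrelated with std sigma
  set.seed(7)
  y <- numeric(2e4)
  for (k in 2:2e4) y[k] <- ou_step(y[k - 1], tau_ou = 0.01, sigma = 2,
                                   dt = 1)
  expect_lt(abs(cor(y[-1], y[-2e4])), 0.03)
  expect_lt(abs(sd(y) - 2), 0.05)
})

test_that("a silent network at the origin is a fixed point of the step", {
  p <- rate_params(J_EE = 0, J_EI = 0, J_EA = 0, J_IE = 0, J_II = 0,
                   J_IA = 0, J_AE = 0, J_AI = 0, J_AA = 0, theta_A = 1)
  p$sigma <- 0
  st <- c(r_E = 0, r_I = 0, r_A = 0, a = 0)
  expect_equal(rate_step(st, p, dt = 0.1), st)
  expect_error(rate_step(st, p, dt = 10), "dt")
})

test_that("adaptation relaxes toward beta * r_E with time constant tau_a", {
  p <- rate_params()
  st <- c(r_E = 4, r_I = 0, r_A = 0, a = 0)
  dt <- 0.1
  a <- 0
  for (k in seq_len(round(1000 / dt))) {
    out <- rate_step(c(r_E = 4, r_I = 0, r_A = 0, a = a), p, dt)
    a <- unname(out["a"])
  }
  closed <- p$beta * 4 * (1 - exp(-1000 / p$tau_a))
  expect_equal(a, closed, tolerance = 1e-3)
})

test_that("noiseless trajectories without astrocytes stay silent", {
  p <- without_astro(rate_params())
  p$sigma <- 0
  tr <- simulate_rate(p, 2000)
  expect_equal(max(tr$states$r_E), 0)
  expect_equal(max(tr$states$r_I), 0)
  # astrocytes settle at their spontaneous level
  expect_equal(tail(tr$states$r_A, 1), down_fixed_point(p)$r_A0,
               tolerance = 1e-6)
})

test_that("rates and adaptation stay nonnegative for any seed", {
  p <- rate_params()
  for (seed in 1:5) {
    tr <- simulate_rate(p, 5000, seed = seed, record_every = 10)
    expect_gte(min(tr$states$r_E), 0)
    expect_gte(min(tr$states$r_I), 0)
    expect_gte(min(tr$states$r_A), 0)
    expect_gte(min(tr$states$a), 0)
  }
})

test_that("the Euler scheme converges at first order in dt", {
  p <- rate_params()
  p$sigma <- 0
  init <- c(3, 5, 4, 2)
  endpoint <- function(dt) {
    tr <- simulate_rate(p, 400, dt = dt, init = init,
                        record_every = round(400 / dt))
    unlist(tail(tr$states, 1)[c("r_E", "r_I", "r_A", "a")])
  }
  e1 <- endpoint(0.4); e2 <- endpoint(0.2); e3 <- endpoint(0.1)
  ratio <- max(abs(e1 - e2)) / max(abs(e2 - e3))
  expect_gt(ratio, 1.5)
  expect_lt(ratio, 3)
})

test_that("simulations are reproducible and noise streams independent", {
  p <- rate_params()
  a <- simulate_rate(p, 500, seed = 3)
  b <- simulate_rate(p, 500, seed = 3)
  expect_identical(a$states, b$states)
  expect_gt(max(abs(a$states$xi_E - a$states$xi_I)), 0.5)
})

test_that("gliotransmission switches the dynamics from silent to Up-Down", {
  p <- rate_params()
  st_with <- phase_statistics(segment_trajectory(
    simulate_rate(p, 20000, seed = 2, record_every = 10)))
  expect_gte(st_with$Up$count, 1)
  st_without <- phase_statistics(segment_trajectory(
    simulate_rate(without_astro(p), 20000, seed = 2, record_every = 10)))
  expect_equal(st_without$Up$count, 0)
})

test_that("astrocyte release stays near its Down fixed level during Down", {
  p <- rate_params()
  tr <- simulate_rate(p, 30000, seed = 11, record_every = 10)
  sm <- median_smooth(trajectory_rate_series(tr))
  down <- sm$values < 1
  expect_gt(sum(down), 1000)
  level <- mean(tr$states$r_A[down])
  # analytic -g_A theta_A / (1 - g_A J_AA) = 3.5/0.9; external noise lifts
  # the rectified astrocyte rate slightly above it
  expect_equal(level, 3.5 / 0.9, tolerance = 0.15)
})
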