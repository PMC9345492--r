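test_that("connectivity uses exact counts, not Bernoulli draws", {
  p <- spiking_params()
  conn <- build_connectivity(p, seed = 1)
  expect_equal(sum(conn$glio_E), 400)
  expect_equal(sum(conn$glio_I), 100)
  expect_equal(sum(conn$recv_A), 1000)
  # counts are exact for every seed
  for (seed in 2:4)
    expect_equal(sum(build_connectivity(p, seed = seed)$glio_E), 400)
  p0 <- spiking_params(frac_glio_targets = 0, frac_astro_receivers = 0)
  conn0 <- build_connectivity(p0, seed = 1)
  expect_equal(sum(conn0$glio_E) + sum(conn0$recv_A), 0)
  expect_error(build_connectivity(spiking_params(N_A = 0), seed = 1),
               "empty population")
  expect_identical(build_connectivity(p, seed = 9),
                   build_connectivity(p, seed = 9))
})

test_that("initial conditions are uniform between reset and threshold", {
  p <- spiking_params(N_E = 2000, N_I = 500, N_A = 1000)
  st <- init_state(p, seed = 2)
  expect_true(all(st$V_E >= 14 & st$V_E < 20))
  expect_true(all(st$V_I >= 14 & st$V_I < 20))
  expect_true(all(st$G_A >= 9 & st$G_A < 13))
  expect_gt(sd(st$V_E), 1)        # spread, not a constant
  expect_equal(st$u, numeric(3))
  expect_identical(init_state(p, seed = 2), init_state(p, seed = 2))
})

test_that("a noiseless subthreshold network stays silent forever", {
  p <- spiking_params(N_E = 50, N_I = 20, N_A = 20,
                      sigma_E = 0, sigma_I = 0, sigma_A = 0)
  st <- init_state(p, seed = 1)
  st$V_E[] <- 12; st$V_I[] <- 12; st$G_A[] <- 10
  conn <- build_connectivity(p, seed = 1)
  out <- network_step(st, p, conn, n_steps = 10000)
  expect_equal(nrow(out$raster), 0)
  expect_equal(sum(out$spikes), 0)
  # membrane potentials relax toward the leak
  expect_equal(max(abs(out$state$V_E - 7.6)), 0, tolerance = 0.1)
  expect_equal(max(abs(out$state$G_A - 7)), 0, tolerance = 0.1)
})

test_that("one spike produces one delayed increment of u (single-event oracle)", {
  p <- spiking_params(N_E = 1, N_I = 0, N_A = 1, sigma_E = 0, sigma_I = 0,
                      sigma_A = 0, J_EE = 0, J_EA = 0, J_AE = 0, J_AI = 0,
                      J_AA = 0, K_a = 0, frac_glio_targets = 0,
                      frac_astro_receivers = 0)
  conn <- build_connectivity(p, seed = 1)
  for (seed in 1:5) {
    st <- init_state(p, seed = 1)
    st$V_E[1] <- 25      # above threshold: fires at the first step
    st$G_A[1] <- 5
    out <- network_step(st, p, conn, n_steps = 30, seed = seed)
    expect_equal(nrow(out$raster), 1)
    expect_equal(out$raster$t_ms, 0.1)           # end-of-step spike time
    expect_equal(out$state$V_E[1], 7.6 + 6.4 * (1 - 0.1 / 20)^29,
                 tolerance = 0.01)  # reset then 29 decay steps
    # u_E received exactly one increment of tau_bar_E / tau_r_E = 1/8,
    # decayed since maturation; delay within [d_min_E, d_max_E]
    expect_equal(out$matured[1], 1)
    expect_gt(out$state$u[1], 1 / 8 * (1 - 0.1 / 8)^30)
    expect_lte(out$state$u[1], 1 / 8)
  }
})

test_that("astrocyte release delays fall in [500, 1500] ms", {
  p <- spiking_params(N_E = 0, N_I = 0, N_A = 1, sigma_A = 0, J_AA = 0,
                      frac_glio_targets = 0, frac_astro_receivers = 0)
  conn <- build_connectivity(p, seed = 1)
  st <- init_state(p, seed = 1)
  st$G_A[1] <- 20        # fires immediately, then stays subthreshold
  out <- network_step(st, p, conn, n_steps = 16000, seed = 3)
  expect_equal(out$spikes[3], 1)
  expect_equal(out$matured[3], 1)
  # locate the maturation time through the u_A trace of a fresh run
  sim <- simulate_spiking(p, 1600, seed = 4, state = st, connectivity = conn,
                          record_every = 1)
  t_jump <- sim$traces$t_ms[which(sim$traces$u_A > 0)[1]]
  expect_gte(t_jump, 500)
  expect_lte(t_jump, 1500 + 0.2)
})

test_that("the AHP current integrates beta/tau_a per spike", {
  # suprathreshold leak drives regular firing of a single E cell
  p <- spiking_params(N_E = 1, N_I = 0, N_A = 0, sigma_E = 0,
                      J_EE = 0, J_EI = 0, K_a = 0, V_L_E = 30,
                      frac_glio_targets = 0, frac_astro_receivers = 0)
  conn <- build_connectivity(p, seed = 1)
  st <- init_state(p, seed = 1)
  st$V_E[1] <- 14
  out <- network_step(st, p, conn, n_steps = 200)   # 20 ms << tau_a
  n_spk <- nrow(out$raster)
  expect_gt(n_spk, 0)
  expect_equal(out$state$I_a[1], n_spk * 1 / 500, tolerance = 0.03)
})

test_that("every threshold crossing is conserved through the event queue", {
  p <- spiking_params(N_E = 400, N_I = 100, N_A = 200)
  sim <- simulate_spiking(p, 2000, seed = 5)
  d <- sim$diagnostics
  expect_equal(d$spikes, d$matured + d$pending)
  expect_equal(sum(sim$raster$population == "E"), d$spikes[1])
  expect_equal(sum(sim$raster$population == "I"), d$spikes[2])
  expect_equal(sum(sim$raster$population == "A"), d$spikes[3])
  # synaptic variables stay nonnegative and bounded by the peak drive
  expect_gte(min(sim$traces[, c("u_E", "u_I", "u_A", "s_E", "s_I",
                                "s_A")]), 0)
  expect_lte(max(sim$traces$s_E), max(sim$traces$u_E) + 1e-9)
})

test_that("identical seeds give identical rasters", {
  p <- spiking_params(N_E = 200, N_I = 50, N_A = 100)
  a <- simulate_spiking(p, 500, seed = 12)
  b <- simulate_spiking(p, 500, seed = 12)
  expect_identical(a$raster, b$raster)
  expect_identical(a$traces, b$traces)
  c <- simulate_spiking(p, 500, seed = 13)
  expect_false(identical(a$raster, c$raster))
})

test_that("without astrocytes the full-size network falls silent", {
  p <- without_astro(spiking_params())
  sim <- simulate_spiking(p, 4000, seed = 1)
  late <- sim$raster[sim$raster$t_ms > 1500 &
                       sim$raster$population %in% c("E", "I"), ]
  rate <- nrow(late) / (5000 * 2.5)
  expect_lt(rate, 0.05)   # Hz per neuron: silence up to stray spikes
})

test_that("large external noise alone restores Up-Down switching", {
  p <- without_astro(spiking_params(sigma_E = 5, sigma_I = 5))
  sim <- simulate_spiking(p, 10000, seed = 7)
  seg <- segment_phases(median_smooth(spiking_rate_series(sim)))
  expect_gte(sum(seg$label == "Up"), 2)
  expect_gte(sum(seg$label == "Down"), 2)
})

test_that("astrocyte drive is phase-insensitive: CV(s_A) << CV(s_E)", {
  sim <- simulate_spiking(spiking_params(), 10000, seed = 21)
  tr <- sim$traces[sim$traces$t_ms > 2000, ]
  cv <- function(x) sd(x) / mean(x)
  expect_lt(cv(tr$s_A) / cv(tr$s_E), 0.5)
})
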