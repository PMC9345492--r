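test_that("the Down fixed point matches the closed form", {
  p <- rate_params()
  d <- down_fixed_point(p)
  expect_equal(d$r_A0, 3.5 / 0.9, tolerance = 1e-12)
  expect_equal(c(d$r_E0, d$r_I0), c(0, 0))
  expect_true(d$exists)      # default theta_E lies right of the D line
  expect_true(d$stable)
  expect_lt(d$residual, 1e-9)
  expect_equal(down_fixed_point(rate_params(J_AA = 0))$r_A0, 3.5)
  expect_error(down_fixed_point(rate_params(g_A = 11)), "diverges")
})

test_that("the Up fixed point solves the active linear system", {
  p <- rate_params(beta = 1, theta_E = 0)
  u <- up_fixed_point(p)
  expect_true(u$exists)
  expect_true(u$stable)
  expect_lt(u$residual, 1e-9)
  expect_equal(u$a0, p$beta * u$r_E0)
  # hand-derived closed form for the default couplings:
  # r_E0 = (43.5 - 1.7 theta_E) / (8.7 + 1.7 beta)
  expect_equal(u$r_E0, 43.5 / (8.7 + 1.7), tolerance = 1e-9)
  # deep in the D region the active solution is not self-consistent
  expect_false(up_fixed_point(rate_params(beta = 5, theta_E = 15))$exists)
})

test_that("noiseless labels cover the four regimes", {
  p <- rate_params()
  expect_equal(classify_noiseless(0.1, -8, p), "U")
  expect_equal(classify_noiseless(5, 15, p), "D")
  expect_equal(classify_noiseless(2.11, 8.95, p), "Bist")
  expect_equal(classify_noiseless(10, 0, p), "Osc")
  # the default operating point: silent without gliotransmission already
  # at the noiseless level
  expect_equal(classify_noiseless(p$beta, p$theta_E, without_astro(p)),
               "D")
})

test_that("noiseless labels agree with the two-initial-condition oracle", {
  p <- rate_params()
  set.seed(1)
  pts <- cbind(beta = runif(8, 0, 10), theta_E = runif(8, -10, 20))
  for (k in seq_len(nrow(pts))) {
    expect_equal(classify_noiseless(pts[k, 1], pts[k, 2], p),
                 oracle_classify(pts[k, 1], pts[k, 2], p),
                 label = sprintf("beta=%.2f theta_E=%.2f", pts[k, 1],
                                 pts[k, 2]))
  }
})

test_that("noise frontiers collapse at sigma = 0 and shift with astrocytes", {
  p <- rate_params()
  betas <- seq(0, 10, by = 1)

  fr0 <- noise_frontiers(p, betas, sigma = 0)
  # the D frontier collapses onto the Down existence line
  expect_equal(unique(fr0$theta_D), p$J["E", "A"] * 3.5 / 0.9)
  # the U frontier collapses onto the Up existence boundary: crossing it
  # flips the existence of the Up fixed point
  for (k in c(1, 5, 11)) {
    th <- fr0$theta_U[k]
    if (is.na(th)) next
    expect_true(up_fixed_point(
      rate_params(beta = betas[k], theta_E = th - 0.01))$exists)
    expect_false(up_fixed_point(
      rate_params(beta = betas[k], theta_E = th + 0.01))$exists)
  }

  # monotone shift: astrocytes push both frontiers to larger theta_E
  fr_w <- noise_frontiers(p, betas)
  fr_wo <- noise_frontiers(without_astro(p), betas)
  expect_true(all(fr_w$theta_D >= fr_wo$theta_D))
  ok <- !is.na(fr_w$theta_U) & !is.na(fr_wo$theta_U)
  expect_true(any(ok))
  expect_true(all(fr_w$theta_U[ok] >= fr_wo$theta_U[ok]))
})

test_that("the simulated phase diagram reports sane Up-time fractions", {
  p <- rate_params()
  pd <- simulate_phase_diagram(p, beta_values = c(0.5, 5),
                               thetaE_values = c(-8, 8, 18),
                               duration = 10000, seed = 4)
  expect_true(all(pd$frac_up >= 0 & pd$frac_up <= 1))
  # deep U cell: persistent Up; deep D cell: silent
  expect_gt(pd$frac_up[pd$beta == 0.5 & pd$theta_E == -8], 0.95)
  expect_lt(pd$frac_up[pd$beta == 5 & pd$theta_E == 18], 0.05)
  # the default operating point switches (intermediate fraction)
  mid <- pd$frac_up[pd$beta == 5 & pd$theta_E == 8]
  expect_gt(mid, 0.05)
  expect_lt(mid, 0.95)
})
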