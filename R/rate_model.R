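#' Rectified-linear transfer function
#'
#' The input-to-rate map of the rate model populations,
#' `phi(x) = g * max(x - theta, 0)`: zero below the threshold, linear with
#' slope `g` above it.
#'
#' @param x input value(s), in input units.
#' @param gain slope `g` in Hz per input unit (must be >= 0).
#' @param theta threshold, in input units.
#' @return Rate(s) in Hz, always >= 0.
#' @examples
#' transfer(30, gain = 4, theta = 25)  # 20 Hz
#' @export
transfer <- function(x, gain, theta) {
  if (any(!is.finite(x))) stop("transfer(): non-finite input x")
  if (any(gain < 0)) stop("transfer(): gain must be >= 0")
  gain * pmax(x - theta, 0)
}

#' Recurrent inputs of the rate model
#'
#' Computes the three internal recurrent inputs
#' `I_X = J_XE r_E + J_XI r_I + J_XA r_A` for X in (E, I, A).
#'
#' @param rates numeric vector `c(r_E, r_I, r_A)` in Hz.
#' @param J 3x3 coupling matrix (s), `J[X, Y]` = strength of Y -> X, as in
#'   [rate_params()].
#' @return Named vector `c(I_E, I_I, I_A)` in input units.
#' @examples
#' recurrent_inputs(c(1, 1, 1), rate_params()$J)
#' @export
recurrent_inputs <- function(rates, J) {
  if (any(!is.finite(rates))) stop("recurrent_inputs(): non-finite rates")
  out <- drop(J %*% rates)
  names(out) <- c("I_E", "I_I", "I_A")
  out
}

#' One exact-discretization step of an Ornstein-Uhlenbeck process
#'
#' Advances an OU state by `dt` using the exact conditional distribution:
#' decay factor `exp(-dt / tau_ou)` and innovation standard deviation
#' `sigma * sqrt(1 - exp(-2 dt / tau_ou))`.  The stationary distribution has
#' mean 0 and standard deviation `sigma` for any `dt`, which makes the
#' update stiffness-free.
#'
#' @param xi current noise value(s).
#' @param tau_ou correlation time (ms), > 0.
#' @param sigma stationary standard deviation, >= 0.
#' @param dt time step (ms).
#' @return The updated noise value(s); vectorized over `xi`.
#' @export
ou_step <- function(xi, tau_ou, sigma, dt) {
  if (tau_ou <= 0) stop("ou_step(): tau_ou must be > 0")
  if (sigma < 0) stop("ou_step(): sigma must be >= 0")
  rho <- exp(-dt / tau_ou)
  xi * rho + sigma * sqrt(1 - rho^2) * rnorm(length(xi))
}

# Full OU sample path of length n_steps + 1 starting from xi0, via the
# exact AR(1) recursion (vectorized with stats::filter).
ou_series <- function(n_steps, dt, tau_ou, sigma, xi0 = 0) {
  rho <- exp(-dt / tau_ou)
  innov <- sigma * sqrt(1 - rho^2) * rnorm(n_steps)
  c(xi0, as.numeric(filter(innov, rho, method = "recursive", init = xi0)))
}

#' One forward-Euler step of the rate model
#'
#' Advances the state `(r_E, r_I, r_A, a)` by one Euler step of the rate
#' dynamics.  The recurrent inputs, the adaptation current (subtracted from
#' the excitatory input) and the noise values all enter inside the
#' rectified-linear transfer argument.  Noise values are supplied
#' explicitly, which keeps the step deterministic and testable; the
#' convenience simulator [simulate_rate()] manages the OU noise streams.
#'
#' @param state named list or vector with `r_E`, `r_I`, `r_A` (Hz) and `a`
#'   (input units).
#' @param params a [rate_params()] object.
#' @param dt time step (ms); must satisfy
#'   `dt <= min(tau_E, tau_I, tau_A) / 4` (forward-Euler stability guard).
#' @param xi unit-variance noise values `c(xi_E, xi_I, xi_A)` (multiplied
#'   by `params$sigma` inside the transfer argument); default 0.
#' @return The updated state as a named numeric vector.
#' @export
rate_step <- function(state, params, dt, xi = c(0, 0, 0)) {
  if (dt > min(params$tau_E, params$tau_I, params$tau_A) / 4)
    stop("rate_step(): dt must be <= min(tau_E, tau_I, tau_A) / 4")
  s <- unlist(state)[c("r_E", "r_I", "r_A", "a")]
  I <- recurrent_inputs(s[1:3], params$J)
  phi <- c(
    transfer(I[1] - s["a"] + params$sigma * xi[1], params$g_E,
             params$theta_E),
    transfer(I[2] + params$sigma * xi[2], params$g_I, params$theta_I),
    transfer(I[3] + params$sigma * xi[3], params$g_A, params$theta_A))
  taus <- c(params$tau_E, params$tau_I, params$tau_A)
  out <- c(s[1:3] + dt / taus * (-s[1:3] + phi),
           s["a"] + dt / params$tau_a * (-s["a"] + params$beta * s["r_E"]))
  names(out) <- c("r_E", "r_I", "r_A", "a")
  out
}

#' Simulate the three-population rate model
#'
#' Integrates the rate dynamics with forward Euler (exact exponential update
#' for the OU noise states) and returns the full trajectory.  A single
#' master seed spawns three independent sub-streams for the noise processes
#' `xi_E`, `xi_I`, `xi_A` (see Details).
#'
#' With the default parameters and gliotransmission on, the trajectory
#' alternates between Up epochs (`r_E` of order 10 Hz) and silent Down
#' epochs; with the astrocyte couplings zeroed ([without_astro()]) the same
#' point is silent.
#'
#' @details The sub-seed splitting rule: `set.seed(seed)` then
#'   `sample.int(2^31 - 2, 3)` gives one sub-seed per noise stream; each
#'   stream is generated under `set.seed(sub_seed)`.  The OU correlation
#'   time `tau_ou` is a model input (default 1 ms); only the stationary
#'   standard deviation of the drive is constrained by the reference
#'   parameter set, so results should be checked for sensitivity to
#'   `tau_ou`.
#'
#' @param params a [rate_params()] object.
#' @param duration total simulated time (ms).
#' @param dt integration step (ms), default 0.1; guarded by
#'   `dt <= min(tau_E, tau_I, tau_A) / 4`.
#' @param seed integer master seed (required when `sigma > 0`).
#' @param tau_ou OU correlation time (ms), default 1.
#' @param init initial state `c(r_E, r_I, r_A, a)`; default the origin.
#' @param record_every record every k-th step (default 1 = every step).
#' @return A `rate_trajectory`: list with `states` (data.frame `t_ms`,
#'   `r_E`, `r_I`, `r_A`, `a`, `xi_E`, `xi_I`, `xi_A`), `dt` (the sampling
#'   step of `states`), `params`, `seed`, `tau_ou`.
#' @examples
#' traj <- simulate_rate(rate_params(), duration = 2000, seed = 1)
#' range(traj$states$r_E)
#' @export
simulate_rate <- function(params, duration, dt = 0.1, seed = NULL,
                          tau_ou = 1, init = c(0, 0, 0, 0),
                          record_every = 1) {
  stopifnot(inherits(params, "rate_params"))
  if (duration <= 0) stop("duration must be > 0")
  if (dt > min(params$tau_E, params$tau_I, params$tau_A) / 4)
    stop("dt must be <= min(tau_E, tau_I, tau_A) / 4 (Euler guard)")
  n_steps <- round(duration / dt)
  if (params$sigma > 0 && is.null(seed))
    stop("a seed is required for a stochastic simulation")
  if (is.null(seed)) seed <- 0L

  xi <- matrix(0, n_steps + 1, 3)
  if (params$sigma > 0) {
    set.seed(seed)
    subseeds <- sample.int(2^31 - 2, 3)
    for (j in 1:3) {
      set.seed(subseeds[j])
      # unit-variance OU; params$sigma scales it inside the transfer
      xi[, j] <- ou_series(n_steps, dt, tau_ou, 1)
    }
  }

  m <- rate_core(as.numeric(init), xi, unclass(params), dt, record_every)
  states <- as.data.frame(m)
  names(states) <- c("t_ms", "r_E", "r_I", "r_A", "a",
                     "xi_E", "xi_I", "xi_A")
  structure(list(states = states, dt = dt * record_every, params = params,
                 seed = seed, tau_ou = tau_ou),
            class = "rate_trajectory")
}

#' @export
print.rate_trajectory <- function(x, ...) {
  st <- x$states
  cat(sprintf(
    "Rate-model trajectory: %.1f ms at %.3g ms sampling (%d samples)\n",
    max(st$t_ms), x$dt, nrow(st)))
  cat(sprintf("  mean r_E=%.2f r_I=%.2f r_A=%.2f Hz | seed %s\n",
              mean(st$r_E), mean(st$r_I), mean(st$r_A), x$seed))
  invisible(x)
}
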