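# R-side drivers of the stochastic spiking network (C++ core in
# src/spiking_core.cpp).  Neuron-to-neuron and astrocyte-to-astrocyte
# connectivity is all-to-all through the population synaptic variables;
# gliotransmission reaches a fixed fraction of the neurons and a fixed
# fraction of the astrocytes listens to the neurons.

#' Build the neuron-astrocyte contact structure
#'
#' Samples which cells participate in gliotransmission, with exact counts
#' (not per-cell Bernoulli draws): `round(frac_glio_targets * N_E)`
#' excitatory and `round(frac_glio_targets * N_I)` inhibitory neurons are
#' contacted by the astrocytes, and `round(frac_astro_receivers * N_A)`
#' astrocytes receive input from the neurons, all chosen uniformly at
#' random.  Every other channel (E-E, E-I, I-E, I-I, A-A) is all-to-all
#' through the population synapse variables.
#'
#' @param params a [spiking_params()] object.
#' @param seed integer seed for the uniform subset draws.
#' @return A `ud_connectivity`: list of 0/1 integer vectors `glio_E`
#'   (length N_E), `glio_I`, `recv_A`.
#' @examples
#' conn <- build_connectivity(spiking_params(), seed = 1)
#' sum(conn$glio_E)  # 400 contacted E cells with the defaults
#' @export
build_connectivity <- function(params, seed = NULL) {
  stopifnot(inherits(params, "spiking_params"))
  pick <- function(n, frac) {
    if (n == 0 && frac > 0)
      stop("cannot contact cells of an empty population")
    k <- round(frac * n)
    v <- integer(n)
    if (k > 0) v[sample.int(n, k)] <- 1L
    v
  }
  if (!is.null(seed)) set.seed(seed)
  structure(list(
    glio_E = pick(params$N_E, params$frac_glio_targets),
    glio_I = pick(params$N_I, params$frac_glio_targets),
    recv_A = pick(params$N_A, params$frac_astro_receivers)),
    class = "ud_connectivity")
}

#' Initial state of the spiking network
#'
#' Membrane potentials start uniformly on `[V_r, V_th)` and astrocyte
#' release variables uniformly on `[G_r, G_th)`; synaptic variables, AHP
#' currents and the delayed-event queues start empty.
#'
#' @param params a [spiking_params()] object.
#' @param seed integer seed.
#' @param dt integration step the event queues are bucketed by (ms).
#' @return A `ud_network_state` list: `V_E`, `V_I`, `G_A`, `I_a`, `u`, `s`,
#'   delay ring buffers `q_E`, `q_I`, `q_A` with `head` indices, and
#'   `t_ms`.
#' @export
init_state <- function(params, seed = NULL, dt = 0.1) {
  stopifnot(inherits(params, "spiking_params"))
  if (!is.null(seed)) set.seed(seed)
  qlen <- function(dmax) as.integer(round(dmax / dt)) + 1L
  structure(list(
    V_E = params$V_r + (params$V_th - params$V_r) * runif(params$N_E),
    V_I = params$V_r + (params$V_th - params$V_r) * runif(params$N_I),
    G_A = params$G_r + (params$G_th - params$G_r) * runif(params$N_A),
    I_a = numeric(params$N_E),
    u = numeric(3), s = numeric(3),
    q_E = numeric(qlen(params$d_max_E)),
    q_I = numeric(qlen(params$d_max_I)),
    q_A = numeric(qlen(params$d_max_A)),
    head = integer(3), t_ms = 0),
    class = "ud_network_state")
}

core_par <- function(params) {
  c(unclass(params)[c("tau_E", "tau_I", "tau_A", "tau_a",
                      "J_EE", "J_EI", "J_EA", "J_IE", "J_II", "J_IA",
                      "J_AE", "J_AI", "J_AA", "beta", "K_a",
                      "sigma_E", "sigma_I", "sigma_A",
                      "V_r", "V_th", "V_L_E", "V_L_I",
                      "G_r", "G_th", "G_L")],
    list(tau_bar = c(params$tau_bar_E, params$tau_bar_I, params$tau_bar_A),
         tau_r = c(params$tau_r_E, params$tau_r_I, params$tau_r_A),
         tau_d = c(params$tau_d_E, params$tau_d_I, params$tau_d_A),
         d_min = c(params$d_min_E, params$d_min_I, params$d_min_A),
         d_max = c(params$d_max_E, params$d_max_I, params$d_max_A)))
}

#' Advance the spiking network by one (or a few) steps
#'
#' Single-step driver around the event-queue Euler core, mainly for
#' testing and for custom integration loops.  Thresholds are tested after
#' the Euler update; a crossing resets the cell the same step, emits one
#' delayed event (delay uniform in `[d_min, d_max]`, rounded to the dt
#' grid) and, for excitatory cells, increments the AHP current by
#' `beta / tau_a`.
#'
#' @param state a `ud_network_state` (see [init_state()]).
#' @param params a [spiking_params()] object.
#' @param conn a `ud_connectivity` from [build_connectivity()].
#' @param dt integration step (ms), at most 0.1.
#' @param n_steps number of steps to take (default 1).
#' @param seed integer seed for the step's noise and delay draws.
#' @return A list: updated `state`, `raster` (events of this stretch) and
#'   diagnostics `spikes`, `matured`, `pending` (per population E, I, A).
#' @export
network_step <- function(state, params, conn, dt = 0.1, n_steps = 1,
                         seed = 1) {
  if (dt > 0.1 + 1e-12)
    stop("network_step(): dt must be <= 0.1 ms")
  res <- spiking_core(state, core_par(params), conn, as.integer(n_steps),
                      dt, as.integer(n_steps), TRUE, seed)
  state <- structure(res$state, class = "ud_network_state")
  list(state = state,
       raster = raster_frame(res),
       spikes = res$spikes, matured = res$matured, pending = res$pending)
}

raster_frame <- function(res) {
  data.frame(
    population = c("E", "I", "A")[res$raster_pop + 1L],
    cell = res$raster_cell,
    t_ms = res$raster_t,
    stringsAsFactors = FALSE)
}

#' Simulate the stochastic spiking network
#'
#' Runs the full network (LIF excitatory and inhibitory neurons,
#' integrate-and-release astrocytes, population synaptic variables with
#' per-event transmission delays, AHP adaptation on the E cells) and
#' records every spike and gliotransmitter release event plus sampled
#' population traces.
#'
#' The master `seed` deterministically spawns three sub-seeds (for the
#' contact structure, the initial conditions and the integration noise),
#' so a run is reproducible from `(params, duration, dt, seed)` alone;
#' passing an explicit `connectivity` or `state` overrides the
#' corresponding stage.
#'
#' @param params a [spiking_params()] object.
#' @param duration simulated time (ms).
#' @param dt integration step (ms), default 0.1 (upper bound).
#' @param seed integer master seed.
#' @param connectivity optional `ud_connectivity` (otherwise drawn from the
#'   seed).
#' @param state optional initial `ud_network_state` (otherwise drawn from
#'   the seed).
#' @param record_every sample the population traces every k-th step
#'   (default: every 1 ms).
#' @param record_raster keep the event raster (default TRUE).
#' @return A `ud_spiking_sim`: list with `raster` (data.frame
#'   `population`, `cell`, `t_ms`), `traces` (data.frame `t_ms`, `u_E`,
#'   `u_I`, `u_A`, `s_E`, `s_I`, `s_A`, `mean_ahp`, `V_E1`, `V_I1`,
#'   `G_A1`), the final `state`, `connectivity`, `params`, `seed`, `dt`
#'   and event-conservation `diagnostics`.
#' @examples
#' p <- spiking_params(N_E = 200, N_I = 50, N_A = 100)
#' sim <- simulate_spiking(p, duration = 500, seed = 1)
#' head(sim$raster)
#' @export
simulate_spiking <- function(params, duration, dt = 0.1, seed = 1,
                             connectivity = NULL, state = NULL,
                             record_every = NULL, record_raster = TRUE) {
  stopifnot(inherits(params, "spiking_params"))
  if (duration <= 0) stop("duration must be > 0")
  if (dt > 0.1 + 1e-12) stop("dt must be <= 0.1 ms")
  set.seed(seed)
  sub <- sample.int(2^31 - 2, 3)
  if (is.null(connectivity))
    connectivity <- build_connectivity(params, seed = sub[1])
  if (is.null(state)) state <- init_state(params, seed = sub[2], dt = dt)
  if (is.null(record_every)) record_every <- max(1L, round(1 / dt))
  n_steps <- round(duration / dt)
  res <- spiking_core(state, core_par(params), connectivity,
                      as.integer(n_steps), dt, as.integer(record_every),
                      record_raster, sub[3])
  traces <- as.data.frame(res$traces)
  names(traces) <- c("t_ms", "u_E", "u_I", "u_A", "s_E", "s_I", "s_A",
                     "mean_ahp", "V_E1", "V_I1", "G_A1")
  structure(list(
    raster = raster_frame(res), traces = traces,
    state = structure(res$state, class = "ud_network_state"),
    connectivity = connectivity, params = params, seed = seed, dt = dt,
    duration = duration,
    diagnostics = list(spikes = res$spikes, matured = res$matured,
                       pending = res$pending)),
    class = "ud_spiking_sim")
}

#' @export
print.ud_spiking_sim <- function(x, ...) {
  ne <- sum(x$raster$population == "E")
  ni <- sum(x$raster$population == "I")
  na <- sum(x$raster$population == "A")
  cat(sprintf(
    "Spiking simulation: %.0f ms, N=(%d E, %d I, %d A), seed %d\n",
    x$duration, x$params$N_E, x$params$N_I, x$params$N_A, x$seed))
  cat(sprintf("  events: %d E spikes, %d I spikes, %d A releases\n",
              ne, ni, na))
  invisible(x)
}

#' Population rate series of a spiking simulation
#'
#' Applies [raster_to_rate()] to the E + I spikes of a simulation
#' (astrocyte release events are excluded), normalized by `N_E + N_I`.
#'
#' @param sim a `ud_spiking_sim`.
#' @param window,step sliding-window parameters (ms).
#' @return A `ud_rate_series`.
#' @export
spiking_rate_series <- function(sim, window = 10, step = 1) {
  raster_to_rate(sim$raster, n_neurons = sim$params$N_E + sim$params$N_I,
                 duration = sim$duration, window = window, step = step)
}
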