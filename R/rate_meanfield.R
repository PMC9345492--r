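# Fixed points, stability and the (beta, theta_E) phase diagram of the
# noiseless rate model.  The model is piecewise linear: each combination of
# active/inactive rectifications defines a linear regime, so fixed points
# are solutions of linear systems plus self-consistency (the arguments must
# lie on the side of the threshold that was assumed).

# Deterministic right-hand side (per ms) of the rate dynamics at sigma = 0.
rate_rhs <- function(state, params) {
  s <- unlist(state)[c("r_E", "r_I", "r_A", "a")]
  I <- recurrent_inputs(s[1:3], params$J)
  phi <- c(
    transfer(I[1] - s["a"], params$g_E, params$theta_E),
    transfer(I[2], params$g_I, params$theta_I),
    transfer(I[3], params$g_A, params$theta_A))
  taus <- c(params$tau_E, params$tau_I, params$tau_A)
  out <- c((-s[1:3] + phi) / taus,
           (-s["a"] + params$beta * s["r_E"]) / params$tau_a)
  names(out) <- c("r_E", "r_I", "r_A", "a")
  out
}

# Jacobian of the deterministic flow in the rectification configuration
# holding at `state`; configurations on a boundary (|margin| <= tol) are
# resolved by treating the rectification as inactive (its one-sided
# derivative towards the fixed point).
rate_jacobian <- function(state, params, tol = 1e-6) {
  s <- unlist(state)[c("r_E", "r_I", "r_A", "a")]
  I <- recurrent_inputs(s[1:3], params$J)
  margins <- c(I[1] - s["a"] - params$theta_E,
               I[2] - params$theta_I,
               I[3] - params$theta_A)
  act <- margins > tol
  g <- c(params$g_E, params$g_I, params$g_A)
  taus <- c(params$tau_E, params$tau_I, params$tau_A)
  Jm <- matrix(0, 4, 4)
  for (x in 1:3) {
    Jm[x, 1:3] <- (act[x] * g[x] * params$J[x, ]) / taus[x]
    Jm[x, x] <- Jm[x, x] - 1 / taus[x]
  }
  Jm[1, 4] <- -(act[1] * params$g_E) / params$tau_E
  Jm[4, 1] <- params$beta / params$tau_a
  Jm[4, 4] <- -1 / params$tau_a
  Jm
}

make_fixed_point <- function(r, a0, exists, params) {
  r <- unname(r)
  a0 <- unname(a0)
  state <- c(r_E = r[1], r_I = r[2], r_A = r[3], a = a0)
  ev <- eigen(rate_jacobian(state, params), only.values = TRUE)$values
  structure(list(
    r_E0 = unname(r[1]), r_I0 = unname(r[2]), r_A0 = unname(r[3]),
    a0 = unname(a0), exists = exists,
    stable = all(Re(ev) < 0), eigenvalues = ev,
    residual = max(abs(rate_rhs(state, params)))),
    class = "ud_fixed_point")
}

#' Down fixed point of the rate model
#'
#' The silent ("Down") equilibrium: neuronal rates vanish while the
#' astrocytes settle at the spontaneous release level
#' `r_A0 = -g_A theta_A / (1 - g_A J_AA)` sustained by the negative
#' astrocyte threshold.  The point exists (as an equilibrium of the full
#' dynamics) only when the excitatory and inhibitory transfer arguments at
#' this point stay at or below their thresholds, i.e. for `theta_E` at or
#' beyond the gliotransmission drive `J_EA * r_A0`; this is the vertical
#' frontier of the D-region in the (theta_E, beta) phase diagram.
#'
#' @param params a [rate_params()] object.
#' @return A `ud_fixed_point`: `r_E0`, `r_I0`, `r_A0`, `a0`, `exists`,
#'   `stable`, `eigenvalues` (Jacobian spectrum in the Down rectification
#'   configuration), `residual`.
#' @examples
#' down_fixed_point(rate_params())$r_A0  # 3.5 / 0.9
#' @export
down_fixed_point <- function(params) {
  gJ <- params$g_A * params$J["A", "A"]
  if (gJ >= 1)
    stop("down_fixed_point(): astrocyte self-excitation diverges ",
         "(g_A * J_AA >= 1)")
  r_A0 <- if (params$theta_A < 0) -params$g_A * params$theta_A / (1 - gJ)
          else 0
  r <- c(0, 0, r_A0)
  I <- recurrent_inputs(r, params$J)
  exists <- (I[1] <= params$theta_E) && (I[2] <= params$theta_I)
  make_fixed_point(r, 0, exists, params)
}

#' Up fixed point of the rate model
#'
#' The active ("Up") equilibrium with every rectification engaged: solves
#' the fully linear system `r_X = g_X (sum_Y J_XY r_Y - [X = E] beta r_E -
#' theta_X)` with the adaptation nullcline `a0 = beta * r_E0` substituted.
#' The solution is accepted (`exists`) only if it is self-consistent, i.e.
#' all transfer arguments strictly exceed their thresholds (equivalently,
#' all equilibrium rates are positive).
#'
#' @inheritParams down_fixed_point
#' @return A `ud_fixed_point` (see [down_fixed_point()]); when the linear
#'   solution is not self-consistent the candidate rates are still
#'   reported with `exists = FALSE`.
#' @export
up_fixed_point <- function(params) {
  g <- c(params$g_E, params$g_I, params$g_A)
  th <- c(params$theta_E, params$theta_I, params$theta_A)
  Jeff <- params$J
  Jeff[1, 1] <- Jeff[1, 1] - params$beta
  M <- diag(3) - diag(g) %*% Jeff
  if (abs(det(M)) < 1e-12)
    stop("up_fixed_point(): degenerate parameters (singular linear system)")
  r <- drop(solve(M, -g * th))
  exists <- all(r > 0)
  make_fixed_point(r, params$beta * r[1], exists, params)
}

#' @export
print.ud_fixed_point <- function(x, ...) {
  cat(sprintf(
    "Fixed point: r_E=%.4g r_I=%.4g r_A=%.4g Hz, a=%.4g (%s, %s)\n",
    x$r_E0, x$r_I0, x$r_A0, x$a0,
    if (x$exists) "exists" else "not self-consistent",
    if (x$stable) "stable" else "unstable"))
  invisible(x)
}

#' Classify a noiseless parameter point
#'
#' Labels a point of the (beta, theta_E) plane by which of the two
#' equilibria of the noiseless dynamics exist: `"U"` (only the Up fixed
#' point), `"D"` (only the Down one), `"Bist"` (both; the attractor is
#' selected by the initial condition) or `"Osc"` (neither; the rectification
#' arguments keep switching sign and the dynamics oscillates).
#'
#' @param beta adaptation strength (s).
#' @param theta_E excitatory threshold.
#' @param params a [rate_params()] object supplying all other parameters.
#' @return One of `"U"`, `"D"`, `"Bist"`, `"Osc"`.
#' @export
classify_noiseless <- function(beta, theta_E, params = rate_params()) {
  params$beta <- beta
  params$theta_E <- theta_E
  up <- up_fixed_point(params)$exists
  down <- down_fixed_point(params)$exists
  if (up && down) "Bist" else if (up) "U" else if (down) "D" else "Osc"
}

#' Noise-regime frontier estimates in the (beta, theta_E) plane
#'
#' First-order estimates of where external noise of amplitude `sigma`
#' converts the monostable regimes into Up-Down switching: the Down state
#' is taken to resist noise once its excitatory distance-to-threshold
#' exceeds one noise standard deviation
#' (`theta_E >= J_EA r_A0 + sigma`, the `D` frontier), and the Up state once
#' its transfer-argument margin `r_E0 / g_E` exceeds `sigma` (the `U`
#' frontier).  At `sigma = 0` both collapse onto the noiseless existence
#' lines.  These are deliberately coarse estimates: they position the pure
#' Down region correctly but underestimate its extent relative to
#' simulations (see the package vignette).
#'
#' @param params a [rate_params()] object.
#' @param beta_values grid of adaptation strengths (s).
#' @param sigma noise amplitude; defaults to `params$sigma`.
#' @return A data.frame with columns `beta`, `theta_D` (estimated
#'   U<->D | D frontier) and `theta_U` (estimated U | U<->D frontier,
#'   `NA` where the Up margin never reaches `sigma`).
#' @export
noise_frontiers <- function(params, beta_values = seq(0, 10, by = 0.25),
                            sigma = params$sigma) {
  p0 <- params
  r_A0 <- down_fixed_point(params)$r_A0
  theta_D <- params$J["E", "A"] * r_A0 + sigma
  theta_U <- vapply(beta_values, function(b) {
    p <- p0
    p$beta <- b
    f <- function(th) {
      p$theta_E <- th
      u <- up_fixed_point(p)
      # inside the U estimate: the Up point must exist (all rates
      # positive) with an excitatory margin of at least one noise SD
      min(u$r_E0, u$r_I0, u$r_A0, u$r_E0 - p$g_E * sigma)
    }
    lo <- -60; hi <- 60
    flo <- f(lo); fhi <- f(hi)
    if (is.na(flo) || is.na(fhi) || flo * fhi > 0) return(NA_real_)
    uniroot(f, c(lo, hi), tol = 1e-9)$root
  }, numeric(1))
  data.frame(beta = beta_values, theta_D = theta_D, theta_U = theta_U)
}

#' Simulated (beta, theta_E) phase diagram
#'
#' Runs the stochastic rate model on a grid of (beta, theta_E) values,
#' segments each trajectory into Up and Down phases and reports the
#' fraction of time spent in the Up state, together with a regime label:
#' `"U"` when `frac_up > 0.95`, `"D"` when `frac_up < 0.05`, `"U<->D"`
#' in between (thresholds chosen to be robust to edge effects).
#'
#' @param params a [rate_params()] object (beta/theta_E taken from the
#'   grid).
#' @param beta_values,thetaE_values grid axes.
#' @param duration per-cell simulated time (ms).
#' @param seed master seed; cell seeds are derived deterministically.
#' @param dt integration step (ms).
#' @param threshold Up/Down segmentation threshold (Hz).
#' @return A data.frame (class `ud_phase_diagram`) with columns `beta`,
#'   `theta_E`, `frac_up`, `label`, plus the noiseless classification
#'   `noiseless` for reference.
#' @export
simulate_phase_diagram <- function(params,
                                   beta_values = seq(0, 10, length.out = 50),
                                   thetaE_values = seq(-10, 20,
                                                       length.out = 50),
                                   duration = 1e5, seed = 1, dt = 0.1,
                                   threshold = 1) {
  grid <- expand.grid(beta = beta_values, theta_E = thetaE_values)
  set.seed(seed)
  cell_seeds <- sample.int(2^31 - 2, nrow(grid))
  res <- vapply(seq_len(nrow(grid)), function(i) {
    p <- params
    p$beta <- grid$beta[i]
    p$theta_E <- grid$theta_E[i]
    traj <- simulate_rate(p, duration, dt = dt, seed = cell_seeds[i],
                          record_every = max(1L, round(1 / dt)))
    sm <- median_smooth(trajectory_rate_series(traj))
    mean(sm$values >= threshold)
  }, numeric(1))
  grid$frac_up <- res
  grid$label <- ifelse(res > 0.95, "U", ifelse(res < 0.05, "D", "U<->D"))
  grid$noiseless <- mapply(classify_noiseless, grid$beta, grid$theta_E,
                           MoreArgs = list(params = params))
  class(grid) <- c("ud_phase_diagram", "data.frame")
  grid
}
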