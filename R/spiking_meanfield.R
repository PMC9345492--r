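# Diffusion-approximation mean-field analysis of the spiking network.
#
# Stationary population rates solve a self-consistency problem: candidate
# rates imply stationary synaptic drives s_X = tau_bar_X N_X r_X, the
# drives imply a mean input to each (sub)population, and the first-passage
# rate of the corresponding leaky integrate-and-fire process must
# reproduce the candidate rates.  Because gliotransmission reaches only a
# fraction of the neurons (and only a fraction of the astrocytes listens
# to the neurons), each population is a mixture of two homogeneous
# subpopulations; the solver works on the six subpopulation rates and
# reports population means.  The after-hyperpolarization current
# contributes its stationary mean -K_a beta r to each excitatory cell's
# input.

# --- numerically stable scaled complementary error function -------------
# erfcx(x) = exp(x^2) erfc(x); the naive product overflows past x ~ 26.
erfcx_stable <- function(x) {
  out <- numeric(length(x))
  hi <- x > 25
  if (any(hi)) {
    v <- x[hi]
    out[hi] <- (1 - 0.5 / v^2 + 0.75 / v^4) / (v * sqrt(pi))
  }
  if (any(!hi))
    out[!hi] <- exp(x[!hi]^2) *
      2 * stats::pnorm(x[!hi] * sqrt(2), lower.tail = FALSE)
  out
}

# G(x) = int_0^x exp(u^2) du for 0 <= x <= 20, by a positive-term Taylor
# series (no cancellation) below 8 and an asymptotic expansion above.
int_exp_sq_0 <- function(x) {
  if (x <= 0) return(0)
  if (x < 8) {
    k <- 0:(ceiling(x^2) + 60)
    sum(exp((2 * k + 1) * log(x) - lgamma(k + 1) - log(2 * k + 1)))
  } else {
    k <- 0:6
    coef <- cumprod(c(1, 2 * k[-1] - 1)) / (2 * x^2)^k   # (2k-1)!!/(2x^2)^k
    exp(x^2) / (2 * x) * sum(coef)
  }
}

# cached 64-point Gauss-Legendre rule on [-1, 1]
.gl_cache <- new.env(parent = emptyenv())
gl_nodes <- function() {
  if (is.null(.gl_cache$x)) {
    gl <- pracma::gaussLegendre(64, -1, 1)
    .gl_cache$x <- gl$x
    .gl_cache$w <- gl$w
  }
  .gl_cache
}

# integral of erfcx over [lo, hi], 0 <= lo <= hi; asymptotic tail past 8
int_erfcx <- function(lo, hi) {
  if (hi <= lo) return(0)
  Fasym <- function(v) (log(v) + 1 / (4 * v^2) - 3 / (16 * v^4)) / sqrt(pi)
  cut <- 8
  out <- 0
  if (lo < cut) {
    b <- min(hi, cut)
    gl <- gl_nodes()
    u <- (b - lo) / 2 * gl$x + (b + lo) / 2
    out <- out + (b - lo) / 2 * sum(gl$w * erfcx_stable(u))
  }
  if (hi > cut) out <- out + Fasym(hi) - Fasym(max(lo, cut))
  out
}

#' Stationary firing rate of a noise-driven leaky integrator
#'
#' First-passage rate of the process
#' `tau dV/dt = -(V - v_leak) + mu + sigma sqrt(tau) eta(t)` with threshold
#' `v_th` and reset `v_r` (no refractory period), from the classical
#' diffusion-approximation formula
#' `1/nu = tau sqrt(pi) * int_{y_r}^{y_th} exp(u^2)(1 + erf(u)) du` with
#' `y = (v - v_leak - mu) / sigma`, evaluated in a numerically stable way
#' (the integrand is `erfcx(-u)`).  For `sigma = 0` the deterministic
#' threshold-crossing rate is returned.
#'
#' Applies both to the neurons (V in mV) and to the astrocyte release
#' variable G (dimensionless).
#'
#' @param mu mean input (same units as V).
#' @param sigma input noise amplitude; the stationary free-membrane
#'   standard deviation is `sigma / sqrt(2)`.
#' @param tau membrane (or release-variable) time constant, ms.
#' @param v_th,v_r threshold and reset.
#' @param v_leak leak/rest value (default 0; pass the absolute leak to use
#'   absolute thresholds).
#' @return Rate in Hz (events per second).
#' @export
lif_stationary_rate <- function(mu, sigma, tau, v_th, v_r, v_leak = 0) {
  if (v_r >= v_th) stop("require v_r < v_th")
  if (sigma < 0) stop("sigma must be >= 0")
  eff <- mu + v_leak
  if (sigma == 0) {
    if (eff <= v_th) return(0)
    return(1000 / (tau * log((eff - v_r) / (eff - v_th))))
  }
  y_th <- (v_th - eff) / sigma
  y_r <- (v_r - eff) / sigma
  if (y_th > 20) return(0)   # rate below ~1e-170 Hz
  I <- 0
  if (y_r < 0) {             # part of the range below the mean
    v2 <- -y_r
    v1 <- max(0, -y_th)
    I <- I + int_erfcx(v1, v2)
  }
  if (y_th > 0) {            # part of the range above the mean
    a <- max(0, y_r)
    I <- I + 2 * (int_exp_sq_0(y_th) - int_exp_sq_0(a)) -
      int_erfcx(a, y_th)
  }
  1000 / (tau * sqrt(pi) * I)
}

# stationary synaptic drives implied by population mean rates (Hz)
stationary_drives <- function(rates, params) {
  c(E = params$tau_bar_E * params$N_E * rates[[1]] / 1000,
    I = params$tau_bar_I * params$N_I * rates[[2]] / 1000,
    A = params$tau_bar_A * params$N_A * rates[[3]] / 1000)
}

# rate maps of the three cell classes
rate_map_E <- function(mu, sigma_X, p)
  lif_stationary_rate(mu, sigma_X, p$tau_E, p$V_th, p$V_r, p$V_L_E)
rate_map_I <- function(mu, sigma_X, p)
  lif_stationary_rate(mu, sigma_X, p$tau_I, p$V_th, p$V_r, p$V_L_I)
rate_map_A <- function(mu, p)
  lif_stationary_rate(mu, p$sigma_A, p$tau_A, p$G_th, p$G_r, p$G_L)

# E subpopulation rate with its own stationary AHP: nu = F(mu - c nu),
# strictly decreasing in nu so the root is unique and bracketed by
# [0, F(mu)].
solve_E_sub <- function(mu_syn, sigma_X, p) {
  cahp <- p$K_a * p$beta / 1000
  f0 <- rate_map_E(mu_syn, sigma_X, p)
  if (f0 <= 0) return(0)
  g <- function(nu) rate_map_E(mu_syn - cahp * nu, sigma_X, p) - nu
  uniroot(g, c(0, f0), tol = 1e-12)$root
}

# six subpopulation residuals given x = (eN, eC, iN, iC, aN, aR) in Hz
residual6 <- function(x, sigma_X, p) {
  fg <- p$frac_glio_targets
  fa <- p$frac_astro_receivers
  rE <- (1 - fg) * x[1] + fg * x[2]
  rI <- (1 - fg) * x[3] + fg * x[4]
  rA <- (1 - fa) * x[5] + fa * x[6]
  s <- stationary_drives(c(rE, rI, rA), p)
  cahp <- p$K_a * p$beta / 1000
  muE <- p$J_EE * s[1] + p$J_EI * s[2]
  muI <- p$J_IE * s[1] + p$J_II * s[2]
  muA <- p$J_AA * s[3]
  c(x[1] - rate_map_E(muE - cahp * x[1], sigma_X, p),
    x[2] - rate_map_E(muE + p$J_EA * s[3] - cahp * x[2], sigma_X, p),
    x[3] - rate_map_I(muI, sigma_X, p),
    x[4] - rate_map_I(muI + p$J_IA * s[3], sigma_X, p),
    x[5] - rate_map_A(muA, p),
    x[6] - rate_map_A(muA + p$J_AE * s[1] + p$J_AI * s[2], p))
}

#' Self-consistency residual of candidate stationary rates
#'
#' Residual `rates - map(rates)` of the mean-field stationary-rate map at
#' candidate population rates `(r_E0, r_I0, r_A0)`: the candidate rates
#' fix the stationary synaptic drives, each subpopulation's
#' first-passage rate is evaluated at the implied mean input (with the
#' excitatory AHP solved self-consistently within each subpopulation), and
#' subpopulation rates are mixed by their fractions.  A zero residual is a
#' mean-field fixed point.
#'
#' @param rates numeric `c(r_E0, r_I0, r_A0)` in Hz, >= 0.
#' @param sigma_X external noise amplitude to the neurons (mV); the
#'   astrocyte noise stays at `params$sigma_A`.
#' @param params a [spiking_params()] object.
#' @param with_astro if `FALSE`, the four neuron-astrocyte couplings are
#'   zeroed first (see [without_astro()]).
#' @return Named residual vector (Hz).
#' @export
selfconsistent_residual <- function(rates, sigma_X, params,
                                    with_astro = TRUE) {
  if (any(rates < 0)) stop("rates must be >= 0")
  p <- if (with_astro) params else without_astro(params)
  s <- stationary_drives(rates, p)
  fg <- p$frac_glio_targets
  fa <- p$frac_astro_receivers
  muE <- p$J_EE * s[1] + p$J_EI * s[2]
  muI <- p$J_IE * s[1] + p$J_II * s[2]
  muA <- p$J_AA * s[3]
  mapped <- c(
    r_E = (1 - fg) * solve_E_sub(muE, sigma_X, p) +
      fg * solve_E_sub(muE + p$J_EA * s[3], sigma_X, p),
    r_I = (1 - fg) * rate_map_I(muI, sigma_X, p) +
      fg * rate_map_I(muI + p$J_IA * s[3], sigma_X, p),
    r_A = (1 - fa) * rate_map_A(muA, p) +
      fa * rate_map_A(muA + p$J_AE * s[1] + p$J_AI * s[2], p))
  out <- c(rates) - mapped
  names(out) <- c("r_E", "r_I", "r_A")
  out
}

# damped quasi-Newton on the six subpopulation rates; returns the
# solution or NULL.  The Jacobian is built by forward differences and then
# kept up to date with Broyden rank-1 corrections (recomputed from scratch
# when a step fails); iterates are clamped nonnegative.
newton6 <- function(x0, sigma_X, p, tol = 1e-9, maxit = 30,
                    known = NULL) {
  fd_jacobian <- function(x, f) {
    J <- matrix(0, 6, 6)
    h <- pmax(1e-7, 1e-7 * abs(x))
    for (j in 1:6) {
      xp <- x; xp[j] <- x[j] + h[j]
      J[, j] <- (residual6(xp, sigma_X, p) - f) / h[j]
    }
    J
  }
  x <- pmax(x0, 0)
  f <- residual6(x, sigma_X, p)
  J <- NULL
  fresh <- FALSE
  for (it in seq_len(maxit)) {
    if (max(abs(f)) < tol) return(x)
    if (it > 3 && length(known)) {
      m <- pop_means(x, p)
      for (kn in known)
        if (max(abs(m - kn)) < 5e-4) return(NULL)   # heading to a known point
    }
    if (is.null(J)) {
      J <- fd_jacobian(x, f)
      fresh <- TRUE
    }
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step)) {
      if (fresh) return(NULL)
      J <- NULL
      next
    }
    lam <- 1
    ok <- FALSE
    while (lam > 1e-7) {
      xn <- pmax(x - lam * step, 0)
      fn <- tryCatch(residual6(xn, sigma_X, p), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn)) &&
          max(abs(fn)) < max(abs(f))) {
        dx <- xn - x
        df <- fn - f
        if (sum(dx^2) > 0)
          J <- J + ((df - J %*% dx) %*% t(dx)) / sum(dx^2)
        x <- xn; f <- fn; ok <- TRUE
        fresh <- FALSE
        break
      }
      lam <- lam / 2
    }
    if (!ok) {
      if (fresh) return(NULL)
      J <- NULL        # stale Broyden Jacobian: rebuild and retry
    }
  }
  if (max(abs(f)) < 1e-7) x else NULL
}

pop_means <- function(x, p) {
  fg <- p$frac_glio_targets
  fa <- p$frac_astro_receivers
  c(r_E = (1 - fg) * x[1] + fg * x[2],
    r_I = (1 - fg) * x[3] + fg * x[4],
    r_A = (1 - fa) * x[5] + fa * x[6])
}

# mean-field relaxation flow on population rates, used for stability:
# dr_X/dt = (map_X(r) - r_X) / tau_X
meanfield_flow <- function(rates, sigma_X, p) {
  -selfconsistent_residual(rates, sigma_X, p, with_astro = TRUE) /
    c(p$tau_E, p$tau_I, p$tau_A)
}

flow_jacobian <- function(rates, sigma_X, p, h = 1e-5) {
  J <- matrix(0, 3, 3)
  for (j in 1:3) {
    rp <- rates; rm <- rates
    rp[j] <- rates[j] + h
    rm[j] <- max(0, rates[j] - h)
    J[, j] <- (meanfield_flow(rp, sigma_X, p) -
                 meanfield_flow(rm, sigma_X, p)) / (rp[j] - rm[j])
  }
  J
}

default_starts <- function(dense = TRUE) {
  g <- if (dense)
    expand.grid(e = c(0, 0.3, 1, 2, 5, 10), i = c(0, 1, 5, 20),
                a = c(0.1, 0.5, 1.5))
  else
    expand.grid(e = c(0, 0.3, 0.8, 1.5, 3), i = c(0, 2, 10),
                a = c(0.12, 0.8))
  lapply(seq_len(nrow(g)), function(k)
    c(g$e[k], g$e[k], g$i[k], g$i[k], g$a[k], g$a[k]))
}

#' Mean-field fixed points of the spiking network
#'
#' Multi-start damped-Newton search for all self-consistent stationary
#' rate triples at a given external noise amplitude.  Solutions closer
#' than 1e-3 Hz (max over the three rates) are deduplicated; each
#' surviving point is certified by the population-level residual and
#' classified stable/unstable from the eigenvalues of the relaxation
#' flow's Jacobian (central finite differences).
#'
#' @inheritParams selfconsistent_residual
#' @param starts optional list of 6-vectors of subpopulation starting
#'   rates (non-contacted E, contacted E, non-contacted I, contacted I,
#'   non-receiving A, receiving A); defaults to a 72-point grid.
#' @return A data.frame (class `ud_fixed_points`) with columns `r_E0`,
#'   `r_I0`, `r_A0`, `stable`, `residual`, plus attribute `eigenvalues`
#'   (list).  Possibly zero rows.
#' @export
find_fixed_points <- function(sigma_X, params, with_astro = TRUE,
                              starts = NULL) {
  p <- if (with_astro) params else without_astro(params)
  if (is.null(starts)) starts <- default_starts()
  sols <- list()
  known <- list()
  for (x0 in starts) {
    x <- newton6(x0, sigma_X, p, known = known)
    if (!is.null(x)) {
      sols[[length(sols) + 1L]] <- x
      m <- pop_means(x, p)
      dup <- any(vapply(known, function(kn) max(abs(m - kn)) < 1e-3,
                        logical(1)))
      if (!dup) known[[length(known) + 1L]] <- m
    }
  }
  collect_fixed_points(sols, sigma_X, p)
}

collect_fixed_points <- function(sols, sigma_X, p) {
  empty <- data.frame(r_E0 = numeric(0), r_I0 = numeric(0),
                      r_A0 = numeric(0), stable = logical(0),
                      residual = numeric(0))
  class(empty) <- c("ud_fixed_points", "data.frame")
  if (!length(sols)) return(empty)
  means <- t(vapply(sols, pop_means, numeric(3), p = p))
  keep <- rep(TRUE, nrow(means))
  for (a in seq_len(nrow(means)))
    for (b in seq_len(nrow(means)))
      if (b < a && keep[a] && keep[b] &&
          max(abs(means[a, ] - means[b, ])) < 1e-3)
        keep[a] <- FALSE
  means <- means[keep, , drop = FALSE]
  sols <- sols[keep]
  ev <- vector("list", nrow(means))
  stable <- logical(nrow(means))
  resid <- numeric(nrow(means))
  for (i in seq_len(nrow(means))) {
    resid[i] <- max(abs(selfconsistent_residual(means[i, ], sigma_X, p)))
    ev[[i]] <- eigen(flow_jacobian(means[i, ], sigma_X, p),
                     only.values = TRUE)$values
    stable[i] <- all(Re(ev[[i]]) < 0)
  }
  ord <- order(means[, 1])
  out <- data.frame(r_E0 = means[ord, 1], r_I0 = means[ord, 2],
                    r_A0 = means[ord, 3], stable = stable[ord],
                    residual = resid[ord])
  attr(out, "eigenvalues") <- ev[ord]
  attr(out, "subpop") <- sols[ord]
  class(out) <- c("ud_fixed_points", "data.frame")
  out
}

#' Bifurcation sweep of the mean-field fixed points along sigma_X
#'
#' Continues the mean-field fixed points over a grid of external-noise
#' amplitudes (warm starts from the previous grid point plus a fresh
#' multi-start at every point, so branches created at folds are picked
#' up), classifies their stability, and reports fold (saddle-node)
#' locations as the grid intervals on which the fixed-point count
#' changes.  The astrocyte noise `sigma_A` is held at its parameter
#' value throughout.
#'
#' @inheritParams selfconsistent_residual
#' @param sigma_from,sigma_to,step sweep range and step (mV).
#' @return A `ud_bifurcation`: list with `branches` (data.frame
#'   `sigma_X`, `r_E0`, `r_I0`, `r_A0`, `stable`, `residual`), `folds`
#'   (data.frame `sigma_lo`, `sigma_hi`, `n_before`, `n_after`),
#'   `bistable_window` (range of sigma_X with >= 2 coexisting stable
#'   points, NA if none) and `with_astro`.
#' @export
sweep_bifurcation <- function(sigma_from, sigma_to, step, params,
                              with_astro = TRUE) {
  p <- if (with_astro) params else without_astro(params)
  sigmas <- seq(sigma_from, sigma_to, by = step)
  cold <- default_starts(dense = FALSE)
  prev <- list()
  rows <- vector("list", length(sigmas))
  counts <- integer(length(sigmas))
  stable2 <- logical(length(sigmas))
  for (k in seq_along(sigmas)) {
    starts <- c(prev, cold)
    fps <- find_fixed_points(sigmas[k], p, with_astro = TRUE,
                             starts = starts)
    prev <- attr(fps, "subpop")
    counts[k] <- nrow(fps)
    stable2[k] <- sum(fps$stable) >= 2
    if (nrow(fps))
      rows[[k]] <- cbind(sigma_X = sigmas[k], as.data.frame(fps))
  }
  branches <- do.call(rbind, rows)
  chg <- which(diff(counts) != 0)
  folds <- data.frame(sigma_lo = sigmas[chg], sigma_hi = sigmas[chg + 1],
                      n_before = counts[chg], n_after = counts[chg + 1])
  window <- if (any(stable2)) range(sigmas[stable2]) else c(NA_real_,
                                                            NA_real_)
  structure(list(branches = branches, folds = folds,
                 bistable_window = window, sigmas = sigmas,
                 counts = counts, with_astro = with_astro),
            class = "ud_bifurcation")
}

#' @export
print.ud_bifurcation <- function(x, ...) {
  cat(sprintf("Mean-field bifurcation sweep (%s astrocytes)\n",
              if (x$with_astro) "with" else "without"))
  cat(sprintf("  sigma_X in [%g, %g], %d points\n", min(x$sigmas),
              max(x$sigmas), length(x$sigmas)))
  if (all(is.na(x$bistable_window))) {
    cat("  no bistable window detected\n")
  } else {
    cat(sprintf("  >= 2 stable fixed points for sigma_X in [%g, %g] mV\n",
                x$bistable_window[1], x$bistable_window[2]))
  }
  if (nrow(x$folds)) {
    cat("  fixed-point count changes:\n")
    for (i in seq_len(nrow(x$folds)))
      cat(sprintf("    %d -> %d between %g and %g mV\n",
                  x$folds$n_before[i], x$folds$n_after[i],
                  x$folds$sigma_lo[i], x$folds$sigma_hi[i]))
  }
  invisible(x)
}
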