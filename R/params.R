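#' Parameters of the three-population firing-rate model
#'
#' Builds the full parameter record of the rate model: membrane/release time
#' constants, rectified-linear transfer gains and thresholds, adaptation
#' strength, the noise amplitude and the 3x3 coupling matrix between the
#' excitatory (E), inhibitory (I) and astrocyte (A) populations.  Defaults
#' are the reference parameter set of the model; couplings are in seconds so
#' that `J %*% r` (rates in Hz) is a dimensionless input.
#'
#' The excitatory threshold `theta_E` and the adaptation strength `beta` are
#' the two free axes of the model's phase diagram (`theta_E` in \[-10, 20\],
#' `beta` in \[0, 10\] s).  Their defaults place the model in the
#' noise-driven Up-Down switching regime when gliotransmission is on while
#' the same point is silent when the astrocyte couplings are zeroed (see
#' [without_astro()]); see the package vignette for how this operating point
#' was chosen.
#'
#' @param ... named overrides of any default, e.g. `theta_E = 6`,
#'   `J_EA = 0`.  Unknown names are an error.
#' @return An object of class `rate_params`: a list with elements `tau_E`,
#'   `tau_I`, `tau_A`, `tau_a` (ms), `g_E`, `g_I`, `g_A` (Hz per input
#'   unit), `theta_E`, `theta_I`, `theta_A`, `sigma` (input units), `beta`
#'   (s) and `J` (3x3 matrix, `J[X, Y]` = strength of Y -> X, in s).
#' @examples
#' p <- rate_params()
#' p$J["E", "A"]   # astrocyte -> excitatory coupling
#' rate_params(beta = 2, theta_E = 0)
#' @export
rate_params <- function(...) {
  defaults <- list(
    tau_E = 10, tau_I = 2, tau_A = 20, tau_a = 500,
    g_E = 1, g_I = 4, g_A = 1,
    theta_E = 8, theta_I = 25, theta_A = -3.5,
    sigma = 3.52, beta = 5,
    J_EE = 5, J_EI = -1, J_EA = 1,
    J_IE = 10, J_II = -0.5, J_IA = 0.5,
    J_AE = 0.5, J_AI = 0.5, J_AA = 0.1)
  p <- apply_overrides(defaults, list(...), "rate_params")
  J <- matrix(c(p$J_EE, p$J_EI, p$J_EA,
                p$J_IE, p$J_II, p$J_IA,
                p$J_AE, p$J_AI, p$J_AA),
              nrow = 3, byrow = TRUE,
              dimnames = list(c("E", "I", "A"), c("E", "I", "A")))
  p <- p[setdiff(names(p), grep("^J_", names(p), value = TRUE))]
  p$J <- J
  class(p) <- "rate_params"
  validate_rate_params(p)
  p
}

validate_rate_params <- function(p) {
  taus <- c(tau_E = p$tau_E, tau_I = p$tau_I, tau_A = p$tau_A,
            tau_a = p$tau_a)
  bad <- names(taus)[!is.finite(taus) | taus <= 0]
  if (length(bad))
    stop("time constants must be positive: ", paste(bad, collapse = ", "))
  gains <- c(g_E = p$g_E, g_I = p$g_I, g_A = p$g_A)
  if (any(!is.finite(gains) | gains < 0))
    stop("gains g_E, g_I, g_A must be >= 0")
  J <- p$J
  if (J["E", "E"] < 0 || J["I", "E"] < 0)
    stop("excitatory couplings J_EE, J_IE must be >= 0")
  if (J["E", "I"] > 0 || J["I", "I"] > 0)
    stop("inhibitory couplings J_EI, J_II must be <= 0")
  if (any(J[, "A"] < 0) || any(J["A", ] < 0))
    stop("astrocyte couplings J_EA, J_IA, J_AE, J_AI, J_AA must be >= 0")
  if (!is.finite(p$sigma) || p$sigma < 0) stop("sigma must be >= 0")
  invisible(p)
}

#' Parameters of the stochastic spiking network model
#'
#' Builds the parameter record of the spiking model: leaky integrate-and-fire
#' excitatory/inhibitory neurons, integrate-and-release astrocytes,
#' population synaptic variables with rise/decay times and per-event
#' transmission delays, and the after-hyperpolarization (AHP) adaptation
#' current on the excitatory cells.  Defaults are the reference parameter
#' set of the model.
#'
#' Couplings onto neurons (`J_EE`, `J_EI`, `J_IE`, `J_II`, `J_EA`, `J_IA`)
#' are in mV; couplings onto astrocytes (`J_AE`, `J_AI`, `J_AA`) are
#' dimensionless, as is the release variable G.  Astrocyte transmission
#' delays are three orders of magnitude slower than neuronal ones
#' (`d_min_A` = 500 ms, `d_max_A` = 1500 ms versus at most 1 ms), reflecting
#' calcium-wave signalling versus action-potential propagation.
#'
#' @param ... named overrides of any default.  Unknown names are an error.
#' @return An object of class `spiking_params` (a named list).
#' @examples
#' p <- spiking_params(N_E = 400, N_I = 100, N_A = 200)
#' p$J_EA
#' @export
spiking_params <- function(...) {
  defaults <- list(
    tau_E = 20, tau_I = 10, tau_A = 160, tau_a = 500,
    tau_bar_E = 1, tau_bar_I = 1, tau_bar_A = 1,
    J_EE = 1.4, J_EI = -1.4, J_II = -1, J_IE = 1.25,
    J_AA = 0.16, J_AE = 0.053, J_EA = 22, J_IA = 4.4, J_AI = 0.058,
    beta = 1, K_a = 600,
    sigma_E = 3, sigma_I = 3, sigma_A = 3,
    V_r = 14, V_th = 20, V_L_E = 7.6, V_L_I = 6.5,
    G_r = 9, G_th = 13, G_L = 7,
    tau_d_E = 23, tau_d_I = 1, tau_d_A = 2,
    tau_r_E = 8, tau_r_I = 1, tau_r_A = 8,
    d_min_E = 0, d_max_E = 1,
    d_min_I = 0, d_max_I = 0.5,
    d_min_A = 500, d_max_A = 1500,
    N_E = 4000, N_I = 1000, N_A = 2000,
    frac_glio_targets = 0.10, frac_astro_receivers = 0.50)
  p <- apply_overrides(defaults, list(...), "spiking_params")
  class(p) <- "spiking_params"
  validate_spiking_params(p)
  p
}

validate_spiking_params <- function(p) {
  taus <- c(tau_E = p$tau_E, tau_I = p$tau_I, tau_A = p$tau_A,
            tau_a = p$tau_a, tau_r_E = p$tau_r_E, tau_r_I = p$tau_r_I,
            tau_r_A = p$tau_r_A, tau_d_E = p$tau_d_E, tau_d_I = p$tau_d_I,
            tau_d_A = p$tau_d_A)
  bad <- names(taus)[!is.finite(taus) | taus <= 0]
  if (length(bad))
    stop("time constants must be positive: ", paste(bad, collapse = ", "))
  if (p$V_r >= p$V_th) stop("require V_r < V_th")
  if (p$G_r >= p$G_th) stop("require G_r < G_th")
  for (x in c("E", "I", "A")) {
    dmin <- p[[paste0("d_min_", x)]]; dmax <- p[[paste0("d_max_", x)]]
    if (dmin < 0 || dmax < dmin)
      stop("require 0 <= d_min_", x, " <= d_max_", x)
  }
  if (any(c(p$sigma_E, p$sigma_I, p$sigma_A) < 0))
    stop("noise amplitudes must be >= 0")
  if (p$frac_glio_targets < 0 || p$frac_glio_targets > 1 ||
      p$frac_astro_receivers < 0 || p$frac_astro_receivers > 1)
    stop("connection fractions must lie in [0, 1]")
  if (any(c(p$N_E, p$N_I, p$N_A) < 0)) stop("network sizes must be >= 0")
  invisible(p)
}

#' Switch off gliotransmission
#'
#' Zeroes the four couplings between neurons and astrocytes (`J_EA`, `J_IA`,
#' `J_AE`, `J_AI`), leaving everything else untouched.  This is the
#' "without astrocytes" configuration used as a control throughout.
#'
#' @param params a `rate_params` or `spiking_params` object.
#' @return The same class of object with the neuron-astrocyte couplings set
#'   to zero.
#' @export
without_astro <- function(params) {
  if (inherits(params, "rate_params")) {
    params$J["E", "A"] <- 0
    params$J["I", "A"] <- 0
    params$J["A", "E"] <- 0
    params$J["A", "I"] <- 0
  } else if (inherits(params, "spiking_params")) {
    params$J_EA <- 0; params$J_IA <- 0; params$J_AE <- 0; params$J_AI <- 0
  } else {
    stop("params must be rate_params or spiking_params")
  }
  params
}

apply_overrides <- function(defaults, overrides, what) {
  if (length(overrides)) {
    nm <- names(overrides)
    if (is.null(nm) || any(nm == ""))
      stop("all ", what, " overrides must be named")
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown))
      stop("unknown ", what, " name(s): ", paste(unknown, collapse = ", "))
    defaults <- modifyList(defaults, overrides)
  }
  defaults
}

#' @export
print.rate_params <- function(x, ...) {
  cat("Rate model parameters (time in ms, rates in Hz, couplings in s)\n")
  cat(sprintf("  tau: E=%g I=%g A=%g a=%g | g: E=%g I=%g A=%g\n",
              x$tau_E, x$tau_I, x$tau_A, x$tau_a, x$g_E, x$g_I, x$g_A))
  cat(sprintf("  theta: E=%g I=%g A=%g | sigma=%g beta=%g s\n",
              x$theta_E, x$theta_I, x$theta_A, x$sigma, x$beta))
  cat("  J (row = target, col = source):\n")
  print(x$J)
  invisible(x)
}

#' @export
print.spiking_params <- function(x, ...) {
  cat("Spiking network parameters\n")
  cat(sprintf("  N_E=%d N_I=%d N_A=%d | sigma_E=%g sigma_I=%g sigma_A=%g\n",
              x$N_E, x$N_I, x$N_A, x$sigma_E, x$sigma_I, x$sigma_A))
  cat(sprintf("  V: leak E=%g I=%g, reset %g, threshold %g mV;",
              x$V_L_E, x$V_L_I, x$V_r, x$V_th))
  cat(sprintf(" G: leak %g, reset %g, threshold %g\n",
              x$G_L, x$G_r, x$G_th))
  cat(sprintf("  glio targets %.0f%% of E/I, %.0f%% of astrocytes receive\n",
              100 * x$frac_glio_targets, 100 * x$frac_astro_receivers))
  invisible(x)
}
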