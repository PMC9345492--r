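# File formats: plain CSV tables with a header line, plus a JSON sidecar
# (same path with extension .json) carrying the full effective parameters
# and the seed, so every output is reconstructible from its files alone.

params_to_list <- function(params) {
  if (inherits(params, "rate_params")) {
    out <- unclass(params)
    J <- out$J
    out$J <- NULL
    for (x in c("E", "I", "A")) for (y in c("E", "I", "A"))
      out[[paste0("J_", x, y)]] <- unname(J[x, y])
    c(list(model = "rate"), out)
  } else if (inherits(params, "spiking_params")) {
    c(list(model = "spiking"), unclass(params))
  } else stop("unsupported params object")
}

write_sidecar <- function(path, fields) {
  jsonlite::write_json(fields, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

#' Write / read a rate-model trajectory
#'
#' The trajectory goes to a CSV with header `t_ms, r_E, r_I, r_A, a`; the
#' parameters, seed, OU correlation time and sampling step go to a JSON
#' sidecar at `<path>.json`.
#'
#' @param traj a `rate_trajectory` from [simulate_rate()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  write.csv(traj$states[c("t_ms", "r_E", "r_I", "r_A", "a")], path,
            row.names = FALSE, quote = FALSE)
  write_sidecar(path, list(kind = "rate_trajectory",
                           params = params_to_list(traj$params),
                           seed = traj$seed, dt_ms = traj$dt,
                           tau_ou_ms = traj$tau_ou))
  invisible(path)
}

#' @rdname write_trajectory
#' @return For `read_trajectory`, a `rate_trajectory` (without noise
#'   states).
#' @export
read_trajectory <- function(path) {
  states <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pl <- side$params
  pl$model <- NULL
  params <- do.call(rate_params, pl)
  structure(list(states = states, dt = side$dt_ms, params = params,
                 seed = side$seed, tau_ou = side$tau_ou_ms),
            class = "rate_trajectory")
}

#' Write / read a spike raster
#'
#' Three-column CSV (`population`, `cell`, `t_ms`) plus a JSON sidecar
#' with the parameters, seed and a connectivity summary (contact counts).
#'
#' @param sim a `ud_spiking_sim`, or a bare raster data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_raster <- function(sim, path) {
  raster <- if (inherits(sim, "ud_spiking_sim")) sim$raster else sim
  write.csv(raster, path, row.names = FALSE, quote = FALSE)
  side <- list(kind = "spike_raster")
  if (inherits(sim, "ud_spiking_sim")) {
    side$params <- params_to_list(sim$params)
    side$seed <- sim$seed
    side$duration_ms <- sim$duration
    side$connectivity <- list(
      n_glio_E = sum(sim$connectivity$glio_E),
      n_glio_I = sum(sim$connectivity$glio_I),
      n_recv_A = sum(sim$connectivity$recv_A))
  }
  write_sidecar(path, side)
  invisible(path)
}

#' @rdname write_raster
#' @return For `read_raster`, the raster data.frame with the sidecar
#'   attached as attribute `"sidecar"` (when present).
#' @export
read_raster <- function(path) {
  raster <- read.csv(path, stringsAsFactors = FALSE)
  sc <- paste0(path, ".json")
  if (file.exists(sc))
    attr(raster, "sidecar") <- jsonlite::read_json(sc,
                                                   simplifyVector = TRUE)
  raster
}

#' Write a phase segmentation and its statistics
#'
#' Interval table as CSV (`label`, `start_ms`, `end_ms`, `duration_ms`,
#' `retained`); the duration statistics as JSON.
#'
#' @param seg a `ud_segmentation`.
#' @param path output CSV path (stats go to `<path>.stats.json`).
#' @return `path`, invisibly.
#' @export
write_segmentation <- function(seg, path) {
  write.csv(as.data.frame(seg), path, row.names = FALSE, quote = FALSE)
  st <- phase_statistics(seg)
  js <- lapply(st, function(x)
    list(count = x$count, mean_ms = x$mean_ms, sd_ms = x$sd_ms,
         cv = x$cv))
  jsonlite::write_json(js, paste0(path, ".stats.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a run configuration
#'
#' Reads a YAML run configuration with fields `model` ("rate" or
#' "spiking"), `params` (named overrides using the canonical parameter
#' names, e.g. `theta_A: -3.5` or `J_EA: 22`), `duration_s`, `dt_ms`,
#' `seed` and the flags `no_astro` and `J_AI_zero`.  Unknown parameter
#' names and invalid values (e.g. non-positive time constants) are
#' rejected with an error naming the offending key.
#'
#' @param path YAML file path.
#' @return A `ud_run_config`: list with the validated fields and a built
#'   `params` object with all overrides and flags applied.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  known <- c("model", "params", "duration_s", "dt_ms", "seed", "no_astro",
             "J_AI_zero")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  model <- if (is.null(cfg$model)) "rate" else cfg$model
  if (!model %in% c("rate", "spiking"))
    stop("config model must be 'rate' or 'spiking'")
  overrides <- if (is.null(cfg$params)) list() else cfg$params
  params <- if (model == "rate") do.call(rate_params, overrides)
            else do.call(spiking_params, overrides)
  if (isTRUE(cfg$no_astro)) params <- without_astro(params)
  if (isTRUE(cfg$J_AI_zero)) {
    if (model == "rate") params$J["A", "I"] <- 0 else params$J_AI <- 0
  }
  structure(list(model = model, params = params,
                 duration_s = cfg$duration_s, dt_ms = cfg$dt_ms,
                 seed = cfg$seed, no_astro = isTRUE(cfg$no_astro),
                 J_AI_zero = isTRUE(cfg$J_AI_zero)),
            class = "ud_run_config")
}

# run manifest: everything needed to reproduce an output file
write_manifest <- function(path, command, params, seed, extra = list()) {
  fields <- c(list(
    package = "astroud",
    version = as.character(utils::packageVersion("astroud")),
    command = command,
    seed = seed,
    params = params_to_list(params)), extra)
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
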