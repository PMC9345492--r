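# Population-rate estimation and automatic Up/Down phase segmentation.
#
# The pipeline is: raster -> sliding-window mean population rate (10 ms
# window, 1 ms step) -> running-median smoothing (+/- 50 points) ->
# threshold crossing at 1.0 Hz (upward crossing opens an Up phase,
# downward crossing a Down phase).  The first and last phases of a
# simulation are systematically discarded from the statistics.

#' Population rate series from a spike raster
#'
#' Computes the mean population firing rate per neuron from a raster, by
#' counting spikes of all neurons (excitatory and inhibitory; astrocyte
#' release events are excluded) inside a sliding window
#' `[t - window/2, t + window/2)`.
#'
#' @param raster data.frame with columns `population` ("E", "I" or "A"),
#'   `cell`, `t_ms`, as produced by [simulate_spiking()].
#' @param n_neurons number of neurons the rate is normalized by (E + I
#'   count).
#' @param duration analyzed span (ms); defaults to the last spike time.
#' @param window sliding window length (ms).
#' @param step sampling step of the output series (ms).
#' @return A `ud_rate_series`: list with `values` (Hz per neuron), `step`
#'   (ms), `t0` and `provenance`.
#' @export
raster_to_rate <- function(raster, n_neurons, duration = NULL, window = 10,
                           step = 1) {
  if (window <= 0) stop("window must be > 0")
  keep <- raster$population %in% c("E", "I")
  times <- sort(raster$t_ms[keep])
  if (is.null(duration))
    duration <- if (length(times)) max(times) else 0
  tt <- seq(0, duration, by = step)
  # count in [t - w/2, t + w/2): findInterval on the sorted times
  lo <- findInterval(tt - window / 2, times, left.open = TRUE)
  hi <- findInterval(tt + window / 2, times, left.open = TRUE)
  counts <- hi - lo
  values <- counts / (window / 1000) / n_neurons
  structure(list(values = values, step = step, t0 = 0,
                 provenance = sprintf("raster window=%g ms", window)),
            class = "ud_rate_series")
}

#' Rate series from a rate-model trajectory
#'
#' Extracts the excitatory rate `r_E` of a [simulate_rate()] trajectory as
#' a `ud_rate_series`, so that the same smoothing/segmentation pipeline
#' applies to rate-model and spiking-network simulations.
#'
#' @param traj a `rate_trajectory`.
#' @return A `ud_rate_series` sampled at the trajectory's recording step.
#' @export
trajectory_rate_series <- function(traj) {
  structure(list(values = traj$states$r_E, step = traj$dt,
                 t0 = traj$states$t_ms[1], provenance = "rate model r_E"),
            class = "ud_rate_series")
}

#' Running-median smoothing
#'
#' Replaces each sample by the median over a window of +/- `half_width`
#' points around it; at the series boundaries the window is truncated
#' (no padding), so no data are fabricated at the edges.  The operation is
#' idempotent on constant series and removes isolated single-point spikes.
#'
#' @param series a `ud_rate_series` (or plain numeric vector).
#' @param half_width half window size in points (default 50).
#' @return The smoothed series, same class and sampling as the input.
#' @export
median_smooth <- function(series, half_width = 50) {
  if (half_width < 0) stop("half_width must be >= 0")
  x <- if (inherits(series, "ud_rate_series")) series$values else series
  n <- length(x)
  if (half_width == 0 || n <= 1) {
    sm <- x
  } else {
    k <- 2 * half_width + 1
    if (n >= k) {
      sm <- as.numeric(stats::runmed(x, k, endrule = "keep"))
      edge <- seq_len(half_width)
      for (i in edge) sm[i] <- median(x[seq_len(i + half_width)])
      for (i in n - edge + 1) sm[i] <- median(x[(i - half_width):n])
    } else {
      sm <- vapply(seq_len(n), function(i)
        median(x[max(1, i - half_width):min(n, i + half_width)]),
        numeric(1))
    }
  }
  if (inherits(series, "ud_rate_series")) {
    series$values <- sm
    series
  } else sm
}

#' Threshold segmentation into Up and Down phases
#'
#' Splits a (smoothed) rate series into alternating Up and Down intervals:
#' samples at or above `threshold` belong to an Up phase, samples below it
#' to a Down phase (upward crossing of the threshold opens an Up phase,
#' downward crossing a Down phase).  The first and last phases touch the
#' simulation boundaries, so their durations are censored; they are kept in
#' the interval table but flagged `retained = FALSE` and excluded from the
#' statistics.
#'
#' The function does not smooth: apply [median_smooth()] first.
#'
#' @param series a `ud_rate_series`.
#' @param threshold rate threshold (Hz), default 1.0.
#' @return A `ud_segmentation`: data.frame with columns `label` ("Up" /
#'   "Down"), `start_ms`, `end_ms`, `duration_ms`, `retained`, plus
#'   attributes `threshold` and `step`.
#' @export
segment_phases <- function(series, threshold = 1) {
  stopifnot(inherits(series, "ud_rate_series"))
  up <- series$values >= threshold
  r <- rle(up)
  n_runs <- length(r$lengths)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  step <- series$step
  t0 <- series$t0
  out <- data.frame(
    label = ifelse(r$values, "Up", "Down"),
    start_ms = t0 + (starts - 1) * step,
    end_ms = t0 + ends * step,
    stringsAsFactors = FALSE)
  out$duration_ms <- out$end_ms - out$start_ms
  out$retained <- rep(TRUE, n_runs)
  if (n_runs >= 1) out$retained[c(1, n_runs)] <- FALSE
  structure(out, threshold = threshold, step = step,
            class = c("ud_segmentation", "data.frame"))
}

#' Duration statistics of segmented Up and Down phases
#'
#' Per-label count, mean, standard deviation (population convention,
#' divisor n), coefficient of variation and a duration histogram over the
#' retained phases of one or several segmentations.
#'
#' @param seg a `ud_segmentation`, or a list of them (durations are pooled
#'   across simulations).
#' @param bin_width histogram bin width (ms).
#' @return A `ud_phase_stats`: list with one element per label ("Up",
#'   "Down"), each holding `count`, `mean_ms`, `sd_ms`, `cv`, `durations`
#'   and `histogram` (counts per bin).  Labels with no retained phase get
#'   `count = 0` and `NA` statistics.
#' @examples
#' # two phases of 500 and 1500 ms -> mean 1000, sd 500, CV 0.5
#' @export
phase_statistics <- function(seg, bin_width = 100) {
  segs <- if (inherits(seg, "ud_segmentation")) list(seg) else seg
  all <- do.call(rbind, lapply(segs, function(s)
    as.data.frame(s)[s$retained, c("label", "duration_ms")]))
  out <- lapply(c(Up = "Up", Down = "Down"), function(lb) {
    d <- all$duration_ms[all$label == lb]
    if (!length(d))
      return(list(count = 0L, mean_ms = NA_real_, sd_ms = NA_real_,
                  cv = NA_real_, durations = numeric(0),
                  histogram = NULL))
    m <- mean(d)
    s <- sqrt(mean((d - m)^2))   # population sd
    breaks <- seq(0, (max(d) %/% bin_width + 1) * bin_width, by = bin_width)
    h <- table(cut(d, breaks, right = FALSE))
    list(count = length(d), mean_ms = m, sd_ms = s, cv = s / m,
         durations = d, histogram = h)
  })
  structure(out, class = "ud_phase_stats")
}

#' @export
print.ud_phase_stats <- function(x, ...) {
  cat("Up/Down phase duration statistics (retained phases only)\n")
  for (lb in c("Up", "Down")) {
    st <- x[[lb]]
    if (st$count == 0) {
      cat(sprintf("  %-4s: no retained phases\n", lb))
    } else {
      cat(sprintf("  %-4s: n=%d  mean=%.0f ms  sd=%.0f ms  CV=%.2f\n",
                  lb, st$count, st$mean_ms, st$sd_ms, st$cv))
    }
  }
  invisible(x)
}

# Segment a rate-model trajectory end to end (smooth + threshold).
#' Segment a rate-model trajectory
#'
#' Convenience wrapper: extracts `r_E`, applies [median_smooth()] and
#' [segment_phases()].
#'
#' @param traj a `rate_trajectory`.
#' @param half_width smoothing half window (points).
#' @param threshold segmentation threshold (Hz).
#' @return A `ud_segmentation`.
#' @export
segment_trajectory <- function(traj, half_width = 50, threshold = 1) {
  segment_phases(median_smooth(trajectory_rate_series(traj), half_width),
                 threshold)
}
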