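# Synthetic fixtures with known ground truth, used by the test-suite and
# available from the command line for end-to-end checks of the
# segmentation pipeline.

#' Generate a synthetic fixture with known ground truth
#'
#' Three fixture kinds:
#' \describe{
#'   \item{`"square_wave"`}{a rate trace alternating between `high_hz`
#'     (for `duty * period_ms`) and 0 Hz; truth = the exact phase
#'     boundaries.}
#'   \item{`"poisson_raster"`}{`n_cells` independent homogeneous Poisson
#'     spike trains at `rate_hz` for `duration_ms`; truth = the generating
#'     rate.}
#'   \item{`"single_event"`}{a raster holding exactly one event.}
#' }
#'
#' @param kind fixture kind (see above).
#' @param seed integer seed (used by the Poisson fixture).
#' @param period_ms,duty,high_hz,n_cycles,step square-wave parameters.
#' @param rate_hz,n_cells,duration_ms Poisson-raster parameters.
#' @param population,cell,t_ms single-event parameters.
#' @param dir if non-NULL, write the data (CSV) and the ground truth
#'   (JSON) into this directory.
#' @return A list with `kind`, the data (`series` or `raster`), `truth`
#'   and, when written, the file `paths`.
#' @export
generate_fixture <- function(kind = c("square_wave", "poisson_raster",
                                      "single_event"),
                             seed = 1,
                             period_ms = 2000, duty = 0.5, high_hz = 5,
                             n_cycles = 10, step = 1,
                             rate_hz = 3, n_cells = 100,
                             duration_ms = 10000,
                             population = "E", cell = 1, t_ms = 100,
                             dir = NULL) {
  kind <- match.arg(kind)
  out <- switch(kind,
    square_wave = {
      high_len <- round(period_ms * duty / step)
      low_len <- round(period_ms * (1 - duty) / step)
      one <- c(rep(high_hz, high_len), rep(0, low_len))
      values <- rep(one, n_cycles)
      series <- structure(list(values = values, step = step, t0 = 0,
                               provenance = "square-wave fixture"),
                          class = "ud_rate_series")
      cyc <- (seq_len(n_cycles) - 1) * (high_len + low_len) * step
      truth <- data.frame(
        label = rep(c("Up", "Down"), n_cycles),
        start_ms = as.numeric(rbind(cyc, cyc + high_len * step)),
        end_ms = as.numeric(rbind(cyc + high_len * step,
                                  cyc + (high_len + low_len) * step)))
      truth$duration_ms <- truth$end_ms - truth$start_ms
      list(kind = kind, series = series, truth = truth)
    },
    poisson_raster = {
      set.seed(seed)
      counts <- stats::rpois(n_cells, rate_hz * duration_ms / 1000)
      raster <- data.frame(
        population = rep(population, sum(counts)),
        cell = rep(seq_len(n_cells), counts),
        t_ms = runif(sum(counts), 0, duration_ms))
      raster <- raster[order(raster$t_ms), ]
      rownames(raster) <- NULL
      list(kind = kind, raster = raster,
           truth = list(rate_hz = rate_hz, n_cells = n_cells,
                        duration_ms = duration_ms,
                        expected_spikes = rate_hz * n_cells *
                          duration_ms / 1000))
    },
    single_event = {
      raster <- data.frame(population = population, cell = cell,
                           t_ms = t_ms)
      list(kind = kind, raster = raster,
           truth = list(population = population, cell = cell,
                        t_ms = t_ms))
    })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    data_path <- file.path(dir, paste0(kind, ".csv"))
    if (kind == "square_wave") {
      df <- data.frame(
        t_ms = out$series$t0 +
          (seq_along(out$series$values) - 1) * out$series$step,
        rate_hz = out$series$values)
      write.csv(df, data_path, row.names = FALSE, quote = FALSE)
    } else {
      write.csv(out$raster, data_path, row.names = FALSE, quote = FALSE)
    }
    truth_path <- file.path(dir, paste0(kind, ".truth.json"))
    jsonlite::write_json(out$truth, truth_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out$paths <- c(data = data_path, truth = truth_path)
  }
  out
}
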