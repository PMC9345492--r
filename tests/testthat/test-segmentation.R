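test_that("raster-to-rate counting matches a direct oracle", {
  set.seed(3)
  raster <- data.frame(
    population = sample(c("E", "I", "A"), 500, replace = TRUE),
    cell = sample.int(20, 500, replace = TRUE),
    t_ms = runif(500, 0, 1000))
  rs <- raster_to_rate(raster, n_neurons = 20, duration = 1000)
  tt <- seq(0, 1000, by = 1)
  neuron_times <- raster$t_ms[raster$population %in% c("E", "I")]
  for (i in c(1, 7, 250, 600, 1001)) {
    cnt <- oracle_window_count(neuron_times, tt[i], 10)
    expect_equal(rs$values[i], cnt / (10 / 1000) / 20)
  }
  # astrocyte events never contribute
  rs2 <- raster_to_rate(raster[raster$population != "A", ], 20,
                        duration = 1000)
  expect_equal(rs$values, rs2$values)
  # empty raster: an all-zero series, not an error
  empty <- raster[0, ]
  expect_true(all(raster_to_rate(empty, 20, duration = 100)$values == 0))
})

test_that("a homogeneous Poisson raster recovers its generating rate", {
  fx <- generate_fixture("poisson_raster", seed = 5, rate_hz = 3,
                         n_cells = 100, duration_ms = 10000)
  rs <- raster_to_rate(fx$raster, n_neurons = 100, duration = 10000)
  se <- sqrt(3 * 100 * 10) / (100 * 10)   # Poisson SE of the mean rate
  expect_lt(abs(mean(rs$values) - 3), 4 * se + 0.05)
})

test_that("running-median smoothing matches the brute-force oracle", {
  set.seed(9)
  for (n in c(30, 101, 400)) {
    x <- rpois(n, 2) + rnorm(n, 0, 0.1)
    for (hw in c(3, 50)) {
      sm <- median_smooth(x, half_width = hw)
      expect_equal(sm, oracle_running_median(x, hw))
    }
  }
  # constants are invariant; an isolated spike is removed entirely
  expect_equal(median_smooth(rep(2, 300)), rep(2, 300))
  z <- numeric(300); z[150] <- 10
  expect_equal(median_smooth(z), numeric(300))
  # smoothing is idempotent on an already-median-filtered square wave
  sq <- rep(c(0, 5), each = 200)
  expect_equal(median_smooth(median_smooth(sq)), median_smooth(sq))
})

test_that("a step edge moves by at most one sample under smoothing", {
  sq <- rep(c(0, 5), each = 300)
  sm <- median_smooth(sq)
  edge <- which(diff(sm >= 1) != 0)
  expect_equal(edge, 300)
})

test_that("threshold segmentation recovers square-wave ground truth", {
  fx <- generate_fixture("square_wave", period_ms = 2000, duty = 0.5,
                         high_hz = 5, n_cycles = 10)
  seg <- segment_phases(median_smooth(fx$series), threshold = 1)
  kept <- seg[seg$retained, ]
  expect_true(all(abs(kept$duration_ms[kept$label == "Up"] - 1000) <= 1))
  expect_true(all(abs(kept$duration_ms[kept$label == "Down"] - 1000) <= 1))
  # first and last phases flagged out
  expect_false(seg$retained[1])
  expect_false(seg$retained[nrow(seg)])
})

test_that("100 randomized square waves are recovered within one step", {
  set.seed(11)
  for (k in 1:100) {
    period <- sample(400:3000, 1)
    duty <- runif(1, 0.2, 0.8)
    fx <- generate_fixture("square_wave", period_ms = period, duty = duty,
                           high_hz = runif(1, 2, 10), n_cycles = 5)
    seg <- segment_phases(median_smooth(fx$series), threshold = 1)
    kept <- seg[seg$retained, ]
    truth_up <- round(period * duty)
    truth_down <- round(period) - truth_up
    expect_true(all(abs(kept$duration_ms[kept$label == "Up"] -
                          truth_up) <= 1))
    expect_true(all(abs(kept$duration_ms[kept$label == "Down"] -
                          truth_down) <= 1))
  }
})

test_that("phases tile the span exactly and alternate strictly", {
  set.seed(13)
  vals <- pmax(0, rnorm(5000, 1, 1.2))
  series <- structure(list(values = vals, step = 1, t0 = 0,
                           provenance = "test"),
                      class = "ud_rate_series")
  seg <- segment_phases(median_smooth(series))
  expect_equal(sum(seg$duration_ms), 5000)        # tiling, exactly
  expect_equal(seg$start_ms[-1], seg$end_ms[-nrow(seg)])
  expect_true(all(seg$label[-1] != seg$label[-nrow(seg)]))
  # raising the threshold never increases total Up time
  up_time <- function(th) {
    s <- segment_phases(median_smooth(series), threshold = th)
    sum(s$duration_ms[s$label == "Up"])
  }
  ths <- c(0.5, 1, 1.5, 2.5)
  expect_true(all(diff(vapply(ths, up_time, numeric(1))) <= 0))
})

test_that("an all-zero series yields no retained phases", {
  series <- structure(list(values = numeric(1000), step = 1, t0 = 0,
                           provenance = "test"),
                      class = "ud_rate_series")
  st <- phase_statistics(segment_phases(series))
  expect_equal(st$Up$count, 0)
  expect_equal(st$Down$count, 0)
  expect_true(is.na(st$Up$mean_ms))
})

test_that("duration statistics match hand computation", {
  seg <- structure(
    data.frame(label = c("Down", "Up", "Down", "Up", "Down"),
               start_ms = c(0, 100, 600, 2100, 2200),
               end_ms = c(100, 600, 2100, 2200, 2400),
               duration_ms = c(100, 500, 1500, 100, 200),
               retained = c(FALSE, TRUE, TRUE, TRUE, FALSE)),
    class = c("ud_segmentation", "data.frame"), step = 1, threshold = 1)
  st <- phase_statistics(seg)
  expect_equal(st$Up$count, 2)
  expect_equal(st$Up$mean_ms, 300)
  expect_equal(st$Up$sd_ms, 200)            # population convention
  expect_equal(st$Up$cv, 2 / 3)
  expect_equal(st$Down$count, 1)
  expect_equal(st$Down$cv, 0)
  # equal durations: zero CV
  seg3 <- seg
  seg3$duration_ms <- c(1, 1000, 1000, 1000, 1)
  seg3$retained <- c(FALSE, TRUE, TRUE, TRUE, FALSE)
  seg3$label <- c("Down", "Up", "Up", "Up", "Down")
  st3 <- phase_statistics(seg3)
  expect_equal(st3$Up$mean_ms, 1000)
  expect_equal(st3$Up$cv, 0)
})
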