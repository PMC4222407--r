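flat_trace <- function(level = -70, dur = 1000, dt = 0.1)
  ephys_trace(rep(level, dur / dt), dt = dt, amplitude = 0,
              t_on = 100, t_off = dur - 200)

test_that("spike detection counts threshold crossings with a refractory period", {
  expect_length(detect_spikes(flat_trace()), 0)
  # three inserted 80-mV transients
  tr <- flat_trace()
  t <- seq_along(tr$values) * tr$dt
  for (ts in c(200, 400, 600))
    tr$values <- tr$values + 80 * exp(-((t - ts) / 0.8)^2)
  expect_length(detect_spikes(tr), 3)
  st <- detect_spikes(tr)
  expect_equal(st, c(200, 400, 600), tolerance = 2)
  vc <- ephys_trace(rep(0, 100), dt = 0.1, mode = "voltage_clamp")
  expect_error(detect_spikes(vc), "current-clamp")
})

test_that("spike counts agree with an independent dV/dt-based detector", {
  # oracle: spikes as upward crossings of dV/dt >= 40 mV/ms (far above the
  # noise floor of the derivative) with the same 2-ms refractory
  dvdt_detector <- function(tr) {
    v <- tr$values
    dv <- diff(v) / tr$dt
    up <- which(dv[-1] >= 40 & dv[-length(dv)] < 40)
    if (!length(up)) return(0L)
    times <- up * tr$dt
    kept <- times[c(TRUE, diff(times) >= 2)]
    n <- 0L
    last <- -Inf
    for (tt in kept) if (tt - last >= 2) { n <- n + 1L; last <- tt }
    n
  }
  set.seed(42)
  mismatches <- 0L
  for (s in 1:20) {
    fam <- generate_trace_fixture(
      list(rheobase = 100 + 10 * (s %% 5), fi_slope = 60 + 5 * s,
           input_resistance = 90, ahp = 4),
      noise_sd = 0.2, seed = s, amplitudes = seq(0, 300, by = 50),
      post = 1200)
    for (tr in fam$traces) {
      a <- length(detect_spikes(tr, window = c(tr$t_on, tr$t_off)))
      b <- dvdt_detector(tr)
      if (a != b) mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("the F-I fit recovers an exact line and resists saturation", {
  counts <- data.frame(amplitude = c(100, 150, 200, 250),
                       count = c(0, 2, 6, 10))
  ft <- fi_features(counts, duration = 1000)
  expect_equal(ft$fi_slope, 80)
  expect_equal(ft$rheobase, 125)
  # a saturating high-amplitude point is excluded by the selection rule
  sat <- rbind(counts, data.frame(amplitude = 300, count = 10.5))
  ft2 <- fi_features(sat, duration = 1000)
  expect_false(300 %in% ft2$fit_points_used)
  expect_equal(ft2$fi_slope, 80)
  # invariance under re-ordering of the input rows
  shuffled <- counts[c(3, 1, 4, 2), ]
  expect_equal(fi_features(shuffled, duration = 1000)$rheobase, 125)
  expect_error(fi_features(data.frame(amplitude = 100, count = 0),
                           duration = 1000), "suprathreshold")
})

test_that("a leading single-spike shelf is excluded from the linear portion", {
  counts <- data.frame(amplitude = seq(100, 500, by = 50),
                       count = c(0, 1, 1, 6, 9, 12, 15, 18, 21))
  ft <- fi_features(counts, duration = 1000)
  expect_false(150 %in% ft$fit_points_used)
  expect_true(all(c(250, 300) %in% ft$fit_points_used))
})

test_that("input resistance follows Ohm's law on constructed steps", {
  mk <- function(amp, dv) {
    tr <- flat_trace(-70 + dv, dur = 1200)
    tr$amplitude <- amp
    tr$t_on <- 100; tr$t_off <- 1100
    tr
  }
  fam <- trace_family(list(mk(-50, 5), mk(0, 0), mk(50, -5)))
  expect_equal(input_resistance(fam), -100) # -5 mV per +50 pA
  fam2 <- trace_family(list(mk(-50, -5), mk(0, 0), mk(50, 5)))
  expect_equal(input_resistance(fam2), 100)
  # adding a common offset to every trace leaves the slope unchanged
  fam3 <- trace_family(lapply(fam2$traces, function(tr) {
    tr$values <- tr$values + 7.3
    tr
  }))
  expect_equal(input_resistance(fam3), 100)
  # spiking traces are rejected
  spiky <- fam2
  spiky$traces[[3]]$values[5000] <- 20
  spiky$traces[[3]]$values[5001] <- 30
  expect_error(input_resistance(spiky), "spike")
})

test_that("AHP amplitude is the undershoot below the settled tail", {
  dt <- 0.1
  t <- seq(dt, 3000, by = dt)
  base <- rep(-70, length(t))
  tr0 <- ephys_trace(base, dt = dt, amplitude = 300, t_on = 100, t_off = 1100)
  expect_equal(ahp_amplitude(tr0), 0) # monotone relaxation, no undershoot
  x <- pmax(t - 1100, 0) / 100
  under <- -5 * x * exp(1 - x)
  tr5 <- ephys_trace(base + under, dt = dt, amplitude = 300,
                     t_on = 100, t_off = 1100)
  expect_equal(ahp_amplitude(tr5), 5, tolerance = 1e-3)
  short <- ephys_trace(base[t < 1500], dt = dt, amplitude = 300,
                       t_on = 100, t_off = 1100)
  expect_error(ahp_amplitude(short), ">= 1 s")
  no_off <- ephys_trace(base, dt = dt, amplitude = 300, t_on = 100, t_off = 4000)
  expect_error(ahp_amplitude(no_off), "offset")
})

test_that("the third-derivative threshold matches a symbolic oracle", {
  # analytic spike onset: Gaussian depolarization; d3V/dt3 available in
  # closed form through symbolic differentiation
  dt <- 0.02
  t <- seq(dt, 200, by = dt)
  tc <- 100; s <- 1.4; A <- 85; B <- -62
  v <- B + A * exp(-((t - tc) / s)^2)
  tr <- ephys_trace(v, dt = dt, amplitude = 200, t_on = 10, t_off = 190)
  d3_expr <- stats::D(stats::D(stats::D(
    quote(B + A * exp(-((t - tc) / s)^2)), "t"), "t"), "t")
  tg <- seq(tc - 6, tc, by = 1e-4)
  d3 <- eval(d3_expr, list(t = tg, tc = tc, s = s, A = A, B = B))
  peaks <- which(diff(sign(diff(d3))) < 0) + 1
  peaks <- peaks[d3[peaks] > 0]
  t_star <- tg[peaks[1]]
  v_star <- B + A * exp(-((t_star - tc) / s)^2)
  expect_equal(ap_voltage_threshold(tr), v_star, tolerance = 0.2)
  # refinement stability: doubling the sampling rate moves it < 0.2 mV
  t2 <- seq(dt / 2, 200, by = dt / 2)
  v2 <- B + A * exp(-((t2 - tc) / s)^2)
  tr2 <- ephys_trace(v2, dt = dt / 2, amplitude = 200, t_on = 10, t_off = 190)
  expect_lt(abs(ap_voltage_threshold(tr2) - ap_voltage_threshold(tr)), 0.2)
  # coarse sampling is refused
  coarse <- ephys_trace(v[seq(1, length(v), by = 10)], dt = 0.2, amplitude = 200)
  expect_error(ap_voltage_threshold(coarse), "0.1 ms")
})

test_that("features are robust to 0.1-mV measurement noise", {
  targets <- list(rheobase = 125, fi_slope = 80, input_resistance = 100, ahp = 5)
  clean <- generate_trace_fixture(targets, noise_sd = 0)
  noisy <- generate_trace_fixture(targets, noise_sd = 0.1, seed = 7)
  f1 <- fi_features(clean)
  f2 <- fi_features(noisy)
  expect_equal(f2$rheobase, f1$rheobase, tolerance = 0.05)
  expect_equal(f2$fi_slope, f1$fi_slope, tolerance = 0.05)
  expect_equal(input_resistance(noisy), input_resistance(clean), tolerance = 0.02)
})
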