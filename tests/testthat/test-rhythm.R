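# Rhythm analysis against analytic signals.

sin_trace <- function(period = 0.5, amp = 10, mid = -60, dur = 2.05,
                      dt = 0.001) {
  time <- seq(0, dur, by = dt)
  list(time = time, v = mid + amp * sin(2 * pi * time / period))
}

as_trace_set <- function(time, v, name = "X") {
  structure(list(time = time, V = matrix(v, ncol = 1,
                                         dimnames = list(NULL, name))),
            class = "trace_set")
}

test_that("rising crossings of a sinusoid land on the analytic times", {
  s <- sin_trace()
  cr <- find_rising_crossings(s$time, s$v, threshold = -60)
  # sin rises through its midline at 0, 0.5, 1.0, ... (the t = 0 crossing
  # has no preceding sample, so detection starts at 0.5)
  expect_equal(cr, c(0.5, 1.0, 1.5, 2.0), tolerance = 1e-6)
  # interpolation error well below the sample spacing
  expect_true(all(abs(cr - c(0.5, 1.0, 1.5, 2.0)) < 1e-3))
})

test_that("cycle detection reports periods as successive differences", {
  s <- sin_trace(dur = 3.05)
  tr <- as_trace_set(s$time, s$v)
  rep <- detect_cycles(tr, "X", threshold = -60)
  expect_s3_class(rep, "cycle_report")
  expect_equal(rep$periods, diff(rep$crossings))
  expect_equal(rep$mean_period, 0.5, tolerance = 1e-4)
  expect_false(rep$empty)
  # offset invariance: shifting trace and threshold together
  tr2 <- as_trace_set(s$time, s$v + 7.5)
  rep2 <- detect_cycles(tr2, "X", threshold = -60 + 7.5)
  expect_equal(rep2$crossings, rep$crossings)
  # a flat trace yields an empty, flagged report
  flat <- detect_cycles(as_trace_set(s$time, rep(-65, length(s$time))), "X")
  expect_true(flat$empty)
  expect_length(flat$crossings, 0)
})

test_that("noisy sinusoid with refractory guard keeps the true period", {
  set.seed(7)
  s <- sin_trace(dur = 5.05)
  v <- s$v + rnorm(length(s$v), sd = 0.5)
  cr <- find_rising_crossings(s$time, v, threshold = -60,
                              refractory = 0.001, hysteresis = 2)
  # brute-force oracle: the clean signal's crossings (which start at 0.5;
  # noise legitimately exposes the t = 0 crossing too, so compare past it)
  clean <- find_rising_crossings(s$time, s$v, threshold = -60)
  expect_equal(length(cr[cr > 0.2]), length(clean))
  expect_equal(mean(diff(cr[cr > 0.2])), 0.5, tolerance = 0.005)
})

test_that("windowed period means use only fully contained cycles", {
  crossings <- seq(0.25, 4.75, by = 0.5)
  rep <- structure(list(crossings = crossings, periods = diff(crossings),
                        threshold = -60, empty = FALSE),
                   class = "cycle_report")
  pw <- period_in_window(rep, 1, 2.6)
  expect_equal(pw$mean, 0.5)
  expect_equal(pw$n, 2)  # 3 crossings inside define 2 full periods
  # alternating 0.4/0.6 periods average to 0.5
  alt <- cumsum(c(0.2, rep(c(0.4, 0.6), 5)))
  rep2 <- structure(list(crossings = alt, periods = diff(alt)),
                    class = "cycle_report")
  expect_equal(period_in_window(rep2, 0, 10)$mean, 0.5)
  # insufficient crossings flagged through n
  expect_equal(period_in_window(rep, 0.3, 0.4)$n, 0)
  expect_true(is.na(period_in_window(rep, 0.3, 0.4)$mean))
})

test_that("phase shift classification behaves on constructed trains", {
  ref <- seq(0.5, 6, by = 0.5)
  # identity: zero shift, non-resetting
  id <- phase_shift(ref, ref, window = c(2, 2.1))
  expect_equal(id$steady_shift, 0)
  expect_equal(id$classification, "non-resetting")
  # persistent half-period offset after the window: resetting at 0.5
  tst <- c(ref[ref <= 2.1], ref[ref > 2.1] + 0.25)
  hp <- phase_shift(ref, tst, window = c(2, 2.1))
  expect_equal(hp$steady_shift, 0.5, tolerance = 1e-6)
  expect_equal(hp$classification, "resetting")
  # a full-cycle slip wraps to zero (memory semantics)
  slip <- c(ref[ref <= 2.1], ref[ref > 2.6])
  expect_equal(phase_shift(ref, slip, c(2, 2.1))$steady_shift, 0,
               tolerance = 1e-6)
  # no post-window crossings -> deletion ongoing
  del <- phase_shift(ref, ref[ref <= 2], c(2, 2.1))
  expect_true(del$deletion_ongoing)
  # monotone in tolerance: lowering tolerance never converts
  # resetting -> non-resetting
  for (tol in c(0.01, 0.05, 0.2, 0.45)) {
    a <- phase_shift(ref, tst, c(2, 2.1), tolerance = tol)
    b <- phase_shift(ref, tst, c(2, 2.1), tolerance = tol / 2)
    expect_false(a$classification == "resetting" &&
                 b$classification == "non-resetting")
  }
})

test_that("burst bounds recover a square wave's duty cycle and gaps", {
  dt <- 0.001
  time <- seq(0, 4.9, by = dt)  # ends between bursts
  period <- 0.5; duty <- 0.4
  up <- (time %% period) < duty * period
  v <- ifelse(up, -40, -70)
  tr <- as_trace_set(time, v)
  bb <- burst_bounds(tr, "X", threshold = -60)
  expect_equal(nrow(bb), 9)
  expect_equal(median(bb$duration), duty * period, tolerance = 2 * dt)
  expect_equal(median(attr(bb, "gaps")), period, tolerance = 2 * dt)
  expect_false(any(attr(bb, "deletion_gaps")))
  # knock one burst out -> its gap is flagged as a deletion
  v2 <- v
  v2[time >= 2.0 & time < 2.5] <- -70
  bb2 <- burst_bounds(tr <- as_trace_set(time, v2), "X", threshold = -60)
  expect_equal(nrow(bb2), 8)
  expect_equal(sum(attr(bb2, "deletion_gaps")), 1)
  # burst count equals rising-crossing count at the same threshold
  expect_equal(nrow(bb2),
               length(find_rising_crossings(time, v2, -60, refractory = 0)))
})
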