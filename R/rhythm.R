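# Rhythm analysis: threshold-crossing cycle detection, windowed period
# statistics, phase-shift measurement against a reference run, and
# burst/deletion bookkeeping on motoneuron traces.

#' Rising threshold crossings of a sampled voltage trace
#'
#' The derivative condition (crossing with dV/dt > 0) is implemented as
#' "previous sample below threshold, current sample at or above", with the
#' crossing time located by linear interpolation between the bracketing
#' samples.  A refractory guard suppresses double counts from noise.
#'
#' @param time sample times, s
#' @param v voltages, mV
#' @param threshold crossing threshold, mV (default -60)
#' @param refractory minimum spacing between accepted crossings, s
#' @param hysteresis re-arming depth, mV: after a crossing the signal must
#'   fall below `threshold - hysteresis` before the next crossing counts.
#'   Suppresses spurious crossings riding on noise near the threshold.
#' @return numeric vector of crossing times, s (possibly empty)
#' @export
find_rising_crossings <- function(time, v, threshold = -60,
                                  refractory = 0.010, hysteresis = 0.5) {
  stopifnot(length(time) == length(v), length(time) >= 2L)
  below <- v[-length(v)] < threshold
  above <- v[-1] >= threshold
  idx <- which(below & above)
  if (!length(idx)) return(numeric(0))
  frac <- (threshold - v[idx]) / (v[idx + 1L] - v[idx])
  times <- time[idx] + frac * (time[idx + 1L] - time[idx])
  if (hysteresis > 0 && length(idx) > 1L) {
    # state machine: a crossing only counts once the signal has re-armed
    # by dipping below threshold - hysteresis since the previous crossing
    armed <- cumsum(v < threshold - hysteresis)
    keep <- logical(length(idx))
    keep[1] <- TRUE
    last <- idx[1]
    for (j in seq_along(idx)[-1]) {
      if (armed[idx[j]] > armed[last]) {
        keep[j] <- TRUE
        last <- idx[j]
      }
    }
    times <- times[keep]
  }
  if (length(times) > 1L && refractory > 0) {
    keep <- times[1]
    for (t in times[-1]) if (t - keep[length(keep)] >= refractory)
      keep <- c(keep, t)
    times <- keep
  }
  times
}

#' Detect locomotor cycles on one neuron's voltage trace
#'
#' Each new cycle begins when the voltage crosses `threshold` while rising
#' (the convention used for the extensor pattern formation neuron at
#' -60 mV).  Periods are successive differences of the crossing times.
#'
#' @param trace a `trace_set` from [run_simulation()]
#' @param neuron neuron name (column of the trace)
#' @param threshold crossing threshold, mV
#' @param refractory minimum crossing spacing, s
#' @param t_min ignore samples before this time, s (e.g. the startup
#'   transient); defaults to the trace start
#' @return an object of class `cycle_report`: crossing times, per-cycle
#'   periods, their mean/sd, and the threshold used.  Zero crossings give
#'   an empty, flagged report.
#' @export
detect_cycles <- function(trace, neuron, threshold = -60, refractory = 0.010,
                          t_min = NULL) {
  stopifnot(inherits(trace, "trace_set"))
  if (!(neuron %in% colnames(trace$V)))
    stop("detect_cycles: no neuron named '", neuron, "' in trace")
  keep <- if (is.null(t_min)) TRUE else trace$time >= t_min
  crossings <- find_rising_crossings(trace$time[keep], trace$V[keep, neuron],
                                     threshold, refractory)
  periods <- diff(crossings)
  structure(list(neuron = neuron, crossings = crossings, periods = periods,
                 mean_period = if (length(periods)) mean(periods) else NA_real_,
                 sd_period = if (length(periods) > 1) stats::sd(periods) else NA_real_,
                 threshold = threshold, refractory = refractory,
                 empty = length(crossings) == 0L),
            class = "cycle_report")
}

#' @export
print.cycle_report <- function(x, ...) {
  cat("<cycle_report> ", x$neuron, ": ", length(x$crossings),
      " crossings at ", x$threshold, " mV", sep = "")
  if (length(x$periods))
    cat(sprintf("; period %.4f +/- %.4f s", x$mean_period,
                ifelse(is.na(x$sd_period), 0, x$sd_period)))
  if (x$empty) cat("  [no crossings]")
  cat("\n")
  invisible(x)
}

#' Mean cycle period within a time window
#'
#' Averages the periods whose two defining crossings both lie inside
#' `[t_start, t_end]`.
#'
#' @param report a `cycle_report`
#' @param t_start,t_end window, s
#' @return list with `mean` (s), `n` (number of periods used) and the
#'   per-cycle `periods`; `mean` is `NA` (flagged via `n < 1`) when fewer
#'   than two crossings fall inside the window
#' @export
period_in_window <- function(report, t_start, t_end) {
  stopifnot(inherits(report, "cycle_report"), t_start < t_end)
  cr <- report$crossings
  inside <- cr >= t_start & cr <= t_end
  use <- which(inside[-length(cr)] & inside[-1])
  periods <- diff(cr)[use]
  list(mean = if (length(periods)) mean(periods) else NA_real_,
       n = length(periods), periods = periods)
}

.wrap_phase <- function(frac) {
  d <- frac %% 1
  pmin(d, 1 - d)
}

#' Phase shift and resetting classification against a reference run
#'
#' Compares the crossing train of a perturbed run with that of a reference
#' run sharing every setting except the perturbation.  The reference clock
#' (its mean pre-window period) predicts where post-window crossings should
#' fall; the shift is the circular distance between predicted and observed
#' crossings in fractions of a period, so a whole-cycle slip counts as
#' zero.  The steady-state shift (mean over the last `n_steady` observed
#' crossings) classifies the perturbation: non-resetting iff the shift is
#' below `tolerance`.
#'
#' @param reference,test crossing-time vectors (s) or `cycle_report`s
#' @param window perturbation window `c(t_on, t_off)`, s
#' @param tolerance classification threshold, fraction of a period
#' @param n_steady number of trailing crossings averaged for the
#'   steady-state shift
#' @return an object of class `reset_report`: predicted and observed
#'   post-window crossings, per-crossing and steady-state phase shift,
#'   classification, and a `deletion_ongoing` flag when the test run has no
#'   post-window crossings
#' @export
phase_shift <- function(reference, test, window, tolerance = 0.05,
                        n_steady = 3L) {
  ref <- if (inherits(reference, "cycle_report")) reference$crossings else reference
  tst <- if (inherits(test, "cycle_report")) test$crossings else test
  stopifnot(length(window) == 2L, window[1] < window[2])
  pre <- ref[ref <= window[1]]
  # reference clock rate: mean pre-window period, falling back to the
  # post-window reference train when the window opens too early to bracket
  # two crossings
  period <- if (length(pre) >= 2L) mean(diff(pre))
            else if (length(ref) >= 2L) mean(diff(ref))
            else stop("phase_shift: need at least two reference crossings")
  post_ref <- ref[ref > window[2]]
  post_tst <- tst[tst > window[2]]
  if (!length(post_tst) || !length(post_ref)) {
    return(structure(list(period = period, predicted = post_ref,
                          observed = post_tst, shifts = numeric(0),
                          steady_shift = NA_real_,
                          classification = NA_character_,
                          deletion_ongoing = TRUE, tolerance = tolerance),
                     class = "reset_report"))
  }
  # predicted clock: reference crossings themselves (the unperturbed run),
  # extended by the pre-window mean period if the test train outlasts it
  predicted <- post_ref
  while (max(post_tst) > max(predicted) + period)
    predicted <- c(predicted, max(predicted) + period)
  shifts <- vapply(post_tst, function(t)
    .wrap_phase((t - predicted[which.min(abs(predicted - t))]) / period),
    numeric(1))
  use <- utils::tail(shifts, n_steady)
  steady <- mean(use)
  structure(list(period = period, predicted = predicted, observed = post_tst,
                 shifts = shifts, steady_shift = steady,
                 classification = if (steady < tolerance) "non-resetting"
                                  else "resetting",
                 deletion_ongoing = FALSE, tolerance = tolerance),
            class = "reset_report")
}

#' @export
print.reset_report <- function(x, ...) {
  cat("<reset_report> period ", sprintf("%.4f", x$period), " s; ", sep = "")
  if (x$deletion_ongoing) {
    cat("deletion ongoing (no post-window crossings)\n")
  } else {
    cat(sprintf("steady-state shift %.3f of a period -> %s (tolerance %g)\n",
                x$steady_shift, x$classification, x$tolerance))
  }
  invisible(x)
}

#' Burst bounds of a motoneuron trace
#'
#' Intervals where the voltage sits at or above `threshold`, with onset and
#' offset located by linear interpolation.  Gaps between successive burst
#' onsets longer than 1.5x the median onset-to-onset interval are flagged
#' as deletions.
#'
#' @param trace a `trace_set`
#' @param neuron neuron name
#' @param threshold burst threshold, mV
#' @param t_min ignore samples before this time, s
#' @return data.frame with columns `onset`, `offset`, `duration` (s) and
#'   attributes `gaps` (onset-to-onset intervals) and `deletion_gaps`
#'   (logical, gap > 1.5x median)
#' @export
burst_bounds <- function(trace, neuron, threshold = -60, t_min = NULL) {
  stopifnot(inherits(trace, "trace_set"))
  keep <- if (is.null(t_min)) rep(TRUE, length(trace$time))
          else trace$time >= t_min
  time <- trace$time[keep]
  v <- trace$V[keep, neuron]
  on <- find_rising_crossings(time, v, threshold, refractory = 0,
                              hysteresis = 0)
  # falling crossings by symmetry
  off <- find_rising_crossings(time, -v, -threshold, refractory = 0,
                               hysteresis = 0)
  if (!length(on)) {
    out <- data.frame(onset = numeric(0), offset = numeric(0),
                      duration = numeric(0))
    attr(out, "gaps") <- numeric(0)
    attr(out, "deletion_gaps") <- logical(0)
    attr(out, "empty") <- TRUE
    return(out)
  }
  bursts <- lapply(on, function(t0) {
    t1 <- off[off > t0]
    c(t0, if (length(t1)) t1[1] else NA_real_)
  })
  bm <- do.call(rbind, bursts)
  # a burst still open at the end of the trace has no offset; drop it
  bm <- bm[!is.na(bm[, 2]), , drop = FALSE]
  out <- data.frame(onset = bm[, 1], offset = bm[, 2],
                    duration = bm[, 2] - bm[, 1])
  gaps <- diff(out$onset)
  attr(out, "gaps") <- gaps
  attr(out, "deletion_gaps") <-
    if (length(gaps)) gaps > 1.5 * median(gaps) else logical(0)
  attr(out, "empty") <- FALSE
  out
}
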