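# Canned, parameterised experiments at the neural level: descending-drive
# period modulation, pattern-formation "memory" stimuli, and deletion
# (resetting vs non-resetting) protocols.  Reference and perturbed runs
# inside one experiment share configuration and seed; only the stimuli
# differ, so every experiment is reproducible bit-exactly from its
# provenance record.

.experiment_result <- function(kind, traces, cycles = NULL,
                               epoch_table = NULL, reset = NULL,
                               bursts = NULL, extra = list(),
                               provenance = list()) {
  structure(c(list(kind = kind, traces = traces, cycles = cycles,
                   epoch_table = epoch_table, reset = reset,
                   bursts = bursts, provenance = provenance), extra),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("<experiment_result> ", x$kind, "\n", sep = "")
  if (!is.null(x$epoch_table)) {
    cat("  epoch periods (s):\n")
    print(x$epoch_table, row.names = FALSE)
  }
  if (!is.null(x$reset)) for (nm in names(x$reset)) {
    cat("  ", nm, ": ", sep = "")
    print(x$reset[[nm]])
  }
  invisible(x)
}

.pf_ext_name <- function(network, side) {
  p <- .side_prefix(side)
  cand <- paste(p, c("hip_PF_EXT", "kneeankle_PF_EXT"), sep = "_")
  hit <- cand[cand %in% neuron_names(network)]
  if (!length(hit)) stop("network has no pattern formation extensor neuron")
  hit[1]
}

.rg_names <- function(network, side) {
  p <- .side_prefix(side)
  nm <- paste(p, "limb_RG", c("EXT", "FLX"), sep = "_")
  if (!all(nm %in% neuron_names(network)))
    stop("network lacks the rhythm generator pair ",
         paste(nm, collapse = ", "))
  nm
}

#' Descending-drive (MLR) period modulation experiment
#'
#' Applies the startup kick, then an excitatory pulse (`+amplitude`, 1.5 to
#' 2.5 s) and an inhibitory pulse (`-amplitude`, 3.5 to 4.5 s) to BOTH
#' rhythm generator neurons simultaneously, emulating tonic drive from the
#' midbrain locomotor region.  Cycle periods of the pattern formation
#' extensor (and flexor) are tabulated per epoch: baseline, excited,
#' recovery, inhibited, final.
#'
#' @param network a deafferented two-layer network
#'   ([build_two_layer_cpg()])
#' @param config a [simulation_config()]; duration should cover 5.5 s
#' @param amplitude drive magnitude, nA
#' @param threshold cycle-detection threshold, mV
#' @return an `experiment_result` with `epoch_table` (one row per epoch and
#'   neuron: mean period, n cycles, per-cycle periods in
#'   `attr(, "per_cycle")`)
#' @export
mlr_drive_experiment <- function(network = build_two_layer_cpg(),
                                 config = simulation_config(duration = 5.5,
                                                            record_every = 10L),
                                 amplitude = 2, threshold = -60) {
  side <- network$metadata$side %||% "left"
  rg <- .rg_names(network, side)
  stimuli <- list(
    startup_kick(network, side),
    stimulus_protocol(rg[1], amplitude, 1.5, 2.5),
    stimulus_protocol(rg[2], amplitude, 1.5, 2.5),
    stimulus_protocol(rg[1], -amplitude, 3.5, 4.5),
    stimulus_protocol(rg[2], -amplitude, 3.5, 4.5))
  trace <- run_simulation(network, stimuli, config = config)
  blank <- config$startup_transient_blank
  p <- .side_prefix(side)
  neurons <- c(ext = .pf_ext_name(network, side))
  neurons["flx"] <- sub("PF_EXT", "PF_FLX", neurons[["ext"]])
  cycles <- lapply(neurons, function(nm)
    detect_cycles(trace, nm, threshold, t_min = blank))
  epochs <- data.frame(
    epoch = c("baseline", "excited", "recovery", "inhibited", "final"),
    t_start = c(blank, 1.5, 2.5, 3.5, 4.5),
    t_end = c(1.5, 2.5, 3.5, 4.5, config$duration))
  rows <- list()
  per_cycle <- list()
  for (nm in names(cycles)) for (i in seq_len(nrow(epochs))) {
    pw <- period_in_window(cycles[[nm]], epochs$t_start[i], epochs$t_end[i])
    rows[[length(rows) + 1L]] <- data.frame(
      neuron = nm, epoch = epochs$epoch[i], t_start = epochs$t_start[i],
      t_end = epochs$t_end[i], mean_period = pw$mean, n = pw$n)
    per_cycle[[paste(nm, epochs$epoch[i], sep = ".")]] <- pw$periods
  }
  tab <- do.call(rbind, rows)
  attr(tab, "per_cycle") <- per_cycle
  .experiment_result("mlr_drive", list(main = trace), cycles = cycles,
                     epoch_table = tab,
                     provenance = list(amplitude = amplitude,
                                       threshold = threshold,
                                       stimuli = lapply(stimuli, unclass),
                                       config = unclass(config)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# extensor/flexor phase durations of the cycle containing time t0
.cycle_phases <- function(trace, neuron, t0, threshold) {
  cr <- find_rising_crossings(trace$time, trace$V[, neuron], threshold)
  if (!any(cr <= t0)) return(NULL)
  k <- max(which(cr <= t0))
  if (k >= length(cr)) return(NULL)
  fall <- find_rising_crossings(trace$time, -trace$V[, neuron], -threshold,
                                refractory = 0)
  off <- fall[fall > cr[k]]
  if (!length(off)) return(NULL)
  list(onset = cr[k], next_onset = cr[k + 1], ext = off[1] - cr[k],
       flx = cr[k + 1] - off[1])
}

#' Pattern-formation "memory" experiment
#'
#' Three runs sharing every setting: an unstimulated reference, a short
#' (0.1 s, shorter than one cycle) and a long (1 s, longer than one cycle)
#' excitatory stimulus to the pattern formation extensor neuron.  The
#' short stimulus should reshape only the ongoing cycle (extensor portion
#' shortened, flexor prolonged) leaving following onsets on the reference
#' clock; the long stimulus should delete motoneuron bursts that reappear
#' on the expected step timing (non-resetting).
#'
#' @param network a deafferented two-layer network
#' @param config a [simulation_config()]
#' @param amplitude stimulus current, nA
#' @param short_window,long_window stimulus windows, s
#' @param threshold cycle/burst threshold, mV
#' @return an `experiment_result`; `reset$short`/`reset$long` are
#'   [phase_shift()] reports, `bursts` holds motoneuron burst tables, and
#'   `phases` the ongoing-cycle extensor/flexor durations (test vs
#'   reference)
#' @export
pf_memory_experiment <- function(network = build_two_layer_cpg(),
                                 config = simulation_config(duration = 5,
                                                            record_every = 10L),
                                 amplitude = 2, short_window = c(1, 1.1),
                                 long_window = c(2.5, 3.5),
                                 threshold = -60) {
  side <- network$metadata$side %||% "left"
  pf_ext <- .pf_ext_name(network, side)
  mn_ext <- sub("PF_EXT", "MN_EXT", pf_ext)
  kick <- startup_kick(network, side)
  ref <- run_simulation(network, list(kick), config = config)
  short <- run_simulation(network, list(kick,
    stimulus_protocol(pf_ext, amplitude, short_window[1], short_window[2])),
    config = config)
  long <- run_simulation(network, list(kick,
    stimulus_protocol(pf_ext, amplitude, long_window[1], long_window[2])),
    config = config)
  blank <- config$startup_transient_blank
  cyc <- lapply(list(ref = ref, short = short, long = long), function(tr)
    detect_cycles(tr, pf_ext, threshold, t_min = blank))
  reset <- list(
    short = phase_shift(cyc$ref, cyc$short, short_window),
    long = phase_shift(cyc$ref, cyc$long, long_window))
  bursts <- list(
    ref = burst_bounds(ref, mn_ext, threshold, t_min = blank),
    long = burst_bounds(long, mn_ext, threshold, t_min = blank))
  # the ongoing cycle is the one the stimulus acts on; index it just past
  # the window end so it is found whether the window opened inside the
  # cycle or a few ms before its onset crossing
  t0 <- short_window[2] + 0.02
  phases <- list(
    ref = .cycle_phases(ref, pf_ext, t0, threshold),
    short = .cycle_phases(short, pf_ext, t0, threshold))
  # expected motoneuron burst onsets (from the reference) with no matching
  # onset in the long-stimulus run: deleted bursts
  T0 <- reset$long$period
  expected <- bursts$ref$onset[bursts$ref$onset > long_window[1] &
                               bursts$ref$onset < long_window[2]]
  observed <- bursts$long$onset
  deleted <- vapply(expected, function(t)
    !any(abs(observed - t) < 0.25 * T0), logical(1))
  .experiment_result("pf_memory",
                     list(ref = ref, short = short, long = long),
                     cycles = cyc, reset = reset, bursts = bursts,
                     extra = list(phases = phases,
                                  deleted_bursts = sum(deleted),
                                  expected_bursts = length(expected)),
                     provenance = list(amplitude = amplitude,
                                       short_window = short_window,
                                       long_window = long_window,
                                       threshold = threshold,
                                       config = unclass(config)))
}

#' Deletion experiment: inhibit the pattern formation or rhythm generator
#'
#' Applies a tonic inhibitory stimulus (default -10 nA from 2 to 2.1 s) to
#' the hip pattern formation extensor (`layer = "PF"`) or the rhythm
#' generator extensor (`layer = "RG"`) of a limb network, against a
#' reference run differing only in the stimulus.  Pattern formation
#' deletions leave the rhythm generator clock untouched (non-resetting);
#' rhythm generator inhibition permanently shifts the rhythm (resetting).
#'
#' @param network a limb network ([build_limb()]) or two-layer chain
#' @param layer "PF" or "RG"
#' @param side "left" or "right"
#' @param amplitude stimulus current, nA (negative = inhibitory)
#' @param window stimulus window, s
#' @param config a [simulation_config()]
#' @param threshold cycle/burst threshold, mV
#' @param plant optional [limb_plant()] used for BOTH runs (closed loop)
#' @return an `experiment_result` with `reset$deletion` and motoneuron
#'   burst tables
#' @export
deletion_experiment <- function(network = build_limb(),
                                layer = c("PF", "RG"), side = "left",
                                amplitude = -10, window = c(2, 2.1),
                                config = simulation_config(duration = 5,
                                                           record_every = 10L),
                                threshold = -60, plant = NULL) {
  layer <- match.arg(layer)
  side <- match.arg(side, c("left", "right"))
  p <- .side_prefix(side)
  target <- if (layer == "PF") .pf_ext_name(network, side)
            else paste(p, "limb_RG_EXT", sep = "_")
  if (!(target %in% neuron_names(network)))
    stop("deletion_experiment: no target neuron ", target)
  kick <- startup_kick(network, side)
  ref <- run_simulation(network, list(kick), config = config, plant = plant)
  tst <- run_simulation(network, list(kick,
    stimulus_protocol(target, amplitude, window[1], window[2])),
    config = config, plant = plant)
  blank <- config$startup_transient_blank
  pf_ext <- .pf_ext_name(network, side)
  mn_ext <- sub("PF_EXT", "MN_EXT", pf_ext)
  cyc <- list(ref = detect_cycles(ref, pf_ext, threshold, t_min = blank),
              test = detect_cycles(tst, pf_ext, threshold, t_min = blank))
  reset <- list(deletion = phase_shift(cyc$ref, cyc$test, window))
  bursts <- list(ref = burst_bounds(ref, mn_ext, threshold, t_min = blank),
                 test = burst_bounds(tst, mn_ext, threshold, t_min = blank))
  .experiment_result("deletion", list(ref = ref, test = tst), cycles = cyc,
                     reset = reset, bursts = bursts,
                     extra = list(target = target, layer = layer),
                     provenance = list(amplitude = amplitude,
                                       window = window,
                                       threshold = threshold,
                                       config = unclass(config),
                                       closed_loop = !is.null(plant)))
}
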