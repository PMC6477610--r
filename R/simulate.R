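# Forward simulation: flattens a network_spec into arrays, integrates it
# with the compiled fixed-step kernel, and wraps the result as a trace_set.
# Time conventions: user-facing times (durations, stimulus edges, trace
# grids) are in seconds; the timestep dt is in milliseconds.

#' Simulation settings
#'
#' @param dt timestep, ms; the default 0.01 ms keeps the calibrated
#'   network's voltages dt-refinement-stable to better than 0.1 mV
#' @param duration total simulated time, s
#' @param integrator "exponential_euler" (default) or "rk4"
#' @param record_gates record m/h gating traces alongside voltages
#' @param startup_transient_blank initial interval, s, that analysis
#'   routines treat as startup transient (recorded but excluded by the
#'   canned experiments)
#' @param record_every record every k-th step (1 = every step)
#' @return an object of class `simulation_config`
#' @export
simulation_config <- function(dt = 0.01, duration = 5,
                              integrator = c("exponential_euler", "rk4"),
                              record_gates = TRUE,
                              startup_transient_blank = 0.5,
                              record_every = 1L) {
  integrator <- match.arg(integrator)
  stopifnot(dt > 0, duration > 0, startup_transient_blank >= 0,
            record_every >= 1)
  structure(list(dt = dt, duration = duration, integrator = integrator,
                 record_gates = record_gates,
                 startup_transient_blank = startup_transient_blank,
                 record_every = as.integer(record_every)),
            class = "simulation_config")
}

#' A square current-pulse stimulus
#'
#' @param target neuron name
#' @param amplitude current, nA (signed)
#' @param t_on,t_off pulse window, s; `t_on < t_off`.  Edges are aligned to
#'   the step grid by flooring `t_on` and ceiling `t_off`.
#' @return an object of class `stimulus_protocol`
#' @export
stimulus_protocol <- function(target, amplitude, t_on, t_off) {
  stopifnot(is.character(target), length(target) == 1L,
            is.numeric(amplitude), t_on < t_off, t_on >= 0)
  structure(list(target = target, amplitude = amplitude,
                 t_on = t_on, t_off = t_off),
            class = "stimulus_protocol")
}

#' Tonic white-noise current injection
#'
#' Gaussian current noise drawn per step and scaled by `1/sqrt(dt)` so its
#' integrated variance is timestep-invariant.
#'
#' @param targets neuron names receiving independent noise
#' @param sd noise intensity, nA sqrt(ms)
#' @param seed integer seed; recorded in trace provenance
#' @return an object of class `noise_spec`
#' @export
noise_spec <- function(targets, sd, seed) {
  stopifnot(is.character(targets), sd >= 0, is.numeric(seed))
  structure(list(targets = targets, sd = sd, seed = as.integer(seed)),
            class = "noise_spec")
}

#' The symmetry-breaking startup kick
#'
#' A tonic 2 nA current of 0.5 s duration into the extensor neuron of the
#' chosen side's rhythm generator at simulation start.  A bilaterally
#' symmetric network started from rest stays symmetric forever; this kick
#' breaks the symmetry so alternation can develop.
#'
#' @param network a `network_spec`
#' @param side "left" or "right"
#' @param amplitude current, nA
#' @param duration kick duration, s
#' @return a [stimulus_protocol()]
#' @export
startup_kick <- function(network, side = "left", amplitude = 2,
                         duration = 0.5) {
  p <- .side_prefix(match.arg(side, c("left", "right")))
  target <- paste(p, "limb", "RG", "EXT", sep = "_")
  if (!(target %in% neuron_names(network)))
    stop("startup_kick: network has no rhythm-generator extensor named ",
         target)
  stimulus_protocol(target, amplitude, 0, duration)
}

#' Resting initial state of a network
#'
#' Every neuron at its resting potential with gates at their steady-state
#' values for `E_rest` (zero for passive cells).
#'
#' @param network a `network_spec`
#' @return data.frame with columns `name`, `V`, `m`, `h`
#' @export
initial_state <- function(network) {
  stopifnot(inherits(network, "network_spec"))
  rows <- lapply(network$neurons, function(n) {
    p <- n$params
    if (p$G_Na > 0)
      data.frame(name = n$name, V = p$E_rest,
                 m = gating_steady_state(p$E_rest, p$m_gate),
                 h = gating_steady_state(p$E_rest, p$h_gate))
    else data.frame(name = n$name, V = p$E_rest, m = 0, h = 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# flatten a network_spec into the arrays the compiled kernel consumes
.as_sim_arrays <- function(network, init) {
  nn <- network$neurons
  n <- length(nn)
  num <- function(f) vapply(nn, f, numeric(1))
  gnum <- function(which, f, default) vapply(nn, function(x) {
    g <- x$params[[which]]
    if (is.null(g)) default else f(g)
  }, numeric(1))
  neurons <- list(
    C = num(function(x) x$params$C),
    G_leak = num(function(x) x$params$G_leak),
    E_rest = num(function(x) x$params$E_rest),
    G_Na = num(function(x) x$params$G_Na),
    E_Na = num(function(x) x$params$E_Na),
    m_A = gnum("m_gate", function(g) g$A, 0),
    m_S = gnum("m_gate", function(g) g$S, 0),
    m_E = gnum("m_gate", function(g) g$E_half, 0),
    m_tau = gnum("m_gate", function(g) g$tau, 1),
    h_A = gnum("h_gate", function(g) g$A, 0),
    h_S = gnum("h_gate", function(g) g$S, 0),
    h_E = gnum("h_gate", function(g) g$E_half, 0),
    h_tau = gnum("h_gate", function(g) g$tau, 1),
    V0 = init$V, m0 = init$m, h0 = init$h)
  idx <- setNames(seq_len(n) - 1L, names(nn))
  ns <- length(network$synapses)
  synapses <- list(
    pre = vapply(network$synapses, function(s) idx[[s$pre]], integer(1)),
    post = vapply(network$synapses, function(s) idx[[s$post]], integer(1)),
    g_max = vapply(network$synapses, function(s) s$params$g_max, numeric(1)),
    E_syn = vapply(network$synapses, function(s) s$params$E_syn, numeric(1)),
    E_lo = vapply(network$synapses, function(s) s$params$E_lo, numeric(1)),
    E_hi = vapply(network$synapses, function(s) s$params$E_hi, numeric(1)))
  if (ns == 0L)
    synapses <- list(pre = integer(0), post = integer(0), g_max = numeric(0),
                     E_syn = numeric(0), E_lo = numeric(0), E_hi = numeric(0))
  list(neurons = neurons, synapses = synapses, index = idx)
}

#' Integrate a network forward in time
#'
#' Runs the compiled fixed-step integrator (exponential Euler by default,
#' classical RK4 for verification) under a list of stimulus protocols and
#' optional tonic noise.  Deterministic given the seed.  Gates are clamped
#' to `[0, 1]` against sub-1e-9 numerical overshoot; larger gate
#' excursions, non-finite voltages or voltages beyond +/-500 mV abort with
#' the offending neuron and time.
#'
#' @param network a `network_spec`
#' @param stimuli list of [stimulus_protocol()]s (a single protocol is
#'   also accepted)
#' @param noise optional [noise_spec()]
#' @param config a [simulation_config()]
#' @param init optional initial state as from [initial_state()]
#' @param plant optional closed-loop plant from [limb_plant()]; when
#'   supplied, afferent currents computed from the plant state are injected
#'   into their routed target neurons each step
#' @return a `trace_set`: list with `time` (s), voltage matrix `V`
#'   (samples x neurons, named columns), gate matrices `m`, `h`, plant
#'   trajectory `plant` (when closed-loop) and a `provenance` record
#' @export
run_simulation <- function(network, stimuli = list(), noise = NULL,
                           config = simulation_config(), init = NULL,
                           plant = NULL) {
  stopifnot(inherits(network, "network_spec"),
            inherits(config, "simulation_config"))
  if (inherits(stimuli, "stimulus_protocol")) stimuli <- list(stimuli)
  if (is.null(init)) init <- initial_state(network)
  arr <- .as_sim_arrays(network, init)
  nms <- names(arr$index)
  dt <- config$dt
  n_steps <- as.integer(round(config$duration * 1000 / dt))

  stim <- list(target = integer(0), amplitude = numeric(0),
               on_step = integer(0), off_step = integer(0))
  for (s in stimuli) {
    stopifnot(inherits(s, "stimulus_protocol"))
    if (!(s$target %in% nms))
      stop("stimulus targets unknown neuron: ", s$target)
    stim$target <- c(stim$target, arr$index[[s$target]])
    stim$amplitude <- c(stim$amplitude, s$amplitude)
    # grid alignment: floor the onset, ceil the offset (documented)
    stim$on_step <- c(stim$on_step, as.integer(floor(s$t_on * 1000 / dt + 1e-9)))
    stim$off_step <- c(stim$off_step, as.integer(ceiling(s$t_off * 1000 / dt - 1e-9)))
  }

  nz <- list(target = integer(0), sd = numeric(0))
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_spec"))
    missing <- setdiff(noise$targets, nms)
    if (length(missing))
      stop("noise targets unknown neuron(s): ", paste(missing, collapse = ", "))
    nz$target <- vapply(noise$targets, function(t) arr$index[[t]], integer(1))
    nz$sd <- rep(noise$sd, length(noise$targets))
    set.seed(noise$seed)
  }

  plant_list <- if (is.null(plant)) list() else .plant_arrays(plant, arr$index)

  res <- .sim_run_cpp(arr$neurons, arr$synapses, stim, nz, plant_list,
                      dt, n_steps, config$record_every,
                      if (config$integrator == "rk4") 1L else 0L,
                      config$record_gates)
  if (!res$ok) {
    what <- res$bad_what
    if (what == "plant")
      stop(sprintf("simulation diverged in plant joint %d at t = %.4f s",
                   res$bad_neuron - length(nms), res$bad_time / 1000))
    stop(sprintf("simulation diverged (%s) in neuron '%s' at t = %.4f s",
                 what, nms[res$bad_neuron], res$bad_time / 1000))
  }
  keep <- seq_len(res$n_recorded)
  V <- res$V[keep, , drop = FALSE]
  colnames(V) <- nms
  out <- list(time = res$time[keep] / 1000, V = V)
  if (config$record_gates) {
    m <- res$m[keep, , drop = FALSE]; colnames(m) <- nms
    h <- res$h[keep, , drop = FALSE]; colnames(h) <- nms
    out$m <- m; out$h <- h
  }
  if (!is.null(plant)) {
    pj <- res$plant[keep, , drop = FALSE]
    cn <- as.vector(vapply(plant$joints, function(j)
      paste(j$label, c("angle", "velocity", "act_ext", "act_flx"), sep = "."),
      character(4)))
    colnames(pj) <- cn
    out$plant <- pj
  }
  out$provenance <- list(
    config = unclass(config),
    stimuli = lapply(stimuli, unclass),
    noise = if (is.null(noise)) NULL else unclass(noise),
    plant = if (is.null(plant)) NULL else plant$label,
    network = network$metadata,
    n_neurons = length(nms))
  class(out) <- "trace_set"
  out
}

#' Final network state of a simulation
#'
#' Extracts the last recorded sample of a trace as an initial-state table,
#' so a run can continue from (or restart at) a settled state.
#'
#' @param trace a `trace_set` recorded with `record_gates = TRUE`
#' @return data.frame with columns `name`, `V`, `m`, `h`
#' @export
final_state <- function(trace) {
  stopifnot(inherits(trace, "trace_set"), !is.null(trace$m))
  n <- nrow(trace$V)
  data.frame(name = colnames(trace$V), V = trace$V[n, ],
             m = trace$m[n, ], h = trace$h[n, ], row.names = NULL)
}

#' @export
print.trace_set <- function(x, ...) {
  cat("<trace_set> ", ncol(x$V), " neurons x ", nrow(x$V), " samples, ",
      "t in [", format(x$time[1]), ", ", format(x$time[length(x$time)]),
      "] s\n", sep = "")
  cat("  neurons:", paste(utils::head(colnames(x$V), 6), collapse = ", "),
      if (ncol(x$V) > 6) "...", "\n")
  invisible(x)
}

# ---- trace I/O -------------------------------------------------------------

#' Export a trace set
#'
#' `format = "tsv"` writes delimited text: a commented header carrying the
#' unit declarations and the JSON-encoded provenance record, then one row
#' per time sample with one column per recorded variable.  `format = "rds"`
#' writes a binary container that round-trips bit-exactly (for long runs).
#'
#' @param trace a `trace_set`
#' @param path output path
#' @param format "tsv" or "rds"
#' @return `path`, invisibly
#' @export
export_traces <- function(trace, path, format = c("tsv", "rds")) {
  format <- match.arg(format)
  stopifnot(inherits(trace, "trace_set"))
  if (nrow(trace$V) == 0L || ncol(trace$V) == 0L)
    stop("export_traces: refusing to write an empty trace_set")
  if (format == "rds") {
    saveRDS(trace, path)
    return(invisible(path))
  }
  df <- data.frame(time = trace$time, trace$V, check.names = FALSE)
  colnames(df) <- c("time_s", paste0("V.", colnames(trace$V)))
  if (!is.null(trace$m)) {
    gdf <- data.frame(trace$m, trace$h, check.names = FALSE)
    colnames(gdf) <- c(paste0("m.", colnames(trace$m)),
                       paste0("h.", colnames(trace$h)))
    df <- cbind(df, gdf)
  }
  if (!is.null(trace$plant))
    df <- cbind(df, as.data.frame(trace$plant, check.names = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# snscpg trace export",
    "# units: time_s = s; V.* = mV; m.*/h.* = fraction; *.angle = rad; *.velocity = rad/s; *.act_* = fraction",
    paste0("# provenance: ",
           jsonlite::toJSON(trace$provenance, auto_unbox = TRUE, digits = NA,
                            null = "null"))), con)
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trace set written by [export_traces()]
#'
#' @param path path to a `.tsv` or `.rds` trace file
#' @return a `trace_set` (text reloads reproduce voltages to better than
#'   1e-6 mV; binary reloads are bit-identical)
#' @export
read_traces <- function(path) {
  if (grepl("\\.rds$", path)) return(readRDS(path))
  lines <- readLines(path, n = 10L)
  prov_line <- grep("^# provenance: ", lines, value = TRUE)
  prov <- if (length(prov_line))
    jsonlite::fromJSON(sub("^# provenance: ", "", prov_line[1]),
                       simplifyVector = FALSE)
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE)
  pick <- function(prefix) {
    cols <- grep(paste0("^", prefix, "\\."), colnames(df), value = TRUE)
    if (!length(cols)) return(NULL)
    m <- as.matrix(df[cols])
    colnames(m) <- sub(paste0("^", prefix, "\\."), "", cols)
    m
  }
  out <- list(time = df$time_s, V = pick("V"), m = pick("m"), h = pick("h"),
              provenance = prov)
  pl <- grep("\\.(angle|velocity|act_ext|act_flx)$", colnames(df),
             value = TRUE)
  if (length(pl)) out$plant <- as.matrix(df[pl])
  out[vapply(out, is.null, logical(1))] <- NULL
  class(out) <- "trace_set"
  out
}
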