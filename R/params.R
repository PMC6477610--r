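# Parameter tables: named neuron and synapse parameter classes consumed by
# the network builders.  Tables ship as editable YAML under inst/extdata so
# the defaults are reviewable and version-controlled; a "tuning delta"
# overlay file can patch individual values without touching the base table.

.required_units <- list(voltage = "mV", time = "ms", current = "nA",
                        conductance = "uS", capacitance = "nF")

.neuron_keys  <- c("C", "G_leak", "E_rest", "G_Na", "E_Na", "m", "h")
.gate_keys    <- c("A", "S", "E", "tau")
.synapse_keys <- c("g_max", "E_syn", "E_lo", "E_hi")

.parse_neuron_row <- function(row, name) {
  unknown <- setdiff(names(row), .neuron_keys)
  if (length(unknown))
    stop(sprintf("parameter table: neuron '%s' has unknown column(s): %s",
                 name, paste(unknown, collapse = ", ")))
  need <- c("C", "G_leak", "E_rest", "G_Na", "E_Na")
  miss <- setdiff(need, names(row))
  if (length(miss))
    stop(sprintf("parameter table: neuron '%s' is missing column(s): %s",
                 name, paste(miss, collapse = ", ")))
  gate <- function(g, which) {
    if (is.null(g))
      stop(sprintf("parameter table: neuron '%s' has G_Na > 0 but no %s gate",
                   name, which))
    unknown <- setdiff(names(g), .gate_keys)
    miss <- setdiff(.gate_keys, names(g))
    if (length(unknown) || length(miss))
      stop(sprintf(
        "parameter table: neuron '%s' gate '%s': missing [%s], unknown [%s]",
        name, which, paste(miss, collapse = ", "),
        paste(unknown, collapse = ", ")))
    gating_params(A = g$A, S = g$S, E_half = g$E, tau = g$tau)
  }
  if (row$G_Na > 0)
    neuron_params(C = row$C, G_leak = row$G_leak, E_rest = row$E_rest,
                  G_Na = row$G_Na, E_Na = row$E_Na,
                  m_gate = gate(row$m, "m"), h_gate = gate(row$h, "h"))
  else
    neuron_params(C = row$C, G_leak = row$G_leak, E_rest = row$E_rest)
}

.parse_synapse_row <- function(row, name) {
  unknown <- setdiff(names(row), .synapse_keys)
  miss <- setdiff(.synapse_keys, names(row))
  if (length(unknown) || length(miss))
    stop(sprintf(
      "parameter table: synapse '%s': missing [%s], unknown [%s]",
      name, paste(miss, collapse = ", "), paste(unknown, collapse = ", ")))
  synapse_params(g_max = row$g_max, E_syn = row$E_syn,
                 E_lo = row$E_lo, E_hi = row$E_hi)
}

.deep_merge <- function(base, patch) {
  for (k in names(patch)) {
    if (is.list(patch[[k]]) && is.list(base[[k]]))
      base[[k]] <- .deep_merge(base[[k]], patch[[k]])
    else
      base[[k]] <- patch[[k]]
  }
  base
}

#' Load a neuron/synapse parameter table
#'
#' Reads a YAML parameter table declaring the fixed unit system
#' (mV / ms / nA / uS / nF), named neuron parameter classes and named
#' synapse parameter classes.  Unknown or missing columns are rejected with
#' the offending row and column named.  An optional overlay file (same
#' schema, any subset of keys) is deep-merged over the base table before
#' validation, so tuning deltas live apart from the base transcription.
#'
#' @param path path to the YAML table
#' @param overlay optional path to an overlay YAML file
#' @return an object of class `parameter_table` with elements `neurons`
#'   (named list of [neuron_params()]), `synapses` (named list of
#'   [synapse_params()]) and `units`
#' @export
load_parameter_table <- function(path, overlay = NULL) {
  if (!file.exists(path)) stop("parameter table not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.null(overlay)) {
    if (!file.exists(overlay)) stop("overlay file not found: ", overlay)
    raw <- .deep_merge(raw, yaml::read_yaml(overlay))
  }
  if (is.null(raw$units))
    stop("parameter table: missing 'units' block")
  for (u in names(.required_units)) {
    if (!identical(raw$units[[u]], .required_units[[u]]))
      stop(sprintf("parameter table: units$%s must be '%s'",
                   u, .required_units[[u]]))
  }
  neurons <- lapply(seq_along(raw$neurons), function(i)
    .parse_neuron_row(raw$neurons[[i]], names(raw$neurons)[i]))
  names(neurons) <- names(raw$neurons)
  synapses <- lapply(seq_along(raw$synapses), function(i)
    .parse_synapse_row(raw$synapses[[i]], names(raw$synapses)[i]))
  names(synapses) <- names(raw$synapses)
  structure(list(neurons = neurons, synapses = synapses,
                 units = .required_units, source = path),
            class = "parameter_table")
}

#' Packaged default parameter table
#'
#' Loads the parameter table shipped with the package.  The defaults are a
#' synthetic transcription: they were calibrated so the assembled networks
#' reproduce the published behaviours of the modelled circuits (0.5 s
#' baseline stride period, period modulation to roughly 0.35 s / 0.65 s
#' under +/-2 nA descending drive, non-resetting pattern-formation
#' deletions and resetting rhythm-generator deletions); see the package
#' vignette for the calibration account.
#'
#' @param overlay optional path to a tuning overlay YAML file
#' @return a `parameter_table`
#' @export
default_parameter_table <- function(overlay = NULL) {
  load_parameter_table(
    system.file("extdata", "default_params.yaml", package = "snscpg",
                mustWork = TRUE),
    overlay = overlay)
}

#' Write a parameter table back to YAML
#'
#' Inverse of [load_parameter_table()]; save -> load round-trips.
#'
#' @param table a `parameter_table`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_parameter_table <- function(table, path) {
  stopifnot(inherits(table, "parameter_table"))
  as_row <- function(p) {
    row <- list(C = p$C, G_leak = p$G_leak, E_rest = p$E_rest,
                G_Na = p$G_Na, E_Na = p$E_Na)
    if (p$G_Na > 0) {
      row$m <- list(A = p$m_gate$A, S = p$m_gate$S, E = p$m_gate$E_half,
                    tau = p$m_gate$tau)
      row$h <- list(A = p$h_gate$A, S = p$h_gate$S, E = p$h_gate$E_half,
                    tau = p$h_gate$tau)
    } else {
      row$G_Na <- 0; row$E_Na <- p$E_Na
    }
    row
  }
  out <- list(units = table$units,
              neurons = lapply(table$neurons, as_row),
              synapses = lapply(table$synapses, function(s)
                list(g_max = s$g_max, E_syn = s$E_syn,
                     E_lo = s$E_lo, E_hi = s$E_hi)))
  writeLines(yaml::as.yaml(out, precision = 15L), path)
  invisible(path)
}

#' @export
print.parameter_table <- function(x, ...) {
  cat("<parameter_table> ", length(x$neurons), " neuron classes, ",
      length(x$synapses), " synapse classes\n", sep = "")
  cat("  neurons: ", paste(names(x$neurons), collapse = ", "), "\n", sep = "")
  cat("  synapses:", paste(names(x$synapses), collapse = ", "), "\n")
  invisible(x)
}
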