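# Network specifications and builders for the locomotor circuit hierarchy:
# a four-neuron half-center rhythm generator (RG), pattern formation (PF)
# half-center groups -- the knee and ankle share one PF group -- and a
# motoneuron/Renshaw output layer.  Naming convention for unambiguous
# stimulus targeting: SIDE_JOINT_ROLE_POLARITY, e.g. "L_hip_PF_EXT".

.roles      <- c("RG", "PF", "MN", "IN", "RE")
.sides      <- c("left", "right", "none")
.joints     <- c("hip", "knee", "ankle", "kneeankle", "limb", "none")
.polarities <- c("EXT", "FLX", "none")

.side_prefix <- function(side) c(left = "L", right = "R", none = "X")[[side]]

#' Declare one named neuron in a network
#'
#' @param name unique identifier within the network
#' @param role one of RG, PF, MN, IN, RE
#' @param side one of left, right, none
#' @param joint one of hip, knee, ankle, kneeankle, limb, none
#' @param polarity one of EXT, FLX, none
#' @param params a [neuron_params()]
#' @return an object of class `neuron_spec`
#' @export
neuron_spec <- function(name, role, side = "none", joint = "none",
                        polarity = "none", params) {
  role <- match.arg(role, .roles)
  side <- match.arg(side, .sides)
  joint <- match.arg(joint, .joints)
  polarity <- match.arg(polarity, .polarities)
  stopifnot(is.character(name), nzchar(name), inherits(params, "neuron_params"))
  structure(list(name = name, role = role, side = side, joint = joint,
                 polarity = polarity, params = params),
            class = "neuron_spec")
}

#' Declare one directed synapse in a network
#'
#' The sign is inferred from the reversal potential when not given:
#' inhibitory iff `E_syn` lies below the postsynaptic operating range
#' (below -60 mV here).
#'
#' @param pre,post neuron names (must differ)
#' @param params a [synapse_params()]
#' @param sign "excitatory" or "inhibitory"; inferred from `E_syn` if `NULL`
#' @return an object of class `synapse_spec`
#' @export
synapse_spec <- function(pre, post, params, sign = NULL) {
  stopifnot(is.character(pre), is.character(post),
            inherits(params, "synapse_params"))
  if (identical(pre, post)) stop("synapse_spec: pre and post must differ")
  inferred <- if (params$E_syn < -60) "inhibitory" else "excitatory"
  if (is.null(sign)) sign <- inferred
  sign <- match.arg(sign, c("excitatory", "inhibitory"))
  structure(list(pre = pre, post = post, params = params, sign = sign),
            class = "synapse_spec")
}

#' Assemble a network specification
#'
#' @param neurons list of [neuron_spec()]s
#' @param synapses list of [synapse_spec()]s
#' @param metadata free-form list of labels
#' @return an object of class `network_spec`
#' @export
network_spec <- function(neurons, synapses = list(), metadata = list()) {
  nm <- vapply(neurons, function(n) n$name, character(1))
  if (anyDuplicated(nm))
    stop("network_spec: duplicate neuron name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  names(neurons) <- nm
  for (s in synapses) {
    if (!(s$pre %in% nm))  stop("network_spec: unknown presynaptic neuron: ", s$pre)
    if (!(s$post %in% nm)) stop("network_spec: unknown postsynaptic neuron: ", s$post)
  }
  structure(list(neurons = neurons, synapses = synapses, metadata = metadata),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat("<network_spec> ", length(x$neurons), " neurons, ",
      length(x$synapses), " synapses\n", sep = "")
  roles <- table(vapply(x$neurons, `[[`, character(1), "role"))
  cat("  roles: ", paste(names(roles), roles, sep = ":", collapse = "  "),
      "\n", sep = "")
  if (length(x$metadata$kind))
    cat("  kind:  ", x$metadata$kind, "\n", sep = "")
  invisible(x)
}

#' Neuron names of a network
#' @param network a `network_spec`
#' @return character vector of neuron names
#' @export
neuron_names <- function(network) {
  stopifnot(inherits(network, "network_spec"))
  names(network$neurons)
}

#' Merge disjoint networks
#'
#' Union of neuron and synapse sets; duplicate neuron names are a
#' composition collision and raise an error.  Inputs are not mutated.
#'
#' @param ... `network_spec` objects
#' @return a combined `network_spec`
#' @export
merge_networks <- function(...) {
  nets <- list(...)
  stopifnot(all(vapply(nets, inherits, logical(1), "network_spec")))
  neurons <- do.call(c, lapply(nets, `[[`, "neurons"))
  synapses <- do.call(c, lapply(nets, `[[`, "synapses"))
  meta <- list(kind = paste(unlist(lapply(nets, function(n) n$metadata$kind)),
                            collapse = "+"),
               omitted = unlist(lapply(nets, function(n) n$metadata$omitted)))
  network_spec(unname(neurons), synapses, metadata = meta)
}

#' Add synapses to an existing network
#' @param network a `network_spec`
#' @param synapses list of [synapse_spec()]s
#' @return a new `network_spec`
#' @export
add_synapses <- function(network, synapses) {
  network_spec(unname(network$neurons), c(network$synapses, synapses),
               network$metadata)
}

# ---- validation ------------------------------------------------------------

#' Validate a network specification
#'
#' Structural diagnostics rather than exceptions: dangling synapse
#' endpoints, duplicate names, synapse sign inconsistent with its reversal
#' potential, persistent sodium on interneuron-class cells (IN/RE), missing
#' sodium on oscillator cells (RG/PF), and half-center pairs that lack a
#' reciprocal inhibitory loop.
#'
#' @param network a `network_spec` (or a raw list in the same shape)
#' @return data.frame with columns `level` ("error"/"warning"), `item`,
#'   `message`; zero rows iff the network is clean
#' @export
validate_network <- function(network) {
  diag <- list()
  note <- function(level, item, message)
    diag[[length(diag) + 1L]] <<- data.frame(level = level, item = item,
                                             message = message)
  nm <- vapply(network$neurons, function(n) n$name, character(1))
  dup <- unique(nm[duplicated(nm)])
  for (d in dup) note("error", d, "duplicate neuron name")
  for (s in network$synapses) {
    for (endp in c(s$pre, s$post))
      if (!(endp %in% nm))
        note("error", endp, "synapse references unknown neuron")
    inferred <- if (s$params$E_syn < -60) "inhibitory" else "excitatory"
    if (!identical(s$sign, inferred))
      note("error", paste0(s$pre, "->", s$post),
           sprintf("sign '%s' inconsistent with E_syn = %g mV",
                   s$sign, s$params$E_syn))
  }
  for (n in network$neurons) {
    if (n$role %in% c("IN", "RE") && n$params$G_Na > 0)
      note("warning", n$name,
           "interneuron-class cell with persistent sodium (G_Na > 0)")
    if (n$role %in% c("RG", "PF") && n$params$G_Na == 0)
      note("warning", n$name, "oscillator cell without persistent sodium")
  }
  # half-center pairs need a reciprocal inhibitory loop (direct or via one
  # interneuron)
  inh_reach <- function(from, to) {
    for (s in network$synapses) {
      if (s$pre == from && s$post == to && s$sign == "inhibitory") return(TRUE)
      if (s$pre == from && s$sign == "excitatory") {
        for (s2 in network$synapses)
          if (s2$pre == s$post && s2$post == to && s2$sign == "inhibitory")
            return(TRUE)
      }
    }
    FALSE
  }
  for (n in network$neurons) {
    if (n$role %in% c("RG", "PF") && n$polarity == "EXT") {
      mate <- sub("_EXT$", "_FLX", n$name)
      if (mate %in% nm) {
        if (!inh_reach(n$name, mate) || !inh_reach(mate, n$name))
          note("warning", paste0(n$name, "/", mate),
               "half-center pair without reciprocal inhibitory loop")
      }
    }
  }
  if (length(diag)) do.call(rbind, diag)
  else data.frame(level = character(), item = character(),
                  message = character())
}

# ---- builders --------------------------------------------------------------

.get_nparam <- function(params, class, where) {
  p <- params$neurons[[class]]
  if (is.null(p))
    stop(sprintf("parameter table has no neuron class '%s' (needed for %s)",
                 class, where))
  p
}

.get_sparam <- function(params, class, where, required = TRUE) {
  p <- params$synapses[[class]]
  if (is.null(p) && required)
    stop(sprintf("parameter table has no synapse class '%s' (needed for %s)",
                 class, where))
  p
}

#' Build the four-neuron half-center rhythm generator
#'
#' Two persistent-sodium half-center neurons coupled by weak mutual
#' excitation and by reciprocal inhibition routed through one passive
#' interneuron per direction.
#'
#' @param side "left" or "right"
#' @param params a `parameter_table`
#' @return a `network_spec` with neurons `<S>_limb_RG_EXT`,
#'   `<S>_limb_RG_FLX`, `<S>_limb_IN_EXT`, `<S>_limb_IN_FLX`
#' @export
build_rhythm_generator <- function(side = "left",
                                   params = default_parameter_table()) {
  side <- match.arg(side, c("left", "right"))
  p <- .side_prefix(side)
  osc <- .get_nparam(params, "RG_osc", "rhythm generator")
  # optional polarity-specific override (extensor-dominant duty cycles)
  osc_flx <- params$neurons[["RG_osc_FLX"]] %||% osc
  inp <- .get_nparam(params, "IN", "rhythm generator")
  nm <- function(role, pol) paste(p, "limb", role, pol, sep = "_")
  neurons <- list(
    neuron_spec(nm("RG", "EXT"), "RG", side, "limb", "EXT", osc),
    neuron_spec(nm("RG", "FLX"), "RG", side, "limb", "FLX", osc_flx),
    neuron_spec(nm("IN", "EXT"), "IN", side, "limb", "EXT", inp),
    neuron_spec(nm("IN", "FLX"), "IN", side, "limb", "FLX", inp))
  mut <- .get_sparam(params, "RG_mutual_excitation", "rhythm generator")
  toin <- .get_sparam(params, "RG_to_IN", "rhythm generator")
  inhib <- .get_sparam(params, "RG_IN_to_RG", "rhythm generator")
  synapses <- list(
    synapse_spec(nm("RG", "EXT"), nm("RG", "FLX"), mut),
    synapse_spec(nm("RG", "FLX"), nm("RG", "EXT"), mut),
    synapse_spec(nm("RG", "EXT"), nm("IN", "EXT"), toin),
    synapse_spec(nm("IN", "EXT"), nm("RG", "FLX"), inhib),
    synapse_spec(nm("RG", "FLX"), nm("IN", "FLX"), toin),
    synapse_spec(nm("IN", "FLX"), nm("RG", "EXT"), inhib))
  network_spec(neurons, synapses,
               metadata = list(kind = "rhythm_generator", side = side))
}

#' Build a pattern formation half-center group
#'
#' A persistent-sodium half-center pair with mutual inhibition via passive
#' interneurons.  The knee and ankle joints share the single group built
#' with `joint = "kneeankle"`.
#'
#' @param joint "hip" or "kneeankle"
#' @param side "left" or "right"
#' @param params a `parameter_table`
#' @return a `network_spec`
#' @export
build_pattern_formation <- function(joint = c("hip", "kneeankle"),
                                    side = "left",
                                    params = default_parameter_table()) {
  joint <- match.arg(joint)
  side <- match.arg(side, c("left", "right"))
  p <- .side_prefix(side)
  osc <- .get_nparam(params, "PF_osc", "pattern formation")
  osc_flx <- params$neurons[["PF_osc_FLX"]] %||% osc
  inp <- .get_nparam(params, "IN", "pattern formation")
  nm <- function(role, pol) paste(p, joint, role, pol, sep = "_")
  neurons <- list(
    neuron_spec(nm("PF", "EXT"), "PF", side, joint, "EXT", osc),
    neuron_spec(nm("PF", "FLX"), "PF", side, joint, "FLX", osc_flx),
    neuron_spec(nm("IN", "EXT"), "IN", side, joint, "EXT", inp),
    neuron_spec(nm("IN", "FLX"), "IN", side, joint, "FLX", inp))
  toin <- .get_sparam(params, "PF_to_IN", "pattern formation")
  inhib <- .get_sparam(params, "PF_IN_to_PF", "pattern formation")
  synapses <- list(
    synapse_spec(nm("PF", "EXT"), nm("IN", "EXT"), toin),
    synapse_spec(nm("IN", "EXT"), nm("PF", "FLX"), inhib),
    synapse_spec(nm("PF", "FLX"), nm("IN", "FLX"), toin),
    synapse_spec(nm("IN", "FLX"), nm("PF", "EXT"), inhib))
  network_spec(neurons, synapses,
               metadata = list(kind = paste0("pattern_formation_", joint),
                               side = side))
}

#' Build a motoneuron/Renshaw output layer for one joint
#'
#' An extensor and a flexor motoneuron, each with a Renshaw cell providing
#' recurrent inhibition (MN excites RE, RE inhibits its MN).  Excitatory
#' drive from a pattern formation group attaches via
#' [connect_pf_to_mn()].
#'
#' @param joint "hip", "knee" or "ankle"
#' @param side "left" or "right"
#' @param params a `parameter_table`
#' @return a `network_spec`
#' @export
build_motoneuron_layer <- function(joint = c("hip", "knee", "ankle"),
                                   side = "left",
                                   params = default_parameter_table()) {
  joint <- match.arg(joint)
  side <- match.arg(side, c("left", "right"))
  p <- .side_prefix(side)
  mn <- .get_nparam(params, "MN", "motoneuron layer")
  re <- .get_nparam(params, "RE", "motoneuron layer")
  nm <- function(role, pol) paste(p, joint, role, pol, sep = "_")
  neurons <- list(
    neuron_spec(nm("MN", "EXT"), "MN", side, joint, "EXT", mn),
    neuron_spec(nm("MN", "FLX"), "MN", side, joint, "FLX", mn),
    neuron_spec(nm("RE", "EXT"), "RE", side, joint, "EXT", re),
    neuron_spec(nm("RE", "FLX"), "RE", side, joint, "FLX", re))
  mnre <- .get_sparam(params, "MN_to_RE", "motoneuron layer")
  remn <- .get_sparam(params, "RE_to_MN", "motoneuron layer")
  synapses <- list(
    synapse_spec(nm("MN", "EXT"), nm("RE", "EXT"), mnre),
    synapse_spec(nm("RE", "EXT"), nm("MN", "EXT"), remn),
    synapse_spec(nm("MN", "FLX"), nm("RE", "FLX"), mnre),
    synapse_spec(nm("RE", "FLX"), nm("MN", "FLX"), remn))
  network_spec(neurons, synapses,
               metadata = list(kind = paste0("motoneurons_", joint),
                               side = side))
}

#' Connect a rhythm generator to a pattern formation group
#'
#' Adds excitatory drive EXT->EXT and FLX->FLX, plus crossed inhibition
#' EXT->FLX / FLX->EXT when the parameter table carries a
#' `RG_cross_inhibit_PF` row; when that row is absent the crossed
#' connection is omitted and recorded in the network metadata.
#'
#' @param network a merged `network_spec` containing both groups
#' @param pf_joint joint label of the pattern formation group
#' @param side "left" or "right"
#' @param params a `parameter_table`
#' @return a new `network_spec` with the drive synapses added
#' @export
connect_rg_to_pf <- function(network, pf_joint, side = "left",
                             params = default_parameter_table()) {
  p <- .side_prefix(match.arg(side, c("left", "right")))
  drv <- .get_sparam(params, "RG_drive_PF", "RG->PF drive")
  crx <- .get_sparam(params, "RG_cross_inhibit_PF", "RG->PF drive",
                     required = FALSE)
  rg <- function(pol) paste(p, "limb", "RG", pol, sep = "_")
  pf <- function(pol) paste(p, pf_joint, "PF", pol, sep = "_")
  syn <- list(synapse_spec(rg("EXT"), pf("EXT"), drv),
              synapse_spec(rg("FLX"), pf("FLX"), drv))
  if (!is.null(crx)) {
    syn <- c(syn, list(synapse_spec(rg("EXT"), pf("FLX"), crx),
                       synapse_spec(rg("FLX"), pf("EXT"), crx)))
  } else {
    network$metadata$omitted <-
      c(network$metadata$omitted,
        sprintf("RG_cross_inhibit_PF (%s %s): no table row", side, pf_joint))
  }
  add_synapses(network, syn)
}

#' Connect a pattern formation group to a motoneuron pair
#'
#' @param network a merged `network_spec`
#' @param pf_joint joint label of the pattern formation group
#' @param mn_joint joint label of the motoneuron layer
#' @param side "left" or "right"
#' @param params a `parameter_table`
#' @return a new `network_spec`
#' @export
connect_pf_to_mn <- function(network, pf_joint, mn_joint, side = "left",
                             params = default_parameter_table()) {
  p <- .side_prefix(match.arg(side, c("left", "right")))
  drv <- .get_sparam(params, "PF_to_MN", "PF->MN drive")
  pf <- function(pol) paste(p, pf_joint, "PF", pol, sep = "_")
  mn <- function(pol) paste(p, mn_joint, "MN", pol, sep = "_")
  add_synapses(network, list(synapse_spec(pf("EXT"), mn("EXT"), drv),
                             synapse_spec(pf("FLX"), mn("FLX"), drv)))
}

#' Build the deafferented two-layer CPG validation chain
#'
#' Rhythm generator -> one pattern formation group -> one
#' extensor/flexor motoneuron pair, with no sensory pathways: the isolated
#' network used for descending-drive and pattern-formation "memory"
#' experiments.
#'
#' @param side "left" or "right"
#' @param params a `parameter_table`
#' @return a `network_spec`
#' @export
build_two_layer_cpg <- function(side = "left",
                                params = default_parameter_table()) {
  side <- match.arg(side, c("left", "right"))
  net <- merge_networks(build_rhythm_generator(side, params),
                        build_pattern_formation("hip", side, params),
                        build_motoneuron_layer("hip", side, params))
  net <- connect_rg_to_pf(net, "hip", side, params)
  net <- connect_pf_to_mn(net, "hip", "hip", side, params)
  net$metadata$kind <- "two_layer_cpg"
  net$metadata$side <- side
  net
}

#' Build a full single-limb control hierarchy
#'
#' One rhythm generator driving a hip pattern formation group and a shared
#' knee-ankle pattern formation group (the knee-ankle synergy), which in
#' turn drive six motoneurons (hip/knee/ankle x extensor/flexor) with
#' Renshaw cells.
#'
#' @param side "left" or "right"
#' @param params a `parameter_table`
#' @return a `network_spec`
#' @export
build_limb <- function(side = "left", params = default_parameter_table()) {
  side <- match.arg(side, c("left", "right"))
  net <- merge_networks(build_rhythm_generator(side, params),
                        build_pattern_formation("hip", side, params),
                        build_pattern_formation("kneeankle", side, params),
                        build_motoneuron_layer("hip", side, params),
                        build_motoneuron_layer("knee", side, params),
                        build_motoneuron_layer("ankle", side, params))
  net <- connect_rg_to_pf(net, "hip", side, params)
  net <- connect_rg_to_pf(net, "kneeankle", side, params)
  net <- connect_pf_to_mn(net, "hip", "hip", side, params)
  net <- connect_pf_to_mn(net, "kneeankle", "knee", side, params)
  net <- connect_pf_to_mn(net, "kneeankle", "ankle", side, params)
  net$metadata$kind <- "limb"
  net$metadata$side <- side
  net
}

#' Build the legacy single-layer joint control circuit
#'
#' The one-layer baseline: a persistent-sodium half-center pair (with
#' interneuron-mediated reciprocal inhibition) synapsing directly onto the
#' motoneurons, with no pattern formation layer.  In this circuit any
#' perturbation of the half-center shifts step timing and motoneuron
#' amplitude together (resetting behaviour).
#'
#' @param side "left" or "right"
#' @param params a `parameter_table`
#' @return a `network_spec`
#' @export
build_single_joint_baseline <- function(side = "left",
                                        params = default_parameter_table()) {
  side <- match.arg(side, c("left", "right"))
  p <- .side_prefix(side)
  osc <- .get_nparam(params, "HC_osc", "single-joint baseline")
  osc_flx <- params$neurons[["HC_osc_FLX"]] %||% osc
  inp <- .get_nparam(params, "IN", "single-joint baseline")
  nm <- function(role, pol) paste(p, "limb", role, pol, sep = "_")
  hc <- network_spec(
    list(neuron_spec(nm("RG", "EXT"), "RG", side, "limb", "EXT", osc),
         neuron_spec(nm("RG", "FLX"), "RG", side, "limb", "FLX", osc_flx),
         neuron_spec(nm("IN", "EXT"), "IN", side, "limb", "EXT", inp),
         neuron_spec(nm("IN", "FLX"), "IN", side, "limb", "FLX", inp)),
    list(synapse_spec(nm("RG", "EXT"), nm("RG", "FLX"),
                      .get_sparam(params, "HC_mutual_excitation", "baseline")),
         synapse_spec(nm("RG", "FLX"), nm("RG", "EXT"),
                      .get_sparam(params, "HC_mutual_excitation", "baseline")),
         synapse_spec(nm("RG", "EXT"), nm("IN", "EXT"),
                      .get_sparam(params, "HC_to_IN", "baseline")),
         synapse_spec(nm("IN", "EXT"), nm("RG", "FLX"),
                      .get_sparam(params, "HC_IN_to_HC", "baseline")),
         synapse_spec(nm("RG", "FLX"), nm("IN", "FLX"),
                      .get_sparam(params, "HC_to_IN", "baseline")),
         synapse_spec(nm("IN", "FLX"), nm("RG", "EXT"),
                      .get_sparam(params, "HC_IN_to_HC", "baseline"))),
    metadata = list(kind = "half_center", side = side))
  net <- merge_networks(hc, build_motoneuron_layer("hip", side, params))
  hcmn <- .get_sparam(params, "HC_to_MN", "single-joint baseline")
  net <- add_synapses(net, list(
    synapse_spec(nm("RG", "EXT"), paste(p, "hip_MN_EXT", sep = "_"), hcmn),
    synapse_spec(nm("RG", "FLX"), paste(p, "hip_MN_FLX", sep = "_"), hcmn)))
  net$metadata$kind <- "single_joint_baseline"
  net$metadata$side <- side
  net
}

# ---- serialization ---------------------------------------------------------

.network_to_list <- function(network) {
  list(
    units = .required_units,
    metadata = network$metadata,
    neurons = lapply(unname(network$neurons), function(n) {
      pr <- n$params
      row <- list(name = n$name, role = n$role, side = n$side,
                  joint = n$joint, polarity = n$polarity,
                  C = pr$C, G_leak = pr$G_leak, E_rest = pr$E_rest,
                  G_Na = pr$G_Na, E_Na = pr$E_Na)
      if (pr$G_Na > 0) {
        row$m <- list(A = pr$m_gate$A, S = pr$m_gate$S, E = pr$m_gate$E_half,
                      tau = pr$m_gate$tau)
        row$h <- list(A = pr$h_gate$A, S = pr$h_gate$S, E = pr$h_gate$E_half,
                      tau = pr$h_gate$tau)
      }
      row
    }),
    synapses = lapply(network$synapses, function(s)
      list(pre = s$pre, post = s$post, sign = s$sign,
           g_max = s$params$g_max, E_syn = s$params$E_syn,
           E_lo = s$params$E_lo, E_hi = s$params$E_hi)))
}

.network_from_list <- function(raw) {
  neurons <- lapply(raw$neurons, function(r) {
    params <- if (r$G_Na > 0)
      neuron_params(r$C, r$G_leak, r$E_rest, r$G_Na, r$E_Na,
                    m_gate = gating_params(r$m$A, r$m$S, r$m$E, r$m$tau),
                    h_gate = gating_params(r$h$A, r$h$S, r$h$E, r$h$tau))
    else neuron_params(r$C, r$G_leak, r$E_rest, E_Na = r$E_Na)
    neuron_spec(r$name, r$role, r$side, r$joint, r$polarity, params)
  })
  synapses <- lapply(raw$synapses, function(r)
    synapse_spec(r$pre, r$post,
                 synapse_params(r$g_max, r$E_syn, r$E_lo, r$E_hi),
                 sign = r$sign))
  network_spec(neurons, synapses, metadata = raw$metadata)
}

#' Write a network specification to YAML or JSON
#'
#' The format is chosen by extension (`.yaml`/`.yml` or `.json`); the file
#' declares the unit system and the load -> save -> load round trip is
#' lossless.
#'
#' @param network a `network_spec`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "network_spec"))
  raw <- .network_to_list(network)
  if (grepl("\\.json$", path))
    jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  else
    writeLines(yaml::as.yaml(raw, precision = 15L), path)
  invisible(path)
}

#' Read a network specification written by [write_network()]
#'
#' @param path path to a `.yaml`/`.yml` or `.json` network file
#' @return a `network_spec`
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("network file not found: ", path)
  raw <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  for (u in names(.required_units))
    if (!identical(raw$units[[u]], .required_units[[u]]))
      stop(sprintf("network file: units$%s must be '%s'",
                   u, .required_units[[u]]))
  .network_from_list(raw)
}
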