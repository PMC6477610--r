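# A minimal stand-in mechanical plant: one rotational degree of freedom per
# pattern formation group (hip; knee-ankle lumped), first-order muscle
# activation, and linear clamped afferent currents.  Every equation here is
# an explicit stand-in whose only job is to close the sensory loop
# plausibly -- it is NOT a biomechanical limb model.  Units: rad, rad/ms,
# ms, nA; torque is in the same arbitrary unit as `gain`.

#' Stand-in plant parameters for one joint
#'
#' Joint dynamics: `I dw/dt = gain (act_ext - act_flx)
#' - stiffness (angle - angle_ref) - damping w`, advanced by semi-implicit
#' Euler.  The soft centering spring (`stiffness`) bounds the angle so a
#' constant activation difference converges to a steady angle.
#'
#' @param inertia joint inertia (> 0)
#' @param damping viscous damping (>= 0), 1/ms scale
#' @param gain muscle torque gain per unit activation difference
#' @param stiffness centering spring constant (> 0)
#' @param angle_ref reference (rest) angle, rad
#' @param act_tau muscle activation time constant, ms (> 0)
#' @param act_lo,act_hi motoneuron voltages (mV) mapped linearly to
#'   activation 0 and 1 (clamped outside)
#' @return an object of class `plant_params`
#' @export
plant_params <- function(inertia = 1, damping = 9.4e-3, gain = 5e-5,
                         stiffness = 8.9e-5, angle_ref = 0, act_tau = 30,
                         act_lo = -60, act_hi = -40) {
  stopifnot(inertia > 0, damping >= 0, act_tau > 0, stiffness > 0,
            act_lo < act_hi)
  structure(list(inertia = inertia, damping = damping, gain = gain,
                 stiffness = stiffness, angle_ref = angle_ref,
                 act_tau = act_tau, act_lo = act_lo, act_hi = act_hi),
            class = "plant_params")
}

#' Joint state
#' @param angle rad
#' @param velocity rad/ms
#' @return an object of class `joint_state`
#' @export
joint_state <- function(angle = 0, velocity = 0) {
  stopifnot(is.finite(angle), is.finite(velocity))
  structure(list(angle = angle, velocity = velocity), class = "joint_state")
}

#' One step of muscle activation dynamics
#'
#' First-order low-pass of a saturating piecewise-linear map of motoneuron
#' voltage: `u = clamp((V - act_lo)/(act_hi - act_lo), 0, 1)`,
#' `da/dt = (u - a)/act_tau`, advanced exactly over `dt`.  Output stays in
#' `[0, 1]` for any input.
#'
#' @param V_mn motoneuron voltage, mV
#' @param act current activation, fraction
#' @param params a [plant_params()]
#' @param dt timestep, ms
#' @return new activation fraction
#' @export
muscle_activation <- function(V_mn, act, params, dt) {
  stopifnot(inherits(params, "plant_params"))
  u <- pmin(pmax((V_mn - params$act_lo) / (params$act_hi - params$act_lo),
                 0), 1)
  act + (u - act) * (1 - exp(-dt / params$act_tau))
}

#' One semi-implicit Euler step of the joint
#'
#' @param joint a [joint_state()]
#' @param act_ext,act_flx muscle activations, fractions
#' @param params a [plant_params()]
#' @param dt timestep, ms
#' @return new `joint_state`
#' @export
plant_step <- function(joint, act_ext, act_flx, params, dt) {
  stopifnot(inherits(joint, "joint_state"), inherits(params, "plant_params"))
  torque <- params$gain * (act_ext - act_flx) -
    params$stiffness * (joint$angle - params$angle_ref)
  v <- joint$velocity +
    dt * (torque - params$damping * joint$velocity) / params$inertia
  a <- joint$angle + dt * v
  if (!is.finite(a) || abs(a) > 1e3) stop("plant_step: joint state diverged")
  joint_state(a, v)
}

#' Afferent currents from one joint (stand-in functional forms)
#'
#' Linear, clamped maps: Ia-like current proportional to angular velocity,
#' II-like to angular excursion from the reference angle, Ib-like to the
#' (positive part of the) extensor muscle torque.  Zero gains give exactly
#' zero currents.
#'
#' @param joint a [joint_state()]
#' @param torque_ext extensor muscle torque (`gain * act_ext`)
#' @param gains named list/vector with elements `Ia`, `II`, `Ib`
#' @param params a [plant_params()]
#' @param clamp currents clipped to `[-clamp, clamp]`, nA
#' @return named numeric vector of currents (nA): `Ia`, `II`, `Ib`
#' @export
afferent_currents <- function(joint, torque_ext, gains, params, clamp = 5) {
  stopifnot(inherits(joint, "joint_state"))
  cur <- c(Ia = gains[["Ia"]] * joint$velocity,
           II = gains[["II"]] * (joint$angle - params$angle_ref),
           Ib = gains[["Ib"]] * max(torque_ext, 0))
  pmin(pmax(cur, -clamp), clamp)
}

#' Assemble the stand-in plant for a limb network
#'
#' One lumped rotational joint per pattern formation group: "hip" actuated
#' by the hip motoneuron pair and "kneeankle" by the knee pair (the ankle
#' motoneurons mirror the knee ones through the shared synergy group).
#' Afferent routes follow the pathway targets of the modelled circuit --
#' hip flexor Ia and II onto the rhythm generator flexor, hip extensor II
#' onto the rhythm generator extensor, ankle (here: lumped knee-ankle)
#' extensor Ib onto the knee-ankle pattern formation extensor -- with
#' linear stand-in functional forms.  All gains default to zero, which
#' decouples the loop exactly.
#'
#' @param network a limb `network_spec` from [build_limb()]
#' @param side "left" or "right"
#' @param params a [plant_params()] shared by both joints
#' @param gains master afferent gains, named `c(Ia=, II=, Ib=)`
#' @param aff_clamp afferent current clamp, nA
#' @return an object of class `limb_plant` consumable by
#'   [run_simulation()]'s `plant` argument
#' @export
limb_plant <- function(network, side = "left", params = plant_params(),
                       gains = c(Ia = 0, II = 0, Ib = 0), aff_clamp = 5) {
  side <- match.arg(side, c("left", "right"))
  p <- .side_prefix(side)
  need <- paste(p, c("hip_MN_EXT", "hip_MN_FLX", "knee_MN_EXT",
                     "knee_MN_FLX"), sep = "_")
  missing <- setdiff(need, neuron_names(network))
  if (length(missing))
    stop("limb_plant: network lacks motoneuron(s): ",
         paste(missing, collapse = ", "))
  joints <- list(
    list(label = paste0(p, "_hip"), mn_ext = need[1], mn_flx = need[2],
         angle0 = params$angle_ref),
    list(label = paste0(p, "_kneeankle"), mn_ext = need[3], mn_flx = need[4],
         angle0 = params$angle_ref))
  routes <- data.frame(
    joint = c(1L, 1L, 1L, 2L),
    type = c("Ia", "II", "II", "Ib"),
    target = paste(p, c("limb_RG_FLX", "limb_RG_FLX", "limb_RG_EXT",
                        "kneeankle_PF_EXT"), sep = "_"),
    gain = c(gains[["Ia"]], gains[["II"]], -gains[["II"]], gains[["Ib"]]))
  missing <- setdiff(routes$target, neuron_names(network))
  if (length(missing))
    stop("limb_plant: afferent route to unknown neuron(s): ",
         paste(missing, collapse = ", "))
  structure(list(label = "limb_plant", side = side, params = params,
                 joints = joints, routes = routes, aff_clamp = aff_clamp),
            class = "limb_plant")
}

# flatten a limb_plant for the compiled kernel (index: name -> 0-based)
.plant_arrays <- function(plant, index) {
  stopifnot(inherits(plant, "limb_plant"))
  pp <- plant$params
  nj <- length(plant$joints)
  type_code <- c(Ia = 0L, II = 1L, Ib = 2L)
  list(
    mn_ext = vapply(plant$joints, function(j) index[[j$mn_ext]], integer(1)),
    mn_flx = vapply(plant$joints, function(j) index[[j$mn_flx]], integer(1)),
    inertia = rep(pp$inertia, nj), damping = rep(pp$damping, nj),
    gain = rep(pp$gain, nj), stiffness = rep(pp$stiffness, nj),
    angle_ref = rep(pp$angle_ref, nj), act_tau = rep(pp$act_tau, nj),
    act_lo = rep(pp$act_lo, nj), act_hi = rep(pp$act_hi, nj),
    angle0 = vapply(plant$joints, function(j) j$angle0, numeric(1)),
    aff_joint = as.integer(plant$routes$joint - 1L),
    aff_type = unname(type_code[plant$routes$type]),
    aff_target = vapply(plant$routes$target, function(t) index[[t]],
                        integer(1)),
    aff_gain = as.numeric(plant$routes$gain),
    aff_clamp = plant$aff_clamp)
}
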