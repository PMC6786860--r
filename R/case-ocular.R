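# Ocular-pursuit fixture: a closed sensorimotor loop in which an eye,
# modelled as a damped second-order mechanical system with resting
# position x0, tracks an object whose position drifts as an
# Ornstein-Uhlenbeck process. Retinal neurons read both positions through
# linked variables and respond to the object's position in retinal
# coordinates through Gaussian tuning curves; they project onto the
# motoneuron of the contralateral muscle with strength proportional to the
# eccentricity of their preferred position, and every motoneuron spike
# displaces the muscular resting position x0 by a decaying "twitch".
# Positions are dimensionless (field of view roughly [-1, 1]).

#' Constants of the ocular-pursuit fixture
#' @return named list: eye mechanics time constant `tau_e` (critically
#'   damped), twitch decay `tau_t` and size `twitch`, object OU time
#'   constant `tau_o` and noise strength `sigma_o` (stationary sd
#'   `sigma_o*sqrt(tau_o/2)` = 0.4), retinal tuning width `w_ret`, drive
#'   amplitude `A_ret`, retinal/motoneuron membrane time constants, and
#'   the retina-to-motoneuron weight scale `w_moto`.
#' @export
ocular_constants <- function() {
  u <- parse_unit_expression
  list(tau_e = u("50*ms"), tau_t = u("150*ms"), twitch = 0.05,
       tau_o = u("500*ms"), sigma_o = u("0.8*second**-0.5"),
       w_ret = 0.25, A_ret = 1.6, tau_r = u("10*ms"),
       tau_m = u("20*ms"), w_moto = 1.0,
       n_retina = 100)
}

#' Build the closed-loop ocular-pursuit network
#'
#' @param coupled if FALSE, the retina-to-motoneuron weights are zero (the
#'   open-loop control condition: the eye stays near rest while the object
#'   wanders).
#' @param dt timestep (default 0.5 ms; the object noise uses
#'   Euler-Maruyama).
#' @return list with `network`, `eye`, `object`, `retina`, `moto`, the two
#'   synapse populations, monitors `eye_state`, `object_state`,
#'   `moto_spikes`, and `constants`.
#' @export
build_ocular <- function(coupled = TRUE, dt = parse_unit_expression("0.5*ms")) {
  k <- ocular_constants()
  eye <- create_group(1, "
      dxe/dt = ve : 1
      dve/dt = -2*ve/tau_e - (xe - x0)/tau_e**2 : 1/second
      dx0/dt = -x0/tau_t : 1",
    namespace = k[c("tau_e", "tau_t")], name = "eye")
  object <- create_group(1, "dxo/dt = -xo/tau_o + sigma_o*xi : 1",
                         namespace = k[c("tau_o", "sigma_o")], name = "object")
  retina <- create_group(k$n_retina, "
      pref : 1 (constant)
      eye_pos : 1 (linked)
      obj_pos : 1 (linked)
      drive = A_ret*exp(-((obj_pos - eye_pos) - pref)**2/(2*w_ret**2)) : 1
      dvr/dt = (drive - vr)/tau_r : 1",
    threshold = "vr > 1", reset = "vr = 0",
    namespace = k[c("A_ret", "w_ret", "tau_r")], name = "retina")
  set_state(retina, "pref", "-1 + 2*i/(N - 1)")
  link_variable(retina, "eye_pos", eye, "xe")
  link_variable(retina, "obj_pos", object, "xo")
  moto <- create_group(2, "dvm/dt = -vm/tau_m : 1",
                       threshold = "vm > 1", reset = "vm = 0",
                       namespace = k["tau_m"], name = "motoneurons")

  # crossed projection: retinal cells preferring the right visual field
  # (pref > 0) drive motoneuron 1, which pulls the eye rightward; cells
  # preferring the left field drive motoneuron 0
  r2m <- create_synapses(retina, moto, model = "w : 1 (constant)",
                         on_pre = "vm_post += w", namespace = k["w_moto"],
                         name = "retina_to_moto")
  connect(r2m, condition = "(pref_pre > 0 and j == 1) or (pref_pre < 0 and j == 0)")
  set_synapse_state(r2m, "w",
                    if (coupled) "w_moto*abs(pref_pre)" else "0*w_moto")
  m2e <- create_synapses(moto, eye, model = "tw : 1 (constant)",
                         on_pre = "x0_post += tw", name = "moto_to_eye")
  connect(m2e, condition = "j == 0")  # both motoneurons onto the one eye
  set_synapse_state(m2e, "tw", sprintf("(2*i - 1)*%.17g", k$twitch))

  eye_state <- state_monitor(eye, c("xe", "x0"), every = 10L)
  object_state <- state_monitor(object, "xo", every = 10L)
  moto_spikes <- spike_monitor(moto)
  net <- create_network(eye, object, retina, moto, r2m, m2e,
                        eye_state, object_state, moto_spikes, dt = dt)
  list(network = net, eye = eye, object = object, retina = retina,
       moto = moto, r2m = r2m, m2e = m2e, eye_state = eye_state,
       object_state = object_state, moto_spikes = moto_spikes, constants = k)
}

#' Run the ocular model and return eye/object trajectories
#'
#' @param duration simulated time.
#' @param coupled closed loop (TRUE) or zero-weight control (FALSE).
#' @param seed RNG seed (the object path is stochastic).
#' @param dt timestep.
#' @return list with `t` (seconds), `eye`, `object` (numeric positions)
#'   and `tracking_error` (time-averaged |eye - object|).
#' @export
run_ocular <- function(duration = parse_unit_expression("5*second"),
                       coupled = TRUE, seed = 1,
                       dt = parse_unit_expression("0.5*ms")) {
  set_seed(seed = seed)
  oc <- build_ocular(coupled = coupled, dt = dt)
  run_network(oc$network, duration)
  tt <- oc$eye_state$times()
  eye <- si_value(oc$eye_state$values("xe"))[, 1]
  obj <- si_value(oc$object_state$values("xo"))[, 1]
  list(t = tt, eye = eye, object = obj,
       tracking_error = mean(abs(eye - obj)), fixture = oc)
}
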