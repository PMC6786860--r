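# Pyloric-circuit fixture: three neurons (the AB/PD pacemaker lumped into
# one cell, plus LP and PY followers) modelled with three-variable
# Hindmarsh-Rose-style bursting dynamics in dimensionless form, mapped to
# membrane potential through v = v_base + v_scale*x for display and spike
# extraction. Activity is sensed by a calcium trace that jumps at each
# spike and decays exponentially; a slow regulation variable z integrates
# the difference between this trace and a neuron-type-specific target and
# steers two intrinsic conductances (g, an excitatory drive, and s, an
# inhibitory leak) in opposite directions, pulling each cell's long-run
# spike rate toward its target. Cells are coupled by fast and slow graded
# (continuous, summed-variable) synapses; the fast connectivity follows
# 'label_pre != label_post and not (label_pre == PY and label_post ==
# ABPD)' and the slow cholinergic synapses run from the pacemaker to both
# followers.
#
# Values of the underlying bursting model follow the standard
# Hindmarsh-Rose parametrization (b = 3, d = 5, s = 4, x_rest = -1.6);
# the regulation, synapse and target constants below are this fixture's
# own calibration, chosen to produce bursting in the pyloric frequency
# range and visible homeostatic adaptation within a 50 s run.

#' Constants of the pyloric-network fixture
#'
#' All dynamics are dimensionless except the time scales. `tau_v` sets the
#' fast (spike) time scale, `eps` the burst time scale; `tau_ca` and the
#' per-spike increment `ca_inc` define the activity sensor; `tau_z` the
#' regulation speed; `ca_target` holds one calcium set point per label
#' (ABPD, LP, PY). `v_base`/`v_scale` map x to membrane potential.
#' @return named list.
#' @export
pyloric_constants <- function() {
  u <- parse_unit_expression
  list(
    tau_v = u("1*ms"),          # one dimensionless time unit of the fast dynamics
    eps = 0.005,                # slow burst variable rate (per time unit)
    x_rest = -1.6,
    # regulated conductances: distant reversal levels and small maxima, so
    # the drive they deliver is nearly additive (little extra damping)
    e_g = 40, e_s = -10,
    g_max = 0.1, s_max = 0.3,
    z0 = -0.5,                  # initial regulation state (mildly active)
    tau_ca = u("300*ms"), ca_inc = 0.1,
    tau_z = u("5*second"), z_sense = 0.2,
    ca_target = c(ABPD = 0.50, LP = 0.30, PY = 0.18),
    v_base = u("-40*mV"), v_scale = u("20*mV"),
    spike_threshold_x = 1.0,    # x = 1 corresponds to v = -20 mV
    refractory = u("2*ms"),
    # graded synapses (inhibitory)
    g_fast = 0.3, g_slow = 0.2, e_syn = -3,
    syn_th = -0.2, syn_slope = 2.5,   # sigmoid on presynaptic x
    tau_m_slow = u("120*ms"),
    labels = c(ABPD = 0, LP = 1, PY = 2)
  )
}

pyloric_model_text <- "
  dx/dt = (y - x**3 + 3*x**2 - u + g*(e_g - x) + s*(e_s - x)
           + I_fast + I_slow)/tau_v : 1
  dy/dt = (1 - 5*x**2 - y)/tau_v : 1
  du/dt = eps*(4*(x - x_rest) - u)/tau_v : 1
  dCa/dt = -Ca/tau_ca : 1
  dz/dt = tanh((Ca - Ca_target)/z_sense)/tau_z : 1
  g = g_max/(1 + exp(2*z)) : 1
  s = s_max/(1 + exp(-2*z)) : 1
  v = v_base + v_scale*x : volt
  I_fast : 1
  I_slow : 1
  Ca_target : 1 (constant)
  label : 1 (constant)"

#' Build the pyloric three-neuron network
#'
#' @param dt timestep (default 0.25 ms; the fast dynamics have a 1 ms time
#'   constant and are integrated with exponential Euler).
#' @param monitor_every record the slow variables every this many steps.
#' @return list with `network`, `group`, `fast`, `slow` (synapse
#'   populations), `spikes`, `state` (Ca/z/v monitor) and `constants`.
#' @export
build_pyloric <- function(dt = parse_unit_expression("0.25*ms"),
                          monitor_every = 40L) {
  k <- pyloric_constants()
  ns <- c(k[c("tau_v", "eps", "x_rest", "e_g", "e_s", "g_max", "s_max",
              "tau_ca", "tau_z", "z_sense", "v_base", "v_scale")],
          list(ca_inc = k$ca_inc),
          as.list(k$labels))
  g <- create_group(3, pyloric_model_text,
                    threshold = sprintf("x > %g", k$spike_threshold_x),
                    reset = "Ca += ca_inc",
                    refractory = k$refractory,
                    namespace = ns, method = "exponential_euler",
                    name = "pyloric")
  set_state(g, "label", "i")  # ABPD = 0, LP = 1, PY = 2
  for (lbl in names(k$labels))
    set_state(g, "Ca_target", k$ca_target[[lbl]],
              subset = sprintf("label == %s", lbl))
  set_state(g, "x", k$x_rest)
  set_state(g, "y", 1 - 5 * k$x_rest^2)
  set_state(g, "z", k$z0)

  syn_ns <- c(k[c("g_fast", "g_slow", "e_syn", "syn_th", "syn_slope", "tau_m_slow")],
              as.list(k$labels))
  fast <- create_synapses(g, g, model =
    "I_fast_post = g_fast*(e_syn - x_post)/(1 + exp(-syn_slope*(x_pre - syn_th))) : 1 (summed)",
    namespace = syn_ns, name = "pyloric_fast")
  connect(fast,
    condition = "label_pre != label_post and not (label_pre == PY and label_post == ABPD)")
  slow <- create_synapses(g, g, model = "
    I_slow_post = g_slow*m_slow*(e_syn - x_post) : 1 (summed)
    dm_slow/dt = (1/(1 + exp(-syn_slope*(x_pre - syn_th))) - m_slow)/tau_m_slow : 1",
    namespace = syn_ns, name = "pyloric_slow")
  connect(slow, condition = "label_pre == ABPD and label_post != ABPD")

  sm <- spike_monitor(g)
  stm <- state_monitor(g, c("Ca", "z", "v"), every = monitor_every)
  net <- create_network(g, fast, slow, sm, stm, dt = dt)
  list(network = net, group = g, fast = fast, slow = slow,
       spikes = sm, state = stm, constants = k)
}

#' Per-label mean calcium over a time window
#'
#' @param pyl result of [build_pyloric()] after running.
#' @param from,to window bounds (time quantities).
#' @return named numeric vector (ABPD, LP, PY) of time-averaged Ca.
#' @export
pyloric_mean_ca <- function(pyl, from, to) {
  tt <- pyl$state$times()
  keep <- tt >= si_value(from) & tt < si_value(to)
  ca <- si_value(pyl$state$values("Ca"))[keep, , drop = FALSE]
  stats::setNames(colMeans(ca), c("ABPD", "LP", "PY"))
}
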