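# CUBA benchmark fixture: a sparsely connected network of leaky
# integrate-and-fire neurons with exponentially decaying excitatory and
# inhibitory synaptic currents, random Bernoulli connectivity over all
# ordered source-target pairs, and weights producing ongoing asynchronous
# activity. The homogeneous variant shares one set of time constants and
# is integrated exactly; the heterogeneous variant draws per-neuron time
# constants uniformly within 90-110% of the homogeneous values.

#' Constants of the CUBA benchmark fixture
#'
#' The classical current-based benchmark values: membrane time constant
#' 20 ms, excitatory/inhibitory synaptic time constants 5 ms / 10 ms,
#' threshold -50 mV, reset -60 mV, resting potential -49 mV, refractory
#' period 5 ms, connection probability 0.02 (mean in-degree 0.02 N),
#' excitatory weight 1.62 mV and inhibitory weight -9 mV, 80% of neurons
#' excitatory.
#' @return named list of quantities and numbers.
#' @export
cuba_constants <- function() {
  u <- parse_unit_expression
  list(taum = u("20*ms"), taue = u("5*ms"), taui = u("10*ms"),
       Vt = u("-50*mV"), Vr = u("-60*mV"), El = u("-49*mV"),
       refractory = u("5*ms"),
       we = u("1.62*mV"), wi = u("-9*mV"),
       p = 0.02, exc_fraction = 0.8)
}

#' Build the CUBA benchmark network
#'
#' @param N total number of neurons (80% excitatory).
#' @param heterogeneous if TRUE, the three time constants are drawn per
#'   neuron uniformly between 90% and 110% of the homogeneous values
#'   (forcing per-instance exact updates); if FALSE all neurons share the
#'   same constants and the integrator specializes to a single exact
#'   affine update.
#' @param p connection probability (default from [cuba_constants()]).
#' @param dt simulation timestep.
#' @param monitor attach a spike monitor (default TRUE).
#' @return list with `network`, `group`, `exc`, `inh` (synapse
#'   populations) and `spikes` (monitor or NULL).
#' @export
build_cuba <- function(N = 4000, heterogeneous = FALSE,
                       p = cuba_constants()$p,
                       dt = parse_unit_expression("0.1*ms"),
                       monitor = TRUE) {
  stopifnot(N >= 10)
  k <- cuba_constants()
  Ne <- round(k$exc_fraction * N)
  ns <- k[c("Vt", "Vr", "El")]
  if (heterogeneous) {
    model <- "
      dv/dt = (ge + gi - (v - El))/taum : volt
      dge/dt = -ge/taue : volt
      dgi/dt = -gi/taui : volt
      taum : second (constant)
      taue : second (constant)
      taui : second (constant)"
  } else {
    model <- "
      dv/dt = (ge + gi - (v - El))/taum : volt
      dge/dt = -ge/taue : volt
      dgi/dt = -gi/taui : volt"
    ns <- c(ns, k[c("taum", "taue", "taui")])
  }
  g <- create_group(N, model, threshold = "v > Vt", reset = "v = Vr",
                    refractory = k$refractory, namespace = ns, name = "cuba")
  if (heterogeneous) {
    for (tc in c("taum", "taue", "taui"))
      set_state(g, tc, sprintf("(0.9 + 0.2*rand())*%g*second", si_value(k[[tc]])))
  }
  set_state(g, "v", "Vr + rand()*(Vt - Vr)")
  syn_ns <- c(k[c("we", "wi")], list(Ne = Ne))
  exc <- create_synapses(g, g, on_pre = "ge_post += we", namespace = syn_ns,
                         name = "cuba_exc")
  inh <- create_synapses(g, g, on_pre = "gi_post += wi", namespace = syn_ns,
                         name = "cuba_inh")
  connect(exc, condition = "i < Ne", p = p)
  connect(inh, condition = "i >= Ne", p = p)
  sm <- if (monitor) spike_monitor(g) else NULL
  net <- create_network(g, exc, inh, dt = dt)
  if (monitor) net$add(sm)
  list(network = net, group = g, exc = exc, inh = inh, spikes = sm, N = N)
}

#' Empirical mean in-degree of a built CUBA network
#' @param cuba result of [build_cuba()].
#' @return mean number of incoming synapses per neuron.
#' @export
cuba_mean_in_degree <- function(cuba) {
  (cuba$exc$n_syn + cuba$inh$n_syn) / cuba$N
}
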