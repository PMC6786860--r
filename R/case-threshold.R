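# Threshold-finding fixture: a population of unconnected conductance-based
# neurons (leak + voltage-gated sodium and potassium currents, Traub-Miles
# style kinetics, per-area densities) whose maximal sodium conductance
# density is swept linearly across instances. Combined with
# find_threshold() this reproduces the programmatic estimation of the
# voltage firing threshold as a function of sodium channel density.

#' Constants of the conductance-based threshold-finding fixture
#'
#' Membrane capacitance 1 uF/cm2, leak 0.05 mS/cm2 to -65 mV, potassium
#' density 30 mS/cm2 (reversal -90 mV), sodium reversal 50 mV, kinetic
#' midpoint shift VT = -63 mV. The sodium density is a per-instance
#' parameter swept between 15 and 100 mS/cm2.
#' @return named list of quantities.
#' @export
hh_constants <- function() {
  u <- parse_unit_expression
  list(Cm = u("1*ufarad/cm2"), gl = u("0.05*mS/cm2"),
       El = u("-65*mV"), EK = u("-90*mV"), ENa = u("50*mV"),
       gkd = u("30*mS/cm2"), VT = u("-63*mV"),
       gna_min = u("15*mS/cm2"), gna_max = u("100*mS/cm2"))
}

hh_model_text <- "
  dv/dt = (gl*(El - v) - gna*m**3*h*(v - ENa) - gkd*n**4*(v - EK))/Cm : volt
  dm/dt = (0.32*4/exprel((13*mV - v + VT)/(4*mV))*(1 - m)
           - 0.28*5/exprel((v - VT - 40*mV)/(5*mV))*m)/ms : 1
  dh/dt = (0.128*exp((17*mV - v + VT)/(18*mV))*(1 - h)
           - 4/(1 + exp((40*mV - v + VT)/(5*mV)))*h)/ms : 1
  dn/dt = (0.032*5/exprel((15*mV - v + VT)/(5*mV))*(1 - n)
           - 0.5*exp((10*mV - v + VT)/(40*mV))*n)/ms : 1
  gna : siemens/metre**2 (constant)"

#' Build the conductance-based population for threshold finding
#'
#' `n` unconnected neurons whose sodium density `gna` is spaced linearly
#' from `gna_min` to `gna_max`; spikes are detected as upward crossings of
#' 0 mV (with a short refractory period so each action potential is one
#' event). Initial conditions are the resting state at El (set v to El and
#' let [find_threshold()]'s `settle` argument relax the gating variables).
#'
#' @param n number of instances.
#' @param gna_min,gna_max sodium-density range (conductance per area).
#' @return a neuron group with per-instance `gna`.
#' @export
build_hh_population <- function(n = 100, gna_min = hh_constants()$gna_min,
                                gna_max = hh_constants()$gna_max) {
  k <- hh_constants()
  g <- create_group(n, hh_model_text,
                    threshold = "v > 0*mV",
                    refractory = parse_unit_expression("3*ms"),
                    namespace = k[c("Cm", "gl", "El", "EK", "ENa", "gkd", "VT")],
                    method = "exponential_euler", name = "hh")
  set_state(g, "v", k$El)
  lo <- si_value(gna_min); hi <- si_value(gna_max)
  if (n == 1) set_state(g, "gna", quantity(lo, quantity_dim(gna_min)))
  else set_state(g, "gna", sprintf("(%.17g + i*(%.17g)/(N - 1))*siemens/metre2", lo, hi - lo))
  g
}

#' Voltage-threshold sweep across sodium densities
#'
#' Builds the population, lets it settle to rest, then runs the parallel
#' bisection of [find_threshold()].
#'
#' @param n number of instances.
#' @param n_iter bisection iterations (default 12).
#' @param initial,step0 initial estimate and step width of the search
#'   (defaults -45 mV and 25 mV, bracketing the whole density range).
#' @param dt timestep (default 0.01 ms).
#' @return list with `group`, `gna` (quantity) and `threshold` (quantity,
#'   per instance).
#' @export
threshold_sweep <- function(n = 100, n_iter = 12L,
                            initial = parse_unit_expression("-45*mV"),
                            step0 = parse_unit_expression("25*mV"),
                            dt = parse_unit_expression("0.01*ms")) {
  g <- build_hh_population(n)
  est <- find_threshold(g, initial, step0, n_iter = n_iter,
                        trial = parse_unit_expression("20*ms"), dt = dt,
                        settle = parse_unit_expression("50*ms"))
  list(group = g, gna = get_state(g, "gna"), threshold = est)
}
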