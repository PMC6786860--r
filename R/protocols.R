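# Experiment protocols expressed as plain host-language control flow
# around run/store/restore -- the "computational experiment" layer. The
# flagship protocol is parallel bisection search for the voltage firing
# threshold of every instance in a group.

#' Find per-instance voltage thresholds by parallel bisection
#'
#' The network state is stored on entry. Each iteration restores the
#' snapshot, sets the membrane potential of every instance to its current
#' estimate, simulates for `trial`, then moves each estimate down by the
#' current step if that instance spiked (the estimate was above threshold)
#' and up if it did not, and finally halves the step. After `n_iter`
#' iterations the estimates bracket the true threshold to within
#' `step0 * 2^(1 - n_iter)` (provided the threshold lies in the initial
#' search range `initial +/- 2*step0`).
#'
#' @param group a neuron group with a spike-generating threshold condition.
#' @param initial initial estimate (voltage [quantity()], scalar).
#' @param step0 initial step width (voltage quantity, scalar).
#' @param n_iter number of bisection iterations.
#' @param trial simulated duration per trial.
#' @param dt timestep for the trial network.
#' @param v_var name of the membrane potential variable (default "v").
#' @param settle optional duration simulated once before storing the
#'   reference state, letting gating variables relax.
#' @return voltage [quantity()] of length `group$N`: the threshold
#'   estimates after `n_iter` iterations.
#' @export
find_threshold <- function(group, initial, step0, n_iter = 20L,
                           trial = parse_unit_expression("20*ms"),
                           dt = parse_unit_expression("0.01*ms"),
                           v_var = "v", settle = NULL) {
  volt <- dimension(kg = 1, m = 2, s = -3, A = -1)
  if (!dim_eq(quantity_dim(initial), volt) || !dim_eq(quantity_dim(step0), volt))
    dimension_mismatch("initial estimate and step width must be voltages")
  sm <- spike_monitor(group)
  net <- create_network(group, sm, dt = dt)
  if (!is.null(settle)) run_network(net, settle)
  store_network(net, "bisection_entry")
  estimate <- rep(si_value(initial), group$N)
  step <- si_value(step0)
  for (it in seq_len(n_iter)) {
    restore_network(net, "bisection_entry")
    set_state(group, v_var, quantity(estimate, volt))
    run_network(net, trial)
    spiked <- sm$spike_counts() > 0
    estimate <- estimate + ifelse(spiked, -step, step)
    step <- step / 2
  }
  quantity(estimate, volt)
}
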