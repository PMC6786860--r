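# clock, schedule, continuation, snapshots, seeding, monitors

test_that("run(0) is a no-op and runs continue seamlessly", {
  g <- make_lif(3); set_state(g, "v0", u("-30*mV"))
  net <- create_network(g)
  v0 <- si_value(get_state(g, "v"))
  run_network(net, sec(0))
  expect_identical(si_value(get_state(g, "v")), v0)
  expect_equal(net$timestep, 0L)

  # two 50 ms runs equal one 100 ms run bit-exactly under a fixed seed
  make_net <- function() {
    set_seed(seed = 7)
    gg <- make_lif(10, refractory = u("2*ms"))
    set_state(gg, "v0", "(-48 - 10*rand())*mV")
    sm <- spike_monitor(gg)
    list(net = create_network(gg, sm), g = gg, sm = sm)
  }
  a <- make_net(); run_network(a$net, u("50*ms")); run_network(a$net, u("50*ms"))
  b <- make_net(); run_network(b$net, u("100*ms"))
  expect_identical(a$sm$times(), b$sm$times())
  expect_identical(a$sm$indices(), b$sm$indices())
  expect_identical(si_value(get_state(a$g, "v")), si_value(get_state(b$g, "v")))
})

test_that("store/restore round-trips all state bit-exactly", {
  set_seed(seed = 3)
  g <- make_lif(20, refractory = u("2*ms"))
  set_state(g, "v0", "(-45 - 10*rand())*mV")
  sm <- spike_monitor(g)
  net <- create_network(g, sm)
  run_network(net, u("20*ms"))
  store_network(net)
  v_stored <- si_value(get_state(g, "v"))
  ls_stored <- g$last_spike
  nsp <- sm$n_spikes()
  run_network(net, u("100*ms"))
  restore_network(net)
  expect_identical(si_value(get_state(g, "v")), v_stored)
  expect_identical(g$last_spike, ls_stored)
  expect_identical(sm$n_spikes(), nsp)  # monitors truncated to snapshot
  # restored continuation reproduces the original bit-exactly
  run_network(net, u("100*ms"))
  t1 <- sm$times(); i1 <- sm$indices()
  restore_network(net)
  run_network(net, u("100*ms"))
  expect_identical(sm$times(), t1)
  expect_identical(sm$indices(), i1)
  expect_error(restore_network(net, "missing"), class = "RestoreWithoutStore")
})

test_that("identical seeds give identical simulations, different seeds differ", {
  build <- function(seed) {
    set_seed(seed = seed)
    g <- create_group(50, "dv/dt = (v0 - v)/tau + s0*xi : 1\nv0 : 1 (constant)",
                      threshold = "v > 1", reset = "v = 0",
                      namespace = list(tau = u("20*ms"), s0 = u("0.5*second**-0.5")))
    set_state(g, "v0", "0.8 + 0.4*rand()")
    sm <- spike_monitor(g)
    net <- create_network(g, sm)
    run_network(net, u("100*ms"))
    list(t = sm$times(), i = sm$indices())
  }
  a <- build(1); b <- build(1); c <- build(2)
  expect_identical(a, b)
  expect_false(identical(a, c))
})

test_that("the slot schedule orders summed, update, threshold, delivery, reset", {
  g <- make_lif(2); set_state(g, "v0", u("-30*mV"))
  s <- create_synapses(g, g, on_pre = "v_post += 0*mV")
  connect(s, condition = "i != j")
  net <- create_network(g, s)
  net$enable_slot_log()
  run_network(net, u("1*ms"))
  log <- do.call(rbind, lapply(net$slot_log, as.data.frame))
  for (step in unique(log$step)) {
    slots <- log$slot[log$step == step]
    expect_false(is.unsorted(slots))  # slots execute in fixed order
    # resets never precede deliveries; deliveries never precede thresholds
    expect_true(max(which(slots == 3)) < min(which(slots == 4)))
    expect_true(max(which(slots == 4)) < min(which(slots == 5)))
  }
})

test_that("durations that are not step multiples warn and round", {
  g <- make_lif(1)
  net <- create_network(g)
  expect_warning(run_network(net, quantity(0.25e-3 + 0.3e-4, dimension(s = 1))),
                 "not a multiple")
  expect_error(run_network(net, u("1*mV")), class = "DimensionMismatch")
})

test_that("monitors sample post-reset values and rates integrate to counts", {
  # without refractoriness, a suprathreshold-driven LIF can never be
  # recorded above threshold: monitors sample after the reset slot
  g0 <- make_lif(1)
  set_state(g0, "v0", u("-20*mV")); set_state(g0, "v", u("-60*mV"))
  vm <- state_monitor(g0, "v")
  net0 <- create_network(g0, vm)
  run_network(net0, u("50*ms"))
  expect_true(all(si_value(vm$values("v"))[, 1] <= -0.05 + 1e-12))

  # a 9.9 ms refractory period pins the firing to one spike per 10 ms
  g <- make_lif(1, refractory = u("9.9*ms"))
  set_state(g, "v0", u("-20*mV")); set_state(g, "v", u("-60*mV"))
  sm <- spike_monitor(g); rm <- rate_monitor(g)
  net <- create_network(g, sm, rm)
  run_network(net, u("100*ms"))
  # rate record: sum(rate * dt * N) equals the spike count
  expect_equal(sum(si_value(rm$rates()) * 1e-4 * g$N), sm$n_spikes())
  expect_equal(mean(si_value(rm$rates())), 100, tolerance = 0.1)
})

test_that("recording an instance subset equals the slice of a full recording", {
  set_seed(seed = 5)
  g <- make_lif(6)
  set_state(g, "v0", "(-40 - 10*rand())*mV")
  full <- state_monitor(g, "v")
  part <- state_monitor(g, "v", record = c(2L, 5L))
  net <- create_network(g, full, part)
  run_network(net, u("20*ms"))
  expect_identical(si_value(part$values("v")),
                   si_value(full$values("v"))[, c(2, 5)])
})

test_that("spike and state CSVs round-trip through the writers", {
  g <- make_lif(2); set_state(g, "v0", u("-30*mV"))
  sm <- spike_monitor(g); vm <- state_monitor(g, "v")
  net <- create_network(g, sm, vm)
  run_network(net, u("20*ms"))
  fs <- tempfile(fileext = ".csv"); fv <- tempfile(fileext = ".csv")
  write_spikes_csv(sm, fs); write_states_csv(vm, fv)
  ds <- read.csv(fs)
  expect_equal(ds$t, sm$times()); expect_equal(ds$neuron, sm$indices())
  dv <- read.csv(fv)
  expect_equal(dv$t_seconds, vm$times())
  expect_equal(dv$v_0, si_value(vm$values("v"))[, 1])
})

test_that("groups load from config lists with unit-string namespaces", {
  g <- group_from_config(list(N = 2, model = "dv/dt = -v/tau : volt",
                              threshold = "v > -50*mV", reset = "v = -60*mV",
                              refractory = "2*ms",
                              namespace = list(tau = "10*ms")))
  expect_equal(g$N, 2L)
  expect_equal(g$refractory_s, 0.002)
  set_state(g, "v", u("-40*mV"))
  expect_equal(apply_threshold(g, sec(0)), c(1L, 2L))
})
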