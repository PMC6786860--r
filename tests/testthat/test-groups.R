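# NeuronGroup behaviour: creation, state setting, thresholds/refractoriness,
# linked variables, spike extraction from traces

test_that("groups are created with allocated, zeroed state", {
  g <- make_lif(1)
  expect_equal(g$N, 1L)
  expect_equal(si_value(get_state(g, "v")), 0)  # zero in its dimension
  lab <- create_group(3, "dx/dt = -x/second : 1\nlabel : 1 (constant)",
                      namespace = list(ABPD = 0, LP = 1, PY = 2))
  set_state(lab, "label", "i")
  expect_equal(si_value(get_state(lab, "label")), c(0, 1, 2))
  expect_error(create_group(1, "dv/dt = -v/tau : volt", threshold = "v",
                            namespace = list(tau = u("10*ms"))),
               class = "DimensionMismatch")
})

test_that("set_state supports quantities, expressions and subsets", {
  g <- create_group(100, "dv/dt = -v/tau : volt\ngna : siemens/metre**2 (constant)\nlabel : 1 (constant)",
                    namespace = list(tau = u("10*ms"), LP = 1))
  # linear ramp over instances spans the configured range exactly
  set_state(g, "gna", "(150 + i*(1000 - 150)/(N - 1))*siemens/metre2")
  gna <- si_value(get_state(g, "gna"))
  expect_equal(gna[1], 150); expect_equal(gna[100], 1000)
  expect_equal(diff(gna), rep((1000 - 150) / 99, 99), tolerance = 1e-12)

  set.seed(5)
  set_state(g, "v", "-65*mV + 10*mV*rand()")
  v <- si_value(get_state(g, "v"))
  expect_true(all(v >= -0.065 & v < -0.055))

  set_state(g, "label", 1, subset = 40:60)
  set_state(g, "v", u("0*mV"), subset = "label == LP")
  v <- si_value(get_state(g, "v"))
  expect_true(all(v[40:60] == 0)); expect_true(all(v[-(40:60)] != 0))

  # a constant quantity equals the equivalent literal expression string
  g2 <- make_lif(5)
  set_state(g2, "v", u("-55*mV")); a <- si_value(get_state(g2, "v"))
  set_state(g2, "v", "-55*mV"); b <- si_value(get_state(g2, "v"))
  expect_identical(a, b)

  expect_error(set_state(g, "nope", 1), class = "UnresolvedIdentifier")
  expect_error(set_state(g, "v", u("1*second")), class = "DimensionMismatch")
  expect_error(set_state(g, "v", u("0*mV"), subset = 200), class = "eqspike_error")
})

test_that("thresholding respects the refractory window", {
  g <- make_lif(2, refractory = u("5*ms"))
  g$set_time(0, 1e-4)
  set_state(g, "v", quantity(c(-0.070, -0.040), quantity_dim(u("volt"))))
  expect_equal(apply_threshold(g, sec(0)), 2L)
  # 1 ms later, still refractory: suppressed even though above threshold
  expect_equal(apply_threshold(g, sec(0.001)), integer(0))
  # at exactly the refractory boundary the instance may spike again
  expect_equal(apply_threshold(g, sec(0.005)), 2L)
})

test_that("successive spike times of one instance differ by >= refractory", {
  g <- make_lif(1, refractory = u("3*ms"))
  set_state(g, "v0", u("-30*mV"))
  set_state(g, "v", u("-60*mV"))
  sm <- spike_monitor(g)
  net <- create_network(g, sm)
  run_network(net, u("200*ms"))
  expect_gt(sm$n_spikes(), 5)
  expect_true(all(diff(sm$times()) >= 0.003 - 1e-12))
})

test_that("linked variables alias the source array", {
  src <- create_group(1, "dx/dt = 1/second : 1", name = "src")
  tgt <- create_group(4, "p : 1 (linked)\ndv/dt = (p - v)/tau : 1",
                      namespace = list(tau = u("10*ms")))
  link_variable(tgt, "p", src, "x")
  set_state(src, "x", 0.5)
  expect_equal(si_value(get_state(tgt, "p")), rep(0.5, 4))
  # after the source updates, the next read sees the new value
  net <- create_network(src, tgt)
  run_network(net, u("10*ms"))
  expect_equal(si_value(get_state(tgt, "p")),
               rep(si_value(get_state(src, "x")), 4))
  expect_equal(si_value(get_state(tgt, "p"))[1], 0.51, tolerance = 1e-9)
  expect_error(set_state(tgt, "p", 1), class = "WriteToLinked")
  # dimensions must match
  mv <- create_group(1, "dy/dt = 0*mV/ms : volt")
  tg2 <- create_group(1, "q : 1 (linked)")
  expect_error(link_variable(tg2, "q", mv, "y"), class = "DimensionMismatch")
})

test_that("spikes extract from traces at strict upward crossings", {
  volt <- quantity_dim(u("volt"))
  tt <- seq(0, 0.3, by = 1e-4)
  # sine of amplitude 40 mV about -50 mV crosses -20 mV once per period
  v <- quantity(-0.05 + 0.04 * sin(2 * pi * 10 * tt), volt)
  st <- extract_spikes_from_trace(v, tt, u("-20*mV"))
  expect_equal(length(st), 3)
  # constant trace above threshold: no prior sub-threshold sample, no spikes
  expect_equal(length(extract_spikes_from_trace(
    quantity(rep(0, 100), volt), seq_len(100) * 1e-4, u("-20*mV"))), 0)
  expect_error(extract_spikes_from_trace(quantity(rep(0, 3)), 1:3, u("-20*mV")),
               class = "DimensionMismatch")
  # brute-force crossing-count oracle on an irregular bursting-like trace
  set.seed(9)
  raw <- -0.05 + cumsum(rnorm(2000, 0, 0.004))
  n_oracle <- 0L
  for (k in 2:length(raw))
    if (raw[k] >= -0.02 && raw[k - 1] < -0.02) n_oracle <- n_oracle + 1L
  st2 <- extract_spikes_from_trace(quantity(raw, volt), seq_along(raw) * 1e-4,
                                   u("-20*mV"))
  expect_equal(length(st2), n_oracle)
})

test_that("unless_refractory freezes flagged variables during the window", {
  g <- create_group(1, "dv/dt = (v0 - v)/tau : volt (unless_refractory)\nv0 : volt (constant)",
                    threshold = "v > -50*mV", reset = "v = -60*mV",
                    refractory = u("5*ms"), namespace = list(tau = u("5*ms")))
  set_state(g, "v0", u("-20*mV")); set_state(g, "v", u("-60*mV"))
  sm <- spike_monitor(g)
  stm <- state_monitor(g, "v")
  net <- create_network(g, sm, stm)
  run_network(net, u("30*ms"))
  v <- si_value(stm$values("v"))[, 1]
  tt <- stm$times()
  # immediately after each spike v stays clamped at reset for the window
  for (ts in sm$times()) {
    inwin <- tt > ts & tt < ts + 0.005 - 1e-9
    expect_true(all(abs(v[inwin] + 0.060) < 1e-12))
  }
})
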