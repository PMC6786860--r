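# connectivity, per-synapse state, delay queues, summed variables

test_that("condition connectivity equals full enumeration", {
  # the 3-type circuit condition: between-type synapses except PY -> pacemaker
  labs <- c(0, 1, 2)  # ABPD, LP, PY
  g <- create_group(3, "dx/dt = -x/second : 1\nlabel : 1 (constant)",
                    namespace = list(ABPD = 0, LP = 1, PY = 2))
  set_state(g, "label", labs)
  s <- create_synapses(g, g, namespace = list(ABPD = 0, LP = 1, PY = 2),
                       on_pre = "x_post += 0.1")
  cond <- "label_pre != label_post and not (label_pre == PY and label_post == ABPD)"
  connect(s, condition = cond)
  oracle <- enumerate_pairs(3, 3, cond, pre_vars = list(label = labs),
                            post_vars = list(label = labs),
                            consts = list(ABPD = 0, LP = 1, PY = 2))
  expect_equal(s$i, oracle$i); expect_equal(s$j, oracle$j)
  expect_equal(s$n_syn, 5L)
  got <- paste(s$i, s$j, sep = "->")
  expect_setequal(got, c("0->1", "0->2", "1->0", "1->2", "2->1"))

  # random boolean conditions over i and j match enumeration exactly
  a <- create_group(17, "dx/dt = -x/second : 1")
  b <- create_group(23, "dy/dt = -y/second : 1")
  conds <- c("i != j", "i < j", "(i + j) == 20", "i > 3 and j <= 5",
             "i == 2*j or j == 2*i", "not (i == j)")
  for (cc in conds) {
    s2 <- create_synapses(a, b)
    connect(s2, condition = cc)
    oracle <- enumerate_pairs(17, 23, cc)
    expect_equal(s2$i, oracle$i, info = cc)
    expect_equal(s2$j, oracle$j, info = cc)
  }
  s3 <- create_synapses(a, a); connect(s3, condition = "i != j")
  expect_equal(s3$n_syn, 17L * 16L)
})

test_that("probabilistic connectivity has binomial synapse counts", {
  g <- create_group(200, "dx/dt = -x/second : 1")
  set_seed(seed = 101)
  s <- create_synapses(g, g)
  connect(s, p = 0.05)
  n <- 200 * 200
  expect_lt(abs(s$n_syn - n * 0.05), 4 * sqrt(n * 0.05 * 0.95))
  expect_error(connect(create_synapses(g, g), p = 1.5), class = "eqspike_error")
  # explicit pairs
  s2 <- create_synapses(g, g)
  connect(s2, pairs = list(i = c(0, 5), j = c(3, 3)))
  expect_equal(s2$n_syn, 2L)
})

test_that("per-synapse state accepts expressions over i, j and suffixed vars", {
  pre <- create_group(10, "dx/dt = -x/second : 1\npref : 1 (constant)")
  set_state(pre, "pref", "-1 + 2*i/(N - 1)")
  post <- create_group(2, "dy/dt = -y/second : 1")
  s <- create_synapses(pre, post, model = "w : 1 (constant)", on_pre = "y_post += w")
  connect(s, condition = "(pref_pre > 0 and j == 1) or (pref_pre < 0 and j == 0)")
  set_synapse_state(s, "w", "abs(pref_pre)")
  w <- si_value(get_synapse_state(s, "w"))
  pref <- si_value(get_state(pre, "pref"))
  expect_equal(w, abs(pref[s$i + 1]))
  # incremental delays grow linearly with the target index
  s2 <- create_synapses(pre, post, on_pre = "y_post += 0.1")
  connect(s2, condition = "i == 0")
  set_synapse_state(s2, "delay", "(j + 1)*1*ms")
  expect_equal(si_value(get_synapse_state(s2, "delay")), (s2$j + 1) * 1e-3)
  expect_error(set_synapse_state(s, "undeclared", 1), class = "UnresolvedIdentifier")
})

test_that("spikes are delivered exactly round(delay/dt) steps later", {
  for (case in 1:6) {
    set.seed(case)
    dt_s <- sample(c(1e-4, 2e-4, 5e-4), 1)
    d_s <- round(runif(1, 0, 0.01) / dt_s) * dt_s + sample(c(0, 0.4, 0.5), 1) * dt_s
    src <- create_group(1, "dv/dt = 0*mV/ms : volt", threshold = "v > -50*mV",
                        reset = "v = -70*mV")
    tgt <- create_group(1, "dy/dt = 0/second : 1")
    s <- create_synapses(src, tgt, on_pre = "y_post += 1")
    connect(s, pairs = list(i = 0, j = 0))
    set_synapse_state(s, "delay", quantity(d_s, dimension(s = 1)))
    ym <- state_monitor(tgt, "y")
    net <- create_network(src, tgt, s, ym, dt = quantity(dt_s, dimension(s = 1)))
    set_state(src, "v", u("-40*mV"))   # spikes at the first step, then resets
    run_network(net, quantity(200 * dt_s, dimension(s = 1)))
    y <- si_value(ym$values("y"))[, 1]
    first <- which(y > 0)[1] - 1L      # 0-based step at which y changed
    expect_equal(first, as.integer(floor(d_s / dt_s + 0.5)), info = sprintf(
      "delay %g at dt %g", d_s, dt_s))
  }
})

test_that("zero-delay spikes arrive within the emitting timestep", {
  src <- create_group(1, "dv/dt = 0*mV/ms : volt", threshold = "v > -50*mV",
                      reset = "v = -70*mV")
  tgt <- create_group(1, "dy/dt = 0/second : 1")
  s <- create_synapses(src, tgt, on_pre = "y_post += 1")
  connect(s, pairs = list(i = 0, j = 0))
  ym <- state_monitor(tgt, "y")
  net <- create_network(src, tgt, s, ym)
  set_state(src, "v", u("-40*mV"))
  run_network(net, u("1*ms"))
  y <- si_value(ym$values("y"))[, 1]
  expect_equal(y[1], 1)  # monitor samples after delivery in the same step
})

test_that("on_pre executions per synapse equal presynaptic spike counts", {
  set_seed(seed = 42)
  src <- make_lif(5)
  set_state(src, "v0", "(-45 - 4*i)*mV")  # heterogeneous rates
  tgt <- create_group(3, "dy/dt = -0*y/second : 1")
  s <- create_synapses(src, tgt, model = "n_deliv : 1", on_pre = "n_deliv += 1")
  connect(s, p = 0.7)
  set_synapse_state(s, "delay", "rand()*3*ms")
  sm <- spike_monitor(src)
  net <- create_network(src, tgt, s, sm)
  run_network(net, u("300*ms"))
  run_network(net, u("100*ms"))  # continuation must keep queues intact
  counts <- sm$spike_counts()
  deliv <- si_value(get_synapse_state(s, "n_deliv"))
  pending <- sum(vapply(s$pathways$pre$ring, length, integer(1)))
  expect_equal(sum(deliv) + pending, sum(counts[s$i + 1]))
  # per synapse: delivered + (pending for that synapse) == source spikes
  pend_syn <- table(factor(unlist(s$pathways$pre$ring), levels = seq_len(s$n_syn)))
  expect_equal(deliv + as.numeric(pend_syn), counts[s$i + 1])
})

test_that("summed variables are set to per-target sums (zero when empty)", {
  pre <- create_group(4, "dx/dt = 0/second : 1")
  post <- create_group(3, "I : amp\ndy/dt = 0/second : 1")
  s <- create_synapses(pre, post, model = "w : amp (constant)\nI_post = w : amp (summed)")
  connect(s, pairs = list(i = c(0, 1, 2), j = c(0, 0, 2)))
  set_synapse_state(s, "w", u("1*nA"))
  update_summed(s)
  expect_equal(si_value(get_state(post, "I")), c(2e-9, 0, 1e-9))

  # randomized small networks against explicit per-target summation
  for (rep in 1:5) {
    set.seed(rep * 13)
    np <- sample(3:8, 1); nq <- sample(3:8, 1)
    a <- create_group(np, "dx/dt = 0/second : 1")
    b <- create_group(nq, "Iin : 1\ndy/dt = 0/second : 1")
    sp <- create_synapses(a, b, model = "g0 : 1 (constant)\nIin_post = g0*(1 + x_pre) : 1 (summed)")
    connect(sp, p = 0.6)
    if (sp$n_syn == 0) next
    set_synapse_state(sp, "g0", "rand()")
    set_state(a, "x", "rand()")
    update_summed(sp)
    g0 <- si_value(get_synapse_state(sp, "g0")); xv <- si_value(get_state(a, "x"))
    oracle <- numeric(nq)
    for (k in seq_len(sp$n_syn))
      oracle[sp$j[k] + 1] <- oracle[sp$j[k] + 1] + g0[k] * (1 + xv[sp$i[k] + 1])
    expect_equal(si_value(get_state(b, "Iin")), oracle, tolerance = 1e-14)
  }
})

test_that("two populations summing into one variable collide", {
  pre <- create_group(2, "dx/dt = 0/second : 1")
  post <- create_group(2, "I : 1\ndy/dt = 0/second : 1")
  s1 <- create_synapses(pre, post, model = "I_post = 1 + 0*x_pre : 1 (summed)")
  s2 <- create_synapses(pre, post, model = "I_post = 2 + 0*x_pre : 1 (summed)")
  connect(s1, p = 1); connect(s2, p = 1)
  net <- create_network(pre, post, s1, s2)
  expect_error(run_network(net, u("1*ms")), class = "Collision")
})

test_that("connectivity round-trips through CSV", {
  g <- create_group(6, "dx/dt = 0/second : 1")
  s <- create_synapses(g, g, model = "w : 1", on_pre = "x_post += w")
  connect(s, condition = "i != j", p = 0.5)
  set_synapse_state(s, "w", "rand()")
  path <- tempfile(fileext = ".csv")
  write_connectivity_csv(s, path)
  df <- read.csv(path)
  expect_equal(df$i, s$i); expect_equal(df$j, s$j)
  s2 <- create_synapses(g, g, on_pre = "x_post += 1")
  connect_from_csv(s2, path)
  expect_equal(s2$i, s$i); expect_equal(s2$j, s$j)
})
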