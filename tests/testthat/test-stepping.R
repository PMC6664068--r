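test_that("a passive neuron at leak equilibrium is a fixed point", {
  net <- rc_network()                      # v_init = E_leak, no stimulus
  res <- run_simulation(net, simulation_clock(0.025, 100, t_io = 0.025))
  expect_lt(max(abs(res$traces[[1]] - (-65))), 1e-6)
})

test_that("the RC charging curve matches the analytic solution", {
  # C = 1 nF, g = 0.1 uS, E = -65 mV, I = 0.5 nA: tau = 10 ms, v_inf = -60
  net <- rc_network(amp = 0.5, onset = 0, dur = Inf)
  clock <- simulation_clock(0.025, 50, t_io = 0.025)
  res <- run_simulation(net, clock)
  analytic <- -65 + 5 * (1 - exp(-res$times / 10))
  err <- abs(res$traces[[1]][1, ] - analytic)
  expect_lt(err[length(err)], 0.05)
  expect_lt(max(err), 0.05)

  # halving dt shrinks the max-norm error monotonically (order >= 1)
  errs <- vapply(c(0.1, 0.05, 0.025, 0.0125), function(dt) {
    cl <- simulation_clock(dt, 50, t_io = 0.1)
    r <- run_simulation(rc_network(amp = 0.5, onset = 0, dur = Inf), cl)
    max(abs(r$traces[[1]][1, ] - (-65 + 5 * (1 - exp(-r$times / 10)))))
  }, 1)
  expect_true(all(diff(errs) < 0))
  order_obs <- log2(errs[1] / errs[3]) / 2
  expect_gte(order_obs, 0.95)            # first-order implicit update
})

test_that("spike detection fires on upward crossings only", {
  expect_equal(detect_spike(-30, -10, threshold = -20, t = 5), 5)
  expect_null(detect_spike(-10, -30, threshold = -20, t = 5))
  expect_null(detect_spike(-10, -5, threshold = -20, t = 5))   # already above
})

test_that("a suprathreshold pulse on an HH soma spikes, matching a refined-dt run", {
  run_counts <- function(dt) {
    res <- run_simulation(hh_soma_network(amp = 10, onset = 1, dur = 5),
                          simulation_clock(dt, 30, t_io = 0.1))
    nrow(res$spikes)
  }
  n_coarse <- run_counts(0.025)
  expect_gte(n_coarse, 1L)
  expect_equal(n_coarse, run_counts(0.025 / 8))
})

test_that("spikes map to events honouring delays and step boundaries", {
  tree <- toy_tree(NA_integer_)
  m1 <- rc_model(); m2 <- rc_model()
  net <- neural_network(list(m1, m2),
                        connections = data.frame(source = 1, target = 2,
                                                 target_comp = 1,
                                                 delay = 0.1, weight = 0.01))
  ev <- exchange_spikes(data.frame(time = 0.26, neuron = 1), net)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$time, 0.36)
  # delivered at the first step whose start is at/past 0.36, i.e. t = 0.375
  st <- init_neuron_state(net$models[[2]], dt = 0.025)
  arborsim:::block_enqueue_events(st, ev)
  for (s in 1:15) advance_step(st, s)       # last of these starts at 0.35
  expect_equal(st$delivered, 0L)
  advance_step(st, 16L)                     # starts at 0.375 >= 0.36
  expect_equal(st$delivered, 1L)
  # no spikes in a window -> no events
  expect_equal(nrow(exchange_spikes(data.frame(time = numeric(),
                                               neuron = integer()), net)), 0L)
  # delays below one timestep cannot define a communication step
  bad <- neural_network(list(rc_model(), rc_model()),
                        connections = data.frame(source = 1, target = 2,
                                                 target_comp = 1,
                                                 delay = 0.01, weight = 1e-3))
  expect_error(run_simulation(bad, simulation_clock(0.025, 1)),
               "communication step")
})

test_that("two connected neurons respect causality and determinism", {
  make_net <- function() {
    neural_network(
      list(random_neuron_model(11, n_comp = 20), random_neuron_model(12, n_comp = 20)),
      connections = data.frame(source = 1, target = 2, target_comp = 1,
                               delay = 0.5, weight = 0.05),
      stimuli = data.frame(neuron = 1, comp = 1, onset = 1, duration = 2,
                           amplitude = 5))
  }
  clock <- simulation_clock(0.025, 15)
  r1 <- run_simulation(make_net(), clock)
  expect_gte(nrow(r1$spikes), 2L)
  tA <- min(r1$spikes$time[r1$spikes$neuron == 1])
  tB <- min(r1$spikes$time[r1$spikes$neuron == 2])
  expect_gt(tB, tA + 0.5)
  # same inputs, second run: bitwise identical raster
  r2 <- run_simulation(make_net(), clock)
  expect_identical(r1$spikes, r2$spikes)
  # event conservation: every spike of neuron 1 yields one delivered event
  n1 <- sum(r1$spikes$neuron == 1)
  expect_equal(r1$stats$events_scheduled, n1)
  expect_equal(r1$stats$events_delivered, r1$stats$events_scheduled)
})

test_that("tstop = 0 runs zero steps and returns empty output", {
  res <- run_simulation(rc_network(), simulation_clock(0.025, 0))
  expect_equal(nrow(res$spikes), 0L)
  expect_length(res$times, 0L)
})
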