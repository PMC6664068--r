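test_that("a single subtree under the channel protocol equals plain stepping", {
  m <- random_neuron_model(21, n_comp = 20)
  st <- init_neuron_state(m, dt = 0.025)
  bl <- init_neuron_state(m, dt = 0.025)
  for (s in 1:200) {
    advance_step(st, s)
    step_subtree(bl, s)
  }
  expect_identical(st$v, bl$v)
})

test_that("decomposed execution reproduces the monolithic run per step", {
  withr::with_seed(33, {
    for (seed in 1:5) {
      net <- random_neuron_network(seed, n_comp = 35)
      clock <- simulation_clock(0.025, 5, t_io = 0.025)
      mono <- run_simulation(net, clock, record = "all")
      costs <- compartment_costs(net$models[[1]])
      thr <- sum(costs) / sample(2:6, 1L)
      plan <- cluster_subtrees(net$models[[1]]$tree, costs, thr)
      dec <- run_network_async(net, clock, plans = list(plan), workers = 2,
                               record = "all")
      expect_lt(max(abs(mono$traces[[1]] - dec$traces[[1]])), 1e-9)
    }
  })
})

test_that("every cross-subtree connection carries exactly three values per step", {
  net <- random_neuron_network(7, n_comp = 40)
  clock <- simulation_clock(0.025, 2)
  costs <- compartment_costs(net$models[[1]])
  plan <- cluster_subtrees(net$models[[1]]$tree, costs, sum(costs) / 5)
  expect_gt(length(plan$subtrees), 2L)
  res <- run_network_async(net, clock, plans = list(plan), record = "soma")
  ch <- res$stats$channels
  expect_equal(nrow(ch), length(plan$subtrees) - 1L)
  expect_true(all(ch$n_vup == clock$n_steps))
  expect_true(all(ch$n_tri == clock$n_steps))
  expect_true(all(ch$n_sub == clock$n_steps))
  # progress: every subtree completed every step
  expect_equal(res$stats$subtree_steps,
               length(plan$subtrees) * clock$n_steps)
})

test_that("a multi-child root waits for all triangulation contributions", {
  # Y tree split into root + two children: the root's triangulation gate
  # expects two contributions
  tree <- toy_tree(c(NA, 1, 2, 2, 3, 4))
  m <- neuron_model(tree)
  m <- add_mechanism(m, "pas", 1:6, g = 0.05)
  plan <- cluster_subtrees(tree, rep(1, 6), 4)   # {1,2} + two branches
  net <- neural_network(list(m),
                        stimuli = data.frame(neuron = 1, comp = 1, onset = 0,
                                             duration = 1, amplitude = 0.5))
  clock <- simulation_clock(0.025, 1, t_io = 0.025)
  res <- run_network_async(net, clock, plans = list(plan), record = "all")
  mono <- run_simulation(net, clock, record = "all")
  expect_lt(max(abs(mono$traces[[1]] - res$traces[[1]])), 1e-12)
  expect_equal(res$stats$channels$n_tri, c(40L, 40L))
})

test_that("results are invariant to worker count and locality assignment", {
  js <- generate_network(network_recipe(n_neurons = 4, p_connect = 0.4,
                                        n_stim = 2, stim_amp = 5, seed = 2))
  net <- read_network(js)
  clock <- simulation_clock(0.025, 8, t_io = 0.1)
  plans <- lapply(net$models, function(m) {
    costs <- compartment_costs(m)
    cluster_subtrees(m$tree, costs, sum(costs) / 3)
  })
  runs <- lapply(c(1, 2, 4, 8), function(w) {
    run_network_async(net, clock, plans = plans, workers = w, record = "all")
  })
  for (r in runs[-1]) {
    expect_identical(runs[[1]]$spikes, r$spikes)
    expect_identical(runs[[1]]$traces, r$traces)
  }
  expect_gte(nrow(runs[[1]]$spikes), 1L)
  # two simulated localities: same results, cross-locality channels counted
  wts <- lapply(plans, neuron_subtree_groups)
  bal <- balance_with_splitting(wts, 2, tolerance = 0)
  loc <- assignment_localities(bal, wts)
  r_loc <- run_network_async(net, clock, plans = plans, workers = 2,
                             assignment = loc, record = "all")
  expect_identical(runs[[1]]$traces, r_loc$traces)
  expect_identical(runs[[1]]$spikes, r_loc$spikes)
})

test_that("event bookkeeping is exact across the async runtime", {
  js <- generate_network(network_recipe(n_neurons = 5, p_connect = 0.5,
                                        n_stim = 2, stim_amp = 5,
                                        feedforward = TRUE, seed = 4))
  net <- read_network(js)
  clock <- simulation_clock(0.025, 12)
  res <- run_network_async(net, clock, workers = 2, cores_count = 4)
  # delivered = scheduled = spikes x out-degree (feedforward net, early stimuli)
  expected <- sum(net$out_degree[res$spikes$neuron])
  expect_equal(res$stats$events_scheduled, expected)
  expect_equal(res$stats$events_delivered, expected)
})
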