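test_that("rate functions evaluate removable singularities by their limit", {
  # alpha_m = 0.1 (v+40) / (1 - exp(-(v+40)/10)) -> 1.0 /ms at v = -40
  expect_equal(rate_functions(-40, "m")$alpha, 1.0, tolerance = 1e-9)
  # alpha_n = 0.01 (v+55) / (1 - exp(-(v+55)/10)) -> 0.1 /ms at v = -55
  expect_equal(rate_functions(-55, "n")$alpha, 0.1, tolerance = 1e-9)
  # continuity across the singular point
  for (g in c("m", "n")) {
    vs <- if (g == "m") -40 else -55
    near <- rate_functions(vs + c(-1e-4, 1e-4), g)$alpha
    expect_lt(abs(diff(near)), 1e-4)
  }
  for (g in c("m", "h", "n")) {
    ab <- rate_functions(seq(-100, 60, by = 2.5), g)
    expect_true(all(ab$alpha >= 0 & ab$beta >= 0))
    xinf <- ab$alpha / (ab$alpha + ab$beta)
    expect_true(all(xinf >= 0 & xinf <= 1))
  }
  expect_error(rate_functions(-60, "q"), "unknown gate")
})

test_that("mechanism currents follow g x (v - E) with the HH gate products", {
  tree <- toy_tree(NA_integer_)
  leak_at <- function(g, e, v) {
    m <- add_mechanism(neuron_model(tree, v_init = v), "pas", 1L, g = g, e = e)
    mechanism_current(m$placements[[1]], v)
  }
  at_rest <- leak_at(0.1, -65, -65)
  expect_equal(at_rest$i, 0)
  expect_equal(at_rest$g, 0.1)
  expect_equal(leak_at(0.1, -65, -60)$i, 0.5)       # 0.1 uS * 5 mV = 0.5 nA

  # sodium with m = 0.5, h = 0.2: x = m^3 h = 0.025; g_inst = 12 * 0.025
  m <- add_mechanism(neuron_model(tree, v_init = -50), "hh", 1L,
                     gna = 12, gk = 0, gl = 0, ena = 50)
  pl <- m$placements[[1]]
  pl$states <- list(m = 0.5, h = 0.2, n = 0)
  cur <- mechanism_current(pl, -50)
  expect_equal(cur$g, 12 * 0.125 * 0.2)
  expect_equal(cur$i, 0.3 * (-100))

  # linearity in g and in (v - E) for fixed states
  cur2 <- mechanism_current({ pl2 <- pl; pl2$params$gna <- 24; pl2 }, -50)
  expect_equal(cur2$i, 2 * cur$i)
})

test_that("gating update is the exponential integrator with its fixed point", {
  # x = 0, x_inf = 1, tau = 1 ms, dt = 1 ms -> 1 - exp(-1)
  expect_equal(arborsim:::rate_update(0, alpha = 1, beta = 0, dt = 1),
               1 - exp(-1))
  # fixed point: x = x_inf stays put
  expect_equal(arborsim:::rate_update(0.25, alpha = 1, beta = 3, dt = 0.5),
               0.25)
  # dt -> large converges to x_inf
  expect_equal(arborsim:::rate_update(0.9, alpha = 1, beta = 3, dt = 1e6),
               0.25)
  # bounded in [0, 1] and monotone convergence to x_inf at constant v
  x <- 0.99
  xs <- numeric(50)
  for (i in 1:50) {
    x <- gating_state_update(x, v = -65, dt = 0.1, gate = "n")
    xs[i] <- x
  }
  ninf <- with(rate_functions(-65, "n"), alpha / (alpha + beta))
  expect_true(all(xs >= 0 & xs <= 1))
  expect_true(all(diff(abs(xs - ninf)) <= 1e-12))
})

test_that("gating variables stay in [0, 1] along arbitrary voltage paths", {
  withr::with_seed(7, {
    v_path <- stats::runif(200, -120, 60)
    for (g in c("m", "h", "n")) {
      x <- stats::runif(1)
      for (v in v_path) {
        x <- gating_state_update(x, v, dt = 0.025, gate = g)
        expect_true(x >= 0 && x <= 1)
      }
    }
  })
})

test_that("synaptic conductance accumulates events and decays exponentially", {
  tree <- toy_tree(NA_integer_)
  m <- add_mechanism(neuron_model(tree), "expsyn", 1L, tau = 2)
  pl <- m$placements[[1]]
  pl$states <- list(gsyn = 0)
  pl <- synapse_event_apply(pl, 1L, 0.01)
  expect_equal(pl$states$gsyn, 0.01)
  # two simultaneous events superpose linearly
  pl <- synapse_event_apply(pl, 1L, 0.02)
  expect_equal(pl$states$gsyn, 0.03)
  expect_error(synapse_event_apply(pl, 1L, -0.1), "negative")
  # one 0.025 ms step of passive decay with tau = 2 ms
  upd <- get_mechanism("expsyn")$update
  st <- upd(list(gsyn = 0.01), v = -65, dt = 0.025, p = list(tau = 2))
  expect_equal(st$gsyn, 0.01 * exp(-0.0125), tolerance = 1e-12)
})

test_that("the registry accepts user-defined mechanism types", {
  register_mechanism("test_shunt", "density", character(), c(g = 0.5, e = 0),
                     function(v, s, p, t) list(i = p$g * (v - p$e), g = p$g))
  expect_true("test_shunt" %in% list_mechanisms())
  m <- add_mechanism(neuron_model(toy_tree(NA_integer_)), "test_shunt", 1L)
  cur <- mechanism_current(m$placements[[1]], -10)
  expect_equal(cur$i, -5)
  expect_error(add_mechanism(m, "no_such_type", 1L), "unknown mechanism")
})
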