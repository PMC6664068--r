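# Membrane mechanisms: ionic currents, point processes, and their
# gating-state update contracts.
#
# A mechanism type is a set of vectorized functions operating on
# structure-of-arrays state: `current(v, states, params, t)` returns the
# instantaneous current (nA) and conductance (uS) per instance;
# `update(states, v, dt, params)` advances the state variables by one step;
# `receive(states, idx, weight)` applies a synaptic event.  All per-instance
# parameters are absolute (uS, mV, nA, ms); density-based placement converts
# S/cm^2 through the compartment membrane area.

.mech_registry <- new.env(parent = emptyenv())

#' Register a mechanism type
#'
#' Adds a mechanism type to the package-level registry so it can be placed on
#' neuron models.  User-defined types follow the same contract as the
#' built-ins (`"hh"`, `"pas"`, `"expsyn"`, `"iclamp"`).
#'
#' @param name Type name.
#' @param kind `"density"` or `"point"`.
#' @param states Character vector of state variable names (may be empty).
#' @param params Named numeric vector of default parameter values.
#' @param current `function(v, states, params, t)` returning `list(i =, g =)`
#'   per instance (nA, uS).
#' @param init `function(v, params)` returning the initial named state list,
#'   or `NULL` when the type has no state.
#' @param update `function(states, v, dt, params, method)` returning the
#'   advanced state list, or `NULL`.
#' @param receive `function(states, idx, weight)` applying an event to
#'   instance `idx`, or `NULL` for types that cannot receive events.
#' @param cost Relative per-instance workload used by the analytic cost model.
#' @export
register_mechanism <- function(name, kind, states, params, current,
                               init = NULL, update = NULL, receive = NULL,
                               cost = 1) {
  stopifnot(is.character(name), kind %in% c("density", "point"),
            is.function(current))
  assign(name, list(name = name, kind = kind, states = states,
                    params = params, current = current, init = init,
                    update = update, receive = receive, cost = cost),
         envir = .mech_registry)
  invisible(name)
}

#' Look up a registered mechanism type
#' @param name Type name.
#' @return The registry entry (a list of functions and defaults).
#' @export
get_mechanism <- function(name) {
  if (!exists(name, envir = .mech_registry, inherits = FALSE)) {
    stop(sprintf("unknown mechanism type '%s'", name))
  }
  get(name, envir = .mech_registry, inherits = FALSE)
}

#' @rdname get_mechanism
#' @export
list_mechanisms <- function() sort(ls(.mech_registry))

# x / (exp(x / y) - 1) with the removable singularity at x = 0 evaluated by
# its series limit, as in classic squid-axon rate implementations
vtrap <- function(x, y) {
  small <- abs(x / y) < 1e-6
  out <- numeric(length(x))
  out[small] <- y * (1 - x[small] / y / 2)
  out[!small] <- x[!small] / expm1(x[!small] / y)
  out
}

#' Voltage-dependent rate functions of the classic squid-axon kinetics
#'
#' Opening (`alpha`) and closing (`beta`) rates (1/ms) for the `m`, `h` and
#' `n` gating particles, in the modern voltage convention (rest near -65 mV).
#' Removable singularities of the form `x / (1 - exp(-x/k))` are evaluated by
#' their limit.
#'
#' @param v Membrane potential (mV), vectorized.
#' @param gate One of `"m"`, `"h"`, `"n"`.
#' @return `list(alpha =, beta =)` in 1/ms.
#' @export
rate_functions <- function(v, gate) {
  if (!is.finite(sum(v))) stop("rate_functions: v must be finite")
  switch(gate,
    m = list(alpha = 0.1 * vtrap(-(v + 40), 10),
             beta  = 4 * exp(-(v + 65) / 18)),
    h = list(alpha = 0.07 * exp(-(v + 65) / 20),
             beta  = 1 / (1 + exp(-(v + 35) / 10))),
    n = list(alpha = 0.01 * vtrap(-(v + 55), 10),
             beta  = 0.125 * exp(-(v + 65) / 80)),
    stop(sprintf("rate_functions: unknown gate '%s'", gate))
  )
}

#' Advance a first-order gating variable by one step
#'
#' Analytic exponential update `x' = x + (1 - exp(-dt/tau)) (x_inf - x)`
#' (the default), which is unconditionally stable and keeps `x` in `[0, 1]`
#' for any voltage trajectory; a forward-Euler variant is available for
#' convergence studies.
#'
#' @param x Current state in `[0, 1]`.
#' @param v Membrane potential (mV).
#' @param dt Timestep (ms).
#' @param gate Gate id passed to [rate_functions()].
#' @param method `"cnexp"` (exponential integrator) or `"euler"`.
#' @return Updated state.
#' @export
gating_state_update <- function(x, v, dt, gate, method = c("cnexp", "euler")) {
  method <- match.arg(method)
  ab <- rate_functions(v, gate)
  rate_update(x, ab$alpha, ab$beta, dt, method)
}

rate_update <- function(x, alpha, beta, dt, method = "cnexp") {
  s <- alpha + beta
  xinf <- alpha / s
  if (method == "cnexp") {
    x + (1 - exp(-dt * s)) * (xinf - x)
  } else {
    pmin(1, pmax(0, x + dt * (alpha * (1 - x) - beta * x)))
  }
}

hh_defaults <- c(gna = 0, gk = 0, gl = 0, ena = 50, ek = -77, el = -54.3)

hh_current <- function(v, s, p, t) {
  gna <- p$gna * s$m * s$m * s$m * s$h
  gk <- p$gk * s$n * s$n * s$n * s$n
  list(i = gna * (v - p$ena) + gk * (v - p$ek) + p$gl * (v - p$el),
       g = gna + gk + p$gl)
}

hh_init <- function(v, p) {
  xinf <- function(g) {
    ab <- rate_functions(v, g)
    ab$alpha / (ab$alpha + ab$beta)
  }
  list(m = xinf("m"), h = xinf("h"), n = xinf("n"))
}

hh_update <- function(s, v, dt, p, method = "cnexp") {
  for (g in c("m", "h", "n")) {
    ab <- rate_functions(v, g)
    s[[g]] <- rate_update(s[[g]], ab$alpha, ab$beta, dt, method)
  }
  s
}

pas_current <- function(v, s, p, t) {
  list(i = p$g * (v - p$e), g = p$g)
}

expsyn_current <- function(v, s, p, t) {
  list(i = s$gsyn * (v - p$e), g = s$gsyn)
}

expsyn_update <- function(s, v, dt, p, method = "cnexp") {
  s$gsyn <- s$gsyn * exp(-dt / p$tau)
  s
}

expsyn_receive <- function(s, idx, weight) {
  s$gsyn[idx] <- s$gsyn[idx] + weight
  s
}

iclamp_current <- function(v, s, p, t) {
  on <- (t >= p$onset - 1e-9) & (t < p$onset + p$dur - 1e-9)
  # injected (depolarizing) current enters the RHS with a positive sign,
  # hence the negative membrane-current convention here
  list(i = -p$amp * on, g = numeric(length(v)))
}

register_builtin_mechanisms <- function() {
  register_mechanism("hh", "density", c("m", "h", "n"), hh_defaults,
                     hh_current, hh_init, hh_update, cost = 5)
  register_mechanism("pas", "density", character(), c(g = 0, e = -65),
                     pas_current, cost = 1)
  register_mechanism("expsyn", "point", "gsyn", c(e = 0, tau = 2),
                     expsyn_current,
                     init = function(v, p) list(gsyn = numeric(length(v))),
                     update = expsyn_update, receive = expsyn_receive,
                     cost = 2)
  register_mechanism("iclamp", "point", character(),
                     c(amp = 0, onset = 0, dur = 0), iclamp_current, cost = 1)
}

.onLoad <- function(libname, pkgname) {
  register_builtin_mechanisms()
}

#' Build a neuron model over a compartment tree
#'
#' @param tree A `compartment_tree`.
#' @param v_init Initial membrane potential (mV), default -65.
#' @return A `neuron_model` holding the tree and an (initially empty) list of
#'   mechanism placements.
#' @export
neuron_model <- function(tree, v_init = -65) {
  validate_tree(tree)
  structure(list(tree = tree, v_init = v_init, placements = list()),
            class = "neuron_model")
}

#' Place mechanism instances on a neuron model
#'
#' One instance is one (type, compartment) pair.  Parameters are absolute per
#' instance (uS, nA, mV, ms); scalars are recycled over `comps`.  For density
#' mechanisms, [add_density_mechanism()] converts S/cm^2 through each
#' compartment's membrane area.
#'
#' @param model A `neuron_model`.
#' @param type Registered mechanism type name.
#' @param comps Compartment indices (1-based).
#' @param ... Named parameter overrides (scalar or per-instance vectors).
#' @return The model with the placement appended (placement order is the
#'   deterministic instance creation order).
#' @export
add_mechanism <- function(model, type, comps, ...) {
  stopifnot(inherits(model, "neuron_model"))
  mech <- get_mechanism(type)
  comps <- as.integer(comps)
  if (length(comps) == 0L) return(model)
  if (any(comps < 1L | comps > model$tree$n)) {
    stop("add_mechanism: compartment index out of range")
  }
  ov <- list(...)
  params <- lapply(stats::setNames(names(mech$params), names(mech$params)),
                   function(nm) {
    val <- if (!is.null(ov[[nm]])) ov[[nm]] else unname(mech$params[[nm]])
    rep_len(as.numeric(val), length(comps))
  })
  unknown <- setdiff(names(ov), names(mech$params))
  if (length(unknown) > 0L) {
    stop(sprintf("add_mechanism: unknown parameter(s) %s for type '%s'",
                 paste(unknown, collapse = ", "), type))
  }
  gpar <- intersect(c("g", "gna", "gk", "gl"), names(params))
  if (any(unlist(params[gpar]) < 0)) {
    stop("add_mechanism: conductances must be non-negative")
  }
  model$placements[[length(model$placements) + 1L]] <-
    list(type = type, comps = comps, params = params)
  model
}

#' @rdname add_mechanism
#' @param densities Named densities in S/cm^2 (conductance-like parameters
#'   only); other named arguments pass through unchanged.
#' @export
add_density_mechanism <- function(model, type, comps, densities, ...) {
  area <- pi * model$tree$diam[comps] * model$tree$length[comps] * 1e-8  # cm^2
  conv <- lapply(densities, function(d) d * area * 1e6)                  # uS
  do.call(add_mechanism, c(list(model, type, comps), conv, list(...)))
}

#' Summed mechanism current and conductance per compartment
#'
#' Evaluates one instance set: per-compartment total ionic current
#' `i_n = sum g_i x_i (v_n - E_i)` (nA) and instantaneous conductance
#' `G_n = sum g_i x_i` (uS), where `x_i` is the gate product of the type
#' (`m^3 h` for the sodium current, `n^4` for potassium, 1 for leak).
#'
#' @param placement A placement as stored in a `neuron_model`
#'   (`list(type, comps, params)`), optionally with a `states` element;
#'   states default to their initialization at `v`.
#' @param v Membrane potential vector over all compartments (mV).
#' @param t Time (ms), needed by stimulus mechanisms.
#' @return `list(i =, g =)`: vectors over all compartments.
#' @export
mechanism_current <- function(placement, v, t = 0) {
  mech <- get_mechanism(placement$type)
  vloc <- v[placement$comps]
  states <- placement$states
  if (is.null(states) && !is.null(mech$init)) states <- mech$init(vloc, placement$params)
  cur <- mech$current(vloc, states, placement$params, t)
  i <- numeric(length(v)); g <- numeric(length(v))
  acc <- rowsum_ordered(cbind(cur$i, cur$g), placement$comps)
  i[acc$group] <- acc$sums[, 1]
  g[acc$group] <- acc$sums[, 2]
  list(i = i, g = g)
}

# deterministic grouped sum: groups ascending, within-group accumulation in
# array order (fixed summation order keeps runs bitwise reproducible)
rowsum_ordered <- function(x, group) {
  o <- order(group)                      # stable
  xs <- x[o, , drop = FALSE]; gs <- group[o]
  sums <- rowsum(xs, gs, reorder = FALSE)
  list(group = as.integer(rownames(sums)), sums = sums)
}

#' Apply a synaptic event to a mechanism instance
#'
#' Adds the event weight to the instance's synaptic conductance state;
#' between events the conductance decays exponentially with the synapse time
#' constant (see the `"expsyn"` built-in).  Simultaneous events superpose
#' linearly.
#'
#' @param placement A placement with a `states` element.
#' @param idx Instance index within the placement.
#' @param weight Event weight (uS), must be non-negative.
#' @return The placement with updated states.
#' @export
synapse_event_apply <- function(placement, idx, weight) {
  if (weight < 0) stop("synapse_event_apply: negative weight")
  mech <- get_mechanism(placement$type)
  if (is.null(mech$receive)) {
    stop(sprintf("mechanism '%s' cannot receive events", placement$type))
  }
  if (is.null(placement$states)) {
    placement$states <- mech$init(numeric(length(placement$comps)), placement$params)
  }
  placement$states <- mech$receive(placement$states, idx, weight)
  placement
}
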