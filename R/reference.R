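# Plain array-of-structures reference evaluator: one record per mechanism
# instance, per-instance loops, no padding, no batching.  Used to verify that
# the structure-of-arrays block kernels are layout-invariant; it shares the
# arithmetic (same formulas, same per-compartment summation order) but none
# of the memory organization.

#' Build an array-of-structures reference state for one neuron
#'
#' @param model A `neuron_model`.
#' @param dt Timestep (ms).
#' @return A `reference_state` list: tree arrays plus one record per
#'   mechanism instance.
#' @export
build_reference <- function(model, dt) {
  tree <- model$tree
  inst <- list()
  for (pi in seq_along(model$placements)) {
    pl <- model$placements[[pi]]
    def <- get_mechanism(pl$type)
    for (j in seq_along(pl$comps)) {
      params <- lapply(pl$params, `[`, j)
      states <- if (!is.null(def$init)) def$init(model$v_init, params) else NULL
      inst[[length(inst) + 1L]] <- list(type = pl$type, def = def,
                                        comp = pl$comps[j], params = params,
                                        states = states)
    }
  }
  ga <- numeric(tree$n)
  if (tree$n > 1L) ga[2:tree$n] <- 1 / tree$r_axial[2:tree$n]
  list(tree = tree, dt = dt, v = rep(model$v_init, tree$n), ga = ga,
       instances = inst)
}

#' Advance the reference state by one step
#'
#' @param ref A `reference_state`.
#' @param step 1-based step index.
#' @return The updated state.
#' @export
step_reference <- function(ref, step) {
  tree <- ref$tree
  n <- tree$n
  t_start <- (step - 1) * ref$dt
  v <- ref$v
  i_comp <- numeric(n); g_comp <- numeric(n)
  for (ins in ref$instances) {
    cur <- ins$def$current(v[ins$comp], ins$states, ins$params, t_start)
    i_comp[ins$comp] <- i_comp[ins$comp] + cur$i
    g_comp[ins$comp] <- g_comp[ins$comp] + cur$g
  }
  d <- tree$cap / ref$dt + g_comp + ref$ga
  rhs <- -i_comp
  if (n > 1L) {
    for (i in 2:n) {
      p <- tree$parent[i]
      e <- ref$ga[i] * (v[p] - v[i])
      rhs[i] <- rhs[i] + e
      rhs[p] <- rhs[p] - e
      d[p] <- d[p] + ref$ga[i]
    }
    for (i in n:2) {
      f <- -ref$ga[i] / d[i]
      p <- tree$parent[i]
      d[p] <- d[p] - f * (-ref$ga[i])
      rhs[p] <- rhs[p] - f * rhs[i]
    }
  }
  rhs[1] <- rhs[1] / d[1]
  if (n > 1L) {
    for (i in 2:n) rhs[i] <- (rhs[i] + ref$ga[i] * rhs[tree$parent[i]]) / d[i]
  }
  ref$v <- v + rhs
  for (k in seq_along(ref$instances)) {
    ins <- ref$instances[[k]]
    if (!is.null(ins$def$update)) {
      ref$instances[[k]]$states <-
        ins$def$update(ins$states, ref$v[ins$comp], ref$dt, ins$params)
    }
  }
  ref
}
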