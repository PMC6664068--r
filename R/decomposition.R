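# Decomposition of a compartment tree into a tree of subtrees whose
# per-subtree workload approximates a threshold.
#
# Subtrees attach to their parent subtree only at their root (to a leaf of
# the parent subtree), so cross-subtree synchronization is confined to
# terminal compartment connections: one voltage, one triangulation
# contribution and one substitution value per connection per step.

#' Maximum workload per subtree
#'
#' `k * runtime / cores`: decomposing a neuron whose whole-cell workload is
#' `runtime` with this threshold yields at most `1/k` subtrees per core,
#' the knob that trades multi-core balance against per-subtree vector width.
#'
#' @param runtime Whole-neuron workload (cost units).
#' @param cores_count Number of compute cores.
#' @param k Scaling constant (> 0); see [default_k()].
#' @return The workload threshold.
#' @export
max_work <- function(runtime, cores_count, k) {
  if (runtime <= 0 || cores_count < 1 || k <= 0) {
    stop("max_work: runtime, cores_count and k must be positive")
  }
  k * runtime / cores_count
}

#' Default subtree-granularity constant per core count
#'
#' Interpolates the empirical optimum of the granularity constant `k` over
#' core counts (0.8 at 1-2 cores up to 2 beyond 16 cores).
#'
#' @param cores_count Number of cores.
#' @return k.
#' @export
default_k <- function(cores_count) {
  stats::approx(x = c(1, 2, 4, 8, 16, 17),
                y = c(0.8, 0.8, 1, 1.5, 1.8, 2),
                xout = pmin(cores_count, 17), rule = 2)$y
}

#' Analytic / measured cost model for compartments
#'
#' @param mode `"analytic"` (deterministic: base cost per compartment plus a
#'   per-instance cost per mechanism type) or `"measured"` (mean wall time of
#'   repeated stepping runs on the subtree's memory block).
#' @param base_cost Cost per compartment (analytic mode).
#' @param mech_costs Named per-instance costs; defaults to each registered
#'   type's `cost`.
#' @param reps,tstop Measurement protocol (measured mode): number of sample
#'   runs and simulated span (ms) per run.
#' @param dt Timestep used by the measurement kernel (ms).
#' @return A `cost_model` list.
#' @export
cost_model <- function(mode = c("analytic", "measured"), base_cost = 1,
                       mech_costs = NULL, reps = 10, tstop = 100, dt = 0.025) {
  mode <- match.arg(mode)
  if (base_cost <= 0) stop("cost_model: base_cost must be positive")
  structure(list(mode = mode, base_cost = base_cost, mech_costs = mech_costs,
                 reps = reps, tstop = tstop, dt = dt),
            class = "cost_model")
}

#' Per-compartment analytic costs of a model
#'
#' Base cost per compartment plus the per-instance cost of every mechanism
#' placed on it.
#'
#' @param model A `neuron_model`.
#' @param cm A [cost_model()].
#' @return Numeric cost vector over compartments.
#' @export
compartment_costs <- function(model, cm = cost_model()) {
  costs <- rep(cm$base_cost, model$tree$n)
  for (pl in model$placements) {
    c_i <- if (!is.null(cm$mech_costs) && !is.na(cm$mech_costs[pl$type])) {
      cm$mech_costs[[pl$type]]
    } else {
      get_mechanism(pl$type)$cost
    }
    for (comp in pl$comps) costs[comp] <- costs[comp] + c_i
  }
  costs
}

#' Cluster a compartment tree into a tree of subtrees
#'
#' Greedy root-to-leaves traversal: the current subtree grows along the
#' depth-first compartment order while its accumulated cost stays within the
#' threshold; a compartment that would exceed it starts the next subtree.  At
#' a bifurcation the branches are all-or-none: they stay inside the current
#' subtree only if the entire remaining subtree below the bifurcation fits
#' the remaining budget, otherwise each branch starts an independent subtree
#' (this guarantees the root/leaf-only attachment rule).  Two kinds of
#' subtree may legitimately miss the threshold: a forced singleton (a single
#' compartment costlier than the threshold) and terminal leftovers that do
#' not aggregate enough cost.
#'
#' @param tree A `compartment_tree`.
#' @param costs Positive per-compartment costs (see [compartment_costs()]).
#' @param threshold Positive workload threshold (see [max_work()]).
#' @return A `decomposition_plan`: `list(subtrees =, threshold =, n =)`,
#'   where each subtree has `id`, `members` (ascending compartment indices),
#'   `root`, `parent` (subtree id or `NA`), `parent_comp` (connecting
#'   compartment in the parent subtree) and `cost`.
#' @export
cluster_subtrees <- function(tree, costs, threshold) {
  validate_tree(tree)
  n <- tree$n
  stopifnot(length(costs) == n)
  if (any(costs <= 0)) stop("cluster_subtrees: costs must be positive")
  if (threshold <= 0) stop("cluster_subtrees: threshold must be positive")

  children <- tree_children(tree)
  tot <- costs
  if (n > 1L) {
    for (i in n:2) tot[tree$parent[i]] <- tot[tree$parent[i]] + tot[i]
  }
  descendants <- function(node) {
    out <- integer(0); stack <- node
    while (length(stack) > 0L) {
      cur <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      out <- c(out, cur)
      stack <- c(stack, children[[cur]])
    }
    out
  }

  subtrees <- list()
  # LIFO of pending branch starts; children pushed in reverse so lower
  # indices are clustered first (deterministic subtree ids)
  pending <- list(list(start = 1L, parent = NA_integer_,
                       parent_comp = NA_integer_))
  while (length(pending) > 0L) {
    job <- pending[[length(pending)]]
    pending[[length(pending)]] <- NULL
    sid <- length(subtrees) + 1L
    members <- integer(0)
    acc <- 0
    node <- job$start
    last <- NA_integer_
    repeat {
      if (length(members) > 0L && acc + costs[node] > threshold) {
        pending[[length(pending) + 1L]] <-
          list(start = node, parent = sid, parent_comp = last)
        break
      }
      members <- c(members, node)
      acc <- acc + costs[node]
      last <- node
      ch <- children[[node]]
      if (length(ch) == 0L) break
      if (length(ch) == 1L) { node <- ch; next }
      if (acc + sum(tot[ch]) <= threshold) {
        for (c_ in ch) members <- c(members, descendants(c_))
        acc <- acc + sum(tot[ch])
        break
      }
      for (c_ in rev(ch)) {
        pending[[length(pending) + 1L]] <-
          list(start = c_, parent = sid, parent_comp = node)
      }
      break
    }
    subtrees[[sid]] <- list(id = sid, members = sort(members),
                            root = job$start, parent = job$parent,
                            parent_comp = job$parent_comp,
                            cost = sum(costs[members]))
  }
  structure(list(subtrees = subtrees, threshold = threshold, n = n),
            class = "decomposition_plan")
}

#' @export
print.decomposition_plan <- function(x, ...) {
  cat(sprintf("decomposition_plan: %d subtrees over %d compartments (threshold %.3g)\n",
              length(x$subtrees), x$n, x$threshold))
  invisible(x)
}

#' Workload of one subtree
#'
#' Analytic mode sums the per-compartment costs deterministically; measured
#' mode builds the subtree's structure-of-arrays block and reports the mean
#' wall time of `reps` stepping runs of `tstop` ms each.
#'
#' @param subtree One subtree entry of a `decomposition_plan`.
#' @param model The `neuron_model`.
#' @param cm A [cost_model()].
#' @return The cost (analytic units, or seconds in measured mode).
#' @export
measure_workload <- function(subtree, model, cm = cost_model()) {
  if (cm$mode == "analytic") {
    return(sum(compartment_costs(model, cm)[subtree$members]))
  }
  bl <- build_layout(subtree, model)
  block_prepare(bl, cm$dt)
  nstep <- max(1L, round(cm$tstop / cm$dt))
  times <- vapply(seq_len(cm$reps), function(r) {
    block_reset(bl, model$v_init)
    as.numeric(system.time({
      for (s in seq_len(nstep)) {
        t0 <- (s - 1) * cm$dt
        block_phase_setup(bl, t0)
        block_phase_triangulate(bl)
        block_phase_substitute(bl)
        block_phase_update(bl, cm$dt)
      }
    })[["elapsed"]])
  }, 1)
  mean(times)
}

#' Validate a decomposition plan
#'
#' Checks that subtree member sets partition the compartments, that each
#' subtree is a connected subgraph rooted at its `root`, that every
#' cross-subtree edge joins a subtree root to a leaf of its parent subtree,
#' and that subtree costs respect the threshold (forced singletons and
#' terminal leftovers are flagged as exceptions, not failures).
#'
#' @param plan A `decomposition_plan`.
#' @param tree The `compartment_tree` it covers.
#' @param costs Optional per-compartment costs for the threshold check.
#' @return `list(valid =, violations =, exceptions =)`.
#' @export
validate_plan <- function(plan, tree, costs = NULL) {
  violations <- character(0)
  exceptions <- character(0)
  subs <- plan$subtrees
  all_members <- unlist(lapply(subs, `[[`, "members"))
  if (length(all_members) != tree$n || anyDuplicated(all_members) ||
      !setequal(all_members, seq_len(tree$n))) {
    violations <- c(violations, "members do not partition the compartments")
  }
  owner <- integer(tree$n)
  for (s in subs) owner[s$members] <- s$id
  has_child_subtree <- rep(FALSE, length(subs))
  for (s in subs) {
    inset <- logical(tree$n); inset[s$members] <- TRUE
    internal_par <- tree$parent[setdiff(s$members, s$root)]
    if (any(is.na(internal_par)) || !all(inset[internal_par])) {
      violations <- c(violations,
                      sprintf("subtree %d is not connected through its root", s$id))
    }
    if (!is.na(s$parent)) {
      has_child_subtree[s$parent] <- TRUE
      pc <- s$parent_comp
      if (!(pc %in% subs[[s$parent]]$members)) {
        violations <- c(violations,
                        sprintf("subtree %d attaches outside its parent", s$id))
      }
      if (!identical(tree$parent[s$root], pc)) {
        violations <- c(violations,
                        sprintf("subtree %d root does not hang below its attachment", s$id))
      }
      kids <- which(!is.na(tree$parent) & tree$parent == pc)
      if (any(owner[kids] == owner[pc])) {
        violations <- c(violations,
                        sprintf("attachment compartment %d is not a leaf of subtree %d",
                                pc, owner[pc]))
      }
    }
  }
  if (!is.null(costs)) {
    for (s in subs) {
      cost <- sum(costs[s$members])
      if (cost > plan$threshold) {
        if (length(s$members) == 1L) {
          exceptions <- c(exceptions, sprintf("subtree %d: forced singleton", s$id))
        } else {
          violations <- c(violations,
                          sprintf("subtree %d exceeds the threshold", s$id))
        }
      } else if (cost < plan$threshold && !has_child_subtree[s$id] &&
                 length(subs) > 1L) {
        exceptions <- c(exceptions,
                        sprintf("subtree %d: terminal leftover below threshold", s$id))
      }
    }
  }
  list(valid = length(violations) == 0L, violations = violations,
       exceptions = exceptions)
}

#' Serialize a decomposition plan to JSON
#' @param plan A `decomposition_plan`.
#' @return JSON text.
#' @export
plan_to_json <- function(plan) {
  jsonlite::toJSON(list(
    threshold = plan$threshold, n = plan$n,
    subtrees = lapply(plan$subtrees, function(s) {
      list(id = s$id, members = s$members, root = s$root,
           parent = if (is.na(s$parent)) NULL else s$parent,
           parent_comp = if (is.na(s$parent_comp)) NULL else s$parent_comp,
           cost = s$cost)
    })
  ), digits = NA, auto_unbox = TRUE)
}
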