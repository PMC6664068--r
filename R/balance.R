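# Static load balancing of neurons across localities: longest-processing-time
# (LPT) assignment of whole neurons, with delegation of terminal subtree
# groups when a locality exceeds the mean-per-locality threshold.  Delegated
# groups communicate only with the neuron's home locality (a star, never a
# chain), so no neuron involves transitive cross-locality traffic.

#' Longest-processing-time assignment
#'
#' Sorts the weights in descending order and assigns each to the currently
#' least-loaded locality (ties: lowest locality id).  The makespan is within
#' `4/3 - 1/(3m)` of optimal.
#'
#' @param weights Positive unit weights (cost units).
#' @param m Number of localities (>= 1).
#' @return `list(assignment =, loads =, makespan =)`; `assignment[i]` is the
#'   locality of `weights[i]`.
#' @export
lpt_assign <- function(weights, m) {
  if (m < 1) stop("lpt_assign: m must be >= 1")
  if (length(weights) == 0L) {
    return(list(assignment = integer(0), loads = numeric(m), makespan = 0))
  }
  if (any(weights <= 0)) stop("lpt_assign: weights must be positive")
  loads <- numeric(m)
  assignment <- integer(length(weights))
  for (i in order(-weights)) {          # stable: ties keep input order
    loc <- which.min(loads)             # ties: lowest locality id
    assignment[i] <- loc
    loads[loc] <- loads[loc] + weights[i]
  }
  list(assignment = assignment, loads = loads, makespan = max(loads))
}

#' Per-locality capacity threshold
#'
#' Mean workload per locality scaled by a tolerance (default 10%); a locality
#' loaded beyond this sheds terminal subtree groups.
#'
#' @param total Total workload.
#' @param m Localities.
#' @param tolerance Fractional tolerance, default 0.10.
#' @return The threshold.
#' @export
compute_locality_threshold <- function(total, m, tolerance = 0.10) {
  if (m < 1) stop("compute_locality_threshold: m must be >= 1")
  (total / m) * (1 + tolerance)
}

#' Terminal subtree groups of a decomposition plan
#'
#' A delegable group is the descendant closure of a non-root subtree: a
#' connected set of subtrees whose removal leaves the rest of the neuron
#' connected.  Shedding only such leaf-ward closures keeps every delegated
#' unit's single channel partner (the parent of the group's root) on the home
#' locality.
#'
#' @param plan A `decomposition_plan`.
#' @param costs Per-subtree costs; defaults to the plan's stored costs.
#' @return A `neuron_weight` list: `total`, and `groups` (data frame with
#'   `root_subtree`, `cost`, `size` and the member subtree ids in
#'   `members`).
#' @export
neuron_subtree_groups <- function(plan, costs = NULL) {
  subs <- plan$subtrees
  if (is.null(costs)) costs <- vapply(subs, `[[`, 1, "cost")
  kids <- vector("list", length(subs))
  for (s in subs) {
    if (!is.na(s$parent)) kids[[s$parent]] <- c(kids[[s$parent]], s$id)
  }
  closure <- function(id) {
    out <- integer(0); stack <- id
    while (length(stack) > 0L) {
      cur <- stack[[length(stack)]]; stack <- stack[-length(stack)]
      out <- c(out, cur); stack <- c(stack, kids[[cur]])
    }
    sort(out)
  }
  gr <- lapply(subs[-1], function(s) {
    mem <- closure(s$id)
    list(root_subtree = s$id, parent_subtree = s$parent,
         cost = sum(costs[mem]), size = length(mem), members = mem)
  })
  structure(list(total = sum(costs), groups = gr,
                 n_subtrees = length(subs)),
            class = "neuron_weight")
}

#' Balance neurons across localities with terminal-group splitting
#'
#' LPT over whole neurons first; then any locality loaded above the
#' [compute_locality_threshold()] sheds terminal subtree groups of its most
#' costly neurons - largest group first - to the least-loaded locality, until
#' it fits or no delegable group remains.  A group is delegable only if it is
#' disjoint from (and not an ancestor of) every group already delegated from
#' the same neuron, which keeps each neuron's cross-locality channels a star
#' centred on its home locality.  A single group larger than the threshold is
#' placed with a warning.
#'
#' @param weights List of `neuron_weight`s (see [neuron_subtree_groups()]).
#' @param m Number of localities.
#' @param tolerance Threshold tolerance, default 0.10.
#' @return A `balance_assignment`: `home` (locality per neuron),
#'   `delegations` (data frame `neuron`, `root_subtree`, `locality`,
#'   `cost`), `loads`, `threshold`, `makespan`.
#' @export
balance_with_splitting <- function(weights, m, tolerance = 0.10) {
  totals <- vapply(weights, `[[`, 1, "total")
  base <- lpt_assign(totals, m)
  home <- base$assignment
  loads <- base$loads
  threshold <- compute_locality_threshold(sum(totals), m, tolerance)
  delegations <- list()
  shed <- lapply(weights, function(w) integer(0))  # delegated subtrees per neuron

  if (m > 1L) {
    repeat {
      loc <- which.max(loads)
      if (loads[loc] <= threshold) break
      # neurons on this locality by descending remaining cost
      on_loc <- which(home == loc)
      rem_cost <- vapply(on_loc, function(nid) {
        totals[nid] - sum(vapply(delegations, function(d)
          if (d$neuron == nid) d$cost else 0, 1))
      }, 1)
      moved <- FALSE
      for (nid in on_loc[order(-rem_cost)]) {
        w <- weights[[nid]]
        elig <- Filter(function(g) {
          length(intersect(g$members, shed[[nid]])) == 0L
        }, w$groups)
        if (length(elig) == 0L) next
        o <- order(-vapply(elig, `[[`, 1, "cost"))
        g <- elig[[o[1]]]
        dest <- which.min(loads)
        if (dest == loc) next           # nowhere lighter to move to
        if (g$cost > threshold) {
          warning(sprintf(
            "neuron %d: delegated group at subtree %d exceeds the locality threshold",
            nid, g$root_subtree))
        }
        loads[loc] <- loads[loc] - g$cost
        loads[dest] <- loads[dest] + g$cost
        shed[[nid]] <- c(shed[[nid]], g$members)
        delegations[[length(delegations) + 1L]] <-
          list(neuron = nid, root_subtree = g$root_subtree,
               locality = dest, cost = g$cost, members = list(g$members))
        moved <- TRUE
        break
      }
      if (!moved) break                 # nothing left to shed
    }
  }
  del_df <- if (length(delegations) > 0L) {
    data.frame(neuron = vapply(delegations, `[[`, 1, "neuron"),
               root_subtree = vapply(delegations, `[[`, 1, "root_subtree"),
               locality = vapply(delegations, `[[`, 1, "locality"),
               cost = vapply(delegations, `[[`, 1, "cost"))
  } else {
    data.frame(neuron = integer(), root_subtree = integer(),
               locality = integer(), cost = numeric())
  }
  members <- lapply(delegations, function(d) d$members[[1]])
  structure(list(home = home, delegations = del_df,
                 delegation_members = members, loads = loads,
                 threshold = threshold, makespan = max(loads), m = m),
            class = "balance_assignment")
}

#' @export
print.balance_assignment <- function(x, ...) {
  cat(sprintf("balance_assignment: %d neurons on %d localities, makespan %.3g (threshold %.3g), %d delegations\n",
              length(x$home), x$m, x$makespan, x$threshold,
              nrow(x$delegations)))
  invisible(x)
}

#' Per-subtree locality vectors of an assignment
#'
#' Expands a `balance_assignment` to the form consumed by
#' [run_network_async()]: one integer vector per neuron giving the locality
#' of each of its subtrees (home everywhere except delegated closures).
#'
#' @param assignment A `balance_assignment`.
#' @param weights The `neuron_weight` list it was computed from.
#' @return List of integer vectors.
#' @export
assignment_localities <- function(assignment, weights) {
  out <- lapply(seq_along(weights), function(nid) {
    rep(assignment$home[nid], weights[[nid]]$n_subtrees)
  })
  if (nrow(assignment$delegations) > 0L) {
    for (i in seq_len(nrow(assignment$delegations))) {
      nid <- assignment$delegations$neuron[i]
      out[[nid]][assignment$delegation_members[[i]]] <-
        assignment$delegations$locality[i]
    }
  }
  out
}

#' Load report of an assignment
#' @param assignment A `balance_assignment`.
#' @return List with per-locality loads, imbalance fraction and split count.
#' @export
load_report <- function(assignment) {
  loads <- assignment$loads
  list(loads = loads,
       imbalance = if (mean(loads) > 0) max(loads) / mean(loads) - 1 else 0,
       splits = nrow(assignment$delegations),
       makespan = assignment$makespan)
}
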