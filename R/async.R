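# Producer-consumer execution of the tree of subtrees.
#
# Every cross-subtree connection carries exactly three values per timestep
# through a shared channel: the child root's voltage (consumed by the
# parent's matrix set-up), the child's triangulation contribution to the
# parent's diagonal and right-hand side, and the parent connecting
# compartment's dV (consumed by the child's substitution and by its cached
# boundary voltage for the next step).  Subtree stepping is divided into
# three kernels (publish voltage / set-up + triangulate / substitute +
# update) executed by a deterministic dependency-gated scheduler: a task
# becomes ready only when all its expected contributions for the step have
# been produced, ready tasks are consumed FIFO by a pool of `workers`
# simulated workers, and blocked tasks consume no worker.  Task values are a
# pure function of the dataflow, so results are bitwise identical for any
# worker count and any locality assignment.

new_channel <- function(neuron, child_id, parent_id, parent_row, ga,
                        v_init, src_loc = 1L, dst_loc = 1L) {
  ch <- new.env(parent = emptyenv())
  ch$neuron <- neuron
  ch$child_id <- child_id; ch$parent_id <- parent_id
  ch$parent_row <- parent_row
  ch$ga <- ga
  ch$vup <- v_init; ch$tri_dd <- 0; ch$tri_drhs <- 0; ch$sub_dv <- 0
  ch$n_vup <- 0L; ch$n_tri <- 0L; ch$n_sub <- 0L
  ch$src_loc <- as.integer(src_loc); ch$dst_loc <- as.integer(dst_loc)
  ch
}

# build blocks + channels for one neuron's plan; returns list(blocks, channels)
wire_plan <- function(plan, model, width, spike_threshold, neuron_id = 1L,
                      localities = NULL) {
  subs <- plan$subtrees
  blocks <- lapply(subs, function(s) {
    bl <- build_layout(s, model, width = width)
    bl$spike_threshold <- spike_threshold
    bl$neuron <- neuron_id
    bl
  })
  channels <- list()
  for (s in subs) {
    if (is.na(s$parent)) next
    pb <- blocks[[s$parent]]
    cb <- blocks[[s$id]]
    parent_row <- match(s$parent_comp, pb$comps)
    loc_c <- if (is.null(localities)) 1L else localities[s$id]
    loc_p <- if (is.null(localities)) 1L else localities[s$parent]
    ch <- new_channel(neuron_id, s$id, s$parent, parent_row,
                      ga = cb$ga[1], v_init = model$v_init,
                      src_loc = loc_c, dst_loc = loc_p)
    cb$parent_channel <- ch
    pb$boundary_children <- c(pb$boundary_children,
                              list(list(row = parent_row, channel = ch)))
    channels[[length(channels) + 1L]] <- ch
  }
  # boundary children in ascending child subtree id: deterministic reduction
  for (bl in blocks) {
    if (length(bl$boundary_children) > 1L) {
      o <- order(vapply(bl$boundary_children,
                        function(bc) bc$channel$child_id, 1L))
      bl$boundary_children <- bl$boundary_children[o]
    }
  }
  list(blocks = blocks, channels = channels)
}

#' Advance one subtree by one step under the channel protocol
#'
#' Runs the three kernels of the per-step protocol in order for a single
#' subtree: publish the root voltage, set up and triangulate (consuming the
#' children's voltages and triangulation contributions), substitute
#' (consuming the parent's dV) and update states.  With no channels this
#' degenerates to [advance_step()].  Intended for serial single-subtree use
#' and for tests; the scheduler in [run_network_async()] interleaves the same
#' kernels across subtrees.
#'
#' @param block A prepared `subtree_block`.
#' @param step 1-based step index.
#' @return The block, invisibly.
#' @export
step_subtree <- function(block, step) {
  task_publish_voltage(block)
  task_setup_triangulate(block, step)
  task_substitute_update(block, step)
  invisible(block)
}

task_publish_voltage <- function(bl) {
  ch <- bl$parent_channel
  if (!is.null(ch)) {
    ch$vup <- bl$v[1]
    ch$n_vup <- ch$n_vup + 1L
  }
  invisible(NULL)
}

task_setup_triangulate <- function(bl, step) {
  block_phase_setup(bl, (step - 1) * bl$dt)
  boundary <- block_phase_triangulate(bl)
  ch <- bl$parent_channel
  if (!is.null(ch)) {
    ch$tri_dd <- boundary$delta_d
    ch$tri_drhs <- boundary$delta_rhs
    ch$n_tri <- ch$n_tri + 1L
  }
  invisible(NULL)
}

task_substitute_update <- function(bl, step) {
  parent_dv <- if (!is.null(bl$parent_channel)) bl$parent_channel$sub_dv else NULL
  block_phase_substitute(bl, parent_dv)
  for (bc in bl$boundary_children) {
    bc$channel$sub_dv <- bl$rhs[bc$row]
    bc$channel$n_sub <- bc$channel$n_sub + 1L
  }
  block_phase_update(bl, step * bl$dt, parent_dv)
  invisible(NULL)
}

#' Run a network on the asynchronous subtree runtime
#'
#' Decomposes every neuron into subtrees (unless plans are supplied), builds
#' their structure-of-arrays blocks and channels, and executes all subtree
#' step kernels under the dependency-gated scheduler.  Neurons synchronize at
#' every communication boundary through a barrier at which spikes are
#' exchanged.  Voltage traces and rasters are bitwise independent of
#' `workers` and of the locality assignment.
#'
#' @param network A `neural_network`.
#' @param clock A `simulation_clock` (its `t_synch` is tightened to the
#'   minimum delay).
#' @param plans Optional list of `decomposition_plan`s, one per neuron.
#' @param workers Simulated worker count (>= 1).
#' @param cores_count Core count used to derive the default decomposition
#'   threshold; defaults to `workers`.
#' @param k Granularity constant; defaults to [default_k()] of `cores_count`.
#' @param assignment Optional locality assignment: a list with one integer
#'   vector per neuron mapping its subtree ids to locality ids (see
#'   [balance_with_splitting()] / [assignment_localities()]).
#' @param record,width,spike_threshold As in [run_simulation()].
#' @return A `simulation_result`; `stats` additionally holds the channel
#'   message counters (`channels` data frame with `n_vup`, `n_tri`, `n_sub`
#'   per connection), `tasks_executed` and `subtree_steps`.
#' @export
run_network_async <- function(network, clock, plans = NULL, workers = 1L,
                              cores_count = workers, k = NULL,
                              assignment = NULL,
                              record = c("soma", "all"), width = 8L,
                              spike_threshold = -20) {
  record <- match.arg(record)
  if (workers < 1L) stop("run_network_async: workers must be >= 1")
  t_synch <- derive_t_synch(network, clock$dt, clock$tstop)
  clock <- simulation_clock(clock$dt, clock$tstop, t_synch, clock$t_io)

  if (is.null(plans)) {
    if (is.null(k)) k <- default_k(cores_count)
    plans <- lapply(network$models, function(m) {
      costs <- compartment_costs(m)
      cluster_subtrees(m$tree, costs, max_work(sum(costs), cores_count, k))
    })
  }
  blocks <- list(); channels <- list(); neuron_of <- integer(0)
  soma_block <- integer(length(network$models))
  for (nid in seq_along(network$models)) {
    loc <- if (is.null(assignment)) NULL else assignment[[nid]]
    wired <- wire_plan(plans[[nid]], network$models[[nid]], width,
                       spike_threshold, nid, loc)
    for (bl in wired$blocks) {
      blocks[[length(blocks) + 1L]] <- bl
      neuron_of <- c(neuron_of, nid)
      if (!is.na(bl$soma_local)) soma_block[nid] <- length(blocks)
    }
    channels <- c(channels, wired$channels)
  }
  nb <- length(blocks)
  for (bl in blocks) block_prepare(bl, clock$dt)

  # static task topology: global block index of each parent / children
  gid_base <- c(0L, cumsum(vapply(plans, function(p) length(p$subtrees), 1L)))
  parent_gid <- rep(NA_integer_, nb)
  children_gids <- vector("list", nb)
  for (g in seq_len(nb)) {
    bl <- blocks[[g]]
    if (!is.null(bl$parent_channel)) {
      pg <- gid_base[neuron_of[g]] + bl$parent_channel$parent_id
      parent_gid[g] <- pg
      children_gids[[pg]] <- c(children_gids[[pg]], g)
    }
  }

  rec <- make_recorder(blocks_as_states(blocks, neuron_of, network), network,
                       clock, record)
  spikes <- list()
  total_scheduled <- 0L
  tasks_executed <- 0L
  subtree_steps <- 0L
  nwin <- if (clock$n_steps == 0L) 0L else
    ceiling(clock$n_steps / clock$steps_per_window)

  for (w in seq_len(nwin)) {
    s0 <- (w - 1L) * clock$steps_per_window + 1L
    s1 <- min(w * clock$steps_per_window, clock$n_steps)
    nsteps <- s1 - s0 + 1L
    ntasks <- nsteps * nb * 3L
    # remaining unmet dependencies per task; task id encodes (step, block, phase)
    tid_of <- function(srel, g, ph) ((srel * nb) + (g - 1L)) * 3L + ph
    remaining <- integer(ntasks)
    for (srel in 0:(nsteps - 1L)) {
      for (g in seq_len(nb)) {
        prev <- if (srel > 0L) 1L else 0L
        remaining[tid_of(srel, g, 1L)] <- prev
        remaining[tid_of(srel, g, 2L)] <- prev + 2L * length(children_gids[[g]])
        remaining[tid_of(srel, g, 3L)] <- 1L + !is.na(parent_gid[g])
      }
    }
    queue <- which(remaining == 0L)
    executed <- 0L
    while (executed < ntasks) {
      if (length(queue) == 0L) {
        blocked <- which(remaining > 0L)[1]
        dec <- blocked - 1L
        stop(sprintf(
          "deadlock: block %d phase %d of step %d is blocked on an unset placeholder",
          (dec %/% 3L) %% nb + 1L, dec %% 3L + 1L,
          s0 + (dec %/% 3L) %/% nb))
      }
      take <- seq_len(min(workers, length(queue)))
      batch <- queue[take]
      queue <- queue[-take]
      newly <- integer(0)
      for (tid in batch) {
        dec <- tid - 1L
        ph <- dec %% 3L + 1L
        g <- (dec %/% 3L) %% nb + 1L
        srel <- (dec %/% 3L) %/% nb
        s <- s0 + srel
        bl <- blocks[[g]]
        deps <- integer(0)
        if (ph == 1L) {
          task_publish_voltage(bl)
          if (!is.na(parent_gid[g])) deps <- tid_of(srel, parent_gid[g], 2L)
        } else if (ph == 2L) {
          task_setup_triangulate(bl, s)
          deps <- tid_of(srel, g, 3L)
          if (!is.na(parent_gid[g])) {
            deps <- c(deps, tid_of(srel, parent_gid[g], 2L))
          }
        } else {
          task_substitute_update(bl, s)
          record_sample(rec, neuron_of[g], bl, s)
          subtree_steps <- subtree_steps + 1L
          if (srel < nsteps - 1L) {
            deps <- c(tid_of(srel + 1L, g, 1L), tid_of(srel + 1L, g, 2L))
          }
          kids <- children_gids[[g]]
          if (length(kids) > 0L) deps <- c(deps, tid_of(srel, kids, 3L))
        }
        for (dd in deps) {
          remaining[dd] <- remaining[dd] - 1L
          if (remaining[dd] == 0L) newly <- c(newly, dd)
        }
        remaining[tid] <- -1L
      }
      executed <- executed + length(batch)
      tasks_executed <- tasks_executed + length(batch)
      queue <- c(queue, sort(newly))
    }
    # barrier: all neurons reached the window end; exchange spikes
    win_spikes <- list()
    for (nid in seq_along(network$models)) {
      g <- soma_block[nid]
      if (g == 0L) next
      bl <- blocks[[g]]
      if (length(bl$spikes) > 0L) {
        win_spikes[[length(win_spikes) + 1L]] <-
          data.frame(time = bl$spikes, neuron = nid)
        bl$spikes <- numeric(0)
      }
    }
    win_spikes <- if (length(win_spikes) > 0L) do.call(rbind, win_spikes) else
      data.frame(time = numeric(), neuron = integer())
    win_spikes <- win_spikes[order(win_spikes$time, win_spikes$neuron), ,
                             drop = FALSE]
    spikes[[w]] <- win_spikes
    ev <- exchange_spikes(win_spikes, network)
    total_scheduled <- total_scheduled + nrow(ev)
    if (nrow(ev) > 0L) {
      for (nid in unique(ev$target)) {
        rows <- ev[ev$target == nid, , drop = FALSE]
        for (g in which(neuron_of == nid)) {
          block_enqueue_events(blocks[[g]], rows)
        }
      }
    }
  }

  spikes <- if (length(spikes) > 0L) do.call(rbind, spikes) else
    data.frame(time = numeric(), neuron = integer())
  chan_df <- if (length(channels) > 0L) {
    data.frame(
      neuron = vapply(channels, function(c) c$neuron, 1L),
      child = vapply(channels, function(c) c$child_id, 1L),
      parent = vapply(channels, function(c) c$parent_id, 1L),
      n_vup = vapply(channels, function(c) c$n_vup, 1L),
      n_tri = vapply(channels, function(c) c$n_tri, 1L),
      n_sub = vapply(channels, function(c) c$n_sub, 1L),
      src_loc = vapply(channels, function(c) c$src_loc, 1L),
      dst_loc = vapply(channels, function(c) c$dst_loc, 1L)
    )
  } else {
    data.frame(neuron = integer(), child = integer(), parent = integer(),
               n_vup = integer(), n_tri = integer(), n_sub = integer(),
               src_loc = integer(), dst_loc = integer())
  }
  structure(list(
    spikes = spikes,
    traces = rec$traces,
    times = rec$times,
    stats = list(events_scheduled = total_scheduled,
                 events_delivered = sum(vapply(blocks, function(b) b$delivered, 1L)),
                 deliveries = collect_deliveries(blocks),
                 steps = clock$n_steps,
                 tasks_executed = tasks_executed,
                 subtree_steps = subtree_steps,
                 n_subtrees = nb,
                 channels = chan_df)
  ), class = "simulation_result")
}

# adaptor so the recorder can size per-neuron trace matrices
blocks_as_states <- function(blocks, neuron_of, network) {
  lapply(seq_along(network$models), function(nid) {
    list(n = network$models[[nid]]$tree$n)
  })
}
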