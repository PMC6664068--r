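# Fixed-step staggered simulation loop: event delivery, current and matrix
# set-up, tree solve, voltage update, gating-state update, spike detection,
# and periodic spike exchange / trace output.
#
# Time within the loop is always computed as step_index * dt (never
# accumulated), so boundary comparisons are reproducible.

#' Simulation clock
#'
#' @param dt Timestep (ms), default 0.025.
#' @param tstop End time (ms).
#' @param t_synch Communication step (ms): spikes are exchanged at these
#'   boundaries.  Must be a positive integer multiple of `dt` and must not
#'   exceed the network's minimum synaptic delay.  Defaults to `tstop`
#'   (a single window) and is tightened by the runners when the network has
#'   synapses.
#' @param t_io Trace output interval (ms), default 0.1; use `dt` to record
#'   every step.
#' @return A `simulation_clock` list, with `n_steps` and `steps_per_window`
#'   precomputed.
#' @export
simulation_clock <- function(dt = 0.025, tstop = 100, t_synch = NULL,
                             t_io = 0.1) {
  if (dt <= 0) stop("simulation_clock: dt must be positive")
  if (tstop < 0) stop("simulation_clock: tstop must be non-negative")
  n_steps <- as.integer(round(tstop / dt))
  if (is.null(t_synch)) t_synch <- tstop
  spw <- if (tstop == 0) 0L else as.integer(round(t_synch / dt))
  if (tstop > 0) {
    if (spw < 1L || abs(spw * dt - t_synch) > 1e-9) {
      stop("simulation_clock: t_synch must be a positive multiple of dt")
    }
  }
  io_every <- max(1L, as.integer(round(t_io / dt)))
  structure(list(dt = dt, tstop = tstop, t_synch = t_synch, t_io = t_io,
                 n_steps = n_steps, steps_per_window = spw,
                 io_every = io_every),
            class = "simulation_clock")
}

# T_synch = minimum delay rounded down to a multiple of dt
derive_t_synch <- function(network, dt, tstop) {
  if (!is.finite(network$min_delay)) return(tstop)
  ts <- floor(network$min_delay / dt + 1e-9) * dt
  if (ts < dt) {
    stop("connection delay smaller than one timestep: no valid communication step")
  }
  min(ts, tstop)
}

#' Threshold-crossing spike detection
#'
#' A spike is emitted iff the somatic voltage crosses the threshold upward
#' during the step (`v_prev < threshold <= v_new`); staying above the
#' threshold does not re-trigger.  The spike time is the step-end time.
#'
#' @param v_prev,v_new Somatic voltage before/after the step (mV).
#' @param threshold Detection threshold (mV), default -20.
#' @param t Step-end time (ms).
#' @return `t` if a spike was detected, otherwise `NULL`.
#' @export
detect_spike <- function(v_prev, v_new, threshold = -20, t = NA_real_) {
  if (v_prev < threshold && v_new >= threshold) t else NULL
}

#' Map spikes of a communication window to synaptic events
#'
#' Each spike becomes one event per outgoing connection of its source, with
#' delivery time `spike time + connection delay`; delivery happens at the
#' first later step whose start time is at or past the delivery time.
#' Because every delay is at least the communication step, deliveries always
#' fall in a strictly future window.
#'
#' @param spikes Data frame with columns `time`, `neuron`.
#' @param network A `neural_network`.
#' @return Data frame of events: `time`, `weight`, `target`,
#'   `syn_placement`, `syn_index`, `source`, `conn_id`, sorted by
#'   `(time, source, conn_id)`.
#' @export
exchange_spikes <- function(spikes, network) {
  conns <- network$connections
  if (nrow(spikes) == 0L || nrow(conns) == 0L) {
    return(data.frame(time = numeric(), weight = numeric(), target = integer(),
                      syn_placement = integer(), syn_index = integer(),
                      source = integer(), conn_id = integer()))
  }
  rows <- lapply(seq_len(nrow(spikes)), function(i) {
    out <- conns[conns$source == spikes$neuron[i], , drop = FALSE]
    if (nrow(out) == 0L) return(NULL)
    data.frame(time = spikes$time[i] + out$delay, weight = out$weight,
               target = out$target, syn_placement = out$syn_placement,
               syn_index = out$syn_index, source = spikes$neuron[i],
               conn_id = out$conn_id)
  })
  ev <- do.call(rbind, rows)
  if (is.null(ev)) return(exchange_spikes(spikes[0, ], network))
  ev[order(ev$time, ev$source, ev$conn_id), , drop = FALSE]
}

# append events to a block's queue, keeping (time, source, conn) order among
# the not-yet-delivered entries
block_enqueue_events <- function(bl, ev_rows) {
  if (nrow(ev_rows) == 0L) return(invisible(bl))
  add <- matrix(0, nrow(ev_rows), 6,
                dimnames = list(NULL, colnames(bl$events)))
  keep <- logical(nrow(ev_rows))
  for (i in seq_len(nrow(ev_rows))) {
    loc <- bl$ev_lookup[[paste0(ev_rows$syn_placement[i], ".",
                                ev_rows$syn_index[i])]]
    if (is.null(loc)) next
    keep[i] <- TRUE
    add[i, ] <- c(ev_rows$time[i], ev_rows$weight[i], loc[1], loc[2],
                  ev_rows$source[i], ev_rows$conn_id[i])
  }
  add <- add[keep, , drop = FALSE]
  if (nrow(add) == 0L) return(invisible(bl))
  pend <- bl$events[seq_len(nrow(bl$events)) >= bl$ev_ptr, , drop = FALSE]
  done <- bl$events[seq_len(nrow(bl$events)) < bl$ev_ptr, , drop = FALSE]
  pend <- rbind(pend, add)
  pend <- pend[order(pend[, "time"], pend[, "source"], pend[, "conn"]), ,
               drop = FALSE]
  bl$events <- rbind(done, pend)
  bl$enqueued <- (bl$enqueued %||% 0L) + nrow(add)
  invisible(bl)
}

#' Advance one neuron state by one timestep
#'
#' The per-step workflow: deliver due events, evaluate mechanism currents,
#' set up the matrix, triangulate and substitute for dV, update the voltage,
#' update the gating states at the new voltage, detect a somatic spike.
#'
#' @param state A whole-neuron `subtree_block` prepared with the clock's
#'   `dt` (see [init_neuron_state()]).
#' @param step 1-based step index; the step spans
#'   `[(step-1) * dt, step * dt]`.
#' @return The state (modified in place and returned).
#' @export
advance_step <- function(state, step) {
  t_start <- (step - 1) * state$dt
  block_phase_setup(state, t_start)
  block_phase_triangulate(state)
  block_phase_substitute(state)
  block_phase_update(state, step * state$dt)
  invisible(state)
}

#' Build a whole-neuron stepping state
#'
#' @param model A `neuron_model`.
#' @param dt Timestep (ms).
#' @param width Vector width for the mechanism arrays.
#' @param spike_threshold Somatic spike detection threshold (mV).
#' @return A prepared `subtree_block` covering the whole neuron.
#' @export
init_neuron_state <- function(model, dt = 0.025, width = 8L,
                              spike_threshold = -20) {
  bl <- build_layout(list(members = seq_len(model$tree$n), root = 1L,
                          parent = NA_integer_, parent_comp = NA_integer_,
                          id = 1L),
                     model, width = width)
  bl$spike_threshold <- spike_threshold
  block_prepare(bl, dt)
  check_diagonal_dominance(solver_arrays(bl$parent_local, bl$a, bl$b,
                                         bl$d_static, numeric(bl$n), bl$v))
  bl
}

#' Run a network simulation with the serial reference loop
#'
#' Loops [advance_step()] over all neurons, exchanging spikes at every
#' communication boundary and recording voltages at every IO boundary.
#' Serial and deterministic; the asynchronous runtime must reproduce it.
#'
#' @param network A `neural_network`.
#' @param clock A `simulation_clock`; its `t_synch` is tightened to the
#'   network's minimum delay (rounded down to a multiple of `dt`).
#' @param record `"soma"` (one trace per neuron) or `"all"` (every
#'   compartment of every neuron).
#' @param width Vector width for mechanism arrays.
#' @param spike_threshold Spike detection threshold (mV).
#' @return A `simulation_result`: `spikes` (data frame `time`, `neuron`),
#'   `traces` (list per neuron: matrix compartments x samples), `times`
#'   (sample times), `stats` (event bookkeeping).
#' @export
run_simulation <- function(network, clock, record = c("soma", "all"),
                           width = 8L, spike_threshold = -20) {
  record <- match.arg(record)
  t_synch <- derive_t_synch(network, clock$dt, clock$tstop)
  clock <- simulation_clock(clock$dt, clock$tstop, t_synch, clock$t_io)
  states <- lapply(network$models, function(m) {
    init_neuron_state(m, clock$dt, width, spike_threshold)
  })
  rec <- make_recorder(states, network, clock, record)
  spikes <- list()
  total_scheduled <- 0L
  nwin <- if (clock$n_steps == 0L) 0L else
    ceiling(clock$n_steps / clock$steps_per_window)
  for (w in seq_len(nwin)) {
    s0 <- (w - 1L) * clock$steps_per_window + 1L
    s1 <- min(w * clock$steps_per_window, clock$n_steps)
    win_spikes <- list()
    for (nid in seq_along(states)) {
      st <- states[[nid]]
      st$spikes <- numeric(0)
      for (s in s0:s1) {
        advance_step(st, s)
        record_sample(rec, nid, st, s)
      }
      if (length(st$spikes) > 0L) {
        win_spikes[[length(win_spikes) + 1L]] <-
          data.frame(time = st$spikes, neuron = nid)
      }
    }
    win_spikes <- if (length(win_spikes) > 0L) do.call(rbind, win_spikes) else
      data.frame(time = numeric(), neuron = integer())
    win_spikes <- win_spikes[order(win_spikes$time, win_spikes$neuron), ,
                             drop = FALSE]
    spikes[[w]] <- win_spikes
    ev <- exchange_spikes(win_spikes, network)
    total_scheduled <- total_scheduled + nrow(ev)
    for (nid in unique(ev$target)) {
      block_enqueue_events(states[[nid]], ev[ev$target == nid, , drop = FALSE])
    }
  }
  spikes <- if (length(spikes) > 0L) do.call(rbind, spikes) else
    data.frame(time = numeric(), neuron = integer())
  delivered <- sum(vapply(states, function(s) s$delivered, 1L))
  structure(list(
    spikes = spikes,
    traces = rec$traces,
    times = rec$times,
    stats = list(events_scheduled = total_scheduled,
                 events_delivered = delivered,
                 deliveries = collect_deliveries(states),
                 steps = clock$n_steps)
  ), class = "simulation_result")
}

make_recorder <- function(states, network, clock, record) {
  rec <- new.env(parent = emptyenv())
  sample_steps <- if (clock$n_steps == 0L) integer(0) else
    seq_len(clock$n_steps)[seq_len(clock$n_steps) %% clock$io_every == 0L]
  rec$times <- sample_steps * clock$dt
  rec$sample_of_step <- integer(clock$n_steps)
  rec$sample_of_step[sample_steps] <- seq_along(sample_steps)
  rec$mode <- record
  rec$traces <- lapply(seq_along(network$models), function(nid) {
    nr <- if (record == "all") network$models[[nid]]$tree$n else 1L
    matrix(NA_real_, nr, length(sample_steps))
  })
  rec
}

# record from a whole-neuron state (all blocks in one)
record_sample <- function(rec, nid, st, step) {
  k <- rec$sample_of_step[step]
  if (k == 0L) return(invisible(NULL))
  if (rec$mode == "all") {
    rec$traces[[nid]][st$comps, k] <- st$v
  } else if (!is.na(st$soma_local)) {
    rec$traces[[nid]][1L, k] <- st$v[st$soma_local]
  }
  invisible(NULL)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("simulation_result: %d steps, %d spikes, %d neurons recorded\n",
              x$stats$steps, nrow(x$spikes), length(x$traces)))
  invisible(x)
}

#' Write a spike raster as two-column text
#' @param result A `simulation_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_raster <- function(result, path) {
  lines <- sprintf("%.17g %d", result$spikes$time, result$spikes$neuron)
  writeLines(lines, path)
  invisible(path)
}

#' Write voltage traces as CSV (`t`, `neuron`, `compartment`, `v`)
#' @param result A `simulation_result`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_traces <- function(result, path) {
  rows <- lapply(seq_along(result$traces), function(nid) {
    tr <- result$traces[[nid]]
    data.frame(t = rep(result$times, each = nrow(tr)),
               neuron = nid,
               compartment = rep(seq_len(nrow(tr)), length(result$times)),
               v = as.vector(tr))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
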