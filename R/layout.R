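# Structure-of-arrays memory image of one subtree: contiguous solver arrays
# with local re-indexing, plus one contiguous array per state variable and
# parameter per mechanism type, padded to the vector width with inert
# (zero-conductance) lanes.  All stepping kernels operate on these blocks;
# a whole neuron is simply a block with no boundaries.

#' Build the structure-of-arrays block of a subtree
#'
#' Compartments are renumbered `1..n` preserving the depth-first order within
#' the subtree.  Instances of each mechanism type are gathered contiguously,
#' ordered by local compartment index with ties broken by instance creation
#' order, and padded to a multiple of `width` with inert lanes (zero
#' conductance, states pinned harmlessly to lane 1's compartment).
#'
#' @param subtree One subtree of a `decomposition_plan` (or
#'   `list(members =, root =, parent = NA, parent_comp = NA)` for a whole
#'   neuron).
#' @param model The `neuron_model`.
#' @param width Vector width (lanes) to pad mechanism arrays to; default 8.
#' @return A `subtree_block` environment.
#' @export
build_layout <- function(subtree, model, width = 8L) {
  tree <- model$tree
  members <- sort(as.integer(subtree$members))
  n <- length(members)
  if (n == 0L) stop("build_layout: empty subtree")
  local_of <- integer(tree$n)            # 0 where not in subtree
  local_of[members] <- seq_len(n)

  parent_local <- local_of[ifelse(is.na(tree$parent[members]), members,
                                  tree$parent[members])]
  parent_local[1] <- NA_integer_
  if (n > 1L && any(parent_local[-1] == 0L | parent_local[-1] >= 2:n)) {
    stop("build_layout: members are not a DFS-ordered connected subtree")
  }

  has_parent <- !is.na(subtree$parent) && !is.na(tree$parent[members[1]])
  ga <- numeric(n)
  if (n > 1L) ga[2:n] <- 1 / tree$r_axial[members[2:n]]
  ga[1] <- if (has_parent) 1 / tree$r_axial[members[1]] else 0

  bl <- new.env(parent = emptyenv())
  bl$id <- if (is.null(subtree$id)) 1L else subtree$id
  bl$comps <- members
  bl$n <- n
  bl$parent_local <- parent_local
  bl$ga <- ga
  bl$a <- -ga
  bl$b <- -ga
  bl$cap <- tree$cap[members]
  bl$has_parent <- has_parent
  bl$parent_comp <- subtree$parent_comp
  bl$width <- as.integer(width)
  bl$v <- rep(model$v_init, n)
  bl$parent_v <- if (has_parent) model$v_init else NA_real_
  bl$soma_local <- if (local_of[1] > 0L) 1L else NA_integer_
  bl$boundary_children <- list()         # filled when wiring a plan
  bl$spike_threshold <- -20

  # axial aggregation map (children contributions to parent rows), fixed once
  if (n > 1L) {
    p2 <- parent_local[2:n]
    bl$p2 <- p2
    bl$agg_rows <- unique(p2)            # order of first appearance
  }

  # gather mechanism instances by type
  inst <- list()                          # type -> list of records
  for (pi in seq_along(model$placements)) {
    pl <- model$placements[[pi]]
    sel <- which(local_of[pl$comps] > 0L)
    if (length(sel) == 0L) next
    rec <- inst[[pl$type]]
    if (is.null(rec)) rec <- list(comp = integer(), placement = integer(),
                                  inst = integer(), params = list())
    rec$comp <- c(rec$comp, local_of[pl$comps[sel]])
    rec$placement <- c(rec$placement, rep(pi, length(sel)))
    rec$inst <- c(rec$inst, sel)
    rec$params <- c(rec$params, list(lapply(pl$params, `[`, sel)))
    inst[[pl$type]] <- rec
  }

  mech <- list()
  ev_lookup <- list()
  for (type in names(inst)) {
    rec <- inst[[type]]
    def <- get_mechanism(type)
    params <- lapply(stats::setNames(names(def$params), names(def$params)),
                     function(nm) unlist(lapply(rec$params, `[[`, nm)))
    o <- order(rec$comp)                  # stable: ties keep creation order
    m <- length(rec$comp)
    npad <- as.integer(ceiling(m / width) * width) - m
    pad_param <- function(nm, x) {
      fill <- if (grepl("^tau", nm)) 1 else 0   # inert lanes: zero g, unit tau
      c(x[o], rep(fill, npad))
    }
    params <- lapply(stats::setNames(names(params), names(params)),
                     function(nm) pad_param(nm, params[[nm]]))
    comp_pad <- c(rec$comp[o], rep(1L, npad))
    mb <- list(type = type, def = def, comp = comp_pad,
               params = params, n_logical = m, n_phys = m + npad,
               agg_rows = unique(comp_pad), states = NULL)
    if (!is.null(def$init)) {
      mb$states <- def$init(bl$v[comp_pad], params)
    }
    mech[[length(mech) + 1L]] <- mb
    key_pl <- rec$placement[o]; key_in <- rec$inst[o]
    for (j in seq_len(m)) {
      ev_lookup[[paste0(key_pl[j], ".", key_in[j])]] <-
        c(length(mech), j)
    }
  }
  bl$mech <- mech
  bl$ev_lookup <- ev_lookup
  bl$events <- matrix(numeric(0), ncol = 6,
                      dimnames = list(NULL, c("time", "weight", "mb", "pos",
                                              "source", "conn")))
  bl$ev_ptr <- 1L
  bl$delivered <- 0L
  bl$deliver_log <- list()             # (delivery time, step start) pairs
  bl$spikes <- numeric(0)
  class(bl) <- "subtree_block"
  bl
}

#' @export
print.subtree_block <- function(x, ...) {
  cat(sprintf("subtree_block %d: %d compartments, %d mechanism types%s\n",
              x$id, x$n, length(x$mech),
              if (x$has_parent) " (hangs below a parent subtree)" else ""))
  invisible(x)
}

# bind dt-dependent constants; must be called before stepping
block_prepare <- function(bl, dt) {
  d_static <- bl$cap / dt + bl$ga
  if (bl$n > 1L) {
    acc <- rowsum(bl$ga[2:bl$n], bl$p2, reorder = FALSE)
    d_static[bl$agg_rows] <- d_static[bl$agg_rows] + acc[, 1]
  }
  for (bc in bl$boundary_children) {
    d_static[bc$row] <- d_static[bc$row] + bc$channel$ga
  }
  bl$dt <- dt
  bl$d_static <- d_static
  invisible(bl)
}

# reinitialize dynamic state (used by the measured cost model)
block_reset <- function(bl, v_init) {
  bl$v <- rep(v_init, bl$n)
  if (bl$has_parent) bl$parent_v <- v_init
  for (k in seq_along(bl$mech)) {
    mb <- bl$mech[[k]]
    if (!is.null(mb$def$init)) {
      bl$mech[[k]]$states <- mb$def$init(bl$v[mb$comp], mb$params)
    }
  }
  bl$ev_ptr <- 1L
  bl$delivered <- 0L
  bl$deliver_log <- list()
  bl$spikes <- numeric(0)
  invisible(bl)
}

collect_deliveries <- function(blocks) {
  rows <- unlist(lapply(blocks, function(b) b$deliver_log), recursive = FALSE)
  if (length(rows) == 0L) {
    return(data.frame(time = numeric(), step_start = numeric()))
  }
  m <- do.call(rbind, rows)
  data.frame(time = m[, 1], step_start = m[, 2])
}

# deliver pending events with delivery time <= step start (ties already
# ordered by time, source, connection when the queue was built)
block_deliver_events <- function(bl, t_start) {
  ev <- bl$events
  while (bl$ev_ptr <= nrow(ev) && ev[bl$ev_ptr, "time"] <= t_start + 1e-9) {
    k <- ev[bl$ev_ptr, "mb"]; pos <- ev[bl$ev_ptr, "pos"]
    mb <- bl$mech[[k]]
    bl$mech[[k]]$states <- mb$def$receive(mb$states, pos, ev[bl$ev_ptr, "weight"])
    bl$delivered <- bl$delivered + 1L
    bl$deliver_log[[bl$delivered]] <- c(ev[bl$ev_ptr, "time"], t_start)
    bl$ev_ptr <- bl$ev_ptr + 1L
  }
  invisible(bl)
}

# mechanism currents + matrix set-up for the step starting at t_start;
# boundary child voltages are read from the channels (set by the children's
# voltage-publication phase for this step)
block_phase_setup <- function(bl, t_start) {
  block_deliver_events(bl, t_start)
  n <- bl$n
  v <- bl$v
  i_comp <- numeric(n); g_comp <- numeric(n)
  for (mb in bl$mech) {
    cur <- mb$def$current(v[mb$comp], mb$states, mb$params, t_start)
    acc <- rowsum(cbind(cur$i, cur$g), mb$comp, reorder = FALSE)
    i_comp[mb$agg_rows] <- i_comp[mb$agg_rows] + acc[, 1]
    g_comp[mb$agg_rows] <- g_comp[mb$agg_rows] + acc[, 2]
  }
  d <- bl$d_static + g_comp
  rhs <- -i_comp
  if (n > 1L) {
    idx <- 2:n
    e <- bl$ga[idx] * (v[bl$p2] - v[idx])
    rhs[idx] <- rhs[idx] + e
    acc <- rowsum(e, bl$p2, reorder = FALSE)
    rhs[bl$agg_rows] <- rhs[bl$agg_rows] - acc[, 1]
  }
  if (bl$has_parent) {
    rhs[1] <- rhs[1] + bl$ga[1] * (bl$parent_v - v[1])
  }
  for (bc in bl$boundary_children) {
    ch <- bc$channel
    rhs[bc$row] <- rhs[bc$row] + ch$ga * (ch$vup - v[bc$row])
  }
  bl$d <- d
  bl$rhs <- rhs
  invisible(bl)
}

# fold boundary-child triangulation contributions, then eliminate
# leaves-to-root; returns the boundary contribution for the parent (or NULL)
block_phase_triangulate <- function(bl) {
  d <- bl$d; rhs <- bl$rhs
  for (bc in bl$boundary_children) {     # ascending child subtree id
    ch <- bc$channel
    d[bc$row] <- d[bc$row] + ch$tri_dd
    rhs[bc$row] <- rhs[bc$row] + ch$tri_drhs
  }
  n <- bl$n
  if (n > 1L) {
    a <- bl$a; b <- bl$b; p <- bl$parent_local
    for (i in n:2) {
      f <- a[i] / d[i]
      pi_ <- p[i]
      d[pi_] <- d[pi_] - f * b[i]
      rhs[pi_] <- rhs[pi_] - f * rhs[i]
    }
  }
  bl$d <- d; bl$rhs <- rhs
  if (bl$has_parent) {
    f <- bl$a[1] / d[1]
    list(delta_d = -f * bl$b[1], delta_rhs = -f * rhs[1])
  } else {
    NULL
  }
}

# root-to-leaves back-solve; parent_dv is the parent connecting compartment's
# dV (NULL for a whole-neuron root).  rhs holds dV afterwards.
block_phase_substitute <- function(bl, parent_dv = NULL) {
  d <- bl$d; rhs <- bl$rhs
  if (bl$has_parent) {
    rhs[1] <- (rhs[1] - bl$b[1] * parent_dv) / d[1]
  } else {
    rhs[1] <- rhs[1] / d[1]
  }
  n <- bl$n
  if (n > 1L) {
    b <- bl$b; p <- bl$parent_local
    for (i in 2:n) rhs[i] <- (rhs[i] - b[i] * rhs[p[i]]) / d[i]
  }
  bl$rhs <- rhs
  invisible(bl)
}

# voltage update, spike detection, gating-state update, cached parent voltage
# advance; t_end is the time at the end of the step
block_phase_update <- function(bl, t_end, parent_dv = NULL) {
  dv <- bl$rhs
  if (!is.na(bl$soma_local)) {
    v_old <- bl$v[bl$soma_local]
    v_new <- v_old + dv[bl$soma_local]
    if (v_old < bl$spike_threshold && v_new >= bl$spike_threshold) {
      bl$spikes <- c(bl$spikes, t_end)
    }
  }
  v <- bl$v + dv
  if (!all(is.finite(v))) {
    stop(sprintf("numerical blow-up at t = %g ms (compartment %d)",
                 t_end, bl$comps[which(!is.finite(v))[1]]))
  }
  bl$v <- v
  for (k in seq_along(bl$mech)) {
    mb <- bl$mech[[k]]
    if (!is.null(mb$def$update)) {
      bl$mech[[k]]$states <-
        mb$def$update(mb$states, v[mb$comp], bl$dt, mb$params)
    }
  }
  if (bl$has_parent && !is.null(parent_dv)) {
    bl$parent_v <- bl$parent_v + parent_dv
  }
  invisible(bl)
}

#' Gather block state back through the index maps
#'
#' @param block A `subtree_block`.
#' @return `list(comps =, v =, instances =)` where `instances` maps every
#'   logical (unpadded) mechanism instance back to
#'   `(placement, instance, compartment, states)` in global coordinates.
#' @export
gather_block <- function(block) {
  inst <- list()
  for (key in names(block$ev_lookup)) {
    loc <- block$ev_lookup[[key]]
    mb <- block$mech[[loc[1]]]
    ids <- as.integer(strsplit(key, ".", fixed = TRUE)[[1]])
    inst[[key]] <- list(placement = ids[1], instance = ids[2],
                        comp = block$comps[mb$comp[loc[2]]],
                        states = lapply(mb$states, `[`, loc[2]))
  }
  list(comps = block$comps, v = block$v, instances = inst)
}

#' Check the scatter/gather round trip of a block
#'
#' Maps block values back through the local/global index maps and verifies
#' that every original value is reproduced exactly.
#'
#' @param block A `subtree_block` freshly built from `model`.
#' @param model The originating `neuron_model`.
#' @return `TRUE` if the round trip is exact.
#' @export
scatter_gather_roundtrip <- function(block, model) {
  g <- gather_block(block)
  if (!identical(g$comps, sort(g$comps))) return(FALSE)
  if (!all(g$v == model$v_init)) return(FALSE)
  for (key in names(g$instances)) {
    rec <- g$instances[[key]]
    pl <- model$placements[[rec$placement]]
    if (pl$comps[rec$instance] != rec$comp) return(FALSE)
    mech <- get_mechanism(pl$type)
    if (!is.null(mech$init)) {
      ref <- mech$init(model$v_init, lapply(pl$params, `[`, rec$instance))
      for (snm in names(ref)) {
        if (!identical(unname(ref[[snm]]), unname(rec$states[[snm]]))) return(FALSE)
      }
    }
  }
  TRUE
}

#' Dump a block's solver arrays to CSV for debugging
#' @param block A `subtree_block`.
#' @param path Output path.
#' @export
dump_block <- function(block, path) {
  df <- data.frame(local = seq_len(block$n), global = block$comps,
                   parent = ifelse(is.na(block$parent_local), 0L, block$parent_local),
                   a = block$a, b = block$b, ga = block$ga, cap = block$cap,
                   v = block$v)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
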