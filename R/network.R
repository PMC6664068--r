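# Network description: neurons (morphology + mechanism placements), synaptic
# connections with per-connection delay and weight, and stimulus protocols.
# Read from / written to a documented JSON dialect.

#' Assemble a network object
#'
#' @param models List of `neuron_model`s (neuron ids are their positions).
#' @param connections Data frame with columns `source`, `target`,
#'   `target_comp`, `delay` (ms), `weight` (uS) and optionally `e` (mV),
#'   `tau` (ms) per synapse; may have zero rows.
#' @param stimuli Data frame with columns `neuron`, `comp`, `onset`,
#'   `duration` (ms), `amplitude` (nA); may have zero rows.
#' @return A `neural_network`: the models (with one `expsyn` placement
#'   appended per neuron holding its incoming synapses, and one `iclamp`
#'   placement holding its stimuli), the connection table (with synapse
#'   instance bookkeeping) and the minimum synaptic delay.
#' @export
neural_network <- function(models, connections = NULL, stimuli = NULL) {
  if (is.null(connections) || nrow(connections) == 0L) {
    connections <- data.frame(source = integer(), target = integer(),
                              target_comp = integer(), delay = numeric(),
                              weight = numeric())
  }
  if (is.null(stimuli) || nrow(stimuli) == 0L) {
    stimuli <- data.frame(neuron = integer(), comp = integer(),
                          onset = numeric(), duration = numeric(),
                          amplitude = numeric())
  }
  if (nrow(connections) > 0L) {
    if (any(connections$delay <= 0)) stop("neural_network: delays must be positive")
    if (any(connections$weight < 0)) stop("neural_network: weights must be non-negative")
    if (is.null(connections$e)) connections$e <- 0
    if (is.null(connections$tau)) connections$tau <- 2
  }
  connections$conn_id <- seq_len(nrow(connections))
  connections$syn_placement <- rep(NA_integer_, nrow(connections))
  connections$syn_index <- rep(NA_integer_, nrow(connections))

  for (nid in seq_along(models)) {
    rows <- which(connections$target == nid)
    if (length(rows) > 0L) {
      models[[nid]] <- add_mechanism(models[[nid]], "expsyn",
                                     connections$target_comp[rows],
                                     e = connections$e[rows],
                                     tau = connections$tau[rows])
      connections$syn_placement[rows] <- length(models[[nid]]$placements)
      connections$syn_index[rows] <- seq_along(rows)
    }
    srows <- which(stimuli$neuron == nid)
    if (length(srows) > 0L) {
      models[[nid]] <- add_mechanism(models[[nid]], "iclamp",
                                     stimuli$comp[srows],
                                     amp = stimuli$amplitude[srows],
                                     onset = stimuli$onset[srows],
                                     dur = stimuli$duration[srows])
    }
  }
  min_delay <- if (nrow(connections) > 0L) min(connections$delay) else Inf
  out_degree <- tabulate(connections$source, nbins = length(models))
  structure(list(models = models, connections = connections,
                 stimuli = stimuli, min_delay = min_delay,
                 out_degree = out_degree),
            class = "neural_network")
}

#' @export
print.neural_network <- function(x, ...) {
  cat(sprintf("neural_network: %d neurons, %d connections (min delay %s ms), %d stimuli\n",
              length(x$models), nrow(x$connections),
              if (is.finite(x$min_delay)) format(x$min_delay) else "-",
              nrow(x$stimuli)))
  invisible(x)
}

#' Read a network from its JSON description
#'
#' The dialect is an object with `neurons` (each: `id`, `swc_text` or `swc`
#' path, `v_init`, `mechanisms`: a list of
#' `{type, where, densities | params}` entries with `where` one of
#' `"soma"`, `"dend"`, `"all"` or a compartment index vector),
#' `connections` (`source`, `target`, `target_comp`, `delay`, `weight`,
#' optional `e`, `tau`) and `stimuli` (`neuron`, `comp`, `onset`,
#' `duration`, `amplitude`).  `max_comp_len` fixes the discretization the
#' compartment indices refer to.
#'
#' @param x Path to a JSON file, JSON text, or an equivalent list.
#' @return A `neural_network`.
#' @export
read_network <- function(x) {
  spec <- if (is.list(x)) {
    x
  } else if (length(x) == 1L && grepl("^\\s*\\{", x)) {
    jsonlite::fromJSON(x, simplifyVector = FALSE)
  } else {
    jsonlite::fromJSON(x, simplifyVector = FALSE)
  }
  max_len <- spec$max_comp_len %||% 20
  models <- lapply(spec$neurons, function(ns) {
    swc <- ns$swc_text %||% ns$swc
    tree <- discretize(read_swc(swc), max_len = max_len)
    model <- neuron_model(tree, v_init = ns$v_init %||% -65)
    for (ms in ns$mechanisms %||% list()) {
      comps <- resolve_where(ms$where %||% "all", tree)
      if (length(comps) == 0L) next
      if (!is.null(ms$densities)) {
        model <- add_density_mechanism(model, ms$type, comps,
                                       lapply(ms$densities, as.numeric))
      } else {
        model <- do.call(add_mechanism,
                         c(list(model, ms$type, comps),
                           lapply(ms$params %||% list(), as.numeric)))
      }
    }
    model
  })
  to_df <- function(lst, cols) {
    if (length(lst) == 0L) return(NULL)
    as.data.frame(do.call(rbind, lapply(lst, function(r) {
      vapply(cols, function(cn) as.numeric(r[[cn]] %||% NA), 1)
    })))
  }
  conns <- to_df(spec$connections %||% list(),
                 c("source", "target", "target_comp", "delay", "weight"))
  stims <- to_df(spec$stimuli %||% list(),
                 c("neuron", "comp", "onset", "duration", "amplitude"))
  if (!is.null(conns)) {
    names(conns) <- c("source", "target", "target_comp", "delay", "weight")
  }
  if (!is.null(stims)) {
    names(stims) <- c("neuron", "comp", "onset", "duration", "amplitude")
  }
  neural_network(models, conns, stims)
}

resolve_where <- function(where, tree) {
  if (is.numeric(where) || is.list(where)) return(as.integer(unlist(where)))
  switch(where,
    all = seq_len(tree$n),
    soma = which(tree$swc_type == SWC_SOMA),
    dend = which(tree$swc_type %in% c(SWC_DEND, SWC_APIC)),
    stop(sprintf("unknown placement target '%s'", where))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
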