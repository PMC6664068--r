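# Run configuration and the pipeline entry points behind the command-line
# script (inst/cli/arborsim).

#' Build and validate a run configuration
#'
#' @param dt Timestep (ms), default 0.025.
#' @param tstop Simulated span (ms).
#' @param workers Simulated worker count.
#' @param cores_count Core count for the decomposition threshold; defaults to
#'   `workers`.
#' @param k Subtree granularity constant; `NULL` uses [default_k()].
#' @param localities Locality count for balancing.
#' @param vector_width Mechanism array padding width (lanes).
#' @param seed RNG seed for synthetic inputs.
#' @param cost_mode `"analytic"` or `"measured"`.
#' @param t_io Trace output interval (ms).
#' @param max_comp_len Discretization length (um).
#' @param spike_threshold Spike detection threshold (mV).
#' @param tolerance Locality threshold tolerance for balancing.
#' @param record `"soma"` or `"all"`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(dt = 0.025, tstop = 100, workers = 1, cores_count = workers,
                       k = NULL, localities = 1, vector_width = 8,
                       seed = 1, cost_mode = "analytic", t_io = 0.1,
                       max_comp_len = 20, spike_threshold = -20,
                       tolerance = 0.10, record = "soma") {
  if (dt <= 0) stop("run_config: dt must be positive")
  if (tstop < 0) stop("run_config: tstop must be non-negative")
  if (workers < 1 || localities < 1) {
    stop("run_config: workers and localities must be >= 1")
  }
  if (!cost_mode %in% c("analytic", "measured")) {
    stop("run_config: cost_mode must be 'analytic' or 'measured'")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Read a YAML run configuration, overlaying the defaults
#' @param path YAML file whose keys match [run_config()] arguments.
#' @return A `run_config`.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L) {
    stop(sprintf("read_config: unknown key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(run_config, vals)
}

#' Simulate a network end to end
#'
#' Pipeline: load the network (JSON, or a single SWC wrapped as a one-neuron
#' network), decompose every neuron, lay out subtree blocks, optionally
#' balance across localities, and run on the asynchronous runtime.  Writes
#' `traces.csv`, `raster.txt` and `report.json` under `out_dir`.
#'
#' @param config A `run_config`.
#' @param network_json Path to (or text of) a network JSON description.
#' @param swc Alternatively, a single SWC path/text simulated in isolation
#'   with an active soma, passive dendrites and a 1 nA / 5 ms somatic step.
#' @param out_dir Output directory (created if missing), or `NULL` to skip
#'   writing.
#' @return The `simulation_result` with `report` attached, invisibly.
#' @export
cmd_simulate <- function(config, network_json = NULL, swc = NULL,
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  network <- if (!is.null(network_json)) {
    read_network(network_json)
  } else if (!is.null(swc)) {
    tree <- discretize(read_swc(swc), max_len = config$max_comp_len)
    model <- neuron_model(tree)
    model <- add_density_mechanism(model, "hh", which(tree$swc_type == SWC_SOMA),
                                   list(gna = 0.12, gk = 0.036, gl = 0.0003))
    dend <- which(tree$swc_type != SWC_SOMA)
    if (length(dend) > 0L) {
      model <- add_density_mechanism(model, "pas", dend, list(g = 1e-4))
    }
    neural_network(list(model),
                   stimuli = data.frame(neuron = 1, comp = 1, onset = 1,
                                        duration = 5, amplitude = 1))
  } else {
    stop("cmd_simulate: provide network_json or swc")
  }
  clock <- simulation_clock(config$dt, config$tstop, t_io = config$t_io)
  k <- if (is.null(config$k)) default_k(config$cores_count) else config$k
  plans <- lapply(network$models, function(m) {
    costs <- compartment_costs(m)
    cluster_subtrees(m$tree, costs,
                     max_work(sum(costs), config$cores_count, k))
  })
  assignment <- NULL
  bal <- NULL
  if (config$localities > 1L) {
    wts <- lapply(plans, neuron_subtree_groups)
    bal <- balance_with_splitting(wts, config$localities, config$tolerance)
    assignment <- assignment_localities(bal, wts)
  }
  elapsed <- system.time({
    res <- run_network_async(network, clock, plans = plans,
                             workers = config$workers, k = k,
                             cores_count = config$cores_count,
                             assignment = assignment, record = config$record,
                             width = config$vector_width,
                             spike_threshold = config$spike_threshold)
  })[["elapsed"]]
  report <- list(
    config = unclass(config),
    n_neurons = length(network$models),
    n_connections = nrow(network$connections),
    subtree_counts = vapply(plans, function(p) length(p$subtrees), 1L),
    loads = if (is.null(bal)) NULL else load_report(bal),
    n_spikes = nrow(res$spikes),
    events = res$stats[c("events_scheduled", "events_delivered")],
    wall_time_s = elapsed
  )
  res$report <- report
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_traces(res, file.path(out_dir, "traces.csv"))
    write_raster(res, file.path(out_dir, "raster.txt"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(res)
}

#' Decompose a morphology and emit the plan with its validation report
#'
#' @param config A `run_config`.
#' @param swc SWC path or text.
#' @param out Optional JSON output path.
#' @return `list(plan =, validation =)`, invisibly when writing.
#' @export
cmd_decompose <- function(config, swc, out = NULL) {
  tree <- discretize(read_swc(swc), max_len = config$max_comp_len)
  model <- neuron_model(tree)
  costs <- compartment_costs(model)
  k <- if (is.null(config$k)) default_k(config$cores_count) else config$k
  plan <- cluster_subtrees(tree, costs,
                           max_work(sum(costs), config$cores_count, k))
  val <- validate_plan(plan, tree, costs)
  if (!is.null(out)) {
    writeLines(as.character(plan_to_json(plan)), out)
  }
  if (!val$valid) stop("cmd_decompose: plan validation failed")
  invisible(list(plan = plan, validation = val))
}

#' Balance a set of decomposition plans across localities
#'
#' @param config A `run_config` (uses `localities` and `tolerance`).
#' @param plans List of `decomposition_plan`s.
#' @param out Optional JSON output path for the assignment + load report.
#' @return The `balance_assignment`, invisibly when writing.
#' @export
cmd_balance <- function(config, plans, out = NULL) {
  wts <- lapply(plans, neuron_subtree_groups)
  bal <- balance_with_splitting(wts, config$localities, config$tolerance)
  if (!is.null(out)) {
    jsonlite::write_json(list(home = bal$home, delegations = bal$delegations,
                              report = load_report(bal)),
                         out, auto_unbox = TRUE, digits = NA)
  }
  invisible(bal)
}

#' Generate synthetic morphologies and a network description
#'
#' @param config A `run_config` (uses `seed` and `max_comp_len`).
#' @param n_neurons Neuron count.
#' @param out_dir Directory receiving `cell<i>.swc` and `network.json`.
#' @param ... Passed to [network_recipe()].
#' @return The network JSON text, invisibly.
#' @export
cmd_generate <- function(config, n_neurons = 10, out_dir = NULL, ...) {
  recipe <- network_recipe(n_neurons = n_neurons, seed = config$seed, ...)
  morphs <- vapply(seq_len(n_neurons), function(i) {
    generate_morphology(morphology_recipe(seed = config$seed * 1000L + i))
  }, "")
  js <- generate_network(recipe, morphs, max_comp_len = config$max_comp_len)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_len(n_neurons)) {
      writeLines(sub("\n$", "", morphs[i]), file.path(out_dir,
                                                      sprintf("cell%d.swc", i)))
    }
    writeLines(as.character(js), file.path(out_dir, "network.json"))
  }
  invisible(js)
}
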