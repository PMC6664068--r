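# Synthetic morphologies and networks with controlled statistical structure,
# so every module is testable without external data.  All randomness flows
# through one seeded generator per recipe; global RNG state is preserved.

#' Recipe for a random branched morphology
#'
#' Sections grow from the soma with log-normal lengths and geometric
#' branching, the diameter tapering at every bifurcation, until the expected
#' compartment count reaches the target - a simple emulation of the
#' heterogeneous branching statistics of reconstructed dendritic trees
#' (breadth and depth vary strongly across seeds), with no claim of
#' biological fidelity.
#'
#' @param n_comp Target compartment count at the default 20 um compartment
#'   length (default 60).
#' @param branch_prob Probability that a finished section bifurcates
#'   (default 0.35); otherwise it continues as a single child until it
#'   terminates with probability `term_prob`.
#' @param length_meanlog,length_sdlog Log-normal section length parameters
#'   (um), defaults `log(80)` and 0.4.
#' @param term_prob Termination probability per completed section
#'   (default 0.2).
#' @param soma_diam Soma diameter (um), default 20.
#' @param stem_diam Initial dendrite diameter (um), default 2.
#' @param taper Diameter factor applied to each daughter at a bifurcation
#'   (default 0.85); growth stops below `min_diam`.
#' @param min_diam Minimum diameter (um), default 0.3.
#' @param n_stem Number of primary dendrites, default 2.
#' @param seed RNG seed; identical recipes produce byte-identical SWC text.
#' @return A `morphology_recipe` list.
#' @export
morphology_recipe <- function(n_comp = 60, branch_prob = 0.35,
                              length_meanlog = log(80), length_sdlog = 0.4,
                              term_prob = 0.2, soma_diam = 20, stem_diam = 2,
                              taper = 0.85, min_diam = 0.3, n_stem = 2,
                              seed = 1) {
  if (n_comp < 1) stop("morphology_recipe: n_comp must be >= 1")
  if (branch_prob < 0 || branch_prob > 1) {
    stop("morphology_recipe: branch_prob must be in [0, 1]")
  }
  structure(as.list(environment()), class = "morphology_recipe")
}

#' Generate a random morphology as SWC text
#'
#' @param recipe A [morphology_recipe()].
#' @return A character scalar of well-formed SWC text (single soma root,
#'   dendrite-typed sections), byte-identical for identical recipes.
#' @export
generate_morphology <- function(recipe) {
  stopifnot(inherits(recipe, "morphology_recipe"))
  withr::with_seed(recipe$seed, {
    rows <- list()
    add <- function(type, x, y, z, r, parent) {
      id <- length(rows) + 1L
      rows[[id]] <<- sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                             id, type, x, y, z, r, parent)
      id
    }
    soma_r <- recipe$soma_diam / 2
    soma <- add(SWC_SOMA, 0, 0, 0, soma_r, -1L)
    comp_budget <- recipe$n_comp - 1L
    # tips: list of (parent sample id, position, direction, diameter)
    tips <- lapply(seq_len(recipe$n_stem), function(i) {
      ang <- 2 * pi * (i - 0.5) / recipe$n_stem
      list(parent = soma, pos = c(soma_r * cos(ang), soma_r * sin(ang), 0),
           dir = c(cos(ang), sin(ang), 0), diam = recipe$stem_diam)
    })
    while (length(tips) > 0L && comp_budget > 0L) {
      tip <- tips[[1]]; tips <- tips[-1]
      L <- stats::rlnorm(1, recipe$length_meanlog, recipe$length_sdlog)
      # two samples per section so sections are polylines, not single segments
      half <- tip$pos + tip$dir * (L / 2)
      endp <- tip$pos + tip$dir * L
      m1 <- add(SWC_DEND, half[1], half[2], half[3], tip$diam / 2, tip$parent)
      m2 <- add(SWC_DEND, endp[1], endp[2], endp[3], tip$diam / 2, m1)
      comp_budget <- comp_budget - ceiling(L / 20)
      if (comp_budget <= 0L) break
      if (stats::runif(1) < recipe$term_prob) next
      nkids <- if (stats::runif(1) < recipe$branch_prob) 2L else 1L
      d <- if (nkids == 2L) tip$diam * recipe$taper else tip$diam
      if (d < recipe$min_diam) next
      for (kk in seq_len(nkids)) {
        theta <- stats::runif(1, -0.9, 0.9)
        rot <- matrix(c(cos(theta), -sin(theta), 0,
                        sin(theta), cos(theta), 0,
                        0, 0, 1), 3, 3, byrow = TRUE)
        tips[[length(tips) + 1L]] <-
          list(parent = m2, pos = endp, dir = as.vector(rot %*% tip$dir),
               diam = d)
      }
    }
    if (length(rows) == 1L) {            # degenerate recipe: add one stub
      add(SWC_DEND, 20, 0, 0, recipe$stem_diam / 2, soma)
    }
    paste0(paste(unlist(rows), collapse = "\n"), "\n")
  })
}

#' Recipe for a random network
#'
#' @param n_neurons Neuron count.
#' @param p_connect Directed connection probability (no self-connections).
#' @param delay_min,delay_max Synaptic delay range (ms); `delay_min` is the
#'   hard minimum from which the communication step is derived
#'   (default 0.1 ms).
#' @param weight_meanlog,weight_sdlog Log-normal synaptic weight parameters
#'   (uS), defaults `log(0.004)` and 0.3.
#' @param n_stim Number of neurons receiving a step-current stimulus.
#' @param stim_amp,stim_onset,stim_dur Stimulus amplitude (nA), onset and
#'   duration (ms).
#' @param feedforward Only allow connections from lower to higher neuron
#'   ids (no recurrent loops); default FALSE.
#' @param seed RNG seed.
#' @return A `network_recipe` list.
#' @export
network_recipe <- function(n_neurons = 10, p_connect = 0.15, delay_min = 0.1,
                           delay_max = 1.0, weight_meanlog = log(0.004),
                           weight_sdlog = 0.3, n_stim = 2, stim_amp = 3,
                           stim_onset = 1, stim_dur = 2, feedforward = FALSE,
                           seed = 1) {
  if (p_connect < 0 || p_connect > 1) {
    stop("network_recipe: p_connect must be in [0, 1]")
  }
  if (delay_min <= 0 || delay_max < delay_min) {
    stop("network_recipe: need 0 < delay_min <= delay_max")
  }
  structure(as.list(environment()), class = "network_recipe")
}

#' Generate a network description (JSON) over morphologies
#'
#' Every neuron gets an active soma (classic squid-axon kinetics) and passive
#' dendrites; the first `n_stim` neurons receive a somatic step current.
#' Connections are sampled independently per ordered pair; synapse targets
#' are drawn uniformly over the target's dendritic compartments (under the
#' `max_comp_len` discretization recorded in the JSON).
#'
#' @param recipe A [network_recipe()].
#' @param morphologies Character vector of SWC texts, recycled over neurons;
#'   defaults to per-neuron random morphologies derived from the recipe seed.
#' @param max_comp_len Compartment length (um) the compartment indices refer
#'   to.
#' @return Network JSON text (see [read_network()]).
#' @export
generate_network <- function(recipe, morphologies = NULL, max_comp_len = 20) {
  stopifnot(inherits(recipe, "network_recipe"))
  n <- recipe$n_neurons
  if (is.null(morphologies)) {
    morphologies <- vapply(seq_len(n), function(i) {
      generate_morphology(morphology_recipe(seed = recipe$seed * 1000L + i))
    }, "")
  }
  morphologies <- rep_len(morphologies, n)
  withr::with_seed(recipe$seed, {
    trees <- lapply(morphologies, function(s) discretize(read_swc(s),
                                                         max_len = max_comp_len))
    neurons <- lapply(seq_len(n), function(i) {
      list(id = i, swc_text = morphologies[[i]], v_init = -65,
           mechanisms = list(
             list(type = "hh", where = "soma",
                  densities = list(gna = 0.12, gk = 0.036, gl = 0.0003)),
             list(type = "pas", where = "dend",
                  densities = list(g = 1e-4))
           ))
    })
    conns <- list()
    for (src in seq_len(n)) {
      for (dst in seq_len(n)) {
        if (src == dst) next
        if (recipe$feedforward && dst < src) next
        if (stats::runif(1) >= recipe$p_connect) next
        dend <- which(trees[[dst]]$swc_type != SWC_SOMA)
        target <- if (length(dend) > 0L) dend[sample.int(length(dend), 1L)] else 1L
        conns[[length(conns) + 1L]] <- list(
          source = src, target = dst, target_comp = target,
          delay = stats::runif(1, recipe$delay_min, recipe$delay_max),
          weight = stats::rlnorm(1, recipe$weight_meanlog, recipe$weight_sdlog))
      }
    }
    stims <- lapply(seq_len(min(recipe$n_stim, n)), function(i) {
      list(neuron = i, comp = 1, onset = recipe$stim_onset,
           duration = recipe$stim_dur, amplitude = recipe$stim_amp)
    })
    jsonlite::toJSON(list(max_comp_len = max_comp_len, neurons = neurons,
                          connections = conns, stimuli = stims),
                     digits = NA, auto_unbox = TRUE)
  })
}
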