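# Fixture builders and independent oracles shared across tests.

# hand-built compartment tree from a parent vector (1-based, NA at root);
# cap in nF, r in MOhm (coupling of each non-root compartment to its parent)
toy_tree <- function(parent, cap = 1, r = 1, length = 10, diam = 1) {
  n <- length(parent)
  structure(list(
    n = n, parent = as.integer(parent),
    length = rep_len(length, n), diam = rep_len(diam, n),
    cap = rep_len(cap, n),
    r_axial = c(NA_real_, rep_len(r, n)[-1])[seq_len(n)] *
      ifelse(is.na(parent), NA_real_, 1),
    swc_type = c(1L, rep(3L, n - 1L)),
    section = seq_len(n), ra = 100, cm = 1
  ), class = "compartment_tree")
}

# random DFS-numbered tree: parent of i drawn from 1..i-1 (chain-biased so
# depth varies)
random_parent_vector <- function(n, chainy = 0.6) {
  p <- c(NA_integer_, integer(n - 1L))
  for (i in seq_len(n - 1L) + 1L) {
    p[i] <- if (i == 2L || stats::runif(1) < chainy) i - 1L else
      sample.int(i - 1L, 1L)
  }
  p
}

# random well-conditioned tree system with a = b = -1/r and diagonally
# dominant d; returns solver_arrays
random_tree_system <- function(n) {
  p <- random_parent_vector(n)
  ga <- c(0, stats::runif(n - 1L, 0.1, 5))
  a <- -ga; b <- -ga
  off <- ga
  for (i in seq_len(n - 1L) + 1L) off[p[i]] <- off[p[i]] + ga[i]
  d <- off + stats::runif(n, 0.1, 10)      # strictly dominant
  solver_arrays(p, a, b, d, rhs = stats::rnorm(n), v = numeric(n))
}

# single-compartment passive cell with absolute parameters: C (nF), g (uS),
# e (mV), plus an optional step current
rc_model <- function(C = 1, g = 0.1, e = -65, v_init = e) {
  tree <- toy_tree(NA_integer_, cap = C)
  m <- neuron_model(tree, v_init = v_init)
  add_mechanism(m, "pas", 1L, g = g, e = e)
}

rc_network <- function(C = 1, g = 0.1, e = -65, amp = 0, onset = 0,
                       dur = Inf, v_init = e) {
  stim <- if (amp != 0) {
    data.frame(neuron = 1, comp = 1, onset = onset, duration = dur,
               amplitude = amp)
  } else {
    NULL
  }
  neural_network(list(rc_model(C, g, e, v_init)), stimuli = stim)
}

# HH soma (single compartment, 20 um x 20 um cylinder) with a current pulse
hh_soma_network <- function(amp = 10, onset = 1, dur = 5) {
  swc <- "1 1 0 0 0 10 -1\n"
  tree <- discretize(read_swc(swc))
  m <- neuron_model(tree)
  m <- add_density_mechanism(m, "hh", 1L,
                             list(gna = 0.12, gk = 0.036, gl = 0.0003))
  neural_network(list(m),
                 stimuli = data.frame(neuron = 1, comp = 1, onset = onset,
                                      duration = dur, amplitude = amp))
}

# random single neuron: synthetic morphology, active soma, passive dendrites,
# somatic step current
random_neuron_model <- function(seed, n_comp = 40, amp = 2) {
  swc <- generate_morphology(morphology_recipe(n_comp = n_comp, seed = seed))
  tree <- discretize(read_swc(swc))
  m <- neuron_model(tree)
  m <- add_density_mechanism(m, "hh", which(tree$swc_type == 1L),
                             list(gna = 0.12, gk = 0.036, gl = 0.0003))
  dend <- which(tree$swc_type != 1L)
  if (length(dend) > 0L) {
    m <- add_density_mechanism(m, "pas", dend, list(g = 1e-4))
  }
  m
}

random_neuron_network <- function(seed, n_comp = 40, amp = 2) {
  neural_network(list(random_neuron_model(seed, n_comp)),
                 stimuli = data.frame(neuron = 1, comp = 1, onset = 1,
                                      duration = 5, amplitude = amp))
}

# the 17-compartment worked morphology: two-compartment trunk, then a
# trifurcation into branches of 4, 4 and 7 compartments (unit costs with
# threshold 5 cluster it into 5 subtrees)
worked_17_tree <- function() {
  toy_tree(c(NA, 1, 2, 3, 4, 5, 2, 7, 8, 9, 2, 11, 12, 13, 14, 15, 16))
}

# exhaustive optimal makespan by depth-first search with dominance pruning
opt_makespan <- function(w, m) {
  w <- sort(w, decreasing = TRUE)
  best <- Inf
  loads <- numeric(m)
  rec <- function(i) {
    if (i > length(w)) {
      best <<- min(best, max(loads))
      return(invisible(NULL))
    }
    tried <- numeric(0)
    for (j in seq_len(m)) {
      if (loads[j] %in% tried) next
      tried <- c(tried, loads[j])
      if (loads[j] + w[i] >= best) next
      loads[j] <<- loads[j] + w[i]
      rec(i + 1L)
      loads[j] <<- loads[j] - w[i]
    }
  }
  rec(1L)
  best
}
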