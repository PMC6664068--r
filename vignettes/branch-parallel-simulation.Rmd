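---
title: "Branch-parallel simulation of detailed neuron models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branch-parallel simulation of detailed neuron models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arborsim)
```

This vignette documents the model, the numerical scheme, the decomposition
and execution machinery, and the design choices behind `arborsim` — in
particular the decisions that were genuinely open and how degenerate inputs
and numerical edge cases are handled.

## Model and discretization

A neuron is a tree of cylindrical compartments.  Morphologies enter as
7-column SWC; unbranched sections are split into `ceiling(L / max_comp_len)`
equal cylinders (`max_comp_len` default 20 µm) and numbered depth-first from
the soma, children visited in ascending SWC sample id.  The DFS numbering
guarantees `p(n) < n` for every non-root compartment, which is what lets the
cable matrix — one sub-diagonal entry per row — be eliminated without
fill-in.  Axon-typed samples are dropped at load (axonal propagation is
subsumed in per-connection event delays); a `keep_axon` switch retains them
as passive cables.  The soma is always a single compartment regardless of
`max_comp_len`, a conventional choice the discretization rule itself does
not force.  Geometry is strictly cylindrical: membrane area `π·d·L`, axial
resistance `4·Ra·L/(π·d²)` (Ra default 100 Ω·cm), specific capacitance
1 µF/cm².  Units throughout are mV, ms, nA, µS, nF, MΩ — a self-consistent
set (`nA = µS·mV`, `ms = nF/µS`).

There is a genuine ambiguity in how a fixed-length rule should interact
with electrotonic length (the `d_lambda`-style rules used elsewhere); we
deliberately use the simpler fixed maximum length, because every property
this package verifies (solver equivalence, decomposition invariants,
layout and scheduling invariance) is independent of the discretization
rule, and a fixed rule makes fixtures exactly reproducible.

## Membrane mechanisms

Mechanisms follow one vectorized contract: `current(v, states, params, t)`
returns instantaneous current (nA) and conductance (µS) per instance, and
`update(states, v, dt, params)` advances the state.  Built-ins: `hh`
(classic squid-axon Na/K/leak with gates `m, h, n`), `pas` (leak), `expsyn`
(single-exponential synapse; events add their weight to `g_syn`, which
decays as `exp(-dt/τ)`, so simultaneous events superpose linearly) and
`iclamp` (step current).  A registry accepts user-defined types under the
same contract.  Rate functions use the modern voltage convention (rest near
−65 mV); the removable singularities of the `x/(1 − e^{−x/k})` forms are
evaluated by their series limit below `|x/k| < 10⁻⁶`, keeping the rates
continuous through the singular voltage.

Gating states advance by the analytic exponential update
`x' = x + (1 − e^{−dt/τ})(x_∞ − x)`, which is unconditionally stable and
keeps `x ∈ [0, 1]` for any voltage trajectory; a forward-Euler variant
exists behind a flag for convergence studies.  Densities (S/cm²) convert to
absolute per-instance conductances through each compartment's membrane
area.

## The timestep and the tree solve

Each step of size `dt` (default 0.025 ms) solves for the voltage increment
ΔV rather than for V directly.  The per-step workflow is: deliver due
synaptic events; evaluate mechanism currents at the current voltage and the
half-step-offset states; assemble `d_n = C_n/dt + G_n + Σ 1/r` and
`rhs_n = −Σ g_i x_i (V_n − E_i) + I_stim + axial terms`; triangulate
leaves-to-root; substitute root-to-leaves; update `V ← V + ΔV`; update
gating states at the new voltage; detect a somatic spike.  The solve-for-ΔV
formulation is important structurally: it is what makes the RHS depend on
the *neighboring voltages*, producing the three cross-subtree flow
dependencies (voltage up, triangulation up, substitution down) that the
whole execution model is built on.  The resulting update is an implicit
(backward-Euler-type) step: unconditionally stable, first-order in `dt`;
the convergence checks measure an observed order of ≈ 1.0 on the analytic
RC fixture.

Numerical details: elimination runs in descending index order (a valid
leaves-to-root topological order; any such order gives the same answer up
to rounding, and a fixed order makes runs bitwise reproducible).  `a` and
`b` are never modified.  A zero pivot raises a singular-matrix error; a
strict-diagonal-dominance check runs once at initialization as a warning
only, since the cable system is dominant by construction
(`C/dt + G > 0`).  Simulation time is always computed as
`step_index · dt`, never accumulated, so boundary comparisons
(event delivery, IO, spike exchange) are exact and reproducible; time
comparisons carry a 10⁻⁹ ms guard against representation noise.
Gating states initialize at `x_∞(v_init)` with `v_init = −65 mV`.

Spikes are upward crossings of a −20 mV somatic threshold, stamped with the
step-end time; staying above threshold does not re-trigger, and the HH
dynamics provide refractoriness naturally.

## Decomposition into a tree of subtrees

`cluster_subtrees()` traverses root-to-leaves, growing the current subtree
along the compartment order while its accumulated cost stays within the
threshold `max_work = k · runtime / cores`.  Two rules were left open by the
clustering idea itself and are fixed here as: (1) *close before exceeding* —
a compartment that would push the accumulated cost above the threshold
starts the next subtree (a lone compartment costlier than the threshold
becomes a forced singleton); (2) *all-or-none at bifurcations* — the
branches below a bifurcation stay in the current subtree only if the entire
remaining subtree fits the remaining budget, otherwise each branch starts
its own subtree.  Rule (2) is what guarantees the attachment invariant:
every cross-subtree edge joins a subtree root to a *leaf* of its parent
subtree, so synchronization is confined to terminal compartment
connections.  Two legitimate exceptions to threshold satisfaction exist
(forced singletons and terminal leftovers too small to aggregate);
`validate_plan()` flags them without failing.

Costs come from an analytic model by default (base cost per compartment
plus a per-instance cost per mechanism type) because deterministic costs
make decomposition tests exact.  A measured mode times repeated stepping
runs of the subtree's memory block (10 repetitions of 100 ms by default)
and averages; it is seeded but inherently noisy, so it is not the test
default.  The granularity constant `k` defaults to an interpolation over
core counts (0.8 at ≤2 cores rising to 2 beyond 16), overridable
everywhere.

## Structure-of-arrays subtree blocks

`build_layout()` renumbers a subtree's compartments `1..n` preserving DFS
order and gathers the instances of each mechanism type into contiguous
per-state-variable and per-parameter arrays, ordered by local compartment
index with ties broken by instance creation order.  Arrays pad to the
configured vector width (default 8 lanes, matching 512-bit doubles) with
inert lanes: zero conductance, unit time constants, states pinned to lane
1's compartment.  Inertness is verifiable, not assumed — runs at width 1
and width 8 produce identical traces.  The contract is layout plus
summation order, not instruction selection: per-compartment sums always
accumulate type by type, and within a type in array order, so monolithic,
decomposed and reference runs agree to rounding.  An array-of-structures
reference evaluator (`build_reference()` / `step_reference()`) implements
the same arithmetic with per-instance loops and no padding; blocks match it
to < 10⁻¹² mV per step, and the scatter/gather index maps round-trip
exactly.

## Asynchronous execution

Each subtree's step divides into three kernels: publish the root voltage to
the parent's channel; consume child voltages and triangulation
contributions, set up and triangulate, publish the boundary contribution;
consume the parent's ΔV, substitute, publish ΔV to the children, update
voltage and states.  A channel therefore carries exactly three values per
connection per step — asserted by counters on every run.  Placeholders are
counted gates: one expected contribution for parent-to-child dependencies,
one per child in the converse direction.

The scheduler is a deterministic in-process simulation of the
producer–consumer model: tasks are keyed by (step, subtree, kernel),
blocked tasks hold no worker, ready tasks queue FIFO, and up to `workers`
tasks execute per round.  Because every kernel's inputs are fixed by the
dataflow, results are bitwise identical for any worker count and any
locality assignment — the scheduling only changes *when* kernels run.
The remote-procedure machinery of a distributed runtime is replaced by
in-memory channels between simulated localities; the counted-gate semantics
are preserved, the transport is not.  An empty ready queue with incomplete
tasks is reported as a deadlock naming the blocked kernel (impossible for
tree-shaped channels; treated as an internal bug).  Within a communication
window subtrees may drift apart by steps as their dependencies allow;
neurons synchronize at every `T_synch` boundary through a barrier at which
spikes are exchanged.

One payload question the three-placeholder scheme leaves open is how the
child learns the parent-side voltage its RHS needs.  Sending it as a fourth
message would break the three-transfers count; instead the child caches the
parent connecting compartment's voltage and advances the cache with the ΔV
it already receives for substitution.  This serves both the RHS set-up
(next step) and the substitution (current step) with the same message.

`T_synch` is the network's minimum synaptic delay rounded down to a
multiple of `dt` (delays below one `dt` are a configuration error); events
deliver at the first step whose start is at or past spike time + delay, with
ties ordered by (time, source, connection id).

## Distributed balancing

Whole neurons are assigned by LPT (sort descending, place on the
least-loaded locality, ties to the lowest id), which is within
`4/3 − 1/(3m)` of optimal.  A locality loaded beyond
`(total/m)·(1 + tolerance)` (tolerance 0.10) sheds *terminal subtree
groups* of its most costly neurons.  "Group" is formalized here as the
descendant closure of a non-root subtree: removing it leaves the neuron
connected, and its only channel partner is its root's parent — kept on the
home locality by requiring delegated groups to be pairwise disjoint.  The
induced cross-locality graph of any neuron is therefore a star centred on
its home (1→2 and 1→3, never 1→2→3).  Shedding order is largest group
first, which moves the most load per channel created.  Balancing is static,
performed once at onset; subtree workloads are quasi-constant over a run,
so migration would buy little and cost determinism.

## The synthetic generators

`generate_morphology()` grows sections with log-normal lengths (default
meanlog `log(80)` µm, sdlog 0.4) and geometric branching (branch
probability 0.35, termination 0.2, diameter taper 0.85 down to 0.3 µm) from
a 20 µm soma until a target compartment count is reached; all randomness
flows through one seeded generator per recipe, and identical recipes yield
byte-identical SWC.  `generate_network()` samples directed connections
independently per ordered pair (default probability 0.15), delays uniform
on [0.1, 1] ms with a hard 0.1 ms floor (the floor is what defines the
communication step downstream), log-normal weights around 0.004 µS, and
somatic step stimuli on the first few neurons.  Defaults were chosen once
as a realistic desk-scale regime — tens of compartments per neuron,
active soma with passive dendrites, suprathreshold stimuli — and are
configuration, not claims about biology.

What the generators emulate is the *structural* heterogeneity that the
decomposition and balancing machinery must handle: variable branching
depth and breadth, variable per-compartment workload, variable delays.
What they do not emulate: reconstructed morphometry, the diversity of real
channel repertoires (a real cell carries dozens of mechanism types; tests
use HH + leak + one synapse type), synaptic plasticity, or axonal
modeling.  Passing tests therefore demonstrate the correctness of the
solver, decomposition, layout, scheduling and balancing — not biological
fidelity of any particular cell.

## Verification sizes and limitations

The test suite checks, among others: solver–dense-solve agreement on 500
random trees of up to 200 compartments (< 10⁻¹⁰ relative); decomposed
versus monolithic execution on 50 random neurons over 10 ms at every
compartment and step (< 10⁻⁹ mV); bitwise raster identity over worker
counts {1, 2, 4, 8} and four locality assignments on a 10-neuron network;
1,000 random decomposition fixtures; 1,000 LPT draws of up to 12 units
against exhaustive optima; and the analytic RC, resting-drift and
refined-dt HH fixtures.  These sizes keep the full suite in the
low minutes on one core while still exercising every invariant at
non-trivial scale.

Known limitations: the runtime parallelism is simulated (deterministic
dataflow in one R process), so wall-clock speed-ups are out of scope by
design; integration is fixed-step and first-order (no variable-order
methods); morphology handling is cylinders-only (no frustum corrections,
spines or 3D repair); and the measured cost model reports means of few
repetitions and should not be used where determinism matters.
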