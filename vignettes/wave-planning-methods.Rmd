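---
title: "Methods: spiking-wave graph traversal with a continuous attractor bump"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spiking-wave graph traversal with a continuous attractor bump}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(WavePlanner)
```

## The model

`WavePlanner` simulates planning as graph traversal on a *cognitive map*: a
regular quadratic grid (spacing 1) in which each node stands for one point
of a task-relevant manifold of stimuli — positions in a maze, pairs of
joint angles — and recurrent connections between nearby nodes encode the
manifold's local metric. Blocked nodes (obstacles, forbidden states) are
removed from the map by zeroing all their synapses and clamping their rates
to zero. Two neural layers share this map at identical resolution.

**Wave propagation layer P.** Every node carries one excitatory and one
inhibitory Izhikevich neuron,

$$\frac{dv}{dt} = 0.04v^2 + 5v + 140 - u + I,\qquad
  \frac{du}{dt} = a(bv - u),$$

with the spike rule $v \ge 30\,\mathrm{mV}\Rightarrow v \leftarrow c,\;
u \leftarrow u + d$. The homogeneous setup uses regular-spiking excitatory
neurons ($a=0.02, b=0.2, c=-65, d=8$) and fast-spiking inhibitory ones
($a=0.1, b=0.2, c=-65, d=2$). Synaptic strengths decay with grid distance
as $s(d) = s^{(max)}/d$, cut off beyond an interaction range; excitatory
projections vanish at $d=0$ (no self-excitation), while the
inhibitory-to-excitatory projection has its full negative peak at $d=0$:
each inhibitory neuron most strongly suppresses its own excitatory partner.
The *target* node of the planning problem receives a permanent DC current
$I=25$, spikes regularly, and each spike recruits its neighborhood one
millisecond later — an expanding wavefront whose first-spike times sort the
nodes by breadth-first-search hop distance from the target. The traversal is
therefore a parallelized BFS executed by neural dynamics, and the package
validates it against a classical BFS oracle (`bfsDistances()`).

**Continuous attractor layer C.** A rate-coded sheet with the
shifted-Gaussian kernel

$$w_{\vec i,\vec j} = J\exp\!\Big(-\tfrac{1}{\sigma^2}\big\|
  \big(\tfrac{i_x-j_x}{N_x},\tfrac{i_y-j_y}{N_y}\big)
  + \vec\Delta(t)\big\|^2\Big) - T$$

(local excitation, uniform inhibitory shift $T$) and the stabilized update
$B_j = \sum_i A_i w_{ij}$, $A' = (1-\tau)B + \tau B/\sum_i A_i$, rates
clipped at zero. A single seeded node relaxes into a stable, radially
symmetric bump; the bump center encodes the *current* state.

**Coupling.** Let $C_t$ be the bump's active set (nodes with
$A \ge$ `activeFrac` $\cdot\max A$) and $P_t$ the excitatory neurons spiking
this millisecond. When a wavefront *newly enters* the bump region — the
overlap $C_t\cap P_t$ goes from empty to nonempty — and the recovery timer
is idle, the direction vector is set to point from the bump center toward
the overlap centroid, normalized and scaled to magnitude `deltaGain` in the
kernel's coordinates. The attractor steps once with this $\vec\Delta$, which
translates the bump a few nodes toward the incoming wave, after which
$\vec\Delta$ returns to zero and a recovery period $R$ suppresses further
updates. Each front can therefore move the bump at most once, and the bump
walks front by front back to the waves' origin: the target.

## Parameters

| Parameter | Meaning | Default | Notes |
|---|---|---|---|
| `sEEMax` | e→e peak strength | 50 | strong, because each neuron has only ~12 neighbors |
| `sEIFactor` | e→i peak / `sEEMax` | 0.5 | peak 25 |
| `sIEFactor` | i→e peak / `sEEMax` | −9 | peak −450; see below |
| `dE` | e→e range (grid units) | 2 | 12 neighbors: 4 at d=1, 4 at √2, 4 at 2 |
| `dI` | e→i range | 1 | see "Inhibition ranges" |
| `dS` | i→e range beyond d=0 | 1 | see "Inhibition ranges" |
| `iDC` | DC drive of stimulated nodes | 25 | applied every step, including through resets |
| `vFloor` | Euler floor on v (mV) | −90 | numerical safeguard, see below |
| `J`, `sigma`, `T`, `tau` | attractor kernel/update | 12, 0.03, 0.05, 0.8 | normalized coordinates |
| `recoveryPeriod` | R (ms) | 12 | ≈ bump diameter / wave speed |
| `activeFrac` | bump activity threshold | 0.1 | defines $C_t$; no physiological threshold exists, so it is relative |
| `deltaGain` | per-front kernel shift | 0.08 | ≈ 3.3 nodes/front on a 41-grid, see calibration |
| `holdSteps` | steps Δ is held | 1 | shift completes in one update |
| `arrivalRadius` | termination distance | 6 | ≈ half the bump diameter; the center oscillates near the stimulated node |
| `maxSteps` | budget (ms) | 6000 | |
| `jitterFraction` | synaptic jitter | 0.10 | heterogeneous setup |

With these defaults the validation suite measures a wavefront speed of about
one cell per millisecond (2 cells per range-2 hop at ≈2 ms per hop), a
Spearman rank agreement ≥ 0.99 between first-spike times and BFS hop
distances, and a relaxed bump diameter of 11 nodes at the 0.1 threshold.

## Numerical choices and their reasons

**Inhibitory peak −450.** The i→e peak is specified as a multiple (−9) of
the e→e peak. The two candidate readings differ enormously in behavior: a
peak of only −9 cannot offset the ~+150 recurrent excitation behind a front
and the layer avalanches (nearly all excitatory neurons spiking at once),
while −450 yields clean repeated fronts with a per-step spiking fraction
below 10%. Both remain reachable through the single knob `sIEFactor`.

**Inhibition ranges `dI = dS = 1`.** Only the excitation range (2) is fixed
by the reference tables. A front survives only if excitation outruns
inhibition: with e→i or i→e ranges of 2 the inhibitory ring reaches *ahead*
of the front and extinguishes it within ~20 ms (a dead grid, in which fewer
than 2% of neurons ever spike). With ranges of 1 the inhibition trails the
front, suppresses re-entry behind it, and the BFS-equivalence property
holds. Both ranges are exposed configuration knobs.

**Membrane floor at −90 mV.** An impulse current of −450·k in a single 1 ms
forward-Euler step can push $v$ to the order of $-10^3$, where the
quadratic term $0.04v^2$ dominates and the next step explodes to $+10^5$
(a spurious spike) or to numerical infinity. The floor — a crude stand-in
for the potassium reversal potential — bounds the update without touching
any above-threshold dynamics. Without it the printed parameters cannot be
integrated at dt = 1 ms with a single sub-step.

**Attractor renormalization.** The literal rate update is homogeneous of
degree 1 in $A$ once $\sum A$ is large (clipping is scale-invariant), and
with the default parameters its spectral gain is ≈10 per step — the
amplitude grows without bound while the *shape* converges. The attractor
family this layer adapts keeps total activity normalized, and the package
does the same: after clipping and clamping, $A$ is divided by its sum.
With $\sum A = 1$ the stabilized update reduces exactly to $A' = B$, so the
normalized dynamics are also the fixed-point form of the written update.
`normalize = FALSE` restores the literal update for inspection.

**Kernel evaluation.** The kernel is separable in x and y, so the transfer
$B$ is computed as two one-dimensional convolutions truncated where the
Gaussian factor falls below $10^{-12}$ (half-width ≈ 7 nodes plus the
current $|\Delta|$); the sheet is planar and sums simply truncate at the
edges, consistent with mazes having walls at boundaries. The uniform $-T$
term contributes $-T\sum A$ to every node and is added in closed form.

**Bump initialization.** Unit activation on the start node, relaxed with
$\vec\Delta = 0$ until $\max|\Delta A| < 10^{-8}$ (budget 2000 steps;
convergence is geometric, ~860 steps on an open sheet, ~1200 in the
narrowest corridors). Initial membrane states in P are the deterministic
resting fixed point $v=-70$, $u=bv$; nothing in the homogeneous model is
random, so runs are exactly reproducible.

**Tie-breaks and degenerate inputs.** The bump center is the activation
argmax with ties broken by the smallest node id; an all-zero activation
raises a collapsed-bump error (and a run in progress reports status
`"collapsed"`); negative distances, blocked endpoints, disconnected
start/target pairs, and ill-sized masks raise contract errors before any
simulation starts.

**Δ-update trigger.** "A wavefront newly enters the bump region" is
implemented as a rising edge — the overlap was empty on the previous
millisecond and is nonempty now — *and* an idle recovery timer. The rising
edge matters: a front needs ~13 ms to cross the 11-node active set, slightly
longer than R = 12, so a timer alone would let the same front re-trigger on
the bump's back side as it exits and drag the bump backwards. Requiring a
fresh entry removes exit re-triggering entirely; the timer additionally
separates consecutive fronts (they arrive in doublets a few ms apart).

**Gain calibration.** One front shifts the kernel by
`deltaGain`·$N$ ≈ 3.3 nodes, within the admissible bracket (at least one
node, at most half the bump width ≈ 5.5). Smaller gains make the bump creep
one node per front, doubling the recorded path length relative to BFS hops
in axis-aligned corridors (a range-2 hop spans two cells); the default keeps
the measured path efficiency of all maze presets at or below ~1.35.

## The maze generators

The generators (`makeMaze()`) are deterministic, parametrized fixtures
reproducing the topological character of the reference planning arenas: an
S-shaped double-wall corridor, a field of rectangular blocks (two of them
sitting on the start–target diagonal), and a serpentine multi-corridor
labyrinth. The exact reference geometries exist only as figures, so the
shapes here are equivalents, not copies. All walls are two nodes thick —
the range-2 connectivity would otherwise step across one-node walls — and
every generated maze is checked for start–target reachability with the BFS
oracle before use. Corner-adjacent free cells across a diagonal wall never
occur by construction, so the model never has to decide whether such cells
communicate.

What the fixtures do *not* emulate: continuous-valued obstacle costs,
dynamic obstacles appearing mid-run, non-planar topologies (tori, branched
manifolds), or maps larger than a few thousand nodes. Passing tests on
these mazes therefore demonstrate the mechanism — BFS-equivalent wavefronts
steering a bump around static obstacles — not performance on arbitrary
graphs.

## Heterogeneous configuration

To probe robustness, per-neuron parameters are drawn once per seed:
excitatory $c = -65 + 15r_e^2$, $d = 8 - 6r_e^2$ (regular spiking at
$r_e=0$, chattering at $r_e=1$; squaring biases towards RS) and inhibitory
$a = 0.02 + 0.08r_i$, $b = 0.25 - 0.05r_i$ (low-threshold spiking to fast
spiking), with every nonzero synaptic weight jittered by up to ±10%.
Wavefronts lose their stereotyped circular shape but still traverse the
whole layer, and the planner still arrives in at least 9 of 10 seeds on the
blocks maze — occasionally faster than the homogeneous run, because broken
symmetry lets one of the competing first fronts win immediately.

## Problem sizes

The test suite and the acceptance script run the reference 41×41 grid
(1681 node pairs) for all planning and wave measurements, 300–500 ms for
wave/stability checks, full planning runs (≈370–1800 ms simulated) for the
four presets, ten seeded heterogeneous runs on the blocks maze, and a
101×101 sheet only in the command-line wave demo. Oracle cross-checks
(dense kernel evaluation, brute-force BFS) use sheets up to 15×15 and grids
up to 9×9 with random masks.

## Known limitations

* Single-neuron encoding: one node per manifold point; no population codes.
* The map is given, not learned; synapses are static (no plasticity).
* Exactly one simultaneous planning problem (one target, one bump).
* Euler integration at dt = 1 ms with a membrane floor is a behavioral,
  not a biophysically exact, treatment of strong inhibitory impulses.
* The `activeFrac` threshold and `deltaGain` are model conveniences; the
  underlying biology offers no direct counterpart for either.
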