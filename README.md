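# WavePlanner

Graph-traversal ("cognitive planning") problems — a mouse finding its way
through a maze, a limb moving between postures — can be solved directly on a
neural substrate. `WavePlanner` simulates a hybrid two-layer neural network
that does exactly that on a grid *cognitive map*, for computational
neuroscientists who want a reproducible, fully parameterized reference
implementation of the mechanism:

* a **wave propagation layer** *P*: paired excitatory/inhibitory Izhikevich
  neurons, one pair per grid node. Permanent DC stimulation (I = 25) of the
  *target* node makes it spike regularly, and distance-decaying excitatory
  synapses carry each spike outward as an expanding, roughly circular
  wavefront, while inhibitory partners suppress the wake and prevent
  avalanches. First-spike times order the nodes by breadth-first-search hop
  distance from the target — the wavefront *is* a parallelized BFS;
* a **continuous attractor layer** *C*: a rate-coded sheet whose
  shifted-Gaussian recurrent kernel sustains a localized bump of activity
  encoding the *current* state. Whenever a wavefront newly enters the bump
  region, a direction vector from the bump center to the overlap centroid
  biases the kernel, shifting the bump a few nodes toward the wave's origin.
  A recovery period R ensures each front moves the bump at most once.

Waves flow from the target; the bump surfs them backwards; the trajectory of
bump centers is a near-shortest path from start to target, also around
obstacles (blocked nodes with zeroed synapses and clamped rates).

## Model summary

Each Izhikevich neuron follows
`dv/dt = 0.04 v² + 5v + 140 − u + I`, `du/dt = a(bv − u)`,
with reset `v ← c`, `u ← u + d` at `v ≥ 30 mV` (RS excitatory:
a=0.02, b=0.2, c=−65, d=8; FS inhibitory: a=0.1, b=0.2, c=−65, d=2; forward
Euler, dt = 1 ms). Synapses decay with grid distance d:
`s_ee(d) = 50/d` for `0 < d ≤ 2`, `s_ei(d) = 25/d`, and
`s_ie(d) = −450/d` with the full peak −450 at d = 0 (self-inhibition of the
paired excitatory neuron).

The attractor kernel between sheet positions i and j is
`w_ij = J·exp(−‖((ix−jx)/Nx, (iy−jy)/Ny) + Δ(t)‖²/σ²) − T`
(J = 12, σ = 0.03, T = 0.05), updated through
`B_j = Σ_i A_i w_ij`, `A′ = (1−τ)B + τB/ΣA` (τ = 0.8), with rate clipping at
zero and total activation kept normalized. The direction vector is
`Δ(t) ∝ mean(C_t ∩ P_t) − p_t`, active once per incoming wavefront
(recovery period R = 12 ms).

## Worked example

```r
library(WavePlanner)

mask <- makeMaze("s_maze", 41, 41)         # two interleaved walls
man  <- buildManifold(41, 41, mask)
man
#> GridManifold: 41 x 41 nodes, 132 blocked, 1549 free

run <- runPlanner(man, start = c(5, 5), target = c(35, 35), seed = 1)
run
#> PlannerRun: status 'arrived'
#>   path hops 61, BFS hops 56, efficiency 1.089286, arrival 995 ms
#>   62 trajectory points, 132225 raster spikes, seed 1

head(trajectory(run), 4)
#>   t_ms  x y
#> 1    0  5 5
#> 2  111  7 7
#> 3  125 10 9
#> 4  140 10 8
```

The bump left the start corner when the first wavefront arrived (t = 111 ms,
the travel time across the maze), then moved once per front. It reached the
target in 995 ms using 61 center moves against a BFS optimum of 56 hops
(efficiency 1.09; 1.0 would be a perfect geodesic). On the open grid the
same call arrives in 368 ms. `initializeBump(man, c(5, 5))` by itself shows
the relaxed bump (`bumpDiameter(bump)` → 11 nodes at the default 0.1
activity threshold).

From a shell, the same run plus artifact files (`trajectory.csv`,
`raster.csv`, `summary.json`):

```sh
Rscript inst/scripts/wave-planner.R run --preset s_maze --seed 1 --out results/
Rscript inst/scripts/wave-planner.R wave-demo --nx 101 --out results/   # expanding rings
Rscript inst/scripts/wave-planner.R validate
```

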