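Package: WavePlanner
Title: Neural Graph Traversal with Spiking Waves and a Continuous Attractor Bump
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Simulates a hybrid two-layer neural network that solves
    graph-traversal (cognitive planning) problems on a grid cognitive map.
    A wave-propagation layer of paired excitatory/inhibitory Izhikevich
    neurons emits travelling activity waves from a permanently stimulated
    target node; a rate-coded continuous attractor layer sustains a
    localized bump of activity encoding the current state, which is pulled
    along incoming wavefronts back to their origin. The wavefront dynamics
    implement a parallelized breadth-first search, and the package provides
    the grid/maze topology tools, a classical BFS oracle, maze generators,
    heterogeneous (randomized) neuron configurations, and a command-line
    harness reproducing the reference simulation setups.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'topology.R'
    'wave.R'
    'attractor.R'
    'coupling.R'
    'io.R'
    'cli.R'
    'show-methods.R'
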