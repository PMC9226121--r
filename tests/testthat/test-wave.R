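cfgDefault <- new("SynapseConfig")

test_that("synaptic strength kernels follow the 1/d law within range", {
  expect_equal(synapticStrengthEE(1, cfgDefault), 50)
  expect_equal(synapticStrengthEE(0, cfgDefault), 0)  # no self-excitation
  expect_equal(synapticStrengthEE(2, cfgDefault), 25)
  expect_equal(synapticStrengthEE(2.5, cfgDefault), 0)

  expect_equal(synapticStrengthEI(1, cfgDefault), 25)
  expect_equal(synapticStrengthEI(0, cfgDefault), 0)
  expect_equal(synapticStrengthEI(3, cfgDefault), 0)

  ## the i->e peak sits at d = 0 (self-inhibition of the paired neuron)
  peak <- cfgDefault@sIEFactor * cfgDefault@sEEMax
  expect_equal(synapticStrengthIE(0, cfgDefault), peak)
  expect_lt(peak, 0)
  wide <- new("SynapseConfig", dS = 2)   # formula contract within range
  expect_equal(synapticStrengthIE(2, wide), peak / 2)
  expect_equal(synapticStrengthIE(wide@dS + 0.5, wide), 0)

  expect_error(synapticStrengthEE(-1, cfgDefault), "contract")
  expect_error(synapticStrengthIE(-0.5, cfgDefault), "contract")
})

test_that("izhikevich step holds the resting fixed point and resets spikes", {
  st <- izhikevichStep(-70, -14, rsParams(), I = 0)
  expect_equal(st$v, -70)
  expect_equal(st$u, -14)
  expect_false(st$spiked)

  st <- izhikevichStep(31, -14, rsParams(), I = 0)
  expect_true(st$spiked)
  expect_equal(st$v, -65)                       # reset to c
  expect_equal(st$u, -14 + 0.02 * (0.2 * 31 + 14) + 8)  # Euler inc + d

  expect_error(izhikevichStep(-70, -14, rsParams(), I = 0, dt = 0), "dt")
})

test_that("RS neuron driven at I = 25 spikes when the oracle says it does", {
  expected <- izhFirstSpikeOracle(0.02, 0.2, -65, 8, I = 25)
  expect_false(is.na(expected))
  expect_lte(expected, 100)

  v <- -70; u <- -14; got <- NA
  for (k in 1:200) {
    st <- izhikevichStep(v, u, rsParams(), I = 25)
    v <- st$v; u <- st$u
    if (st$spiked) { got <- k; break }
  }
  expect_equal(got, expected)
})

test_that("synaptic gathering sums last-step spikes plus DC", {
  m <- buildManifold(7, 7)
  layer <- buildWaveLayer(m, cfgDefault, stimNodes = c(3, 3))
  inp <- gatherSynapticInput(layer)   # no spikes yet
  expect_equal(sum(inp$Ie != 0), 1L)
  expect_equal(inp$Ie[nodeId(3, 3, 7) + 1], 25)
  expect_true(all(inp$Ii == 0))

  layer2 <- buildWaveLayer(m, cfgDefault)
  layer2@spikedE[nodeId(2, 3, 7) + 1] <- TRUE   # one spike at distance 1
  inp2 <- gatherSynapticInput(layer2)
  expect_equal(inp2$Ie[nodeId(3, 3, 7) + 1], 50)
  expect_equal(inp2$Ie[nodeId(2, 3, 7) + 1], 0)  # no self-excitation
  expect_equal(inp2$Ii[nodeId(3, 3, 7) + 1], 25)
  expect_equal(inp2$Ie[nodeId(4, 3, 7) + 1], 25)  # d = 2

  layer3 <- buildWaveLayer(m, cfgDefault)
  layer3@spikedI[nodeId(3, 3, 7) + 1] <- TRUE
  inp3 <- gatherSynapticInput(layer3)
  expect_equal(inp3$Ie[nodeId(3, 3, 7) + 1], -450)  # d = 0 self term
  expect_equal(inp3$Ie[nodeId(3, 4, 7) + 1], -450)  # d = 1
})

test_that("unstimulated layer stays at rest; stimulation produces waves", {
  m <- buildManifold(21, 21)
  quiet <- simulateWaveLayer(buildWaveLayer(m), 300, recordRaster = FALSE)
  expect_equal(sum(quiet$excPerStep), 0L)
  expect_true(all(is.na(quiet$firstSpikeE)))

  layer <- buildWaveLayer(m, stimNodes = c(10, 10))
  sim <- simulateWaveLayer(layer, 120, recordRaster = FALSE)
  expect_equal(sum(is.na(sim$firstSpikeE)), 0L)   # wave reached every node
})

test_that("waves cannot cross a sealed ring of blocked nodes", {
  mask <- matrix(FALSE, 21, 21)
  mask[7:15, 7:8] <- TRUE; mask[7:15, 14:15] <- TRUE
  mask[7:8, 7:15] <- TRUE; mask[14:15, 7:15] <- TRUE  # 2-thick sealed ring
  m <- buildManifold(21, 21, mask)
  layer <- buildWaveLayer(m, stimNodes = c(10, 10))   # inside the ring
  sim <- simulateWaveLayer(layer, 200, recordRaster = FALSE)
  outside <- is.na(bruteBFS(mask, c(10, 10), 2))
  blockedIds <- as.vector(mask)
  expect_true(all(is.na(sim$firstSpikeE[outside & !blockedIds])))
  expect_true(all(is.na(sim$firstSpikeE[blockedIds])))
  expect_gt(sum(!is.na(sim$firstSpikeE)), 10)   # but the inside did spike
})

test_that("randomized neuron parameters span RS..CH and LTS..FS", {
  p <- randomizeNeuronParams(500, seed = 42)
  ## endpoints of the published interpolation formulas
  expect_equal(-65 + 15 * 0^2, -65)    # r_e = 0: RS
  expect_equal(8 - 6 * 0^2, 8)
  expect_equal(-65 + 15 * 1^2, -50)    # r_e = 1: chattering
  expect_equal(8 - 6 * 1^2, 2)
  expect_equal(0.02 + 0.08 * 1, 0.1)   # r_i = 1: fast spiking
  expect_equal(0.25 - 0.05 * 1, 0.2)
  expect_equal(p$exc@c, -65 + 15 * p$rE^2)
  expect_equal(p$exc@d, 8 - 6 * p$rE^2)
  expect_equal(p$inh@a, 0.02 + 0.08 * p$rI)
  expect_equal(p$inh@b, 0.25 - 0.05 * p$rI)
  expect_true(all(p$rE >= 0 & p$rE <= 1))
  p2 <- randomizeNeuronParams(500, seed = 42)
  expect_identical(p$exc@c, p2$exc@c)  # reproducible
  p3 <- randomizeNeuronParams(500, seed = 43)
  expect_false(identical(p$exc@c, p3$exc@c))
})

test_that("synaptic jitter is bounded, sign-preserving and reproducible", {
  W <- Matrix::sparseMatrix(i = 1:10, j = c(2:10, 1),
                            x = c(seq(-5, 4) + 0.5), dims = c(10, 10))
  expect_identical(jitterSynapses(W, 1, fraction = 0), W)
  J1 <- jitterSynapses(W, 1)
  expect_true(all(abs(J1@x / W@x - 1) <= 0.1))
  expect_true(all(sign(J1@x) == sign(W@x)))
  expect_identical(J1, jitterSynapses(W, 1))
  expect_false(identical(J1@x, jitterSynapses(W, 2)@x))
  expect_error(jitterSynapses(W, 1, fraction = 1.2), "fraction")
})

test_that("heterogeneous layer wiring differs but stays within jitter bounds", {
  m <- buildManifold(15, 15)
  hom <- buildWaveLayer(m)
  het <- buildWaveLayer(m, het = new("HeterogeneityConfig", enabled = TRUE,
                                     seed = 5L))
  expect_null(hom@wEE)
  expect_false(is.null(het@wEE))
  ## jittered weights stay within +/-10% of the homogeneous law
  ref <- Reduce(`+`, Map(function(a, s) s * a, hom@adj,
                         synapticStrengthEE(hom@adjDist, hom@cfg)))
  ratio <- het@wEE@x / methods::as(ref, "CsparseMatrix")@x
  expect_true(all(abs(ratio - 1) <= 0.1))
  expect_length(het@excParams@c, 225L)
})
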