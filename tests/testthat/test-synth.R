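test_that("random network generation hits the requested edge count", {
  net <- generateNetwork(100, density = 0.163, topology = "random", seed = 1)
  expect_true(isDirected(net))
  expect_equal(sum(adjacencyMatrix(net)), round(0.163 * 100 * 99))  # 1614
  expect_equal(diag(adjacencyMatrix(net)), rep(0, 100))
  expect_equal(networkDensity(net), 1614 / 9900)

  # near-saturation: both possible directed edges between 2 neurons
  net2 <- generateNetwork(2, density = 0.99, seed = 3)
  expect_equal(sum(adjacencyMatrix(net2)), 2)

  # realized density within one edge of the request, over assorted sizes
  for (n in c(10, 37, 80)) {
    net3 <- generateNetwork(n, 0.12, seed = n)
    expect_lte(abs(sum(adjacencyMatrix(net3)) - 0.12 * n * (n - 1)), 1)
  }
})

test_that("network generation is reproducible and rejects degenerate density", {
  a <- generateNetwork(50, 0.02, seed = 42)
  b <- generateNetwork(50, 0.02, seed = 42)
  expect_identical(adjacencyMatrix(a), adjacencyMatrix(b))
  expect_error(generateNetwork(5, 0.001, seed = 1), "0 edges")
  expect_error(generateNetwork(10, 1.2, seed = 1), "density")
})

test_that("small-world topology yields a valid undirected network", {
  net <- generateNetwork(40, 0.2, topology = "small_world", seed = 2)
  a <- adjacencyMatrix(net)
  expect_false(isDirected(net))
  expect_equal(a, t(a))
  expect_equal(diag(a), rep(0, 40))
  expect_lt(abs(networkDensity(net) - 0.2), 0.05)
})

test_that("uncoupled spike totals match the Poisson expectation", {
  net <- generateNetwork(100, 0.1, seed = 1)
  cfg <- simConfig(100, 600, coupling_strength = 0, seed = 9)
  sp <- simulateSpikes(net, cfg)
  expect_true(all(as.matrix(sp) >= 0))
  expect_true(all(as.matrix(sp) == round(as.matrix(sp))))
  mu <- 100 * 0.1 * 600                       # expected total count
  expect_lt(abs(sum(as.matrix(sp)) - mu), 3 * sqrt(mu))
  # realized mean rate within 50% of the configured rate
  rate <- sum(as.matrix(sp)) / (100 * 600)
  expect_lt(abs(rate - 0.1), 0.05)
})

test_that("spike simulation is deterministic and respects empty networks", {
  net <- generateNetwork(10, 0.1, seed = 4)
  cfg <- simConfig(10, 60, seed = 5)
  expect_identical(as.matrix(simulateSpikes(net, cfg)),
                   as.matrix(simulateSpikes(net, cfg)))

  cfg0 <- simConfig(10, 60, firing_rate_hz = 0, coupling_strength = 0,
                    seed = 5)
  expect_true(all(as.matrix(simulateSpikes(net, cfg0)) == 0))
})

test_that("connected pairs co-fire at lag 1 more than unconnected pairs", {
  # two neurons driving one target each, plus an unconnected control
  adj <- matrix(0, 4, 4)
  adj[1, 2] <- 1            # 1 -> 2; neurons 3, 4 unconnected
  adj[3, 4] <- 0
  net <- new("GroundTruthNetwork", adjacency = adj, directed = TRUE)
  cfg <- simConfig(4, 1200, firing_rate_hz = 0.5, coupling_strength = 0.5,
                   seed = 8)
  s <- as.matrix(simulateSpikes(net, cfg))
  lag1 <- function(i, j) sum(s[i, -ncol(s)] * s[j, -1])
  expect_gt(lag1(1, 2), lag1(3, 4))
  expect_gt(lag1(1, 2), lag1(1, 3))
})

test_that("excessive coupling triggers the clipping warning", {
  adj <- matrix(1, 3, 3); diag(adj) <- 0
  net <- new("GroundTruthNetwork", adjacency = adj, directed = TRUE)
  cfg <- simConfig(3, 20, firing_rate_hz = 30, frame_rate_hz = 50,
                   coupling_strength = 5, seed = 1)
  expect_warning(simulateSpikes(net, cfg), "clipped")
})

test_that("fluorescence rendering is the exact AR(1) convolution", {
  s <- matrix(0, 1, 30); s[1, 10] <- 1
  cfg <- simConfig(1, 30 / 50, noise_sd = 0, seed = 1,
                   decay_s = -1 / (50 * log(0.5)))  # gamma = 0.5
  tr <- renderFluorescence(spk(s, "ground_truth"), cfg)
  v <- as.matrix(tr)
  expect_equal(v[1, 10:12], c(1, 0.5, 0.25))
  expect_equal(v[1, 1:9], rep(0, 9))
  expect_equal(v[1, 13:30], 0.5^(3:20) , tolerance = 1e-12)

  # all-zero spikes render to an all-zero trace
  z <- renderFluorescence(spk(matrix(0, 2, 20), "ground_truth"), cfg)
  expect_true(all(as.matrix(z) == 0))
})

test_that("rendering is linear in the spike amplitudes at zero noise", {
  set.seed(31)
  s <- matrix(rpois(200, 0.2), 2, 100)
  cfg <- simConfig(2, 2, noise_sd = 0, seed = 1)
  one <- as.matrix(renderFluorescence(spk(s, "ground_truth"), cfg))
  three <- as.matrix(renderFluorescence(spk(3 * s, "ground_truth"), cfg))
  expect_equal(three, 3 * one, tolerance = 1e-12)
})

test_that("rendering noise has the configured standard deviation", {
  cfg <- simConfig(1, 2000, noise_sd = 0.1, seed = 17)
  tr <- renderFluorescence(spk(matrix(0, 1, 1e5), "ground_truth"), cfg)
  expect_gt(sd(as.matrix(tr)), 0.095)
  expect_lt(sd(as.matrix(tr)), 0.105)
})

test_that("simulateDataset wires network, spikes and traces consistently", {
  ds <- simulateDataset(simConfig(12, 30, seed = 3), density = 0.15)
  expect_s4_class(ds$network, "GroundTruthNetwork")
  expect_s4_class(ds$spikes, "SpikeMatrix")
  expect_s4_class(ds$traces, "FluorescenceTraces")
  expect_equal(nNeurons(ds$traces), 12)
  expect_equal(nFrames(ds$traces), round(30 * 50))
  ds2 <- simulateDataset(simConfig(12, 30, seed = 3), density = 0.15)
  expect_identical(as.matrix(ds$traces), as.matrix(ds2$traces))
})
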