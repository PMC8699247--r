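#' Simulation configuration constructor
#'
#' Builds a [SimConfig-class] with defaults matching the study conditions
#' the simulator emulates: sparse random networks imaged at 50 Hz with a
#' baseline firing rate of 0.1 Hz per neuron.
#'
#' @param n_neurons number of neurons.
#' @param duration_s recording duration in seconds.
#' @param frame_rate_hz imaging rate (frames/second); default 50.
#' @param firing_rate_hz baseline firing rate per neuron; default 0.1.
#' @param coupling_strength per-presynaptic-spike increment of a neuron's
#'   next-frame firing probability. The default 0.1 keeps a 60-neuron,
#'   density-0.1 network subcritical (branching ratio about 0.6).
#' @param decay_s indicator decay time constant in seconds; default 0.5.
#' @param noise_sd additive Gaussian noise sd on dF/F0; default 0.2.
#' @param seed integer RNG seed.
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(n_neurons = 10, duration_s = 60, seed = 1)
#' @export
simConfig <- function(n_neurons, duration_s, frame_rate_hz = 50,
                      firing_rate_hz = 0.1, coupling_strength = 0.1,
                      decay_s = 0.5, noise_sd = 0.2, seed = 1L) {
  new("SimConfig", n_neurons = as.integer(n_neurons),
      duration_s = as.numeric(duration_s),
      frame_rate_hz = as.numeric(frame_rate_hz),
      firing_rate_hz = as.numeric(firing_rate_hz),
      coupling_strength = as.numeric(coupling_strength),
      decay_s = as.numeric(decay_s), noise_sd = as.numeric(noise_sd),
      seed = as.integer(seed))
}

#' Generate a ground-truth network
#'
#' Draws a random network over \code{n_neurons} nodes at a requested edge
#' density. Topology \code{"random"} places directed edges uniformly at
#' random (Erdos-Renyi); \code{"small_world"} draws an undirected
#' Watts-Strogatz small-world graph via \pkg{igraph}, with the ring
#' neighbourhood chosen to match the requested density.
#'
#' @param n_neurons number of neurons (>= 2).
#' @param density requested edge density, strictly between 0 and 1. The
#'   realized number of edges is \code{round(density * n * (n - 1))} for
#'   the directed random topology.
#' @param topology \code{"random"} (directed) or \code{"small_world"}
#'   (undirected).
#' @param seed integer RNG seed; the draw is reproducible for a fixed seed.
#' @return a [GroundTruthNetwork-class].
#' @examples
#' net <- generateNetwork(50, density = 0.1, seed = 1)
#' networkDensity(net)
#' @export
generateNetwork <- function(n_neurons, density,
                            topology = c("random", "small_world"),
                            seed = 1L) {
  topology <- match.arg(topology)
  n_neurons <- as.integer(n_neurons)
  stopifnot(n_neurons >= 2L)
  if (density <= 0 || density >= 1)
    stop("density must be strictly between 0 and 1")

  if (topology == "random") {
    n_slots <- n_neurons * (n_neurons - 1L)
    n_edges <- round(density * n_slots)
    if (n_edges < 1)
      stop("requested density ", density, " rounds to 0 edges for ",
           n_neurons, " neurons; increase density or network size")
    adj <- matrix(0, n_neurons, n_neurons)
    off_diag <- which(row(adj) != col(adj))
    set.seed(seed)
    adj[sample(off_diag, n_edges)] <- 1
    new("GroundTruthNetwork", adjacency = adj, directed = TRUE)
  } else {
    # Watts-Strogatz: ring lattice of nei neighbours per side, then rewire.
    # Undirected edge count is n * nei, so nei is set from the density.
    nei <- round(density * (n_neurons - 1) / 2)
    if (nei < 1)
      stop("requested density ", density, " rounds to 0 ring neighbours for ",
           n_neurons, " neurons; increase density or network size")
    set.seed(seed)
    g <- igraph::sample_smallworld(dim = 1, size = n_neurons, nei = nei,
                                   p = 0.1, loops = FALSE, multiple = FALSE)
    adj <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    adj[adj > 1] <- 1
    diag(adj) <- 0
    new("GroundTruthNetwork", adjacency = adj, directed = FALSE)
  }
}

#' Simulate coupled spike trains on a network
#'
#' Discrete-time conditionally Poisson spiking: neuron j's firing intensity
#' in frame t is the baseline \code{firing_rate_hz / frame_rate_hz} plus
#' \code{coupling_strength} times the summed spike counts of its presynaptic
#' neurons in frame t - 1, clipped to \eqn{[0, 1]}. Frame counts are drawn
#' Poisson with that intensity, so several spikes may land between two
#' frames. Connected pairs therefore show excess lag-1 co-firing, the
#' signal the downstream inference exploits.
#'
#' @param network a [GroundTruthNetwork-class]; entry (i, j) couples the
#'   spikes of i into the intensity of j.
#' @param cfg a [SimConfig-class]. \code{cfg@seed} drives the RNG.
#' @return a [SpikeMatrix-class] at stage \code{"ground_truth"} with
#'   integer spike counts.
#' @examples
#' net <- generateNetwork(10, 0.1, seed = 1)
#' sp <- simulateSpikes(net, simConfig(10, 60, seed = 2))
#' @export
simulateSpikes <- function(network, cfg) {
  stopifnot(is(network, "GroundTruthNetwork"), is(cfg, "SimConfig"))
  n <- nNeurons(network)
  if (n != cfg@n_neurons)
    stop("network has ", n, " neurons but cfg declares ", cfg@n_neurons)
  base <- cfg@firing_rate_hz / cfg@frame_rate_hz
  if (base >= 1)
    stop("firing_rate_hz / frame_rate_hz must be < 1 (got ", base, ")")
  n_frames <- round(cfg@duration_s * cfg@frame_rate_hz)
  adj_t <- t(network@adjacency)   # row j = inputs of neuron j

  set.seed(cfg@seed)
  spikes <- matrix(0, n, n_frames)
  clipped <- 0L
  prev <- numeric(n)
  for (t in seq_len(n_frames)) {
    lambda <- base + cfg@coupling_strength * as.numeric(adj_t %*% prev)
    n_clip <- sum(lambda > 1)
    if (n_clip > 0) {
      clipped <- clipped + n_clip
      lambda <- pmin(lambda, 1)
    }
    prev <- rpois(n, lambda)
    spikes[, t] <- prev
  }
  if (clipped > 0.1 * n * n_frames)
    warning("firing intensity was clipped in ",
            sprintf("%.1f%%", 100 * clipped / (n * n_frames)),
            " of neuron-frames; coupling_strength is too strong for a ",
            "faithful simulation")
  new("SpikeMatrix", values = spikes, frame_rate_hz = cfg@frame_rate_hz,
      stage = "ground_truth")
}

#' Render fluorescence traces from spikes
#'
#' Convolves each neuron's spike train with a causal exponential indicator
#' kernel via the AR(1) recursion \eqn{c(t) = \gamma c(t-1) + s(t)} with
#' \eqn{\gamma = \exp(-1 / (decay_s \cdot frame\_rate))}, then adds i.i.d.
#' Gaussian measurement noise. With \code{noise_sd = 0} the trace is the
#' exact AR(1) convolution, so rendering is linear in the spike amplitudes.
#'
#' @param spikes a [SpikeMatrix-class].
#' @param cfg a [SimConfig-class] supplying \code{decay_s},
#'   \code{noise_sd} and the RNG seed (the noise stream is seeded with
#'   \code{cfg@seed + 1} so it is independent of the spike draw).
#' @return a [FluorescenceTraces-class] of dF/F0 values.
#' @export
renderFluorescence <- function(spikes, cfg) {
  stopifnot(is(spikes, "SpikeMatrix"), is(cfg, "SimConfig"))
  gamma <- exp(-1 / (cfg@decay_s * spikes@frame_rate_hz))
  s <- spikes@values
  traces <- t(apply(s, 1L, function(row)
    as.numeric(stats::filter(row, gamma, method = "recursive"))))
  if (nrow(s) == 1L) traces <- matrix(traces, nrow = 1L)
  if (cfg@noise_sd > 0) {
    set.seed(cfg@seed + 1L)
    traces <- traces + matrix(rnorm(length(traces), sd = cfg@noise_sd),
                              nrow = nrow(traces))
  }
  new("FluorescenceTraces", values = traces,
      frame_rate_hz = spikes@frame_rate_hz)
}

#' Simulate a complete dataset
#'
#' Convenience wrapper: network, spikes and fluorescence in one call, the
#' standard entry point for benchmarking the pipeline against known ground
#' truth.
#'
#' @param cfg a [SimConfig-class].
#' @param density network edge density.
#' @param topology passed to [generateNetwork()].
#' @return list with elements \code{network} ([GroundTruthNetwork-class]),
#'   \code{spikes} ([SpikeMatrix-class]) and \code{traces}
#'   ([FluorescenceTraces-class]).
#' @examples
#' ds <- simulateDataset(simConfig(20, 120, seed = 3), density = 0.1)
#' @export
simulateDataset <- function(cfg, density, topology = "random") {
  network <- generateNetwork(cfg@n_neurons, density, topology,
                             seed = cfg@seed)
  spikes <- simulateSpikes(network, cfg)
  traces <- renderFluorescence(spikes, cfg)
  list(network = network, spikes = spikes, traces = traces)
}
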