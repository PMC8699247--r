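#' @describeIn nNeurons rows of the adjacency matrix.
#' @export
setMethod("nNeurons", "GroundTruthNetwork", function(x) nrow(x@adjacency))

#' @describeIn nNeurons rows of the spike matrix.
#' @export
setMethod("nNeurons", "SpikeMatrix", function(x) nrow(x@values))

#' @describeIn nNeurons rows of the trace matrix.
#' @export
setMethod("nNeurons", "FluorescenceTraces", function(x) nrow(x@values))

#' @describeIn nNeurons dimension of the partial-correlation matrix.
#' @export
setMethod("nNeurons", "Connectome", function(x) nrow(x@partial_corr))

#' @describeIn nFrames columns of the spike matrix.
#' @export
setMethod("nFrames", "SpikeMatrix", function(x) ncol(x@values))

#' @describeIn nFrames columns of the trace matrix.
#' @export
setMethod("nFrames", "FluorescenceTraces", function(x) ncol(x@values))

#' @describeIn frameRate imaging rate of the spike matrix.
#' @export
setMethod("frameRate", "SpikeMatrix", function(x) x@frame_rate_hz)

#' @describeIn frameRate imaging rate of the traces.
#' @export
setMethod("frameRate", "FluorescenceTraces", function(x) x@frame_rate_hz)

#' @describeIn spikeStage stage tag accessor.
#' @export
setMethod("spikeStage", "SpikeMatrix", function(x) x@stage)

#' @describeIn adjacencyMatrix adjacency accessor.
#' @export
setMethod("adjacencyMatrix", "GroundTruthNetwork", function(x) x@adjacency)

#' @describeIn isDirected directedness flag accessor.
#' @export
setMethod("isDirected", "GroundTruthNetwork", function(x) x@directed)

#' @describeIn networkDensity realized density.
#' @export
setMethod("networkDensity", "GroundTruthNetwork", function(x) {
  n <- nNeurons(x)
  if (n < 2) return(0)
  m <- sum(x@adjacency)
  if (x@directed) m / (n * (n - 1)) else (m / 2) / (n * (n - 1) / 2)
})

#' @describeIn pcorMatrix matrix accessor.
#' @export
setMethod("pcorMatrix", "Connectome", function(x) x@partial_corr)

#' @describeIn neuronIds identifier accessor.
#' @export
setMethod("neuronIds", "Connectome", function(x) x@neuron_ids)

#' @describeIn silentNeurons silent-neuron accessor.
#' @export
setMethod("silentNeurons", "Connectome", function(x) x@silent_neurons)

#' @describeIn auroc AUROC accessor.
#' @export
setMethod("auroc", "EvalResult", function(x) x@auroc)

#' @describeIn aupr AUPR accessor.
#' @export
setMethod("aupr", "EvalResult", function(x) x@aupr)

#' Extract the numeric matrix from a spike matrix
#' @param x a [SpikeMatrix-class].
#' @param ... ignored.
#' @return numeric matrix (neurons x frames).
#' @export
setMethod("as.matrix", "SpikeMatrix", function(x, ...) x@values)

#' Extract the numeric matrix from fluorescence traces
#' @param x a [FluorescenceTraces-class].
#' @param ... ignored.
#' @return numeric matrix (neurons x frames).
#' @export
setMethod("as.matrix", "FluorescenceTraces", function(x, ...) x@values)

setMethod("show", "GroundTruthNetwork", function(object) {
  cat(sprintf("GroundTruthNetwork: %d neurons, %s, %d edges (density %.3f)\n",
              nNeurons(object),
              if (object@directed) "directed" else "undirected",
              if (object@directed) sum(object@adjacency)
              else sum(object@adjacency) / 2,
              networkDensity(object)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf(paste0(
    "SimConfig: %d neurons, %.0f s at %.1f Hz\n",
    "  firing %.3f Hz, coupling %.3f, decay %.2f s, noise sd %.3f, seed %d\n"),
    object@n_neurons, object@duration_s, object@frame_rate_hz,
    object@firing_rate_hz, object@coupling_strength, object@decay_s,
    object@noise_sd, object@seed))
})

setMethod("show", "SpikeMatrix", function(object) {
  cat(sprintf(
    "SpikeMatrix [%s]: %d neurons x %d frames at %.1f Hz, %d nonzero\n",
    object@stage, nNeurons(object), nFrames(object), object@frame_rate_hz,
    sum(object@values > 0)))
})

setMethod("show", "FluorescenceTraces", function(object) {
  cat(sprintf("FluorescenceTraces: %d neurons x %d frames at %.1f Hz\n",
              nNeurons(object), nFrames(object), object@frame_rate_hz))
})

setMethod("show", "Connectome", function(object) {
  cat(sprintf(
    "Connectome: %d neurons, ridge %.2e, %d silent\n",
    nNeurons(object), object@regularization_used,
    length(object@silent_neurons)))
})

setMethod("show", "EvalResult", function(object) {
  cat(sprintf(
    "EvalResult: AUROC %.4f, AUPR %.4f (%d positives / %d negatives)\n",
    object@auroc, object@aupr, object@n_positives, object@n_negatives))
})
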