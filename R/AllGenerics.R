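#' Number of neurons in an object
#' @param x a fluoroconn data object.
#' @return integer scalar.
#' @export
setGeneric("nNeurons", function(x) standardGeneric("nNeurons"))

#' Number of imaging frames in an object
#' @param x a fluoroconn data object.
#' @return integer scalar.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Imaging frame rate (Hz)
#' @param x a fluoroconn data object.
#' @return numeric scalar, frames per second.
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))

#' Processing stage tag of a spike matrix
#' @param x a [SpikeMatrix-class].
#' @return character scalar.
#' @export
setGeneric("spikeStage", function(x) standardGeneric("spikeStage"))

#' Adjacency matrix of a ground-truth network
#' @param x a [GroundTruthNetwork-class].
#' @return square 0/1 matrix.
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' Is the network directed?
#' @param x a [GroundTruthNetwork-class].
#' @return logical scalar.
#' @export
setGeneric("isDirected", function(x) standardGeneric("isDirected"))

#' Realized edge density of a network
#'
#' Fraction of possible off-diagonal entries that are present: the edge
#' count divided by n(n-1) for a directed network, or by n(n-1)/2 for an
#' undirected one.
#'
#' @param x a [GroundTruthNetwork-class].
#' @return numeric scalar in \eqn{[0, 1]}.
#' @export
setGeneric("networkDensity", function(x) standardGeneric("networkDensity"))

#' Partial-correlation matrix of a connectome
#' @param x a [Connectome-class].
#' @return symmetric numeric matrix with zero diagonal.
#' @export
setGeneric("pcorMatrix", function(x) standardGeneric("pcorMatrix"))

#' Neuron identifiers of a connectome
#' @param x a [Connectome-class].
#' @return integer vector.
#' @export
setGeneric("neuronIds", function(x) standardGeneric("neuronIds"))

#' Silent neurons excluded from a connectome fit
#' @param x a [Connectome-class].
#' @return integer vector of indices into [neuronIds()].
#' @export
setGeneric("silentNeurons", function(x) standardGeneric("silentNeurons"))

#' Area under the ROC curve
#' @param x an [EvalResult-class].
#' @return numeric scalar in \eqn{[0, 1]}.
#' @export
setGeneric("auroc", function(x) standardGeneric("auroc"))

#' Area under the precision-recall curve
#' @param x an [EvalResult-class].
#' @return numeric scalar in \eqn{[0, 1]}.
#' @export
setGeneric("aupr", function(x) standardGeneric("aupr"))
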