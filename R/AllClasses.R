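#' @import methods
#' @importFrom stats cov quantile rpois rnorm runif rbinom sd var
#' @importFrom utils head tail
#' @useDynLib fluoroconn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.VALID_STAGES <- c("ground_truth", "deconvolved", "thresholded",
                   "binarized", "smoothed")

#' Ground-truth neuronal network
#'
#' Adjacency structure of a simulated neuronal network, used both to drive
#' the spiking simulator and as the reference when scoring an inferred
#' connectome. Entry \code{(i, j) = 1} means a connection from neuron i to
#' neuron j; the diagonal is always zero (no self-connections).
#'
#' @slot adjacency square 0/1 matrix with zero diagonal.
#' @slot directed logical; if \code{FALSE} the adjacency is symmetric and
#'   each undirected pair is stored in both triangles.
#'
#' @seealso [generateNetwork()], [symmetrizeTruth()]
#' @export
setClass("GroundTruthNetwork",
  representation(adjacency = "matrix", directed = "logical"),
  validity = function(object) {
    a <- object@adjacency
    msg <- character()
    if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
    if (!all(a %in% c(0, 1))) msg <- c(msg, "adjacency entries must be 0 or 1")
    if (nrow(a) > 0 && any(diag(a) != 0))
      msg <- c(msg, "adjacency diagonal must be zero (no self-connections)")
    if (length(object@directed) != 1L)
      msg <- c(msg, "directed must be a single logical")
    if (isFALSE(object@directed) && nrow(a) > 0 && !isTRUE(all(a == t(a))))
      msg <- c(msg, "undirected network must have a symmetric adjacency")
    if (length(msg)) msg else TRUE
  })

#' Simulation configuration
#'
#' Parameters of the ground-truth simulator: a discrete-time conditionally
#' Poisson spiking network observed through a calcium indicator with AR(1)
#' decay and additive Gaussian measurement noise.
#'
#' @slot n_neurons number of neurons.
#' @slot duration_s recording length in seconds.
#' @slot frame_rate_hz imaging rate in frames per second.
#' @slot firing_rate_hz baseline firing rate per neuron (spikes/second).
#' @slot coupling_strength per-spike increment in a postsynaptic neuron's
#'   next-frame firing probability (dimensionless, excitatory).
#' @slot decay_s fluorescence indicator decay time constant in seconds.
#' @slot noise_sd standard deviation of additive Gaussian noise on dF/F0.
#' @slot seed integer RNG seed.
#'
#' @seealso [simConfig()], [simulateSpikes()], [renderFluorescence()]
#' @export
setClass("SimConfig",
  representation(n_neurons = "integer", duration_s = "numeric",
                 frame_rate_hz = "numeric", firing_rate_hz = "numeric",
                 coupling_strength = "numeric", decay_s = "numeric",
                 noise_sd = "numeric", seed = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@n_neurons < 1L) msg <- c(msg, "n_neurons must be >= 1")
    if (object@duration_s <= 0) msg <- c(msg, "duration_s must be > 0")
    if (object@frame_rate_hz <= 0) msg <- c(msg, "frame_rate_hz must be > 0")
    if (object@firing_rate_hz < 0) msg <- c(msg, "firing_rate_hz must be >= 0")
    if (object@coupling_strength < 0)
      msg <- c(msg, "coupling_strength must be >= 0")
    if (object@decay_s <= 0) msg <- c(msg, "decay_s must be > 0")
    if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Spike amplitude matrix
#'
#' A neurons-by-frames matrix of non-negative spike amplitudes, tagged with
#' the processing stage it came from (simulator ground truth, deconvolved,
#' thresholded, binarized or smoothed).
#'
#' @slot values numeric matrix, neurons in rows, frames in columns; all
#'   entries non-negative. At stage \code{"binarized"} entries are 0/1.
#' @slot frame_rate_hz imaging rate of the underlying recording.
#' @slot stage character stage tag.
#' @slot metadata list of stage-specific extras (e.g. the per-neuron
#'   thresholds applied by [thresholdSpikes()]).
#'
#' @export
setClass("SpikeMatrix",
  representation(values = "matrix", frame_rate_hz = "numeric",
                 stage = "character", metadata = "list"),
  prototype(metadata = list()),
  validity = function(object) {
    msg <- character()
    v <- object@values
    if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
    if (any(!is.finite(v))) msg <- c(msg, "values must be finite")
    else if (any(v < 0)) msg <- c(msg, "spike amplitudes must be non-negative")
    if (!(object@stage %in% .VALID_STAGES))
      msg <- c(msg, paste0("stage must be one of: ",
                           paste(.VALID_STAGES, collapse = ", ")))
    if (identical(object@stage, "binarized") && is.numeric(v) &&
        !all(v %in% c(0, 1)))
      msg <- c(msg, "binarized stage requires all entries in {0, 1}")
    if (object@frame_rate_hz <= 0) msg <- c(msg, "frame_rate_hz must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Fluorescence traces
#'
#' A neurons-by-frames matrix of baseline-normalized fluorescence (dF/F0)
#' with its imaging rate. Rows are neurons, columns are frames.
#'
#' @slot values numeric matrix of dF/F0 values.
#' @slot frame_rate_hz imaging rate in frames per second.
#'
#' @export
setClass("FluorescenceTraces",
  representation(values = "matrix", frame_rate_hz = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@values)) msg <- c(msg, "values must be numeric")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "values must be finite")
    if (object@frame_rate_hz <= 0) msg <- c(msg, "frame_rate_hz must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Inferred functional connectome
#'
#' Symmetric matrix of partial correlation coefficients between neuron
#' pairs, with zero diagonal. Off-diagonal entry \eqn{p_{ij}} is the
#' correlation between the activity of neurons i and j after controlling
#' for all other recorded neurons, computed from the precision matrix as
#' \eqn{p_{ij} = -\Phi_{ij} / \sqrt{\Phi_{ii} \Phi_{jj}}}.
#'
#' @slot partial_corr symmetric numeric matrix, zero diagonal, entries in
#'   \eqn{[-1, 1]}.
#' @slot neuron_ids ordered neuron identifiers (0-based integers by
#'   convention in files).
#' @slot regularization_used ridge multiplier actually applied when the
#'   covariance matrix was inverted (0 when none was needed).
#' @slot silent_neurons indices (into \code{neuron_ids}) of neurons whose
#'   activity was all-zero after preprocessing and which were excluded from
#'   the covariance step; their partial correlations are reported as 0.
#'
#' @seealso [inferConnectome()], [partialCorrelations()], [rankEdges()]
#' @export
setClass("Connectome",
  representation(partial_corr = "matrix", neuron_ids = "integer",
                 regularization_used = "numeric", silent_neurons = "integer"),
  prototype(regularization_used = 0, silent_neurons = integer()),
  validity = function(object) {
    p <- object@partial_corr
    msg <- character()
    if (nrow(p) != ncol(p)) msg <- c(msg, "partial_corr must be square")
    if (length(object@neuron_ids) != nrow(p))
      msg <- c(msg, "neuron_ids length must match matrix dimension")
    if (nrow(p) > 0) {
      if (max(abs(p - t(p))) > 1e-10)
        msg <- c(msg, "partial_corr must be symmetric (tol 1e-10)")
      if (any(abs(diag(p)) > 0))
        msg <- c(msg, "partial_corr diagonal must be zero")
      if (max(abs(p)) > 1 + 1e-10)
        msg <- c(msg, "|partial correlations| must be <= 1")
    }
    if (length(msg)) msg else TRUE
  })

#' Ranked-list evaluation result
#'
#' ROC and precision-recall curves with their areas (AUROC, AUPR) from
#' scoring a ranked edge list against a ground-truth network.
#'
#' @slot auroc area under the ROC curve, in \eqn{[0, 1]}.
#' @slot aupr area under the precision-recall curve, in \eqn{[0, 1]}.
#' @slot roc_points two-column matrix (FPR, TPR) from (0,0) to (1,1).
#' @slot pr_points two-column matrix (recall, precision).
#' @slot n_positives number of true pairs in the ground truth.
#' @slot n_negatives number of absent pairs.
#'
#' @seealso [scoreRanking()]
#' @export
setClass("EvalResult",
  representation(auroc = "numeric", aupr = "numeric",
                 roc_points = "matrix", pr_points = "matrix",
                 n_positives = "integer", n_negatives = "integer"),
  validity = function(object) {
    msg <- character()
    if (object@auroc < 0 || object@auroc > 1)
      msg <- c(msg, "auroc must be in [0, 1]")
    if (object@aupr < 0 || object@aupr > 1)
      msg <- c(msg, "aupr must be in [0, 1]")
    rp <- object@roc_points
    if (ncol(rp) != 2) msg <- c(msg, "roc_points must have two columns")
    else {
      if (any(rp[1, ] != c(0, 0))) msg <- c(msg, "ROC must start at (0, 0)")
      if (any(rp[nrow(rp), ] != c(1, 1))) msg <- c(msg, "ROC must end at (1, 1)")
    }
    if (length(msg)) msg else TRUE
  })
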