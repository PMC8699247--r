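#' Covariance matrix of neuronal activity
#'
#' Sample covariance of the neurons' activity with frames as observations
#' (n - 1 denominator). Neurons with zero variance are flagged in the
#' \code{"zero_variance"} attribute; callers must drop or handle them
#' before inverting.
#'
#' @param z a [SpikeMatrix-class] or a neurons-by-frames numeric matrix.
#' @return symmetric positive semidefinite neurons-by-neurons matrix.
#' @export
covarianceMatrix <- function(z) {
  v <- if (is(z, "SpikeMatrix")) z@values else z
  stopifnot(is.matrix(v), is.numeric(v))
  if (ncol(v) < 2) stop("need at least 2 frames to estimate covariance")
  sigma <- cov(t(v))
  zv <- which(diag(sigma) == 0)
  if (length(zv)) attr(sigma, "zero_variance") <- zv
  sigma
}

#' Precision matrix with ridge escalation
#'
#' Inverts the covariance matrix, \eqn{\Phi = \Sigma^{-1}}. If \eqn{\Sigma}
#' is singular or numerically ill-conditioned (duplicated or silent
#' neurons, fewer frames than neurons), a ridge \code{ridge * mean(diag) *
#' I} is added, escalating 0, 1e-8, 1e-6, ... until the inverse is finite
#' and well-defined; each escalation is reported via \code{message()}. The
#' multiplier actually used is returned in the \code{"ridge_used"}
#' attribute.
#'
#' @param sigma symmetric covariance matrix with strictly positive
#'   diagonal.
#' @param ridge starting ridge multiplier (default 0: plain inversion when
#'   possible).
#' @return the precision matrix, with attribute \code{"ridge_used"}.
#' @export
precisionMatrix <- function(sigma, ridge = 0) {
  stopifnot(is.matrix(sigma), nrow(sigma) == ncol(sigma))
  if (max(abs(sigma - t(sigma))) > 1e-8 * max(1, max(abs(sigma))))
    stop("sigma must be symmetric")
  zd <- which(diag(sigma) <= 0)
  if (length(zd))
    stop("sigma has non-positive diagonal entries (constant neurons) at ",
         "indices: ", paste(zd, collapse = ", "),
         "; drop or jitter them before inversion")
  stopifnot(ridge >= 0)
  scale <- mean(diag(sigma))
  ladder <- unique(c(ridge, 1e-8 * 100^(0:6)))
  ladder <- ladder[ladder >= ridge]
  for (r in ladder) {
    sig_r <- sigma + r * scale * diag(nrow(sigma))
    phi <- tryCatch(solve(sig_r), error = function(e) NULL)
    if (!is.null(phi) && all(is.finite(phi)) &&
        is.finite(kappa(sig_r, exact = FALSE))) {
      if (r > ridge)
        message("covariance ill-conditioned; ridge escalated to ", r)
      attr(phi, "ridge_used") <- r
      return(phi)
    }
  }
  stop("covariance matrix could not be inverted even with maximal ridge")
}

#' Partial correlations from a precision matrix
#'
#' Normalizes the precision matrix into partial correlation coefficients,
#' \eqn{p_{ij} = -\Phi_{ij} / \sqrt{\Phi_{ii}\Phi_{jj}}}: the correlation
#' between neurons i and j's activity after controlling for all other
#' neurons. The diagonal is set to 0 by convention (self-edges are
#' meaningless). Tiny numerical overshoot beyond |1| (< 1e-8) is clipped;
#' larger overshoot is an error.
#'
#' @param phi symmetric precision matrix with strictly positive diagonal.
#' @return a [Connectome-class].
#' @examples
#' sigma <- matrix(0.5, 3, 3); diag(sigma) <- 1
#' pcorMatrix(partialCorrelations(solve(sigma)))[1, 2]  # 1/3
#' @export
partialCorrelations <- function(phi) {
  stopifnot(is.matrix(phi), nrow(phi) == ncol(phi))
  if (max(abs(phi - t(phi))) > 1e-8 * max(1, max(abs(phi))))
    stop("phi must be symmetric")
  d <- diag(phi)
  if (any(d <= 0))
    stop("invalid precision matrix: non-positive diagonal at indices ",
         paste(which(d <= 0), collapse = ", "))
  p <- -phi / sqrt(outer(d, d))
  p <- (p + t(p)) / 2  # remove rounding asymmetry
  diag(p) <- 0
  overshoot <- max(abs(p)) - 1
  if (overshoot > 1e-8)
    stop("partial correlations overshoot |1| by ", signif(overshoot, 3),
         "; precision matrix is not valid")
  p[p > 1] <- 1
  p[p < -1] <- -1
  ridge <- attr(phi, "ridge_used")
  new("Connectome", partial_corr = p,
      neuron_ids = seq_len(nrow(p)) - 1L,
      regularization_used = if (is.null(ridge)) 0 else ridge)
}

#' Ranked edge list of a connectome
#'
#' Orders all neuron pairs (i < j) by decreasing magnitude of partial
#' correlation; ties are broken lexicographically by (i, j) so the ranking
#' is deterministic. The signed coefficient is retained alongside the
#' magnitude score.
#'
#' @param conn a [Connectome-class].
#' @return \code{data.frame} with columns \code{neuron_i}, \code{neuron_j}
#'   (identifiers, i < j), \code{pcor} (signed) and \code{score}
#'   (\code{abs(pcor)}), exactly n(n-1)/2 rows, scores non-increasing.
#' @export
rankEdges <- function(conn) {
  stopifnot(is(conn, "Connectome"))
  p <- conn@partial_corr
  ids <- conn@neuron_ids
  ut <- which(upper.tri(p), arr.ind = TRUE)
  df <- data.frame(neuron_i = ids[ut[, 1]], neuron_j = ids[ut[, 2]],
                   pcor = p[ut], score = abs(p[ut]))
  df <- df[order(-df$score, df$neuron_i, df$neuron_j), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Infer a functional connectome from fluorescence traces
#'
#' Runs the full inference pipeline: per-neuron sparse non-negative
#' deconvolution, neuron-specific thresholding (mean + alpha sd), weighted
#' smoothing, then partial correlations from the inverse covariance of the
#' smoothed activity. Neurons whose activity is all-zero after thresholding
#' ("silent" neurons) are excluded from the covariance step — their pairs
#' are reported with partial correlation 0 and their indices recorded in
#' the result.
#'
#' @param traces a [FluorescenceTraces-class].
#' @param alpha thresholding strength (default 2).
#' @param kernel smoothing weights from [smoothingKernel()].
#' @param params deconvolution parameters from [deconvParams()].
#' @param ridge starting ridge multiplier for [precisionMatrix()].
#' @return a [Connectome-class] covering all input neurons.
#' @examples
#' ds <- simulateDataset(simConfig(20, 300, seed = 5), density = 0.1)
#' conn <- inferConnectome(ds$traces)
#' head(rankEdges(conn))
#' @export
inferConnectome <- function(traces, alpha = 2, kernel = smoothingKernel(),
                            params = deconvParams(), ridge = 0) {
  stopifnot(is(traces, "FluorescenceTraces"))
  x <- deconvolveAll(traces, params)
  y <- thresholdSpikes(x, alpha = alpha)
  connectomeFromSpikes(y, kernel = kernel, ridge = ridge)
}

#' Connectome from conditioned spikes
#'
#' The tail of the inference pipeline, for callers that already hold a
#' (thresholded) spike matrix: smoothing, covariance, precision, partial
#' correlations, with silent-neuron exclusion. [inferConnectome()] is
#' deconvolution + thresholding followed by this.
#'
#' @param y a [SpikeMatrix-class], typically stage \code{"thresholded"}.
#' @param kernel smoothing weights from [smoothingKernel()]; \code{NULL}
#'   skips the smoothing stage (used for ablations on raw or binarized
#'   spikes).
#' @param ridge starting ridge multiplier for [precisionMatrix()].
#' @return a [Connectome-class] covering all neurons of \code{y}.
#' @export
connectomeFromSpikes <- function(y, kernel = smoothingKernel(), ridge = 0) {
  stopifnot(is(y, "SpikeMatrix"))
  silent <- which(rowSums(y@values) == 0)
  n <- nNeurons(y)
  active <- setdiff(seq_len(n), silent)
  if (length(active) < 2)
    stop("fewer than 2 active neurons; cannot infer a connectome")
  z <- if (is.null(kernel)) y else smoothSpikes(y, kernel)
  sigma <- covarianceMatrix(z@values[active, , drop = FALSE])
  phi <- precisionMatrix(sigma, ridge = ridge)
  sub <- partialCorrelations(phi)

  p <- matrix(0, n, n)
  p[active, active] <- sub@partial_corr
  new("Connectome", partial_corr = p, neuron_ids = seq_len(n) - 1L,
      regularization_used = sub@regularization_used,
      silent_neurons = as.integer(silent))
}
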