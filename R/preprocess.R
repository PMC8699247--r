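#' Weighted smoothing kernel
#'
#' Builds (and validates) the weight vector used by [smoothSpikes()]. The
#' default five-frame window (1/3, 2/3, 1, 2/3, 1/3) gives full weight to
#' the current frame and decreasing weight with time distance. The weights
#' deliberately do not sum to one: the downstream partial-correlation step
#' is invariant to a common scale factor per neuron, so no renormalization
#' is needed. At lower imaging rates more center-heavy weights are
#' appropriate.
#'
#' @param weights odd-length numeric vector of non-negative weights,
#'   symmetric about its center, with the center weight maximal.
#' @return the validated weight vector.
#' @export
smoothingKernel <- function(weights = c(1/3, 2/3, 1, 2/3, 1/3)) {
  stopifnot(is.numeric(weights), length(weights) >= 1L)
  if (length(weights) %% 2 == 0) stop("kernel length must be odd")
  if (any(weights < 0)) stop("kernel weights must be non-negative")
  center <- (length(weights) + 1L) / 2L
  if (any(weights > weights[center]))
    stop("center weight must be the maximum")
  if (!isTRUE(all.equal(weights, rev(weights))))
    stop("kernel weights must be symmetric about the center")
  weights
}

#' Neuron-specific spike thresholding
#'
#' Removes low-amplitude deconvolved activity, which mostly reflects noise.
#' For neuron i the threshold is \eqn{\Theta_i = \mu_i + \alpha \sigma_i},
#' the sample mean plus \code{alpha} standard deviations (n-1 denominator)
#' of that neuron's deconvolved amplitudes computed over all frames, zeros
#' included. Entries below the threshold become 0; entries at or above it
#' pass through unchanged, so every nonzero output equals its input.
#'
#' @param x a [SpikeMatrix-class] (typically stage \code{"deconvolved"}).
#' @param alpha non-negative multiple of the standard deviation; default 2.
#' @return a [SpikeMatrix-class] at stage \code{"thresholded"}; the
#'   per-neuron thresholds are in \code{metadata$thresholds}. A neuron with
#'   zero variance gets \eqn{\Theta_i = \mu_i} (its constant value passes
#'   through); such rows are reported via a message.
#' @examples
#' sp <- new("SpikeMatrix", values = rbind(c(1, 2, 3)), frame_rate_hz = 50,
#'           stage = "deconvolved")
#' as.matrix(thresholdSpikes(sp, alpha = 0))  # (0, 2, 3)
#' @export
thresholdSpikes <- function(x, alpha = 2) {
  stopifnot(is(x, "SpikeMatrix"), is.numeric(alpha), length(alpha) == 1L,
            alpha >= 0)
  v <- x@values
  mu <- rowMeans(v)
  sdv <- apply(v, 1L, sd)
  degenerate <- sdv == 0
  if (any(degenerate))
    message("zero-variance rows (threshold = mean): ",
            paste(which(degenerate), collapse = ", "))
  theta <- mu + alpha * sdv
  out <- v
  out[v < theta[row(v)]] <- 0
  new("SpikeMatrix", values = out, frame_rate_hz = x@frame_rate_hz,
      stage = "thresholded",
      metadata = c(x@metadata, list(thresholds = theta, alpha = alpha)))
}

#' Percentile-based spike thresholding
#'
#' Alternative thresholding rule: per neuron, entries below the q-th
#' sample percentile of that neuron's row (linear-interpolation percentile)
#' become 0; ties at the cutoff survive. Optionally the survivors are set
#' to 1.
#'
#' @param x a [SpikeMatrix-class].
#' @param q percentile in (0, 100); 90 and 95 are the usual choices.
#' @param binarize_after if \code{TRUE}, surviving entries are set to 1.
#' @return a [SpikeMatrix-class] (stage \code{"binarized"} when
#'   \code{binarize_after}, else \code{"thresholded"}).
#' @export
percentileThreshold <- function(x, q = 90, binarize_after = FALSE) {
  stopifnot(is(x, "SpikeMatrix"), q > 0, q < 100)
  v <- x@values
  cutoffs <- apply(v, 1L, quantile, probs = q / 100, names = FALSE)
  out <- v
  out[v < cutoffs[row(v)]] <- 0
  if (binarize_after) out[out > 0] <- 1
  new("SpikeMatrix", values = out, frame_rate_hz = x@frame_rate_hz,
      stage = if (binarize_after) "binarized" else "thresholded",
      metadata = c(x@metadata, list(percentile = q)))
}

#' Binarize spike amplitudes
#'
#' Sets every nonzero amplitude to 1, discarding amplitude information.
#' Kept as an ablation: amplitudes carry substantial information for
#' connectome inference and binarization degrades accuracy.
#'
#' @param x a [SpikeMatrix-class] with non-negative entries.
#' @return a [SpikeMatrix-class] at stage \code{"binarized"}.
#' @export
binarizeSpikes <- function(x) {
  stopifnot(is(x, "SpikeMatrix"))
  v <- x@values
  v[v > 0] <- 1
  new("SpikeMatrix", values = v, frame_rate_hz = x@frame_rate_hz,
      stage = "binarized", metadata = x@metadata)
}

#' Weighted spike smoothing
#'
#' Spreads each neuron's (thresholded) spikes over a short window:
#' \deqn{z_i(t) = \tfrac13 y_i(t-2) + \tfrac23 y_i(t-1) + y_i(t)
#'   + \tfrac23 y_i(t+1) + \tfrac13 y_i(t+2)}
#' for the default kernel. Because typical imaging rates are slow relative
#' to spike timing, true co-firing between connected neurons lands a frame
#' or two apart; smoothing makes it visible to the zero-lag covariance
#' used downstream. Frames beyond either boundary are treated as zero
#' (zero padding), the natural resting value for sparse spike trains. The
#' operator is linear in its input.
#'
#' @param y a [SpikeMatrix-class].
#' @param kernel weight vector from [smoothingKernel()].
#' @return a [SpikeMatrix-class] at stage \code{"smoothed"}.
#' @examples
#' imp <- matrix(0, 1, 21); imp[11] <- 1
#' sp <- new("SpikeMatrix", values = imp, frame_rate_hz = 50,
#'           stage = "thresholded")
#' as.matrix(smoothSpikes(sp))[9:13]  # 1/3 2/3 1 2/3 1/3
#' @export
smoothSpikes <- function(y, kernel = smoothingKernel()) {
  stopifnot(is(y, "SpikeMatrix"))
  kernel <- smoothingKernel(kernel)
  v <- y@values
  Tn <- ncol(v)
  if (Tn < length(kernel))
    stop("need at least ", length(kernel), " frames to smooth, got ", Tn)
  h <- (length(kernel) - 1L) / 2L
  out <- matrix(0, nrow(v), Tn)
  for (o in -h:h) {
    w <- kernel[o + h + 1L]
    if (w == 0) next
    dst <- max(1L, 1L - o):min(Tn, Tn - o)
    out[, dst] <- out[, dst] + w * v[, dst + o, drop = FALSE]
  }
  new("SpikeMatrix", values = out, frame_rate_hz = y@frame_rate_hz,
      stage = "smoothed", metadata = y@metadata)
}

#' Downsample fluorescence traces
#'
#' Keeps every \code{factor}-th frame starting from the first (frames 0,
#' factor, 2*factor, ... in 0-based terms) and divides the frame rate by
#' \code{factor}, emulating acquisition at a lower imaging rate (e.g.,
#' factor 2 turns a 50 Hz recording into 25 Hz).
#'
#' @param traces a [FluorescenceTraces-class].
#' @param factor integer >= 2.
#' @return a [FluorescenceTraces-class] with \code{ceiling(n/factor)}
#'   frames.
#' @export
downsampleTraces <- function(traces, factor) {
  stopifnot(is(traces, "FluorescenceTraces"))
  factor <- as.integer(factor)
  if (factor < 2L) stop("factor must be >= 2")
  keep <- seq(1L, ncol(traces@values), by = factor)
  new("FluorescenceTraces",
      values = traces@values[, keep, drop = FALSE],
      frame_rate_hz = traces@frame_rate_hz / factor)
}
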