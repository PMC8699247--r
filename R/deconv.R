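#' Estimate the AR(1) fluorescence decay per frame
#'
#' The indicator decay per frame, gamma, is estimated from the ratio of the
#' lag-2 to the lag-1 autocovariance of the trace. For an AR(1) calcium
#' signal observed with additive white noise the noise inflates only the
#' lag-0 term, so this ratio is a noise-robust estimate of gamma (the
#' lag-1/lag-0 ratio would be biased toward zero).
#'
#' @param trace numeric dF/F0 vector of length >= 100.
#' @param frame_rate_hz imaging rate; recorded for context only, the
#'   estimate itself is per frame.
#' @return gamma in (0, 1). If the autocovariance ratio is not a usable
#'   decay (non-positive or >= 1, e.g. on a pure-noise or constant trace)
#'   the documented default 0.95 is returned with a warning.
#' @examples
#' g <- exp(-1 / 25)
#' tr <- as.numeric(stats::filter(rpois(5000, 0.02), g, "recursive"))
#' estimateGamma(tr)
#' @export
estimateGamma <- function(trace, frame_rate_hz = NULL) {
  stopifnot(is.numeric(trace), all(is.finite(trace)))
  if (length(trace) < 100)
    stop("trace must have at least 100 frames to estimate gamma")
  x <- trace - mean(trace)
  n <- length(x)
  acv0 <- sum(x * x) / n
  acv1 <- sum(x[-n] * x[-1]) / n
  acv2 <- sum(x[seq_len(n - 2)] * x[-seq_len(2)]) / n
  ratio <- acv2 / acv1
  # require a clearly positive lag-1 autocorrelation: under white noise
  # acv1/acv0 ~ N(0, 1/n), so 3/sqrt(n) separates signal from pure noise
  signal_ok <- is.finite(acv1) && acv0 > 0 && acv1 / acv0 > 3 / sqrt(n)
  if (!signal_ok || !is.finite(ratio) || ratio <= 0 || ratio >= 1) {
    warning("autocovariance ratio is not a usable AR(1) decay; ",
            "falling back to default gamma = 0.95")
    return(0.95)
  }
  ratio
}

#' Deconvolution parameter bundle
#'
#' Collects the parameters of the sparse non-negative deconvolver. With the
#' defaults the solver is essentially unregularized: the pipeline's own
#' thresholding stage is the intended noise filter, so lambda stays 0 and
#' only a relative amplitude floor removes numerically negligible output.
#'
#' @param gamma AR(1) decay per frame in (0, 1), or \code{"auto"} to
#'   estimate it per neuron with [estimateGamma()].
#' @param lambda sparsity penalty on the total spike amplitude, >= 0.
#' @param min_spike amplitude floor below which solver output is clamped to
#'   zero; \code{NULL} means \code{1e-6 * max(trace)} per trace.
#' @return a named list of class \code{"DeconvParams"}.
#' @export
deconvParams <- function(gamma = "auto", lambda = 0, min_spike = NULL) {
  if (!identical(gamma, "auto")) {
    stopifnot(is.numeric(gamma), length(gamma) == 1L)
    if (gamma <= 0 || gamma >= 1) stop("gamma must be in (0, 1) or \"auto\"")
  }
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda >= 0)
  if (!is.null(min_spike))
    stopifnot(is.numeric(min_spike), length(min_spike) == 1L, min_spike >= 0)
  structure(list(gamma = gamma, lambda = lambda, min_spike = min_spike),
            class = "DeconvParams")
}

#' Deconvolve one fluorescence trace into spike amplitudes
#'
#' Solves the sparse non-negative AR(1) deconvolution problem
#' \deqn{\min_c \tfrac12 \|c - y\|^2 + \lambda \sum_t s_t
#'   \quad \mathrm{s.t.}\quad s_t = c_t - \gamma c_{t-1} \ge 0}
#' by an online active-set (pool-adjacent-violators) sweep, and returns the
#' spike vector s. Output entries below \code{min_spike} are clamped to 0.
#' At \code{lambda = 0} the solution is scale-covariant: deconvolving
#' \code{a * trace} gives \code{a} times the spikes.
#'
#' @param trace numeric dF/F0 vector; all values must be finite.
#' @param gamma AR(1) decay per frame, in (0, 1).
#' @param lambda sparsity penalty, >= 0.
#' @param min_spike amplitude floor; default \code{1e-6 * max(trace)}.
#' @return non-negative numeric vector of spike amplitudes, same length as
#'   \code{trace}.
#' @examples
#' g <- 0.5
#' tr <- as.numeric(stats::filter(c(rep(0, 9), 1, rep(0, 10)), g, "recursive"))
#' which(deconvolveTrace(tr, gamma = g) > 0)  # frame 10
#' @export
deconvolveTrace <- function(trace, gamma, lambda = 0, min_spike = NULL) {
  if (!is.numeric(trace) || any(!is.finite(trace)))
    stop("trace must be numeric with all values finite")
  stopifnot(length(gamma) == 1L, gamma > 0, gamma < 1, lambda >= 0)
  if (is.null(min_spike))
    min_spike <- if (length(trace) && max(trace) > 0) 1e-6 * max(trace) else 0
  s <- oasis_ar1(as.numeric(trace), gamma, lambda)$s
  s[s < min_spike] <- 0
  s
}

#' Deconvolve all neurons of a recording
#'
#' Applies [deconvolveTrace()] row by row; neurons are independent, so
#' permuting the rows of the input permutes the output rows identically.
#'
#' @param traces a [FluorescenceTraces-class].
#' @param params a [deconvParams()] bundle (or individual values via
#'   \code{...} style fields \code{gamma}, \code{lambda}, \code{min_spike}).
#' @return a [SpikeMatrix-class] at stage \code{"deconvolved"}; the
#'   per-neuron gamma values used are stored in
#'   \code{metadata$gamma}.
#' @export
deconvolveAll <- function(traces, params = deconvParams()) {
  stopifnot(is(traces, "FluorescenceTraces"))
  if (!inherits(params, "DeconvParams"))
    params <- do.call(deconvParams, as.list(params))
  v <- traces@values
  n <- nrow(v)
  out <- matrix(0, n, ncol(v))
  gammas <- numeric(n)
  for (i in seq_len(n)) {
    res <- tryCatch({
      g <- if (identical(params$gamma, "auto"))
        estimateGamma(v[i, ], traces@frame_rate_hz)
      else params$gamma
      gammas[i] <- g
      deconvolveTrace(v[i, ], g, params$lambda, params$min_spike)
    }, error = function(e)
      stop("deconvolution failed for neuron ", i, ": ",
           conditionMessage(e), call. = FALSE))
    out[i, ] <- res
  }
  new("SpikeMatrix", values = out, frame_rate_hz = traces@frame_rate_hz,
      stage = "deconvolved", metadata = list(gamma = gammas))
}
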