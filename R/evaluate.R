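#' Reduce a ground-truth network to undirected pairs
#'
#' Partial correlations are symmetric and carry no directionality, so a
#' directed ground truth must be reduced to undirected pairs before
#' scoring: pair \{i, j\} is positive iff there is a connection i to j or
#' j to i (reciprocal connections count once).
#'
#' @param net a [GroundTruthNetwork-class].
#' @return an undirected [GroundTruthNetwork-class].
#' @export
symmetrizeTruth <- function(net) {
  stopifnot(is(net, "GroundTruthNetwork"))
  a <- net@adjacency
  a <- 1 * ((a + t(a)) > 0)
  new("GroundTruthNetwork", adjacency = a, directed = FALSE)
}

# Confusion-count sweep over a score-ranked list; ties processed as a
# block. Returns cumulative TP/FP at each distinct-score boundary.
.confusion_sweep <- function(scores, labels) {
  ord <- order(-scores)
  scores <- scores[ord]
  labels <- labels[ord]
  # block ends: last index of each run of equal scores
  block_end <- which(c(scores[-1] != scores[-length(scores)], TRUE))
  cum_tp <- cumsum(labels)[block_end]
  cum_fp <- block_end - cum_tp
  list(tp = cum_tp, fp = cum_fp)
}

#' Score a ranked edge list against ground truth
#'
#' Sweeps the top-k cutoff down the score-sorted pair list (tied scores as
#' one block), accumulating true/false positives, and computes the ROC
#' curve (TPR vs FPR) and precision-recall curve with their areas. AUROC
#' uses trapezoidal integration, which on tie blocks equals the
#' Mann-Whitney concordance count with ties counted one half. AUPR uses
#' step interpolation (precision held at the block value across its recall
#' increment), avoiding the optimistic linear interpolation between PR
#' points. An AUROC of 1 is a perfect ranking; 0.5 is the expectation for
#' random scores. For sparse truth, AUPR is the more sensitive metric: a
#' random ranking's AUPR concentrates near the positive prevalence.
#'
#' @param ranked a ranked edge list from [rankEdges()] (columns
#'   \code{neuron_i}, \code{neuron_j}, \code{score}), covering exactly the
#'   neuron pairs of \code{truth}.
#' @param truth an undirected [GroundTruthNetwork-class] (use
#'   [symmetrizeTruth()] first if needed).
#' @return an [EvalResult-class].
#' @examples
#' net <- symmetrizeTruth(generateNetwork(10, 0.2, seed = 1))
#' conn <- new("Connectome",
#'   partial_corr = adjacencyMatrix(net) * 0.9,
#'   neuron_ids = 0:9)
#' auroc(scoreRanking(rankEdges(conn), net))
#' @export
scoreRanking <- function(ranked, truth) {
  stopifnot(is(truth, "GroundTruthNetwork"), is.data.frame(ranked))
  if (truth@directed)
    stop("truth must be undirected; apply symmetrizeTruth() first")
  n <- nNeurons(truth)
  if (nrow(ranked) != n * (n - 1) / 2)
    stop("ranked list must cover exactly the ", n * (n - 1) / 2,
         " neuron pairs of the truth network (got ", nrow(ranked), ")")
  i <- pmin(ranked$neuron_i, ranked$neuron_j) + 1L
  j <- pmax(ranked$neuron_i, ranked$neuron_j) + 1L
  key <- (i - 1L) * n + j
  if (anyDuplicated(key) || any(i < 1) || any(j > n) || any(i == j))
    stop("ranked list does not enumerate each neuron pair exactly once")
  labels <- truth@adjacency[cbind(i, j)]
  n_pos <- sum(labels)
  n_neg <- length(labels) - n_pos
  if (n_pos == 0 || n_neg == 0)
    stop("truth must contain at least one positive and one negative pair; ",
         "ROC/PR curves are undefined otherwise")

  sweep <- .confusion_sweep(ranked$score, labels)
  tpr <- sweep$tp / n_pos
  fpr <- sweep$fp / n_neg
  roc <- cbind(fpr = c(0, fpr), tpr = c(0, tpr))
  auroc <- sum(diff(roc[, 1]) * (head(roc[, 2], -1) + tail(roc[, 2], -1)) / 2)

  recall <- tpr
  precision <- sweep$tp / (sweep$tp + sweep$fp)
  aupr <- sum(diff(c(0, recall)) * precision)
  pr <- cbind(recall = recall, precision = precision)

  new("EvalResult", auroc = auroc, aupr = aupr,
      roc_points = roc, pr_points = pr,
      n_positives = as.integer(n_pos), n_negatives = as.integer(n_neg))
}

#' Missing-neuron robustness experiment
#'
#' Emulates unrecorded (hidden) neurons: repeatedly subsamples a set of
#' neurons, reruns the full inference on the subsampled traces, and scores
#' the result against the induced subnetwork of the ground truth. Hidden
#' presynaptic partners can induce spurious partial correlations among the
#' recorded neurons, so this measures how gracefully accuracy degrades
#' with the fraction of missing neurons.
#'
#' @param traces a [FluorescenceTraces-class] for the full population.
#' @param truth the matching [GroundTruthNetwork-class].
#' @param sizes integer vector of subsample sizes (each <= n neurons).
#' @param n_reps replicates per size.
#' @param seed RNG seed; the whole table is reproducible for a fixed seed.
#' @param ... further arguments passed to [inferConnectome()].
#' @return \code{data.frame} with columns \code{size}, \code{rep},
#'   \code{auroc}, \code{aupr}, \code{scorable}. A replicate whose induced
#'   truth has no positive (or no negative) pair is recorded with
#'   \code{scorable = FALSE} and NA scores rather than dropped.
#' @export
missingNeuronExperiment <- function(traces, truth, sizes, n_reps = 5,
                                    seed = 1L, ...) {
  stopifnot(is(traces, "FluorescenceTraces"),
            is(truth, "GroundTruthNetwork"),
            all(sizes >= 2), all(sizes <= nNeurons(traces)), n_reps >= 1)
  truth_u <- symmetrizeTruth(truth)
  set.seed(seed)
  subsets <- list()
  for (size in sizes)
    for (r in seq_len(n_reps))
      subsets[[length(subsets) + 1L]] <-
        list(size = size, rep = r, idx = sort(sample(nNeurons(traces), size)))

  rows <- lapply(subsets, function(sb) {
    idx <- sb$idx
    sub_traces <- new("FluorescenceTraces",
                      values = traces@values[idx, , drop = FALSE],
                      frame_rate_hz = traces@frame_rate_hz)
    sub_truth <- new("GroundTruthNetwork",
                     adjacency = truth_u@adjacency[idx, idx, drop = FALSE],
                     directed = FALSE)
    res <- tryCatch({
      conn <- inferConnectome(sub_traces, ...)
      scoreRanking(rankEdges(conn), sub_truth)
    }, error = function(e) NULL)
    if (is.null(res))
      data.frame(size = sb$size, rep = sb$rep, auroc = NA_real_,
                 aupr = NA_real_, scorable = FALSE)
    else
      data.frame(size = sb$size, rep = sb$rep, auroc = auroc(res),
                 aupr = aupr(res), scorable = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
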