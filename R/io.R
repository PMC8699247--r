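# Delimited-text interchange formats. Conventions (also printed in file
# headers): tab-separated values, '#'-prefixed "key: value" header lines,
# 0-based neuron identifiers, edge lists store i < j for undirected
# networks.

.read_header <- function(lines) {
  hdr_idx <- grep("^#", lines)
  hdr <- list()
  for (ln in lines[hdr_idx]) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_0-9]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) hdr[[m[2]]] <- trimws(m[3])
  }
  list(header = hdr, data_idx = setdiff(seq_along(lines), hdr_idx))
}

.parse_numeric_rows <- function(lines, idx, path) {
  rows <- strsplit(lines[idx], "\t", fixed = TRUE)
  widths <- lengths(rows)
  if (length(unique(widths)) > 1) {
    bad <- idx[widths != widths[1]][1]
    stop("ragged row in ", path, " at line ", bad, ": expected ",
         widths[1], " fields, got ", widths[which(idx == bad)])
  }
  out <- matrix(NA_real_, length(rows), widths[1])
  for (k in seq_along(rows)) {
    v <- suppressWarnings(as.numeric(rows[[k]]))
    if (any(is.na(v)))
      stop("non-numeric cell in ", path, " at line ", idx[k],
           ", field ", which(is.na(v))[1])
    out[k, ] <- v
  }
  out
}

#' Write fluorescence traces to a delimited text file
#'
#' One row per neuron; the first data row holds the frame times in
#' seconds. Header lines carry the frame rate.
#'
#' @param traces a [FluorescenceTraces-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTraces <- function(traces, path) {
  stopifnot(is(traces, "FluorescenceTraces"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fluoroconn traces v1 (rows: neurons; first row: frame times s)",
               sprintf("# frame_rate_hz: %.10g", traces@frame_rate_hz)), con)
  times <- (seq_len(ncol(traces@values)) - 1) / traces@frame_rate_hz
  writeLines(paste(format(times, digits = 10, trim = TRUE, scientific = FALSE),
                   collapse = "\t"), con)
  utils::write.table(traces@values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read fluorescence traces written by [writeTraces()]
#' @param path input file path.
#' @return a [FluorescenceTraces-class].
#' @export
readTraces <- function(path) {
  lines <- readLines(path)
  parsed <- .read_header(lines)
  if (length(parsed$data_idx) < 2)
    stop("no trace rows in ", path, " (need a frame-time row plus at least ",
         "one neuron row)")
  fr <- as.numeric(parsed$header$frame_rate_hz)
  if (!length(fr) || is.na(fr))
    stop("missing or invalid '# frame_rate_hz:' header in ", path)
  m <- .parse_numeric_rows(lines, parsed$data_idx, path)
  new("FluorescenceTraces", values = m[-1, , drop = FALSE],
      frame_rate_hz = fr)
}

#' Write a spike matrix to a delimited text file
#'
#' Same layout as [writeTraces()] with an additional stage header.
#'
#' @param spikes a [SpikeMatrix-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeSpikes <- function(spikes, path) {
  stopifnot(is(spikes, "SpikeMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fluoroconn spikes v1 (rows: neurons; first row: frame times s)",
               sprintf("# frame_rate_hz: %.10g", spikes@frame_rate_hz),
               sprintf("# stage: %s", spikes@stage)), con)
  times <- (seq_len(ncol(spikes@values)) - 1) / spikes@frame_rate_hz
  writeLines(paste(format(times, digits = 10, trim = TRUE, scientific = FALSE),
                   collapse = "\t"), con)
  utils::write.table(spikes@values, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a spike matrix written by [writeSpikes()]
#' @param path input file path.
#' @return a [SpikeMatrix-class].
#' @export
readSpikes <- function(path) {
  lines <- readLines(path)
  parsed <- .read_header(lines)
  if (length(parsed$data_idx) < 2)
    stop("no spike rows in ", path)
  fr <- as.numeric(parsed$header$frame_rate_hz)
  if (!length(fr) || is.na(fr))
    stop("missing or invalid '# frame_rate_hz:' header in ", path)
  stage <- parsed$header$stage
  if (is.null(stage)) stage <- "deconvolved"
  m <- .parse_numeric_rows(lines, parsed$data_idx, path)
  new("SpikeMatrix", values = m[-1, , drop = FALSE], frame_rate_hz = fr,
      stage = stage)
}

#' Write a ground-truth network as an edge list
#'
#' Three tab-separated columns (source, target, weight 1) with 0-based
#' neuron identifiers; undirected networks store each pair once with
#' source < target.
#'
#' @param net a [GroundTruthNetwork-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeNetwork <- function(net, path) {
  stopifnot(is(net, "GroundTruthNetwork"))
  a <- net@adjacency
  if (net@directed) {
    e <- which(a == 1, arr.ind = TRUE)
  } else {
    e <- which(a == 1 & upper.tri(a), arr.ind = TRUE)
  }
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fluoroconn network v1 (0-based ids; undirected lists i < j once)",
               sprintf("# n_neurons: %d", nrow(a)),
               sprintf("# directed: %s", net@directed),
               "source\ttarget\tweight"), con)
  if (nrow(e))
    writeLines(sprintf("%d\t%d\t1", e[, 1] - 1L, e[, 2] - 1L), con)
  invisible(path)
}

#' Read a ground-truth network edge list written by [writeNetwork()]
#' @param path input file path.
#' @return a [GroundTruthNetwork-class].
#' @export
readNetwork <- function(path) {
  lines <- readLines(path)
  parsed <- .read_header(lines)
  n <- as.integer(parsed$header$n_neurons)
  if (!length(n) || is.na(n))
    stop("missing or invalid '# n_neurons:' header in ", path)
  directed <- toupper(parsed$header$directed) %in% c("TRUE", "YES", "1")
  data_idx <- parsed$data_idx
  # first data line is the column header
  if (length(data_idx) == 0)
    stop("no edge rows (not even a column header) in ", path)
  data_idx <- data_idx[-1]
  adj <- matrix(0, n, n)
  seen <- new.env(hash = TRUE)
  for (k in data_idx) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3)
      stop("edge line ", k, " in ", path, " must have 3 fields, got ",
           length(f))
    v <- suppressWarnings(as.numeric(f))
    if (any(is.na(v)))
      stop("non-numeric cell in ", path, " at line ", k)
    i <- v[1] + 1L; j <- v[2] + 1L; w <- v[3]
    if (i < 1 || i > n || j < 1 || j > n || i == j)
      stop("invalid edge (", v[1], ", ", v[2], ") at line ", k, " in ", path)
    if (!w %in% c(0, 1))
      stop("edge weight must be 0 or 1 at line ", k, " in ", path)
    key <- paste0(i, "_", j)
    if (!is.null(seen[[key]]))
      stop("duplicate edge (", v[1], ", ", v[2], ") at line ", k, " in ", path)
    seen[[key]] <- TRUE
    if (w == 1) {
      adj[i, j] <- 1
      if (!directed) adj[j, i] <- 1
    }
  }
  new("GroundTruthNetwork", adjacency = adj, directed = directed)
}

#' Write a connectome as a full matrix plus metadata headers
#' @param conn a [Connectome-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeConnectome <- function(conn, path) {
  stopifnot(is(conn, "Connectome"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fluoroconn connectome v1 (full symmetric partial-correlation matrix)",
               sprintf("# n_neurons: %d", nNeurons(conn)),
               sprintf("# ridge_used: %.10g", conn@regularization_used),
               sprintf("# silent_neurons: %s",
                       paste(conn@silent_neurons - 1L, collapse = ","))), con)
  utils::write.table(conn@partial_corr, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Write a ranked edge list as TSV
#' @param ranked data frame from [rankEdges()].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeRankedEdges <- function(ranked, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# fluoroconn ranked edges v1 (0-based ids, i < j, |pcor| descending)",
               "neuron_i\tneuron_j\tpcor\tscore"), con)
  if (nrow(ranked))
    writeLines(sprintf("%d\t%d\t%.12g\t%.12g", ranked$neuron_i,
                       ranked$neuron_j, ranked$pcor, ranked$score), con)
  invisible(path)
}

#' Write an evaluation result as JSON
#' @param res an [EvalResult-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeEvalResult <- function(res, path) {
  stopifnot(is(res, "EvalResult"))
  jsonlite::write_json(list(
    auroc = res@auroc, aupr = res@aupr,
    n_positives = res@n_positives, n_negatives = res@n_negatives,
    roc = list(fpr = res@roc_points[, 1], tpr = res@roc_points[, 2]),
    pr = list(recall = res@pr_points[, 1], precision = res@pr_points[, 2])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
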