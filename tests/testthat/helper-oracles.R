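# Independent reference implementations used to cross-check the package.

# Spike matrix constructor shortcut for hand-built fixtures.
spk <- function(values, stage = "deconvolved", frame_rate_hz = 50) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  new("SpikeMatrix", values = values, frame_rate_hz = frame_rate_hz,
      stage = stage)
}

flt <- function(values, frame_rate_hz = 50) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  new("FluorescenceTraces", values = values, frame_rate_hz = frame_rate_hz)
}

# AR(1) convolution of a spike train (forward model).
ar1_conv <- function(s, gamma) {
  as.numeric(stats::filter(s, gamma, method = "recursive"))
}

# Deconvolution objective: 0.5 * ||c - y||^2 + lambda * sum(s), c built
# from s by the AR(1) recursion.
deconv_objective <- function(s, y, gamma, lambda) {
  c_ <- ar1_conv(s, gamma)
  0.5 * sum((c_ - y)^2) + lambda * sum(s)
}

# Numerical oracle for the deconvolution problem: box-constrained
# quasi-Newton minimization over s >= 0 from several starts. Independent of
# the pool-adjacent-violators path used by the package.
deconv_oracle <- function(y, gamma, lambda = 0) {
  Tn <- length(y)
  obj <- function(s) deconv_objective(s, y, gamma, lambda)
  grad <- function(s) {
    c_ <- ar1_conv(s, gamma)
    r <- c_ - y
    # d obj / d s_t = sum_{u >= t} gamma^(u-t) r_u + lambda
    g <- rev(as.numeric(stats::filter(rev(r), gamma, method = "recursive")))
    g + lambda
  }
  starts <- list(rep(0, Tn), pmax(y - gamma * c(0, y[-Tn]), 0), rep(0.5, Tn))
  best <- Inf
  best_s <- NULL
  for (s0 in starts) {
    fit <- stats::optim(s0, obj, grad, method = "L-BFGS-B",
                        lower = rep(0, Tn),
                        control = list(maxit = 500, factr = 1e4))
    if (fit$value < best) { best <- fit$value; best_s <- fit$par }
  }
  list(s = best_s, objective = best)
}

# KKT residuals of a candidate solution of the deconvolution problem.
deconv_kkt_grad <- function(s, y, gamma, lambda = 0) {
  r <- ar1_conv(s, gamma) - y
  rev(as.numeric(stats::filter(rev(r), gamma, method = "recursive"))) + lambda
}

# Partial correlation of rows i and j of z given all other rows, by
# regressing both on the others and correlating the residuals.
pcor_residual_oracle <- function(z, i, j) {
  others <- setdiff(seq_len(nrow(z)), c(i, j))
  if (length(others) == 0) return(cor(z[i, ], z[j, ]))
  X <- t(z[others, , drop = FALSE])
  ri <- stats::lm.fit(cbind(1, X), z[i, ])$residuals
  rj <- stats::lm.fit(cbind(1, X), z[j, ])$residuals
  cor(ri, rj)
}

# AUROC by exhaustive concordance counting (ties count one half).
auroc_concordance <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Cached 60-neuron simulated benchmark (shared across test files).
bench60 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulateDataset(simConfig(60, 600, seed = 7), density = 0.1)
      cache <<- ds
    }
    cache
  }
})
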