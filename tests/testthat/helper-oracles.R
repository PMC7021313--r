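# Independent brute-force oracles for the chart recursions. These store the
# full history and recompute from scratch at every step, so they share no
# code path with the streaming/vectorised implementations they check.

bf_ma <- function(x, w) {
  vapply(seq_along(x), function(i) mean(x[max(1, i - w + 1):i]), numeric(1))
}

# explicit geometric-weight sum: Z_i = lam * sum_j (1-lam)^j x_{i-j}
#                                      + (1-lam)^i * z0
bf_ewma <- function(x, lam, z0 = 0) {
  vapply(seq_along(x), function(i) {
    lam * sum((1 - lam)^(0:(i - 1)) * x[i:1]) + (1 - lam)^i * z0
  }, numeric(1))
}

bf_ewma_ma <- function(x, lam, w, z0 = 0) bf_ewma(bf_ma(x, w), lam, z0)
bf_ma_ewma <- function(x, lam, w, z0 = 0) bf_ma(bf_ewma(x, lam, z0), w)

# geometric run-length facts for a chart that signals i.i.d. with prob p
geom_arl <- function(p) 1 / p
geom_sdrl <- function(p) sqrt(1 - p) / p
geom_mrl <- function(p) ceiling(log(0.5) / log(1 - p))

# two-sided signal probability of a Shewhart chart under a dist_spec (uses
# the shifted exact CDF, independent of the package's internals)
shewhart_tail_p <- function(d, h) {
  shift <- d$delta * d$sigma0
  lcl <- d$mu0 - h * d$sigma0
  ucl <- d$mu0 + h * d$sigma0
  cdf <- switch(d$family,
    normal      = function(q) pnorm(q, d$params$mean + shift, d$params$sd),
    logistic    = function(q) plogis(q, d$params$location + shift,
                                     d$params$scale),
    exponential = function(q) pexp(q - shift, d$params$rate),
    laplace     = function(q) {
      z <- (q - d$params$location - shift) / d$params$scale
      ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
    },
    stop("no closed-form tail for family ", d$family))
  cdf(lcl) + (1 - cdf(ucl))
}
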