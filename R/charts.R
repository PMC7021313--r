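#' Control chart specification
#'
#' Builds a specification for one of five charts for monitoring a process
#' mean: the Shewhart individuals chart, the moving average (MA) chart of
#' span \code{w}, the EWMA chart with smoothing constant \code{lambda}, and
#' the two mixed charts MA-EWMA (moving average of EWMA values) and EWMA-MA
#' (EWMA of moving averages). The plotted statistic at time \eqn{i} is
#' compared with symmetric control limits
#' \deqn{\mathrm{UCL/LCL} = \mu_0 \pm H\sqrt{V_i},}
#' where the variance term \eqn{V_i} depends on the chart (see
#' \code{\link{chart_limits}}) and \eqn{H} is the control-limit coefficient,
#' usually calibrated so that the in-control average run length hits a
#' target such as 370 (see \code{\link{calibrate_h}}).
#'
#' @param kind one of \code{"shewhart"}, \code{"ma"}, \code{"ewma"},
#'   \code{"ma_ewma"}, \code{"ewma_ma"}.
#' @param h control-limit coefficient \eqn{H \ge 0}.
#' @param lambda EWMA smoothing constant in \eqn{(0, 1]}; stored but unused
#'   for \code{shewhart} and \code{ma}.
#' @param w moving-average span (integer \eqn{\ge 1}); stored but unused for
#'   \code{shewhart} and \code{ewma}.
#' @param center in-control mean \eqn{\mu_0}; also the EWMA starting value
#'   \eqn{Z_0}.
#' @param scale in-control process standard deviation \eqn{\sigma_0} of an
#'   individual observation.
#' @param limit_mode \code{"time_varying"} (exact finite-time variance,
#'   including MA warm-up branches) or \code{"asymptotic"} (stationary
#'   variance for all \eqn{i}). The EWMA-MA and Shewhart limits are constant
#'   in time either way.
#' @param subgroup subgroup size \eqn{n}; per-period inputs are subgroup
#'   means, so the effective input SD is \code{scale/sqrt(subgroup)}.
#'   Default 1 (individual observations).
#'
#' @return An object of class \code{"chart_spec"}.
#' @examples
#' chart_spec("ewma_ma", h = 6.480, lambda = 0.25, w = 5)
#' @export
chart_spec <- function(kind = c("shewhart", "ma", "ewma", "ma_ewma", "ewma_ma"),
                       h, lambda = 0.25, w = 5, center = 0, scale = 1,
                       limit_mode = c("time_varying", "asymptotic"),
                       subgroup = 1) {
  kind <- match.arg(kind)
  limit_mode <- match.arg(limit_mode)
  stopifnot(is.numeric(h), length(h) == 1L, is.finite(h))
  if (h < 0) stop("control-limit coefficient 'h' must be >= 0")
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0 || lambda > 1)
    stop("'lambda' must lie in (0, 1]")
  if (!is.numeric(w) || length(w) != 1L || w < 1 || w != round(w))
    stop("'w' must be a positive integer span")
  if (!is.numeric(scale) || scale <= 0) stop("'scale' must be positive")
  if (!is.numeric(subgroup) || subgroup < 1 || subgroup != round(subgroup))
    stop("'subgroup' must be a positive integer")
  structure(list(kind = kind, h = h, lambda = lambda, w = as.integer(w),
                 center = center, scale = scale, limit_mode = limit_mode,
                 subgroup = as.integer(subgroup)),
            class = "chart_spec")
}

#' Moving-average statistic
#'
#' \eqn{MA_i} is the mean of all observations so far while \eqn{i < w}
#' (warm-up) and the mean of the last \eqn{w} observations once
#' \eqn{i \ge w}.
#'
#' @param x numeric input sequence.
#' @param w span.
#' @return numeric vector of the statistic at each time index.
#' @export
ma_stat <- function(x, w) {
  n <- length(x)
  cs0 <- c(0, cumsum(x))
  out <- cs0[-1] / seq_len(n)
  if (n >= w) {
    i <- w:n
    out[i] <- (cs0[i + 1] - cs0[i - w + 1]) / w
  }
  out
}

#' EWMA statistic
#'
#' The recursion \eqn{Z_i = \lambda x_i + (1-\lambda) Z_{i-1}} with
#' \eqn{Z_0 = } \code{z0}.
#'
#' @param x numeric input sequence.
#' @param lambda smoothing constant in \eqn{(0, 1]}.
#' @param z0 starting value \eqn{Z_0} (the in-control mean).
#' @return numeric vector of \eqn{Z_i}.
#' @export
ewma_stat <- function(x, lambda, z0 = 0) {
  as.numeric(stats::filter(lambda * x, 1 - lambda,
                           method = "recursive", init = z0))
}

#' EWMA-MA statistic: EWMA applied to moving averages
#'
#' Computes \eqn{MA_i} of the raw observations (including the warm-up
#' branch) and feeds it into the EWMA recursion
#' \eqn{Z_i = \lambda MA_i + (1-\lambda) Z_{i-1}}.
#'
#' @inheritParams ewma_stat
#' @param w moving-average span.
#' @return numeric vector of the statistic.
#' @export
ewma_ma_stat <- function(x, lambda, w, z0 = 0) {
  ewma_stat(ma_stat(x, w), lambda, z0)
}

#' MA-EWMA statistic: moving average applied to EWMA values
#'
#' Computes the EWMA values \eqn{Z_i} from the raw observations and returns
#' the mean of the last \eqn{\min(i, w)} of them.
#'
#' @inheritParams ewma_ma_stat
#' @return numeric vector of the statistic.
#' @export
ma_ewma_stat <- function(x, lambda, w, z0 = 0) {
  ma_stat(ewma_stat(x, lambda, z0), w)
}

# statistic trace for an arbitrary chart spec
chart_stat <- function(chart, x) {
  switch(chart$kind,
         shewhart = x,
         ma       = ma_stat(x, chart$w),
         ewma     = ewma_stat(x, chart$lambda, chart$center),
         ewma_ma  = ewma_ma_stat(x, chart$lambda, chart$w, chart$center),
         ma_ewma  = ma_ewma_stat(x, chart$lambda, chart$w, chart$center))
}

# variance term V_t inserted under the square root of the limits; vectorised
# over t
chart_variance <- function(chart, t) {
  sigma2 <- chart$scale^2 / chart$subgroup
  lam <- chart$lambda
  w <- chart$w
  tv <- chart$limit_mode == "time_varying"
  switch(chart$kind,
         shewhart = rep(sigma2, length(t)),
         ma       = if (tv) sigma2 / pmin(t, w) else rep(sigma2 / w, length(t)),
         ewma     = {
           a <- sigma2 * lam / (2 - lam)
           if (tv) a * (1 - (1 - lam)^(2 * t)) else rep(a, length(t))
         },
         ma_ewma  = {
           a <- sigma2 * lam / (2 - lam)
           if (tv) a / pmin(t, w) else rep(a / w, length(t))
         },
         # constant in t: the published form has no warm-up branch
         ewma_ma  = rep(sigma2 / w * lam / (2 - lam), length(t)))
}

#' Control limits of a chart at given time indices
#'
#' Returns \eqn{\mu_0 \pm H\sqrt{V_t}} where the variance term \eqn{V_t}
#' (with \eqn{\sigma^2 = \sigma_0^2/n} the per-period input variance) is:
#' \itemize{
#'   \item Shewhart: \eqn{\sigma^2};
#'   \item MA: \eqn{\sigma^2/\min(t, w)};
#'   \item EWMA: \eqn{\sigma^2 \frac{\lambda}{2-\lambda}(1-(1-\lambda)^{2t})}
#'     in time-varying mode, or its \eqn{t \to \infty} limit
#'     \eqn{\sigma^2 \lambda/(2-\lambda)} in asymptotic mode;
#'   \item MA-EWMA: \eqn{\frac{\sigma^2}{\min(t,w)}\frac{\lambda}{2-\lambda}};
#'   \item EWMA-MA: \eqn{\frac{\sigma^2}{w}\frac{\lambda}{2-\lambda}},
#'     constant in \eqn{t}.
#' }
#' The MA-type warm-up branches apply in time-varying mode; asymptotic mode
#' uses the \eqn{t \ge w} form throughout.
#'
#' @param chart a \code{\link{chart_spec}}.
#' @param t vector of time indices (each \eqn{\ge 1}).
#' @return data frame with columns \code{t}, \code{lcl}, \code{ucl},
#'   \code{variance}.
#' @export
chart_limits <- function(chart, t) {
  stopifnot(inherits(chart, "chart_spec"))
  if (any(t < 1)) stop("time index 't' must be >= 1")
  v <- chart_variance(chart, t)
  half <- chart$h * sqrt(v)
  data.frame(t = t, lcl = chart$center - half, ucl = chart$center + half,
             variance = v)
}

#' Apply a chart to a sequence of observations
#'
#' Runs the chart recursion over \code{x} from its initial state
#' (\eqn{Z_0 = \mu_0}, empty MA buffer) and flags every point falling
#' strictly outside its control limits. An observation exactly on a limit
#' does not signal.
#'
#' @param chart a \code{\link{chart_spec}}.
#' @param x numeric observations (per-period inputs).
#' @return data frame with columns \code{t}, \code{x}, \code{stat},
#'   \code{lcl}, \code{ucl}, \code{signal}.
#' @export
chart_apply <- function(chart, x) {
  stopifnot(inherits(chart, "chart_spec"))
  if (!length(x)) stop("empty observation sequence")
  if (anyNA(x) || !all(is.finite(x))) stop("observations must be finite")
  stat <- chart_stat(chart, x)
  lim <- chart_limits(chart, seq_along(x))
  data.frame(t = lim$t, x = x, stat = stat, lcl = lim$lcl, ucl = lim$ucl,
             signal = stat < lim$lcl | stat > lim$ucl)
}

#' Initial streaming state for a chart
#'
#' @param chart a \code{\link{chart_spec}}.
#' @return a list with the time index \code{t = 0}, the EWMA value
#'   \code{z = center} and an empty buffer; pass it to
#'   \code{\link{chart_step}}.
#' @export
chart_state <- function(chart) {
  stopifnot(inherits(chart, "chart_spec"))
  list(t = 0L, z = chart$center, buffer = numeric(0))
}

#' Advance a chart by one observation
#'
#' Streaming equivalent of \code{\link{chart_apply}}: consumes one
#' observation, updates the state and returns the plotted statistic, the
#' limits at the new time index and the signal flag.
#'
#' @param chart a \code{\link{chart_spec}}.
#' @param state state list from \code{\link{chart_state}} or a previous step.
#' @param x one finite observation.
#' @return list with elements \code{state}, \code{stat}, \code{lcl},
#'   \code{ucl}, \code{signal}.
#' @export
chart_step <- function(chart, state, x) {
  stopifnot(inherits(chart, "chart_spec"), is.list(state),
            length(x) == 1L, is.finite(x))
  t <- state$t + 1L
  w <- chart$w
  buf <- state$buffer
  z <- state$z
  stat <- switch(chart$kind,
    shewhart = x,
    ma = {
      buf <- c(buf, x); if (length(buf) > w) buf <- buf[-1L]
      mean(buf)
    },
    ewma = {
      z <- chart$lambda * x + (1 - chart$lambda) * z
      z
    },
    ewma_ma = {
      buf <- c(buf, x); if (length(buf) > w) buf <- buf[-1L]
      z <- chart$lambda * mean(buf) + (1 - chart$lambda) * z
      z
    },
    ma_ewma = {
      z <- chart$lambda * x + (1 - chart$lambda) * z
      buf <- c(buf, z); if (length(buf) > w) buf <- buf[-1L]
      mean(buf)
    })
  lim <- chart_limits(chart, t)
  list(state = list(t = t, z = z, buffer = buf),
       stat = stat, lcl = lim$lcl, ucl = lim$ucl,
       signal = stat < lim$lcl || stat > lim$ucl)
}

#' @export
print.chart_spec <- function(x, ...) {
  lab <- c(shewhart = "Shewhart", ma = "MA", ewma = "EWMA",
           ma_ewma = "MA-EWMA", ewma_ma = "EWMA-MA")[x$kind]
  cat(lab, "control chart\n")
  cat(sprintf("  H = %g, center = %g, scale = %g, limits: %s\n",
              x$h, x$center, x$scale, x$limit_mode))
  if (x$kind %in% c("ewma", "ma_ewma", "ewma_ma"))
    cat(sprintf("  lambda = %g\n", x$lambda))
  if (x$kind %in% c("ma", "ma_ewma", "ewma_ma"))
    cat(sprintf("  w = %d\n", x$w))
  if (x$subgroup > 1L) cat(sprintf("  subgroup size n = %d\n", x$subgroup))
  invisible(x)
}
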