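#' Calibrate a control-limit coefficient to a target in-control ARL
#'
#' Finds the coefficient \eqn{H} such that the Monte-Carlo in-control
#' average run length of the chart equals \code{target_arl0} (370
#' throughout the performance studies). The search is bisection with common
#' random numbers: the same observation streams (fixed \code{seed}) are
#' reused at every trial \eqn{H}. Because the statistic path does not
#' depend on \eqn{H}, each simulated run length is non-decreasing in
#' \eqn{H} stream-by-stream, so the estimated ARL is a monotone
#' non-decreasing step function of \eqn{H} and the bracket stays valid.
#'
#' The search stops when \eqn{|\widehat{ARL}_0 - \mathrm{target}| \le}
#' \code{tolerance} or the bracket is narrower than \code{1e-3}. The
#' initial bracket auto-expands (doubling the upper end) up to
#' \code{h_max}; if the target is still not straddled — for example under a
#' censoring horizon too short to reach it — the calibration fails with an
#' error.
#'
#' @param kind,lambda,w chart kind and parameters, as in
#'   \code{\link{chart_spec}}.
#' @param dist in-control \code{\link{dist_spec}} (must have
#'   \code{delta = 0}); the chart is centred at \code{dist$mu0} with scale
#'   \code{dist$sigma0}.
#' @param target_arl0 requested in-control ARL (> 1).
#' @param n_reps Monte-Carlo replications per trial \eqn{H}.
#' @param seed integer seed shared by all trials (common random numbers).
#' @param tolerance acceptable \eqn{|\widehat{ARL}_0 - \mathrm{target}|}.
#' @param max_steps censoring horizon per run.
#' @param limit_mode limit convention, as in \code{\link{chart_spec}}.
#' @param h_bracket initial bracket for \eqn{H} (in \eqn{\sigma} units of
#'   the plotted statistic's SD).
#' @param h_max upper bound for bracket auto-expansion.
#' @return object of class \code{"chart_calibration"}: list with \code{h},
#'   \code{achieved_arl0}, \code{target_arl0}, \code{bracket},
#'   \code{n_reps}, \code{seed}, \code{tolerance}, \code{n_eval} and the
#'   calibrated \code{chart}.
#' @examples
#' \donttest{
#' cal <- calibrate_h("shewhart", dist = dist_spec("normal"),
#'                    n_reps = 5000, seed = 1, tolerance = 10)
#' cal$h  # close to 3
#' }
#' @export
calibrate_h <- function(kind, lambda = 0.25, w = 5, dist,
                        target_arl0 = 370, n_reps = 100000L, seed = 1L,
                        tolerance = 2, max_steps = 10000L,
                        limit_mode = "time_varying",
                        h_bracket = c(0, 20), h_max = 200) {
  stopifnot(inherits(dist, "dist_spec"))
  if (dist$delta != 0)
    stop("calibration requires the in-control distribution (delta = 0)")
  if (target_arl0 <= 1) stop("'target_arl0' must exceed 1")
  if (target_arl0 > max_steps)
    stop("'target_arl0' unreachable under the censoring horizon 'max_steps'")
  mk <- function(h) chart_spec(kind, h = h, lambda = lambda, w = w,
                               center = dist$mu0, scale = dist$sigma0,
                               limit_mode = limit_mode)
  # one set of simulated paths, stored as exceedance records, serves every
  # trial H: exact common random numbers, and ARL(H) is exactly monotone
  gen <- function(cap) {
    set.seed(seed)
    .g_records(mk(0), dist, as.integer(n_reps), as.integer(max_steps),
               h_cap = cap)
  }
  lo <- h_bracket[1]; hi <- h_bracket[2]
  rec <- gen(hi)
  n_eval <- 0L
  arl_at <- function(h) {
    n_eval <<- n_eval + 1L
    mean(.rl_at_h(rec, h)$rl)
  }
  f_hi <- arl_at(hi)
  while (f_hi < target_arl0) {
    if (hi >= h_max)
      stop("could not bracket the target ARL0: ARL at H = ", hi,
           " is ", round(f_hi, 2))
    lo <- hi; hi <- min(2 * hi, h_max)
    rec <- gen(hi)
    f_hi <- arl_at(hi)
  }
  h <- hi; achieved <- f_hi
  while (hi - lo > 1e-3) {
    mid <- (lo + hi) / 2
    f_mid <- arl_at(mid)
    if (abs(f_mid - target_arl0) <= tolerance) {
      h <- mid; achieved <- f_mid
      break
    }
    if (f_mid < target_arl0) lo <- mid else hi <- mid
    h <- mid; achieved <- f_mid
  }
  structure(list(h = h, achieved_arl0 = achieved, target_arl0 = target_arl0,
                 bracket = c(lo, hi), n_reps = as.integer(n_reps),
                 seed = seed, tolerance = tolerance, n_eval = n_eval,
                 chart = mk(h)),
            class = "chart_calibration")
}

#' In-control ARL as a function of the control-limit coefficient
#'
#' Evaluates the Monte-Carlo ARL of one chart at several coefficients
#' \eqn{H} using a single set of simulated paths (the common-random-numbers
#' scheme of \code{\link{calibrate_h}}). On a fixed path set the run length
#' is non-decreasing in \eqn{H} replication by replication, so the returned
#' profile is an exactly non-decreasing step function of \eqn{H} — the
#' property that makes bisection calibration reliable.
#'
#' @inheritParams calibrate_h
#' @param dist a \code{\link{dist_spec}} (any \code{delta}; the chart is
#'   centred at \code{dist$mu0} with scale \code{dist$sigma0}).
#' @param h_values coefficients at which to evaluate the ARL.
#' @return data frame with columns \code{h}, \code{arl}, \code{sdrl},
#'   \code{n_censored}, ordered as \code{h_values}.
#' @export
arl_h_profile <- function(kind, lambda = 0.25, w = 5, dist, h_values,
                          n_reps, seed = 1L, max_steps = 10000L,
                          limit_mode = "time_varying") {
  stopifnot(inherits(dist, "dist_spec"), length(h_values) >= 1)
  ch <- chart_spec(kind, h = 0, lambda = lambda, w = w, center = dist$mu0,
                   scale = dist$sigma0, limit_mode = limit_mode)
  set.seed(seed)
  rec <- .g_records(ch, dist, as.integer(n_reps), as.integer(max_steps),
                    h_cap = max(h_values))
  rows <- lapply(h_values, function(h) {
    r <- .rl_at_h(rec, h)
    data.frame(h = h, arl = mean(r$rl),
               sdrl = sqrt(mean(r$rl^2) - mean(r$rl)^2),
               n_censored = sum(r$censored))
  })
  do.call(rbind, rows)
}

#' Closed-form Shewhart coefficient
#'
#' Deterministic counterpart of \code{\link{calibrate_h}} for the Shewhart
#' chart: solves \eqn{P(X < \mu_0 - H\sigma_0) + P(X > \mu_0 + H\sigma_0) =
#' 1/\mathrm{target}} on the exact in-control CDF by root-finding. For
#' right-skewed families the LCL drops below the support once \eqn{H} is
#' large enough and only the upper tail contributes (an effectively
#' one-sided chart); no clamping is applied.
#'
#' @param dist in-control \code{\link{dist_spec}} (\code{delta = 0}).
#' @param target_arl0 target in-control ARL.
#' @return the coefficient \eqn{H} (numeric scalar).
#' @examples
#' shewhart_h_exact(dist_spec("normal"), 370.4)          # 3.000
#' shewhart_h_exact(dist_spec("exponential"), 370)       # log(370) - 1
#' @export
shewhart_h_exact <- function(dist, target_arl0 = 370) {
  stopifnot(inherits(dist, "dist_spec"))
  if (dist$delta != 0)
    stop("use the in-control distribution (delta = 0)")
  alpha <- 1 / target_arl0
  f <- function(h) {
    .dist_cdf(dist, dist$mu0 - h * dist$sigma0) +
      (1 - .dist_cdf(dist, dist$mu0 + h * dist$sigma0)) - alpha
  }
  stats::uniroot(f, c(1e-8, 200), tol = 1e-10)$root
}

#' @export
print.chart_calibration <- function(x, ...) {
  cat(sprintf("Calibrated H = %.4f (target ARL0 = %g, achieved %.2f)\n",
              x$h, x$target_arl0, x$achieved_arl0))
  cat(sprintf("  bracket [%.4f, %.4f], %d ARL evaluations at N = %d, seed %d\n",
              x$bracket[1], x$bracket[2], x$n_eval, x$n_reps, x$seed))
  invisible(x)
}
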