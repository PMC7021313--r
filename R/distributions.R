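#' Sampling distribution with a standardized location shift
#'
#' Defines one of the six process distributions used in the performance
#' studies, together with its in-control mean \eqn{\mu_0}, in-control scale
#' \eqn{\sigma_0} and a dimensionless shift multiplier \eqn{\delta}. Samples
#' are drawn from the family at the stated parameters and then location
#' shifted so that the mean becomes \eqn{\mu_1 = \mu_0 + \delta\sigma_0};
#' shape and scale are unchanged (a pure location shift).
#'
#' Two conventions for \eqn{\sigma_0} are supported. Under
#' \code{scale_convention = "sd"} (the default) \eqn{\sigma_0} is the true
#' standard deviation of the family, obtained in closed form:
#' \eqn{b\sqrt{2}} for Laplace(location, scale \eqn{b}), \eqn{s\pi/\sqrt{3}}
#' for logistic(location, scale \eqn{s}), \eqn{\sqrt{\nu/(\nu-2)}} for
#' Student t, \eqn{1/\lambda} for exponential(rate \eqn{\lambda}) and
#' \eqn{\theta\sqrt{k}} for gamma(shape \eqn{k}, scale \eqn{\theta}). Under
#' \code{"scale_param"} the raw scale parameter is used instead; the two
#' conventions coincide for the normal and exponential families.
#'
#' @param family one of \code{"normal"}, \code{"laplace"}, \code{"logistic"},
#'   \code{"student_t"}, \code{"exponential"}, \code{"gamma"}.
#' @param params named list of family parameters. Recognised entries:
#'   \code{mean}, \code{sd} (normal); \code{location}, \code{scale} (laplace,
#'   logistic); \code{df} (student_t, must exceed 2); \code{rate}
#'   (exponential); \code{shape}, \code{scale} (gamma). Missing entries take
#'   the study defaults: Normal(0,1), Laplace(0,1), Logistic(6,2), Student
#'   t with 10 df, Exponential(rate 1), Gamma(shape 4, scale 1).
#' @param delta shift multiplier \eqn{\delta}; for the right-skewed
#'   exponential and gamma families only \eqn{\delta \ge 0} is admitted.
#' @param scale_convention \code{"sd"} or \code{"scale_param"}, see Details.
#'
#' @return An object of class \code{"dist_spec"}: a list with elements
#'   \code{family}, \code{params}, \code{delta}, \code{scale_convention},
#'   \code{mu0}, \code{sigma0}, \code{sd0} (the true SD, whatever the
#'   convention) and \code{mu1}.
#'
#' @examples
#' d <- dist_spec("gamma", delta = 0)
#' d$mu0    # 4
#' d$sigma0 # 2
#' x <- rdist(dist_spec("normal", delta = 2), 1e4)
#' mean(x)  # close to 2
#' @export
dist_spec <- function(family = c("normal", "laplace", "logistic",
                                 "student_t", "exponential", "gamma"),
                      params = list(), delta = 0,
                      scale_convention = c("sd", "scale_param")) {
  family <- match.arg(family)
  scale_convention <- match.arg(scale_convention)
  stopifnot(is.numeric(delta), length(delta) == 1L, is.finite(delta))
  p <- .dist_defaults(family)
  if (length(params)) {
    bad <- setdiff(names(params), names(p))
    if (length(bad))
      stop("unknown parameter(s) for family '", family, "': ",
           paste(bad, collapse = ", "))
    p[names(params)] <- params
  }
  mom <- .dist_moments(family, p)
  if (family %in% c("exponential", "gamma") && delta < 0)
    stop("only delta >= 0 shifts are supported for the ", family, " family")
  sigma0 <- if (scale_convention == "sd") mom$sd else mom$scale_param
  structure(list(family = family, params = p, delta = delta,
                 scale_convention = scale_convention,
                 mu0 = mom$mean, sigma0 = sigma0, sd0 = mom$sd,
                 mu1 = mom$mean + delta * sigma0),
            class = "dist_spec")
}

.dist_defaults <- function(family) {
  switch(family,
         normal      = list(mean = 0, sd = 1),
         laplace     = list(location = 0, scale = 1),
         logistic    = list(location = 6, scale = 2),
         student_t   = list(df = 10),
         exponential = list(rate = 1),
         gamma       = list(shape = 4, scale = 1))
}

# closed-form in-control moments; errors on invalid parameters
.dist_moments <- function(family, p) {
  chk <- function(v, nm) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("parameter '", nm, "' must be a positive number")
    v
  }
  switch(family,
         normal = list(mean = p$mean, sd = chk(p$sd, "sd"),
                       scale_param = p$sd),
         laplace = list(mean = p$location,
                        sd = chk(p$scale, "scale") * sqrt(2),
                        scale_param = p$scale),
         logistic = list(mean = p$location,
                         sd = chk(p$scale, "scale") * pi / sqrt(3),
                         scale_param = p$scale),
         student_t = {
           df <- chk(p$df, "df")
           if (df <= 2) stop("student_t requires df > 2 (finite variance)")
           list(mean = 0, sd = sqrt(df / (df - 2)), scale_param = 1)
         },
         exponential = {
           r <- chk(p$rate, "rate")
           list(mean = 1 / r, sd = 1 / r, scale_param = 1 / r)
         },
         gamma = {
           k <- chk(p$shape, "shape"); th <- chk(p$scale, "scale")
           list(mean = k * th, sd = sqrt(k) * th, scale_param = th)
         })
}

#' Draw shifted samples from a distribution specification
#'
#' Generates \code{n} i.i.d. draws from the family of \code{d}, location
#' shifted by \eqn{\delta\sigma_0} so that the mean equals \code{d$mu1}.
#' Draws are taken from the session RNG; seed beforehand for
#' reproducibility.
#'
#' @param d a \code{\link{dist_spec}}.
#' @param n number of draws (positive integer).
#' @return numeric vector of length \code{n}.
#' @export
rdist <- function(d, n) {
  stopifnot(inherits(d, "dist_spec"), n >= 1)
  .dist_sampler(d)(n)
}

# returns a function(m) drawing m shifted values; used in hot loops so the
# switch happens once per simulation, not per step
.dist_sampler <- function(d) {
  p <- d$params
  shift <- d$delta * d$sigma0
  f <- switch(d$family,
              normal      = function(m) stats::rnorm(m, p$mean, p$sd),
              laplace     = function(m) {
                u <- stats::runif(m) - 0.5
                p$location - p$scale * sign(u) * log1p(-2 * abs(u))
              },
              logistic    = function(m) stats::rlogis(m, p$location, p$scale),
              student_t   = function(m) stats::rt(m, p$df),
              exponential = function(m) stats::rexp(m, p$rate),
              gamma       = function(m) stats::rgamma(m, p$shape,
                                                      scale = p$scale))
  if (shift == 0) f else function(m) f(m) + shift
}

# in-control CDF evaluated at q (raw measurement scale); used by the
# closed-form Shewhart calibration
.dist_cdf <- function(d, q) {
  p <- d$params
  switch(d$family,
         normal      = stats::pnorm(q, p$mean, p$sd),
         laplace     = {
           z <- (q - p$location) / p$scale
           ifelse(z < 0, 0.5 * exp(z), 1 - 0.5 * exp(-z))
         },
         logistic    = stats::plogis(q, p$location, p$scale),
         student_t   = stats::pt(q, p$df),
         exponential = stats::pexp(q, p$rate),
         gamma       = stats::pgamma(q, p$shape, scale = p$scale))
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("Distribution:", x$family,
      paste0("(", paste(names(x$params), unlist(x$params), sep = "=",
                        collapse = ", "), ")"), "\n")
  cat(sprintf("  mu0 = %g, sigma0 = %g (%s convention), delta = %g, mu1 = %g\n",
              x$mu0, x$sigma0, x$scale_convention, x$delta, x$mu1))
  invisible(x)
}
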