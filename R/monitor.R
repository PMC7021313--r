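#' Observed series for Phase-II monitoring
#'
#' Couples an ordered univariate series (e.g. annual observations) with the
#' known in-control mean and standard deviation used to build the control
#' limits. No Phase-I estimation is performed: \code{mu0} and \code{sigma0}
#' are taken as given.
#'
#' @param labels ordered period identifiers (e.g. years); must be unique
#'   and strictly increasing.
#' @param values numeric observations, same length as \code{labels}; missing
#'   values are rejected.
#' @param mu0 in-control mean.
#' @param sigma0 in-control standard deviation (> 0).
#' @return object of class \code{"observed_series"}.
#' @export
observed_series <- function(labels, values, mu0, sigma0) {
  if (!length(values)) stop("empty series")
  if (length(labels) != length(values))
    stop("'labels' and 'values' must have equal length")
  if (anyNA(values) || !is.numeric(values) || !all(is.finite(values)))
    stop("missing or non-numeric values are not allowed (no imputation)")
  if (anyDuplicated(labels)) stop("duplicate labels")
  if (is.unsorted(labels, strictly = TRUE))
    stop("labels must be strictly ordered")
  stopifnot(is.numeric(mu0), is.numeric(sigma0))
  if (sigma0 <= 0) stop("'sigma0' must be positive")
  structure(list(labels = labels, values = as.numeric(values),
                 mu0 = mu0, sigma0 = sigma0),
            class = "observed_series")
}

#' Read an observed series from CSV
#'
#' Expects a header \code{label,value}; values must be numeric and complete,
#' labels unique and strictly increasing. Lines starting with \code{#} are
#' ignored.
#'
#' @param path CSV file path.
#' @param mu0,sigma0 in-control parameters attached to the series.
#' @return an \code{\link{observed_series}}.
#' @examples
#' nile <- read_series_csv(system.file("extdata", "nile_flow.csv",
#'                                     package = "spcmix"),
#'                         mu0 = 1100, sigma0 = 125)
#' @export
read_series_csv <- function(path, mu0, sigma0) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("label", "value") %in% names(df)))
    stop("CSV must have columns 'label' and 'value'")
  if (anyNA(df$value))
    stop("blank or non-numeric value in row(s): ",
         paste(which(is.na(df$value)), collapse = ", "))
  if (!is.numeric(df$value)) {
    v <- suppressWarnings(as.numeric(df$value))
    if (anyNA(v))
      stop("blank or non-numeric value in row(s): ",
           paste(which(is.na(v)), collapse = ", "))
    df$value <- v
  }
  observed_series(df$label, df$value, mu0 = mu0, sigma0 = sigma0)
}

#' Monitor an observed series with a control chart
#'
#' Applies the chart recursion sequentially from the first observation
#' (\eqn{Z_0 = \mu_0}, empty buffer), with the chart centred at the series'
#' in-control mean and scaled by its in-control SD. All signals are
#' recorded, not only the first; the first-signal label is the headline
#' output.
#'
#' @param chart a \code{\link{chart_spec}}; its \code{center} and
#'   \code{scale} are replaced by the series' \code{mu0} and \code{sigma0}.
#' @param series an \code{\link{observed_series}}.
#' @return object of class \code{"chart_monitor"}: list with \code{trace}
#'   (data frame \code{label}, \code{x}, \code{stat}, \code{lcl},
#'   \code{ucl}, \code{signal}), \code{first_signal_label} (or \code{NA}),
#'   \code{chart} and \code{series}.
#' @examples
#' nile <- read_series_csv(system.file("extdata", "nile_flow.csv",
#'                                     package = "spcmix"),
#'                         mu0 = 1100, sigma0 = 125)
#' m <- monitor_series(chart_spec("shewhart", h = 3), nile)
#' first_signal(m)  # 1902
#' @export
monitor_series <- function(chart, series) {
  stopifnot(inherits(chart, "chart_spec"), inherits(series, "observed_series"))
  chart$center <- series$mu0
  chart$scale <- series$sigma0
  tr <- chart_apply(chart, series$values)
  tr <- data.frame(label = series$labels, tr[, -1, drop = FALSE])
  first <- if (any(tr$signal)) tr$label[which(tr$signal)[1]] else NA
  structure(list(trace = tr, first_signal_label = first,
                 chart = chart, series = series),
            class = "chart_monitor")
}

#' First out-of-control label of a monitoring result
#'
#' @param result a \code{\link{monitor_series}} result.
#' @return the earliest signaling label, or \code{NA} if no period signals.
#' @export
first_signal <- function(result) {
  stopifnot(inherits(result, "chart_monitor"))
  result$first_signal_label
}

#' @export
print.chart_monitor <- function(x, ...) {
  print(x$chart)
  n_sig <- sum(x$trace$signal)
  cat(sprintf("Monitored %d periods (%s to %s): %d signal(s)\n",
              nrow(x$trace), x$trace$label[1],
              x$trace$label[nrow(x$trace)], n_sig))
  if (n_sig > 0)
    cat("  first signal at:", format(x$first_signal_label), "\n")
  invisible(x)
}

#' @export
summary.chart_monitor <- function(object, ...) {
  tr <- object$trace
  cat(sprintf("In-control parameters: mu0 = %g, sigma0 = %g\n",
              object$series$mu0, object$series$sigma0))
  print(object)
  if (any(tr$signal)) {
    cat("Signaling periods:\n")
    print(tr[tr$signal, c("label", "x", "stat", "lcl", "ucl")],
          row.names = FALSE)
  }
  invisible(object)
}

#' Plot a monitoring result
#'
#' Base-graphics chart plot: the plotted statistic against the period
#' labels, the control limits as step lines, the center line, and signaling
#' periods marked in red.
#'
#' @param x a \code{\link{monitor_series}} result.
#' @param ... further arguments passed to \code{plot}.
#' @return \code{x}, invisibly.
#' @export
plot.chart_monitor <- function(x, ...) {
  tr <- x$trace
  lab <- if (is.numeric(tr$label)) tr$label else seq_len(nrow(tr))
  ylim <- range(tr$stat, tr$lcl, tr$ucl)
  plot(lab, tr$stat, type = "b", pch = 20, ylim = ylim,
       xlab = "period", ylab = "chart statistic", ...)
  graphics::lines(lab, tr$ucl, lty = 2, col = "red3")
  graphics::lines(lab, tr$lcl, lty = 2, col = "red3")
  graphics::abline(h = x$chart$center, lty = 3, col = "grey40")
  if (any(tr$signal))
    graphics::points(lab[tr$signal], tr$stat[tr$signal], pch = 19,
                     col = "red3")
  invisible(x)
}
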