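#' Side-by-side ARL performance table for several charts
#'
#' Regenerates a performance-comparison table: one row per shift
#' \eqn{\delta} and one column group per chart, each cell carrying the
#' Monte-Carlo ARL, its standard error, the SDRL and the MRL. All charts
#' are run on the same family with coefficients held fixed at their
#' in-control calibration, so rows and columns can be diffed directly
#' against published tables.
#'
#' @param charts named list of \code{\link{chart_spec}} objects; names
#'   become column-group prefixes.
#' @param dist a \code{\link{dist_spec}} giving the family and parameters
#'   (its \code{delta} is ignored; the grid below is used).
#' @param deltas non-empty vector of shift multipliers.
#' @param n_reps Monte-Carlo replications per cell.
#' @param seed integer base seed.
#' @param max_steps censoring horizon per run.
#' @return data frame with column \code{delta} followed, for each chart
#'   name \code{nm}, by \code{nm_arl}, \code{nm_se}, \code{nm_sdrl},
#'   \code{nm_mrl}.
#' @examples
#' \donttest{
#' tab <- arl_table(
#'   list(shewhart = chart_spec("shewhart", h = 3),
#'        ma = chart_spec("ma", h = 3, w = 5)),
#'   dist_spec("normal"), deltas = c(0, 1), n_reps = 5000, seed = 1)
#' }
#' @export
arl_table <- function(charts, dist, deltas, n_reps, seed = NULL,
                      max_steps = 10000L) {
  if (!length(charts)) stop("'charts' must be a non-empty named list")
  if (is.null(names(charts)) || any(names(charts) == ""))
    stop("'charts' must be named")
  ok <- vapply(charts, inherits, logical(1), what = "chart_spec")
  if (!all(ok))
    stop("unknown chart object(s): ", paste(names(charts)[!ok], collapse = ", "))
  if (!length(deltas)) stop("'deltas' must be non-empty")
  stopifnot(inherits(dist, "dist_spec"))
  out <- data.frame(delta = deltas)
  for (j in seq_along(charts)) {
    nm <- names(charts)[j]
    cur <- arl_curve(charts[[j]], dist, deltas, n_reps,
                     seed = if (is.null(seed)) NULL else seed + 1000L * j,
                     max_steps = max_steps)
    out[[paste0(nm, "_arl")]] <- cur$arl
    out[[paste0(nm, "_se")]] <- cur$se_arl
    out[[paste0(nm, "_sdrl")]] <- cur$sdrl
    out[[paste0(nm, "_mrl")]] <- cur$mrl
  }
  out
}

# small polynomial rolling hash of a deparsed object, for provenance headers
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = " "))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483629
  sprintf("%08x", as.integer(h))
}

#' Write a result table with a provenance header
#'
#' Writes \code{x} as CSV (\code{.} decimal, comma separator, full
#' precision) or JSON. The first line is a \code{#} comment carrying the
#' package version, the seed and a hash of the generating configuration, so
#' any output file records how it was produced.
#'
#' @param path output file path.
#' @param x data frame (CSV) or list (JSON).
#' @param seed the seed that produced \code{x} (recorded in the header).
#' @param config the generating configuration (hashed into the header).
#' @param format \code{"csv"} or \code{"json"}.
#' @return \code{path}, invisibly.
#' @export
write_results <- function(path, x, seed = NA, config = list(),
                          format = c("csv", "json")) {
  format <- match.arg(format)
  ver <- as.character(utils::packageVersion("spcmix"))
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# spcmix %s seed=%s config=%s", ver,
                       format(seed), .config_hash(config)), con)
    utils::write.csv(x, con, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(
      c(list(version = ver, seed = seed, config_hash = .config_hash(config)),
        list(results = x)),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read back a result table written by \code{\link{write_results}}
#'
#' @param path CSV file path.
#' @return data frame (the provenance header line is skipped).
#' @export
read_results <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
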