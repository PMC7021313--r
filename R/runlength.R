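#' @title Monte-Carlo run-length engine
#' @description Zero-state run lengths: the shift (if any) is present from
#'   observation 1 and the chart starts at its in-control state
#'   (\eqn{Z_0 = \mu_0}, empty buffer). The run length is the 1-based index
#'   of the first observation whose statistic falls strictly outside the
#'   control limits; runs that never signal within \code{max_steps} are
#'   censored at the cap and counted, not discarded.
#' @name runlength
NULL

# Simulates m independent run lengths for one chart/distribution pair.
# One R-level loop over time; vector operations across the replications
# still running. MA-type windows are kept in a (w x m) circular matrix with
# a shared row pointer (all replications are time-synchronised), plus a
# running window sum.
.rl_block <- function(chart, dist, m, max_steps) {
  draw <- .dist_sampler(dist)
  kind <- chart$kind
  lam <- chart$lambda
  w <- chart$w
  half <- chart$h * sqrt(chart_variance(chart, seq_len(max_steps)))
  lcl <- chart$center - half
  ucl <- chart$center + half

  rl <- integer(m)
  idx <- seq_len(m)                      # replication ids still running
  z <- rep(chart$center, m)
  need_xwin <- kind %in% c("ma", "ewma_ma")
  need_zwin <- kind == "ma_ewma"
  if (need_xwin || need_zwin) {
    buf <- matrix(0, w, m)
    wsum <- numeric(m)
  }

  for (t in seq_len(max_steps)) {
    x <- draw(length(idx))
    if (need_xwin) {
      r <- (t - 1L) %% w + 1L
      if (t <= w) wsum <- wsum + x
      else wsum <- wsum + x - buf[r, ]
      buf[r, ] <- x
      mstat <- wsum / min(t, w)
    }
    stat <- switch(kind,
      shewhart = x,
      ma       = mstat,
      ewma     = {z <- lam * x + (1 - lam) * z; z},
      ewma_ma  = {z <- lam * mstat + (1 - lam) * z; z},
      ma_ewma  = {
        z <- lam * x + (1 - lam) * z
        r <- (t - 1L) %% w + 1L
        if (t <= w) wsum <- wsum + z
        else wsum <- wsum + z - buf[r, ]
        buf[r, ] <- z
        wsum / min(t, w)
      })
    sig <- stat < lcl[t] | stat > ucl[t]
    if (any(sig)) {
      rl[idx[sig]] <- t
      keep <- !sig
      idx <- idx[keep]
      if (!length(idx)) break
      z <- z[keep]
      if (need_xwin || need_zwin) {
        buf <- buf[, keep, drop = FALSE]
        wsum <- wsum[keep]
      }
    }
  }
  censored <- rl == 0L
  rl[censored] <- max_steps
  list(rl = rl, censored = censored)
}

# Record-value representation of simulated chart paths, used for exact
# common-random-numbers calibration. For each replication the normalized
# exceedance G_t = |stat_t - center| / sqrt(V_t) is tracked and every new
# running maximum (a "record") is stored as (replication, t, G). Because the
# statistic path does not depend on H, the run length at ANY coefficient H
# is recovered from the records alone: RL(H) is the time of the first
# record exceeding H (censored at max_steps if none does). Replications are
# dropped once their running maximum exceeds h_cap, so records are valid
# for any h <= h_cap.
.g_records <- function(chart, dist, m, max_steps, h_cap = Inf) {
  draw <- .dist_sampler(dist)
  kind <- chart$kind
  lam <- chart$lambda
  w <- chart$w
  sdv <- sqrt(chart_variance(chart, seq_len(max_steps)))
  center <- chart$center

  idx <- seq_len(m)
  z <- rep(center, m)
  gmax <- rep(-Inf, m)
  need_xwin <- kind %in% c("ma", "ewma_ma")
  need_zwin <- kind == "ma_ewma"
  if (need_xwin || need_zwin) {
    buf <- matrix(0, w, m)
    wsum <- numeric(m)
  }
  acc_rep <- list(); acc_g <- list(); acc_t <- list(); k <- 0L

  for (t in seq_len(max_steps)) {
    x <- draw(length(idx))
    if (need_xwin) {
      r <- (t - 1L) %% w + 1L
      if (t <= w) wsum <- wsum + x
      else wsum <- wsum + x - buf[r, ]
      buf[r, ] <- x
      mstat <- wsum / min(t, w)
    }
    stat <- switch(kind,
      shewhart = x,
      ma       = mstat,
      ewma     = {z <- lam * x + (1 - lam) * z; z},
      ewma_ma  = {z <- lam * mstat + (1 - lam) * z; z},
      ma_ewma  = {
        z <- lam * x + (1 - lam) * z
        r <- (t - 1L) %% w + 1L
        if (t <= w) wsum <- wsum + z
        else wsum <- wsum + z - buf[r, ]
        buf[r, ] <- z
        wsum / min(t, w)
      })
    g <- abs(stat - center) / sdv[t]
    nr <- g > gmax
    if (any(nr)) {
      k <- k + 1L
      acc_rep[[k]] <- idx[nr]
      acc_g[[k]] <- g[nr]
      acc_t[[k]] <- rep(t, sum(nr))
      gmax[nr] <- g[nr]
      keep <- gmax <= h_cap
      if (!all(keep)) {
        idx <- idx[keep]
        if (!length(idx)) break
        z <- z[keep]
        gmax <- gmax[keep]
        if (need_xwin || need_zwin) {
          buf <- buf[, keep, drop = FALSE]
          wsum <- wsum[keep]
        }
      }
    }
  }
  list(rep = unlist(acc_rep), t = unlist(acc_t), g = unlist(acc_g),
       m = m, max_steps = max_steps, h_cap = h_cap)
}

# run lengths at coefficient h (<= h_cap) from a stored record set
.rl_at_h <- function(rec, h) {
  hit <- rec$g > h
  r <- rec$rep[hit]
  first <- !duplicated(r)
  rl <- rep(rec$max_steps, rec$m)
  censored <- rep(TRUE, rec$m)
  rl[r[first]] <- rec$t[hit][first]
  censored[r[first]] <- FALSE
  list(rl = rl, censored = censored)
}

#' Simulate a single run length
#'
#' Runs the chart on a fresh stream from \code{dist} until the first signal
#' or the censoring horizon.
#'
#' @param chart a \code{\link{chart_spec}}.
#' @param dist a \code{\link{dist_spec}}.
#' @param max_steps censoring horizon (default 10000).
#' @param seed optional integer seed for this run.
#' @return list with \code{rl} (integer, the index of the first signaling
#'   observation, or \code{max_steps} if censored) and \code{censored}
#'   (logical).
#' @export
run_length <- function(chart, dist, max_steps = 10000L, seed = NULL) {
  stopifnot(inherits(chart, "chart_spec"), inherits(dist, "dist_spec"),
            max_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  b <- .rl_block(chart, dist, 1L, as.integer(max_steps))
  list(rl = b$rl, censored = b$censored)
}

#' Estimate the run-length distribution by Monte Carlo
#'
#' Simulates \code{n_reps} independent run lengths and summarises them as
#' \deqn{ARL = \frac{1}{N}\sum_t RL_t,\quad
#'       SDRL = \sqrt{E(RL^2) - ARL^2},\quad MRL = \mathrm{median}(RL),}
#' with the SDRL in population (divide-by-\eqn{N}) form and the median of an
#' even number of runs the mean of the two central order statistics. The
#' standard error of the ARL is \eqn{SDRL/\sqrt{N}}. Censored runs enter at
#' \code{max_steps} and are counted in \code{n_censored}.
#'
#' Replications are split into blocks of at most \code{block_size}; block
#' seeds are derived deterministically from \code{seed}, so results are
#' reproducible for a fixed \code{(seed, n_reps)}.
#'
#' @inheritParams run_length
#' @param n_reps number of replications \eqn{N}.
#' @param seed integer base seed (or \code{NULL} to use the session RNG).
#' @param block_size replications simulated per block.
#' @param keep_rl keep the raw run-length vector in the result.
#' @return object of class \code{"run_length_summary"}: a list with
#'   \code{n_reps}, \code{arl}, \code{sdrl}, \code{mrl}, \code{se_arl},
#'   \code{max_steps}, \code{n_censored}, \code{seed} and (optionally)
#'   \code{rl}.
#' @examples
#' ch <- chart_spec("shewhart", h = 3)
#' d <- dist_spec("normal")
#' estimate_run_length(ch, d, n_reps = 2000, seed = 1)
#' @export
estimate_run_length <- function(chart, dist, n_reps, seed = NULL,
                                max_steps = 10000L, block_size = 10000L,
                                keep_rl = TRUE) {
  stopifnot(inherits(chart, "chart_spec"), inherits(dist, "dist_spec"),
            n_reps >= 1, max_steps >= 1)
  n_reps <- as.integer(n_reps)
  max_steps <- as.integer(max_steps)
  sizes <- rep(as.integer(block_size), n_reps %/% block_size)
  if (n_reps %% block_size) sizes <- c(sizes, n_reps %% as.integer(block_size))
  if (!is.null(seed)) {
    set.seed(seed)
    bseeds <- sample.int(.Machine$integer.max, length(sizes))
  } else bseeds <- NULL
  rl <- integer(0); cens <- logical(0)
  for (b in seq_along(sizes)) {
    if (!is.null(bseeds)) set.seed(bseeds[b])
    blk <- .rl_block(chart, dist, sizes[b], max_steps)
    rl <- c(rl, blk$rl); cens <- c(cens, blk$censored)
  }
  arl <- mean(rl)
  sdrl <- sqrt(mean(rl^2) - arl^2)        # population form
  out <- list(n_reps = n_reps, arl = arl, sdrl = sdrl,
              mrl = stats::median(rl), se_arl = sdrl / sqrt(n_reps),
              max_steps = max_steps, n_censored = sum(cens),
              seed = if (is.null(seed)) NA_integer_ else seed)
  if (keep_rl) out$rl <- rl
  structure(out, class = "run_length_summary")
}

#' Run-length performance over a grid of mean shifts
#'
#' Re-simulates the run-length summary of one chart (coefficients fixed at
#' their in-control calibration) for each shift \eqn{\delta} in
#' \code{deltas}, with the sampling family and parameters taken from
#' \code{dist}.
#'
#' @inheritParams estimate_run_length
#' @param deltas non-empty numeric vector of shift multipliers.
#' @return data frame with one row per shift: \code{delta}, \code{arl},
#'   \code{se_arl}, \code{sdrl}, \code{mrl}, \code{n_reps},
#'   \code{n_censored}, \code{seed}.
#' @export
arl_curve <- function(chart, dist, deltas, n_reps, seed = NULL,
                      max_steps = 10000L, block_size = 10000L) {
  if (!length(deltas)) stop("'deltas' must be non-empty")
  rows <- lapply(seq_along(deltas), function(i) {
    d <- dist_spec(dist$family, dist$params, delta = deltas[i],
                   scale_convention = dist$scale_convention)
    s <- estimate_run_length(chart, d, n_reps,
                             seed = if (is.null(seed)) NULL else seed + i - 1L,
                             max_steps = max_steps, block_size = block_size,
                             keep_rl = FALSE)
    data.frame(delta = deltas[i], arl = s$arl, se_arl = s$se_arl,
               sdrl = s$sdrl, mrl = s$mrl, n_reps = s$n_reps,
               n_censored = s$n_censored,
               seed = if (is.null(seed)) NA_integer_ else seed + i - 1L)
  })
  do.call(rbind, rows)
}

#' @export
print.run_length_summary <- function(x, ...) {
  cat(sprintf("Run-length summary (N = %d, cap = %d)\n", x$n_reps, x$max_steps))
  cat(sprintf("  ARL  = %.2f (SE %.3f)\n", x$arl, x$se_arl))
  cat(sprintf("  SDRL = %.2f\n  MRL  = %g\n", x$sdrl, x$mrl))
  if (x$n_censored > 0)
    cat(sprintf("  censored runs: %d\n", x$n_censored))
  invisible(x)
}
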