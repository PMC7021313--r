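test_that("chart specifications are validated", {
  expect_error(chart_spec("ma", h = 3, w = 0), "positive integer span")
  expect_error(chart_spec("ewma", h = 3, lambda = 0), "lambda")
  expect_error(chart_spec("ewma", h = 3, lambda = 1.2), "lambda")
  expect_error(chart_spec("shewhart", h = -1), ">= 0")
  expect_error(chart_spec("shewhart", h = 3, scale = 0), "positive")
  ch <- chart_spec("ewma_ma", h = 6.480, lambda = 0.25, w = 5)
  expect_s3_class(ch, "chart_spec")
  expect_equal(ch$w, 5L)
})

test_that("recursions agree with brute-force oracles to 1e-12", {
  set.seed(31)
  for (n in c(50, 1000)) {
    x <- rnorm(n, 2, 3)
    for (w in c(1, 5, 12)) {
      expect_equal(ma_stat(x, w), bf_ma(x, w), tolerance = 1e-12)
      for (lam in c(0.05, 0.25, 0.75)) {
        expect_equal(ewma_stat(x, lam, z0 = 2), bf_ewma(x, lam, z0 = 2),
                     tolerance = 1e-12)
        expect_equal(ewma_ma_stat(x, lam, w, z0 = 2),
                     bf_ewma_ma(x, lam, w, z0 = 2), tolerance = 1e-12)
        expect_equal(ma_ewma_stat(x, lam, w, z0 = 2),
                     bf_ma_ewma(x, lam, w, z0 = 2), tolerance = 1e-12)
      }
    }
  }
})

test_that("degenerate parameters reduce one chart to another", {
  set.seed(5)
  x <- rnorm(200)
  # MA(w=1), EWMA(lambda=1) and the raw statistic coincide
  expect_equal(ma_stat(x, 1), x)
  expect_equal(ewma_stat(x, 1, z0 = 0), x)
  # mixed charts with w = 1 collapse to the EWMA
  expect_equal(ewma_ma_stat(x, 0.25, 1, z0 = 0), ewma_stat(x, 0.25, 0))
  expect_equal(ma_ewma_stat(x, 0.25, 1, z0 = 0), ewma_stat(x, 0.25, 0))
  # MA-EWMA with lambda = 1 collapses to the MA
  expect_equal(ma_ewma_stat(x, 1, 5, z0 = 0), ma_stat(x, 5))
  # constant input held at the center is a fixed point
  expect_equal(ewma_ma_stat(rep(2, 50), 0.3, 5, z0 = 2), rep(2, 50))
})

test_that("control limits evaluate to their closed forms", {
  em <- chart_spec("ewma_ma", h = 6.480, lambda = 0.25, w = 5)
  lim <- chart_limits(em, c(1, 3, 10))
  hw <- 6.480 * sqrt((1 / 5) * (0.25 / 1.75))
  expect_equal(lim$ucl, rep(hw, 3), tolerance = 1e-12)   # constant in t
  expect_equal(lim$lcl, rep(-hw, 3), tolerance = 1e-12)

  ma <- chart_spec("ma", h = 3, w = 5)
  lim <- chart_limits(ma, 1:8)
  expect_equal(lim$ucl, 3 / sqrt(pmin(1:8, 5)))
  expect_equal(lim$ucl[5:8], rep(3 / sqrt(5), 4))

  # EWMA with lambda = 1 has Shewhart limits in either mode
  for (mode in c("time_varying", "asymptotic")) {
    ew <- chart_spec("ewma", h = 2.5, lambda = 1, limit_mode = mode)
    expect_equal(chart_limits(ew, 1:4)$ucl, rep(2.5, 4))
  }
  expect_error(chart_limits(ma, 0), ">= 1")
})

test_that("limit width is monotone during warm-up and converges", {
  ma <- chart_spec("ma", h = 3, w = 5)
  hw <- chart_limits(ma, 1:20)$ucl
  expect_true(all(diff(hw) <= 1e-12))            # non-increasing
  expect_equal(hw[5:20], rep(hw[5], 16))         # constant from t = w

  ew <- chart_spec("ewma", h = 2.927, lambda = 0.25)
  hw <- chart_limits(ew, 1:200)$ucl
  expect_true(all(diff(hw) >= -1e-12))           # non-decreasing
  asym <- chart_limits(chart_spec("ewma", h = 2.927, lambda = 0.25,
                                  limit_mode = "asymptotic"), 1)$ucl
  expect_equal(hw[200], asym, tolerance = 1e-8)

  me <- chart_spec("ma_ewma", h = 7.632, lambda = 0.25, w = 5)
  hw <- chart_limits(me, 1:10)$ucl
  expect_true(all(diff(hw) <= 1e-12))
  expect_equal(hw[5:10], rep(hw[5], 6))
})

test_that("streaming steps replay the vectorised trace for every kind", {
  set.seed(17)
  x <- rnorm(60, 10, 2)
  for (kind in c("shewhart", "ma", "ewma", "ma_ewma", "ewma_ma")) {
    ch <- chart_spec(kind, h = 2, lambda = 0.25, w = 5, center = 10,
                     scale = 2)
    tr <- chart_apply(ch, x)
    st <- chart_state(ch)
    for (i in seq_along(x)) {
      stp <- chart_step(ch, st, x[i])
      st <- stp$state
      expect_equal(stp$stat, tr$stat[i], tolerance = 1e-12)
      expect_identical(stp$signal, tr$signal[i])
    }
    expect_equal(st$t, length(x))
  }
})

test_that("a point exactly on a limit does not signal", {
  ch <- chart_spec("shewhart", h = 3, center = 0, scale = 1)
  tr <- chart_apply(ch, c(3, -3, 3.0000001, 1))
  expect_identical(tr$signal, c(FALSE, FALSE, TRUE, FALSE))
})

test_that("chart_apply rejects degenerate input", {
  ch <- chart_spec("shewhart", h = 3)
  expect_error(chart_apply(ch, numeric(0)), "empty")
  expect_error(chart_apply(ch, c(1, NA, 2)), "finite")
})
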