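test_that("zero-width limits signal at the first observation", {
  ch <- chart_spec("shewhart", h = 0)
  s <- estimate_run_length(ch, dist_spec("normal"), 500, seed = 1)
  expect_equal(s$arl, 1)
  expect_equal(s$sdrl, 0)
  expect_equal(s$mrl, 1)
  expect_equal(s$se_arl, 0)
})

test_that("runs that never signal are censored at the cap, not dropped", {
  ch <- chart_spec("shewhart", h = 50)
  s <- estimate_run_length(ch, dist_spec("normal"), 200, seed = 2,
                           max_steps = 10)
  expect_equal(s$n_censored, 200)
  expect_equal(s$arl, 10)
  expect_true(all(s$rl == 10L))
})

test_that("summary identities hold on the recorded run lengths", {
  ch <- chart_spec("shewhart", h = 2)
  s <- estimate_run_length(ch, dist_spec("normal"), 5000, seed = 3)
  expect_true(all(s$rl >= 1L & s$rl <= s$max_steps))
  expect_identical(s$se_arl, s$sdrl / sqrt(s$n_reps))
  expect_equal(s$arl, mean(s$rl))
  expect_equal(s$sdrl, sqrt(mean(s$rl^2) - mean(s$rl)^2))
  expect_equal(s$mrl, median(s$rl))
})

test_that("Shewhart run lengths are geometric for families with exact tails", {
  n <- 20000
  cases <- list(list(d = dist_spec("normal"), h = 3),
                list(d = dist_spec("normal", delta = 1), h = 3),
                list(d = dist_spec("exponential"), h = log(370) - 1),
                list(d = dist_spec("laplace", delta = 0.5), h = 3.2),
                list(d = dist_spec("logistic"), h = 9.338 / (pi / sqrt(3))))
  for (cs in cases) {
    p <- shewhart_tail_p(cs$d, cs$h)
    s <- estimate_run_length(chart_spec("shewhart", h = cs$h,
                                        center = cs$d$mu0,
                                        scale = cs$d$sigma0),
                             cs$d, n, seed = 11, max_steps = 50000)
    se <- geom_sdrl(p) / sqrt(n)
    expect_lt(abs(s$arl - geom_arl(p)), 4 * se)
    expect_lt(abs(s$sdrl / geom_sdrl(p) - 1), 0.05)
    expect_lt(abs(s$mrl - geom_mrl(p)), max(4, 0.06 * geom_mrl(p)))
  }
})

test_that("results are reproducible and block seeding splits variance", {
  ch <- chart_spec("shewhart", h = 2.5)
  d <- dist_spec("normal")
  a <- estimate_run_length(ch, d, 4000, seed = 9)
  b <- estimate_run_length(ch, d, 4000, seed = 9)
  expect_identical(a$rl, b$rl)
  # doubling the replication count roughly halves the squared standard error
  big <- estimate_run_length(ch, d, 8000, seed = 9)
  expect_lt(abs(big$se_arl^2 / a$se_arl^2 - 0.5), 0.06)
})

test_that("detection speeds up with the shift size and is symmetric", {
  d <- dist_spec("normal")
  ch <- chart_spec("shewhart", h = 3)
  cur <- arl_curve(ch, d, deltas = c(0, 0.5, 1, 2), n_reps = 10000, seed = 21)
  # geometric closed form at each shift
  expected <- vapply(c(0, 0.5, 1, 2), function(dd)
    geom_arl(shewhart_tail_p(dist_spec("normal", delta = dd), 3)), numeric(1))
  expect_lt(max(abs(cur$arl / expected - 1)), 0.05)
  expect_true(all(diff(cur$arl) < 0))           # non-increasing in |delta|
  # symmetric family: ARL(delta) = ARL(-delta) within Monte-Carlo error
  up <- estimate_run_length(ch, dist_spec("normal", delta = 1), 20000,
                            seed = 22)
  dn <- estimate_run_length(ch, dist_spec("normal", delta = -1), 20000,
                            seed = 23)
  expect_lt(abs(up$arl - dn$arl), 4 * sqrt(up$se_arl^2 + dn$se_arl^2))
})

test_that("the engine matches per-replication brute force for a mixed chart", {
  ch <- chart_spec("ewma_ma", h = 3, lambda = 0.25, w = 5)
  d <- dist_spec("normal", delta = 0.5)
  s <- estimate_run_length(ch, d, 3000, seed = 31, max_steps = 2000)
  set.seed(77)
  rls <- replicate(1500, {
    tr <- chart_apply(ch, rnorm(500) + 0.5)
    i <- which(tr$signal)[1]
    if (is.na(i)) 500L else i
  })
  se <- sqrt(s$se_arl^2 + var(rls) / length(rls))
  expect_lt(abs(s$arl - mean(rls)), 4 * se)
})

test_that("arl_curve refuses an empty shift grid", {
  expect_error(arl_curve(chart_spec("shewhart", h = 3), dist_spec("normal"),
                         deltas = numeric(0), n_reps = 10), "non-empty")
})
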