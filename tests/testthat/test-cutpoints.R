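test_that("log-rank statistic matches the hand-computed O/E/V table", {
  # group A events at t = 1, 2; group B censored at t = 3, 4
  # t=1: n=4, n_A=2, d=1 -> E 1/2, V 1/4;  t=2: n=3, n_A=1, d=1 -> E 1/3, V 2/9
  # O=2, E=5/6, V=17/36 -> chi2 = (7/6)^2 / (17/36) = 49/17
  lr <- logrank_statistic(c("A", "A", "B", "B"), c(1, 2, 3, 4), c(1, 1, 0, 0))
  expect_equal(lr$statistic, 49 / 17, tolerance = 1e-12)
  expect_equal(lr$observed, 2)
  expect_equal(lr$expected, 5 / 6, tolerance = 1e-12)
})

test_that("log-rank is zero on identical groups, errors on one group", {
  t <- c(1, 3, 5, 7); e <- c(1, 0, 1, 1)
  lr <- logrank_statistic(rep(c(0, 1), each = 4), c(t, t), c(e, e))
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_error(logrank_statistic(rep(1, 4), t, e), "two non-empty groups")
  expect_warning(lr0 <- logrank_statistic(c(0, 0, 1, 1), t, rep(0, 4)),
                 "censored")
  expect_equal(lr0$statistic, 0)
})

test_that("log-rank agrees with survival::survdiff on random censored data", {
  for (s in 1:20) {
    d <- random_surv(60, seed = s, tie_round = if (s %% 2) 0 else NULL)
    g <- d$risk > 0
    if (length(unique(g)) < 2 || sum(d$event) == 0) next
    sd <- survival::survdiff(survival::Surv(d$time, d$event) ~ g)
    expect_equal(logrank_statistic(g, d$time, d$event)$statistic, sd$chisq,
                 tolerance = 1e-8, info = paste("seed", s))
  }
})

test_that("log-rank is invariant under monotone time transforms", {
  d <- random_surv(80, seed = 3)
  g <- d$risk > 0
  s1 <- logrank_statistic(g, d$time, d$event)$statistic
  s2 <- logrank_statistic(g, log1p(d$time), d$event)$statistic
  expect_equal(s1, s2, tolerance = 1e-12)
})

test_that("optimal cutpoint equals the exhaustive survdiff scan (n <= 100)", {
  for (s in 1:8) {
    n <- sample(60:100, 1)
    d <- random_surv(n, seed = 100 + s)
    values <- round(rnorm(n, 50, 10), 1)
    # plant signal: low values hasten events
    d2 <- random_surv(n, seed = 200 + s)
    cp <- optimal_cutpoint(values, d2$time, d2$event)
    oracle <- brute_force_cutpoint(values, d2$time, d2$event)
    expect_equal(cp$threshold, oracle$threshold, info = paste("seed", s))
    expect_equal(cp$max_statistic, oracle$stat, tolerance = 1e-8)
  }
})

test_that("cutpoint is equivariant under strictly increasing transforms", {
  d <- random_surv(150, seed = 9)
  values <- runif(150, 10, 90)
  cp1 <- optimal_cutpoint(values, d$time, d$event)
  cp2 <- optimal_cutpoint(exp(values / 20), d$time, d$event)
  expect_equal(cp2$threshold, exp(cp1$threshold / 20), tolerance = 1e-10)
  expect_equal(cp2$max_statistic, cp1$max_statistic, tolerance = 1e-10)
  expect_identical(cp2$direction, cp1$direction)
})

test_that("degenerate inputs are rejected", {
  d <- random_surv(50, seed = 5)
  expect_error(optimal_cutpoint(rep(1, 50), d$time, d$event),
               "no admissible cutpoint")
  expect_error(optimal_cutpoint(rnorm(10), d$time[1:10], d$event[1:10]),
               "at least 20")
})

test_that("threshold recovery improves with n and the permutation p is sane", {
  errs <- vapply(c(500, 2000), function(n) {
    cs <- make_changepoint_series(n, threshold = 50, hr = 2.5, seed = 17)
    cp <- optimal_cutpoint(cs$values, cs$times, cs$events)
    expect_identical(cp$direction, "below")
    abs(cp$threshold - 50)
  }, numeric(1))
  expect_lt(errs[2], 2)

  # null data: naive p can be tiny, permutation p should not be
  csn <- make_changepoint_series(300, threshold = 50, hr = 1, seed = 4)
  cpn <- optimal_cutpoint(csn$values, csn$times, csn$events,
                          n_perm = 60, seed = 1)
  expect_gt(cpn$p_permutation, 0.05)
})
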