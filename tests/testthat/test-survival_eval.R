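test_that("Kaplan-Meier matches product-limit arithmetic and hand fixture", {
  km <- km_estimate(1:4, rep(1, 4))
  expect_equal(km$surv, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$surv_at(0), 1)
  expect_equal(km$surv_at(2.5), 0.5)

  # hand computation, 6 patients: (1,1) (2,0) (3,1) (4,1) (4,0) (5,1)
  km2 <- km_estimate(c(1, 2, 3, 4, 4, 5), c(1, 0, 1, 1, 0, 1))
  expect_equal(km2$surv_at(c(1, 3, 4, 5)), c(5/6, 5/8, 5/12, 0),
               tolerance = 1e-12)

  kmc <- km_estimate(c(2, 5, 9), c(0, 0, 0))
  expect_equal(kmc$surv_at(100), 1)  # no events: S stays at 1
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM is order-invariant and non-increasing", {
  d <- random_surv(60, seed = 2)
  km1 <- km_estimate(d$time, d$event)
  perm <- sample(60)
  km2 <- km_estimate(d$time[perm], d$event[perm])
  expect_equal(km1$surv, km2$surv)
  expect_true(all(diff(km1$surv) <= 1e-12))
})

test_that("Harrell's C: perfect ordering, all ties, and brute-force oracle", {
  t <- c(5, 3, 9, 1, 7)
  expect_equal(harrell_c(t, rep(1, 5), -t)$c, 1)
  expect_equal(harrell_c(t, rep(1, 5), rep(2, 5))$c, 0.5)
  expect_error(harrell_c(t, rep(0, 5), -t), "no events")

  for (s in 1:12) {
    n <- sample(20:80, 1)
    d <- random_surv(n, seed = 300 + s, tie_round = if (s %% 3 == 0) 0 else NULL)
    if (sum(d$event) == 0) next
    cc <- harrell_c(d$time, d$event, d$risk)
    expect_equal(cc$c, brute_force_c(d$time, d$event, d$risk),
                 tolerance = 1e-12, info = paste("seed", s))
    expect_true(cc$lcl <= cc$c && cc$c <= cc$ucl)
  }
})

test_that("paired C comparison: null identity, antisymmetry, signal detection", {
  d <- random_surv(120, seed = 21)
  same <- compare_c(d$time, d$event, d$risk, d$risk, B = 50, seed = 1)
  expect_equal(same$delta, 0)
  expect_equal(same$p_value, 1)

  noise <- rnorm(120)
  ab <- compare_c(d$time, d$event, d$risk, noise, B = 50, seed = 1)
  ba <- compare_c(d$time, d$event, noise, d$risk, B = 50, seed = 1)
  expect_equal(ab$delta, -ba$delta, tolerance = 1e-12)

  # risk_b adds real signal on top of risk_a
  set.seed(5)
  hits <- 0
  for (r in 1:20) {
    n <- 250
    z1 <- rnorm(n); z2 <- rnorm(n)
    tt <- rexp(n, 0.05 * exp(0.6 * z1 + 0.6 * z2))
    cc <- pmin(tt + runif(n, 0, 30), quantile(tt, 0.9))
    time <- pmin(tt, cc); ev <- as.numeric(tt <= cc)
    if (compare_c(time, ev, z1, z1 + z2, B = 10, seed = r)$delta > 0)
      hits <- hits + 1
  }
  expect_gte(hits, 17)
})

test_that("cNRI/IDI vanish for identical models and reduce to textbook forms", {
  d <- random_surv(150, seed = 31)
  r0 <- cnri_idi(d$time, d$event, d$risk, d$risk, horizon = 10, B = 0)
  expect_equal(r0$cnri, 0)
  expect_equal(r0$idi, 0)

  # uncensored: everyone followed past the horizon or until death
  set.seed(41)
  n <- 200
  p_old <- runif(n, 0.05, 0.9)
  p_new <- pmin(0.99, p_old + rnorm(n, 0, 0.15))
  t_event <- rexp(n, 0.08)
  time <- pmin(t_event, 50)          # administrative cutoff beyond horizon
  event <- as.numeric(t_event <= 50)
  horizon <- 15
  y <- as.numeric(time <= horizon & event == 1)
  got <- cnri_idi(time, event, p_old, p_new, horizon = horizon,
                  prob_map = "identity", B = 0)
  want <- binary_cnri_idi(y, p_old, p_new)
  expect_equal(got$cnri, want$cnri, tolerance = 1e-12)
  expect_equal(got$idi, want$idi, tolerance = 1e-12)

  expect_error(cnri_idi(d$time, d$event, d$risk, d$risk, horizon = 1e6),
               "beyond last observed")
})

test_that("a genuinely better model has positive IDI nearly always", {
  pos <- 0
  for (r in 1:40) {
    set.seed(500 + r)
    n <- 300
    z1 <- rnorm(n); z2 <- rnorm(n)
    tt <- rexp(n, 0.03 * exp(0.5 * z1 + 0.8 * z2))
    cc <- runif(n, 10, 80)
    time <- pmin(tt, cc); ev <- as.numeric(tt <= cc)
    r1 <- cnri_idi(time, ev, z1, 0.5 * z1 + 0.8 * z2, horizon = 24, B = 0)
    if (r1$idi > 0) pos <- pos + 1
  }
  expect_gte(pos / 40, 0.95)
})

test_that("time-dependent AUC: separation, null, uncensored rank reduction", {
  # perfect separation at t = 10
  time <- c(2, 4, 6, 20, 25, 30)
  event <- c(1, 1, 1, 0, 0, 0)
  risk <- c(9, 8, 7, 1, 2, 3)
  expect_equal(unname(time_dependent_auc(time, event, risk, 10)), 1)

  set.seed(61)
  n <- 1000
  tt <- rexp(n, 0.05)
  time2 <- pmin(tt, 60); ev2 <- as.numeric(tt <= 60)
  auc_null <- time_dependent_auc(time2, ev2, rnorm(n), 20)
  expect_lt(abs(auc_null - 0.5), 0.05)

  # uncensored before t: equals the plain rank AUC
  y <- as.numeric(time2 <= 20 & ev2 == 1)
  r <- rnorm(n)
  expect_equal(unname(time_dependent_auc(time2, ev2, r, 20)),
               rank_auc(y, r), tolerance = 1e-12)
  expect_error(time_dependent_auc(time2, ev2, r, 1e6), "no controls")
})

test_that("Cox model recovers a known rate ratio and reports trend", {
  set.seed(71)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  tt <- rexp(n, 0.03 * 2^x)
  cc <- runif(n, 10, 80)
  d <- data.frame(os_time = pmin(tt, cc), event = as.numeric(tt <= cc),
                  exposure = factor(x))
  fit <- cox_model(d, "exposure")
  expect_gt(fit$hr_table$hr[1], 1.7)
  expect_lt(fit$hr_table$hr[1], 2.3)
  expect_lt(fit$p_trend, 0.001)
  expect_error(cox_model(transform(d, exposure = 1), "exposure"), "constant")
})

test_that("adjustment moves a confounded HR toward the truth", {
  set.seed(81)
  n <- 3000
  conf <- rnorm(n)                       # confounder: drives exposure and hazard
  x <- rbinom(n, 1, plogis(1.5 * conf))
  tt <- rexp(n, 0.03 * exp(0.0 * x + 1.0 * conf))  # true exposure effect null
  cc <- runif(n, 5, 80)
  d <- data.frame(os_time = pmin(tt, cc), event = as.numeric(tt <= cc),
                  exposure = factor(x), age = conf)
  crude <- cox_model(d, "exposure", adjust = "model_a")
  adj <- cox_model(d, "exposure", adjust = c("age"))
  expect_lt(abs(log(adj$hr_table$hr[1])), abs(log(crude$hr_table$hr[1])))
})

test_that("restricted cubic spline basis and nonlinearity test behave", {
  x <- seq(0, 10, length.out = 200)
  B <- rcs_basis(x, quantile(x, c(0.1, 0.5, 0.9)))
  expect_equal(ncol(B), 2)  # k - 1 columns for k = 3 knots
  # linear tails: second differences vanish outside the outer knots
  lo <- x < quantile(x, 0.1)
  expect_true(all(abs(diff(B[lo, 2], differences = 2)) < 1e-10))

  set.seed(91)
  n <- 1500
  z <- runif(n, -2, 2)
  tt <- rexp(n, 0.05 * exp(0.8 * z^2))   # U-shaped log-hazard
  cc <- runif(n, 5, 60)
  rc <- rcs_dose_response(z, pmin(tt, cc), as.numeric(tt <= cc))
  expect_lt(rc$p_nonlinear, 0.05)
  expect_equal(rc$curve$hr[which.min(abs(rc$curve$x - median(z)))], 1,
               tolerance = 0.05)
  expect_error(rcs_dose_response(rep(1:2, 20), tt[1:40], rep(1, 40)),
               "3 distinct")
})

test_that("screening ranks the signal biomarker first and prunes duplicates", {
  set.seed(101)
  n <- 400
  signal <- rnorm(n)
  panel <- data.frame(A = signal, B = rnorm(n), C = rnorm(n),
                      A2 = signal + rnorm(n, 0, 0.01))
  tt <- rexp(n, 0.05 * exp(0.8 * signal))
  cc <- runif(n, 5, 60)
  time <- pmin(tt, cc); ev <- as.numeric(tt <= cc)
  sc <- screen_biomarkers(panel, time, ev, seed = 1)
  expect_true(sc$c_table$index[1] %in% c("A", "A2"))
  expect_equal(diag(sc$cor_matrix), setNames(rep(1, 4), names(panel)))
  expect_equal(sc$cor_matrix, t(sc$cor_matrix))
  # near-duplicate columns: L1 keeps at most one of the pair
  expect_lte(sum(c("A", "A2") %in% sc$lasso_retained), 1)

  panel$D <- NA_real_
  expect_warning(screen_biomarkers(panel, time, ev), "all-missing")
})

test_that("top-2 per group selection follows C then registry order", {
  ctab <- data.frame(
    index = c("LCR", "CAR", "NLR", "SII", "ALI", "NRI", "PNI", "GNRI"),
    group = rep(c("inflammation", "nutrition"), each = 4),
    c = c(0.652, 0.649, 0.623, 0.608, 0.643, 0.623, 0.624, 0.623))
  # mimics the published ordering, except PNI here outranks NRI
  expect_equal(select_top2_per_group(ctab), c("LCR", "CAR", "ALI", "PNI"))

  ctab2 <- ctab
  ctab2$c <- 0.6
  w <- capture_warnings(sel <- select_top2_per_group(ctab2))
  expect_match(w, "tie", all = TRUE)
  expect_equal(sel, c("LCR", "CAR", "ALI", "PNI"))  # registry order breaks ties
  expect_error(select_top2_per_group(ctab[c(1, 5, 6), ]), "fewer than 2")
})

test_that("random split partitions exhaustively and reproducibly", {
  co <- toy_cohort(10)
  sp <- random_split(co, 0.7, seed = 3)
  expect_equal(nrow(sp$a), 7)
  expect_equal(nrow(sp$b), 3)
  expect_setequal(c(sp$a$patient_id, sp$b$patient_id), co$patient_id)
  expect_length(intersect(sp$a$patient_id, sp$b$patient_id), 0)
  sp2 <- random_split(co, 0.7, seed = 3)
  expect_identical(sp$a$patient_id, sp2$a$patient_id)
  expect_error(random_split(co[1:5, ], 0.7, 1), "at least 10")
})
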