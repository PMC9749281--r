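test_that("ideal weight follows the Lorentz convention", {
  expect_equal(ideal_weight(170, "male"), 65)
  expect_equal(ideal_weight(160, "female"), 56)
  expect_equal(ideal_weight(150, "male"), 50)  # correction term vanishes
  expect_error(ideal_weight(-1, "male"), "positive")
})

test_that("index worked examples", {
  r <- complete_record()
  expect_equal(compute_index(r, "NLR"), 3)
  expect_equal(compute_index(complete_record(platelets = 250, neutrophils = 4,
                                             lymphocytes = 2), "SII"), 500)
  # CRP 8.25 mg/L over albumin 50 g/L lands exactly on the published CAR cutpoint
  expect_equal(compute_index(complete_record(crp = 8.25, albumin = 50), "CAR"),
               0.165)
  expect_equal(compute_index(complete_record(crp = 20, albumin = 30), "mGPS"), 2)
  expect_equal(compute_index(complete_record(crp = 20, albumin = 40), "mGPS"), 1)
  expect_equal(compute_index(complete_record(crp = 5, albumin = 30), "mGPS"), 0)
  # LCR on the lymphocytes-per-uL over CRP-mg/dL scale
  expect_equal(compute_index(complete_record(lymphocytes = 1.4, crp = 8), "LCR"),
               1400 / 0.8)
  expect_true(is.na(compute_index(complete_record(total_protein = NA), "AGR")))
  expect_error(compute_index(r, "XYZ"), "unknown index")
})

test_that("zero denominators propagate as missing with a message", {
  r <- complete_record(lymphocytes = 1.4, crp = 8)
  r$lymphocytes <- 0  # bypasses validation on purpose
  expect_message(v <- compute_index(r, "NLR"), "zero denominator")
  expect_true(is.na(v))
})

test_that("panel has exactly the 15 registry indices, cell-wise missingness", {
  co <- toy_cohort(20)
  p <- compute_panel(co)
  expect_setequal(setdiff(names(p), "patient_id"), index_registry()$index)
  expect_equal(ncol(p), 16)
  expect_false(anyNA(p[setdiff(names(p), "patient_id")]))

  co2 <- co
  co2$cholesterol <- NA
  p2 <- compute_panel(co2)
  expect_true(all(is.na(p2$CONUT)))
  others <- setdiff(names(p2), c("patient_id", "CONUT"))
  expect_false(anyNA(p2[others]))
})

test_that("panel agrees with per-index computation and is deterministic", {
  co <- toy_cohort(10)
  p <- compute_panel(co)
  for (nm in index_registry()$index)
    expect_equal(p[[nm]], compute_index(as.data.frame(co), nm), info = nm)
  expect_identical(p, compute_panel(co))
  same <- as_cohort(do.call(rbind, lapply(1:4, function(i)
    complete_record(patient_id = paste0("S", i)))))
  psame <- compute_panel(same)
  for (nm in index_registry()$index)
    expect_equal(length(unique(psame[[nm]])), 1, info = nm)
})

test_that("scale equivariance of the ratio indices", {
  r <- complete_record()
  r2 <- complete_record(neutrophils = r$neutrophils * 2,
                        lymphocytes = r$lymphocytes * 2)
  expect_equal(compute_index(r2, "NLR"), compute_index(r, "NLR"))
  rc <- complete_record(crp = r$crp * 2)
  expect_equal(compute_index(rc, "CAR"), 2 * compute_index(r, "CAR"))
  expect_equal(compute_index(rc, "LCR"), compute_index(r, "LCR") / 2)
  # the CRP term of mGNRI halves; the weight-ratio term is unchanged
  wr <- 41.7 * min(1, r$weight / ideal_weight(r$height, r$sex))
  expect_equal(compute_index(rc, "mGNRI") - wr,
               (compute_index(r, "mGNRI") - wr) / 2)
})

test_that("ordinal indices stay in their declared ranges", {
  set.seed(11)
  for (i in 1:50) {
    r <- complete_record(
      crp = rlnorm(1, 1.5, 1), albumin = runif(1, 20, 55),
      lymphocytes = runif(1, 0.2, 4), cholesterol = runif(1, 1.5, 8))
    expect_true(compute_index(r, "mGPS") %in% 0:2)
    expect_true(compute_index(r, "LCS") %in% 0:2)
    expect_true(compute_index(r, "CONUT") %in% 0:12)
  }
})
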