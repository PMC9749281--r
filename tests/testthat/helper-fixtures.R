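# Shared fixture builders and independent oracles. Everything here is
# deliberately naive: oracles enumerate or delegate to a different code
# path than the implementation they check.

# one complete canonical-unit record, overridable field by field
complete_record <- function(...) {
  rec <- data.frame(
    patient_id = "P1", sex = "male", age = 60, height = 170, weight = 65,
    wbc = 6.5, neutrophils = 4.2, lymphocytes = 1.4, platelets = 250,
    rbc = 4.5, hemoglobin = 140, albumin = 40, total_protein = 70,
    cholesterol = 4.5, crp = 8, glucose = 5.5, tnm_stage = "II",
    tumor_type = "gastric", surgery = TRUE, radiotherapy = FALSE,
    chemotherapy = TRUE, hypertension = FALSE, diabetes = FALSE,
    smoking = FALSE, drinking = FALSE, family_history = FALSE,
    os_time = 24, event = 1, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# small in-memory cohort of m complete records with varying labs
toy_cohort <- function(m = 5, seed = 42) {
  set.seed(seed)
  recs <- do.call(rbind, lapply(seq_len(m), function(i)
    complete_record(patient_id = paste0("P", i),
                    lymphocytes = round(runif(1, 0.8, 3), 2),
                    crp = round(runif(1, 1, 30), 2),
                    albumin = round(runif(1, 30, 50), 1),
                    os_time = round(runif(1, 5, 60), 1),
                    event = rbinom(1, 1, 0.6))))
  as_cohort(recs, provenance = "fixture")
}

# write a cohort-like data.frame to a temp CSV
write_fixture_csv <- function(df, path = tempfile(fileext = ".csv")) {
  lg <- vapply(df, is.logical, logical(1))
  df[lg] <- lapply(df[lg], as.integer)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

# O(n^2) pair-enumeration Harrell's C: usable pair iff the shorter time is
# an observed event; tied risks count one half
brute_force_c <- function(time, event, risk) {
  n <- length(time)
  conc <- disc <- ties <- 0
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    if (time[i] == time[j]) {
      if (event[i] + event[j] != 1L) next  # both events or both censored
      ev <- if (event[i] == 1) i else j; cs <- if (event[i] == 1) j else i
      d <- risk[ev] - risk[cs]
    } else {
      s <- if (time[i] < time[j]) i else j
      l <- if (time[i] < time[j]) j else i
      if (event[s] != 1) next
      d <- risk[s] - risk[l]
    }
    if (d > 0) conc <- conc + 1 else if (d < 0) disc <- disc + 1
    else ties <- ties + 1
  }
  (conc + 0.5 * ties) / (conc + disc + ties)
}

# exhaustive cutpoint scan through survival::survdiff, independent of the
# package's vectorized scan
brute_force_cutpoint <- function(values, time, event,
                                 search_range = c(0.10, 0.90),
                                 min_group_frac = 0.10) {
  n <- length(values)
  q <- quantile(values, search_range, names = FALSE)
  cand <- sort(unique(values))
  cand <- cand[cand >= q[1] & cand <= q[2]]
  best <- NULL
  for (cth in cand) {
    g <- values < cth
    if (sum(g) < min_group_frac * n || sum(!g) < min_group_frac * n) next
    sd <- survival::survdiff(survival::Surv(time, event) ~ g)
    if (is.null(best) || sd$chisq > best$stat + 1e-12)
      best <- list(threshold = cth, stat = sd$chisq)
  }
  best
}

# random censored survival dataset
random_surv <- function(n, seed, cens_rate = 0.05, tie_round = NULL) {
  set.seed(seed)
  risk <- rnorm(n)
  t_event <- rexp(n, 0.05 * exp(0.5 * risk))
  t_cens <- rexp(n, cens_rate)
  time <- pmin(t_event, t_cens)
  if (!is.null(tie_round)) time <- round(time, tie_round)
  list(time = time, event = as.numeric(t_event <= t_cens), risk = risk)
}

# textbook binary-outcome continuous NRI and IDI by direct enumeration
binary_cnri_idi <- function(y, p_old, p_new) {
  up <- p_new > p_old; down <- p_new < p_old
  cnri <- (mean(up[y == 1]) - mean(down[y == 1])) +
    (mean(down[y == 0]) - mean(up[y == 0]))
  idi <- (mean(p_new[y == 1]) - mean(p_old[y == 1])) -
    (mean(p_new[y == 0]) - mean(p_old[y == 0]))
  list(cnri = cnri, idi = idi)
}

# plain rank AUC by pair enumeration
rank_auc <- function(y, risk) {
  cases <- risk[y == 1]; ctrls <- risk[y == 0]
  s <- 0
  for (a in cases) for (b in ctrls) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(cases) * length(ctrls))
}
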