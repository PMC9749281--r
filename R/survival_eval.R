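# Evaluation battery: Kaplan-Meier, Harrell's C, paired C comparison,
# IPCW cNRI/IDI at a horizon, time-dependent AUC, Cox models with trend
# tests, biomarker screening (univariable C + Pearson + LASSO Cox) and the
# randomized internal split.
#
# Standard fits (KM, Cox partial likelihood, penalized Cox) are delegated to
# the survival and glmnet packages; the discrimination statistics and their
# censoring handling are implemented here.

#' Kaplan-Meier product-limit estimate
#'
#' @param time,event survival outcome (months, 1 = death).
#' @return list of class `ins_km`: `time`, `surv`, `se` (Greenwood),
#'   `n_risk`, `n_event`, and `surv_at(t)`, a right-continuous step function
#'   with `S(0) = 1`.
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0, na.rm = TRUE)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  sfun <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  structure(list(time = fit$time, surv = fit$surv, se = fit$std.err * fit$surv,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 surv_at = function(t) sfun(t)),
            class = "ins_km")
}

#' @export
print.ins_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier estimate: %d event times, S(max) = %.3f\n",
              length(x$time), min(x$surv)))
  invisible(x)
}

#' Harrell's concordance statistic
#'
#' Probability that, of a usable pair (the shorter follow-up being an
#' observed event), the patient with the higher risk score fails first; tied
#' risks count one half. The point estimate and its infinitesimal-jackknife
#' standard error come from [survival::concordance()]; the 95% CI is normal.
#'
#' @param time,event survival outcome.
#' @param risk per-patient risk score, higher = worse prognosis.
#' @return list with `c`, `se`, `lcl`, `ucl`, `n`, `n_pairs` (usable pairs).
#' @export
harrell_c <- function(time, event, risk) {
  keep <- !(is.na(time) | is.na(event) | is.na(risk))
  time <- time[keep]; event <- event[keep]; risk <- risk[keep]
  if (length(time) < 2L) stop("need at least 2 observations")
  if (sum(event) < 1L) stop("no events: concordance undefined")
  cf <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)
  se <- sqrt(cf$var)
  np <- sum(cf$count[c("concordant", "discordant", "tied.x")])
  list(c = unname(cf$concordance), se = se,
       lcl = unname(cf$concordance - qnorm(0.975) * se),
       ucl = unname(cf$concordance + qnorm(0.975) * se),
       n = length(time), n_pairs = unname(np))
}

#' Paired comparison of two concordance statistics
#'
#' Difference in Harrell's C between two risk scores on the same patients,
#' with a two-sided p-value from a paired nonparametric bootstrap over
#' patients.
#'
#' @param time,event survival outcome.
#' @param risk_a,risk_b the two risk scores (same patients, same order).
#' @param B bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return list with `delta` (`C_b - C_a`), `c_a`, `c_b`, `se`, `lcl`,
#'   `ucl`, `p_value`, `B`.
#' @export
compare_c <- function(time, event, risk_a, risk_b, B = 1000L, seed = 1L) {
  n <- length(time)
  if (length(risk_a) != n || length(risk_b) != n)
    stop("risk_a and risk_b must match the outcome length")
  ca <- harrell_c(time, event, risk_a)$c
  cb <- harrell_c(time, event, risk_b)$c
  delta <- cb - ca
  set.seed(seed)
  boot <- vapply(seq_len(B), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (sum(event[idx]) < 1L) return(NA_real_)
    harrell_c(time[idx], event[idx], risk_b[idx])$c -
      harrell_c(time[idx], event[idx], risk_a[idx])$c
  }, numeric(1))
  boot <- boot[!is.na(boot)]
  se <- sd(boot)
  p <- min(1, 2 * min(mean(boot <= 0), mean(boot >= 0)))
  list(delta = delta, c_a = ca, c_b = cb, se = se,
       lcl = unname(quantile(boot, 0.025)),
       ucl = unname(quantile(boot, 0.975)),
       p_value = p, B = length(boot))
}

# censoring survivor function G via KM of the censoring distribution;
# returns a function g(t, left) with g(t, TRUE) = G(t-)
.cens_surv <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  right <- stats::stepfun(fit$time, c(1, fit$surv), right = FALSE)
  left <- stats::stepfun(fit$time, c(1, fit$surv), right = TRUE)
  function(t, left_limit = FALSE) if (left_limit) left(t) else right(t)
}

# map a risk score to P(event by horizon) through a univariable Cox fit
.cox_event_prob <- function(time, event, risk, horizon) {
  fit <- survival::coxph(survival::Surv(time, event) ~ risk)
  bh <- survival::basehaz(fit, centered = FALSE)
  H0 <- approx(c(0, bh$time), c(0, bh$hazard), xout = horizon,
               method = "constant", rule = 2)$y
  1 - exp(-H0 * exp(coef(fit) * risk))
}

# IPCW weights and event status at a horizon: events by t* weighted by
# 1/G(T-), known survivors by 1/G(t*), censored-before-horizon weight 0
.ipcw_status <- function(time, event, horizon) {
  g <- .cens_surv(time, event)
  is_event <- event == 1 & time <= horizon
  is_ctrl <- time > horizon
  w <- numeric(length(time))
  w[is_event] <- 1 / g(time[is_event], left_limit = TRUE)
  w[is_ctrl] <- 1 / g(horizon)
  list(is_event = is_event, is_ctrl = is_ctrl, w = w)
}

#' Continuous NRI and IDI at a horizon under censoring
#'
#' Maps each risk score to a predicted event probability at the horizon
#' (by default through a univariable Cox fit and its baseline hazard), then
#' computes the continuous net reclassification improvement and the
#' integrated discrimination improvement with event/non-event status at the
#' horizon weighted by inverse probability of censoring (Kaplan-Meier of the
#' censoring distribution). With no censoring before the horizon the
#' estimator reduces exactly to the textbook binary-outcome forms.
#'
#' @param time,event survival outcome.
#' @param risk_old,risk_new risk scores of the two models being compared.
#' @param horizon evaluation horizon t* (months); default 36.
#' @param prob_map `"cox"` to map risks to probabilities through a Cox
#'   baseline at the horizon, or `"identity"` when the inputs already are
#'   event probabilities in `[0, 1]`.
#' @param B bootstrap replicates for the CIs (0 skips them).
#' @param seed RNG seed for the bootstrap.
#' @return list with `cnri`, `idi`, their `lcl`/`ucl` (when `B > 0`),
#'   `horizon`, `prob_map`, `n_events`, `n_controls`.
#' @export
cnri_idi <- function(time, event, risk_old, risk_new, horizon = 36,
                     prob_map = c("cox", "identity"), B = 1000L, seed = 1L) {
  prob_map <- match.arg(prob_map)
  if (horizon > max(time)) stop("horizon beyond last observed time")
  point <- .cnri_idi_once(time, event, risk_old, risk_new, horizon, prob_map)
  if (point$n_events == 0L) stop("no events by the horizon")
  out <- point[c("cnri", "idi", "n_events", "n_controls")]
  out$horizon <- horizon
  out$prob_map <- prob_map
  if (B > 0L) {
    set.seed(seed)
    n <- length(time)
    boot <- t(vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      r <- try(.cnri_idi_once(time[idx], event[idx], risk_old[idx],
                              risk_new[idx], horizon, prob_map),
               silent = TRUE)
      if (inherits(r, "try-error") || r$n_events == 0L)
        return(c(NA_real_, NA_real_))
      c(r$cnri, r$idi)
    }, numeric(2)))
    out$cnri_lcl <- unname(quantile(boot[, 1], 0.025, na.rm = TRUE))
    out$cnri_ucl <- unname(quantile(boot[, 1], 0.975, na.rm = TRUE))
    out$idi_lcl <- unname(quantile(boot[, 2], 0.025, na.rm = TRUE))
    out$idi_ucl <- unname(quantile(boot[, 2], 0.975, na.rm = TRUE))
  }
  out
}

.cnri_idi_once <- function(time, event, risk_old, risk_new, horizon,
                           prob_map) {
  p_old <- switch(prob_map,
                  cox = .cox_event_prob(time, event, risk_old, horizon),
                  identity = risk_old)
  p_new <- switch(prob_map,
                  cox = .cox_event_prob(time, event, risk_new, horizon),
                  identity = risk_new)
  st <- .ipcw_status(time, event, horizon)
  we <- st$w[st$is_event]; wc <- st$w[st$is_ctrl]
  up <- p_new > p_old; down <- p_new < p_old
  pe <- function(ind) if (sum(we) > 0) sum(we * ind[st$is_event]) / sum(we) else 0
  pc <- function(ind) if (sum(wc) > 0) sum(wc * ind[st$is_ctrl]) / sum(wc) else 0
  cnri <- (pe(up) - pe(down)) + (pc(down) - pc(up))
  dd <- p_new - p_old
  idi <- (if (sum(we) > 0) weighted.mean(dd[st$is_event], we) else 0) -
    (if (sum(wc) > 0) weighted.mean(dd[st$is_ctrl], wc) else 0)
  list(cnri = cnri, idi = idi,
       n_events = sum(st$is_event), n_controls = sum(st$is_ctrl))
}

#' Time-dependent AUC with IPCW
#'
#' Cumulative-case / dynamic-control AUC at time `t`: the probability that a
#' patient with an event by `t` carries a higher risk score than one still
#' event-free past `t`, with cases weighted by `1/G(T-)` and controls by
#' `1/G(t)` (inverse probability of censoring). Tied risks count one half.
#' Without censoring before `t` this is the plain rank AUC of cases versus
#' controls at `t`.
#'
#' @param time,event survival outcome.
#' @param risk risk score, higher = worse.
#' @param t evaluation time(s).
#' @return named numeric vector `AUC(t)`, one entry per `t`.
#' @export
time_dependent_auc <- function(time, event, risk, t) {
  vapply(t, function(tt) {
    st <- .ipcw_status(time, event, tt)
    if (!any(st$is_event)) stop("no cases at t = ", tt)
    if (!any(st$is_ctrl)) stop("no controls at t = ", tt)
    rc <- risk[st$is_event]; wc <- st$w[st$is_event]
    rk <- risk[st$is_ctrl]; wk <- st$w[st$is_ctrl]
    cmp <- outer(rc, rk, function(a, b) (a > b) + 0.5 * (a == b))
    sum((wc %o% wk) * cmp) / (sum(wc) * sum(wk))
  }, numeric(1), USE.NAMES = FALSE) -> auc
  setNames(auc, paste0("t=", t))
}

#' Cox proportional hazards model with per-stratum HRs and trend test
#'
#' Fits the partial likelihood through [survival::coxph()]. A categorical
#' exposure is modelled against its first level (reference); the p-for-trend
#' refits the model with the exposure entered as a single continuous ordinal
#' term. `adjust = "model_a"` is unadjusted; `adjust = "model_b"` adds the
#' standard adjustment set (age, sex, BMI, TNM stage, tumor type, surgery,
#' radiotherapy, chemotherapy, hypertension, diabetes, smoking, drinking,
#' family history), restricted to columns present and non-constant.
#'
#' @param data data.frame with `os_time`, `event`, the exposure column, and
#'   any adjustment columns.
#' @param exposure name of the exposure column. Factors/characters are
#'   treated as categorical with the first level as reference; numeric
#'   exposures enter linearly.
#' @param adjust `"model_a"` (none) or `"model_b"`; or a character vector of
#'   column names for a custom adjustment set.
#' @return list of class `ins_coxfit`: `hr_table` (term, hr, lcl, ucl, p),
#'   `p_trend` (`NA` for a numeric exposure, whose own p is the trend),
#'   `n`, `n_events`, `fit`.
#' @export
cox_model <- function(data, exposure, adjust = "model_a") {
  stopifnot(all(c("os_time", "event", exposure) %in% names(data)))
  x <- data[[exposure]]
  if (length(unique(x[!is.na(x)])) < 2L) stop("constant exposure")
  model_b_set <- c("age", "sex", "bmi", "tnm_stage", "tumor_type", "surgery",
                   "radiotherapy", "chemotherapy", "hypertension", "diabetes",
                   "smoking", "drinking", "family_history")
  covars <- if (identical(adjust, "model_a")) character(0)
  else if (identical(adjust, "model_b")) model_b_set
  else adjust
  covars <- covars[covars %in% names(data)]
  covars <- covars[vapply(covars, function(v)
    length(unique(data[[v]][!is.na(data[[v]])])) > 1L, logical(1))]

  categorical <- is.factor(x) || is.character(x)
  d <- data
  if (categorical) d[[exposure]] <- factor(x)
  rhs <- paste(c(sprintf("`%s`", exposure),
                 sprintf("`%s`", covars)), collapse = " + ")
  fml <- as.formula(paste("survival::Surv(os_time, event) ~", rhs))
  fit <- survival::coxph(fml, data = d)
  if (any(abs(coef(fit)) > 15, na.rm = TRUE))
    stop("monotone likelihood / separation suspected: |log HR| > 15 for ",
         paste(names(coef(fit))[abs(coef(fit)) > 15], collapse = ", "))
  npar <- length(coef(fit))
  nev <- fit$nevent
  if (nev < 10 * npar)
    warning(sprintf("only %d events for %d parameters (< 10 per parameter)",
                    nev, npar))
  sm <- summary(fit)
  keep <- grepl(sprintf("^`?%s`?", exposure), rownames(sm$coefficients))
  hr_table <- data.frame(
    term = rownames(sm$coefficients)[keep],
    hr = sm$conf.int[keep, "exp(coef)"],
    lcl = sm$conf.int[keep, "lower .95"],
    ucl = sm$conf.int[keep, "upper .95"],
    p = sm$coefficients[keep, "Pr(>|z|)"],
    row.names = NULL, stringsAsFactors = FALSE)

  p_trend <- NA_real_
  if (categorical) {
    d$.trend <- as.numeric(factor(x, levels = levels(factor(x))))
    rhs_t <- paste(c(".trend", sprintf("`%s`", covars)), collapse = " + ")
    fit_t <- survival::coxph(
      as.formula(paste("survival::Surv(os_time, event) ~", rhs_t)), data = d)
    p_trend <- summary(fit_t)$coefficients[".trend", "Pr(>|z|)"]
  } else {
    p_trend <- hr_table$p[1]
  }
  structure(list(hr_table = hr_table, p_trend = p_trend,
                 n = fit$n, n_events = nev, adjust = adjust, fit = fit),
            class = "ins_coxfit")
}

#' @export
print.ins_coxfit <- function(x, ...) {
  cat(sprintf("Cox model (%s): n = %d, events = %d\n",
              paste(x$adjust, collapse = "+"), x$n, x$n_events))
  tab <- x$hr_table
  tab$hr <- sprintf("%.3f (%.3f-%.3f)", tab$hr, tab$lcl, tab$ucl)
  print(tab[, c("term", "hr", "p")], row.names = FALSE)
  cat(sprintf("P for trend: %.3g\n", x$p_trend))
  invisible(x)
}

#' Restricted cubic spline basis
#'
#' Truncated-power restricted cubic spline basis with linear tails
#' (Harrell's parameterization, normalized by the squared knot span):
#' `k` knots give `k - 1` columns, the first being `x` itself.
#'
#' @param x numeric vector.
#' @param knots knot locations (ascending).
#' @return matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  knots <- sort(knots)
  k <- length(knots)
  stopifnot(k >= 3L)
  tk <- knots[k]; tk1 <- knots[k - 1]
  norm <- (knots[k] - knots[1])^2
  cub <- function(u) pmax(u, 0)^3
  cols <- lapply(seq_len(k - 2L), function(j) {
    tj <- knots[j]
    (cub(x - tj) - cub(x - tk1) * (tk - tj) / (tk - tk1) +
       cub(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  })
  out <- cbind(x, do.call(cbind, cols))
  colnames(out) <- c("lin", paste0("nl", seq_len(k - 2L)))
  out
}

#' Restricted cubic spline dose-response for survival
#'
#' Fits a Cox model on a 3-knot (default) restricted cubic spline of the
#' biomarker; the nonlinearity p-value is the Wald test of the nonlinear
#' term(s), and the hazard-ratio curve is referenced to the median of `x`.
#'
#' @param x biomarker vector.
#' @param time,event survival outcome.
#' @param knots either knot locations or quantile levels in (0,1); default
#'   quantiles 0.10, 0.50, 0.90.
#' @param grid_n points on the returned curve.
#' @return list of class `ins_rcs`: `curve` (data.frame x, loghr, hr, lcl,
#'   ucl), `p_nonlinear`, `p_overall`, `knots`, `fit`.
#' @export
rcs_dose_response <- function(x, time, event, knots = c(0.10, 0.50, 0.90),
                              grid_n = 100L) {
  keep <- !(is.na(x) | is.na(time) | is.na(event))
  x <- x[keep]; time <- time[keep]; event <- event[keep]
  if (length(unique(x)) < 3L) stop("need at least 3 distinct x values")
  if (all(knots > 0 & knots < 1)) knots <- quantile(x, knots, names = FALSE)
  knots <- sort(unique(knots))
  if (length(knots) < 3L) stop("knots collapsed: fewer than 3 distinct")
  X <- rcs_basis(x, knots)
  fit <- survival::coxph(survival::Surv(time, event) ~ X)
  beta <- coef(fit); V <- vcov(fit)
  nl <- grep("nl", names(beta))
  w <- t(beta[nl]) %*% solve(V[nl, nl, drop = FALSE]) %*% beta[nl]
  p_nonlinear <- pchisq(drop(w), df = length(nl), lower.tail = FALSE)
  w_all <- t(beta) %*% solve(V) %*% beta
  p_overall <- pchisq(drop(w_all), df = length(beta), lower.tail = FALSE)

  gx <- seq(min(x), max(x), length.out = grid_n)
  ref <- median(x)
  D <- rcs_basis(gx, knots) -
    matrix(rcs_basis(rep(ref, grid_n), knots), grid_n, ncol(X))
  loghr <- drop(D %*% beta)
  se <- sqrt(pmax(0, rowSums((D %*% V) * D)))
  curve <- data.frame(x = gx, loghr = loghr, hr = exp(loghr),
                      lcl = exp(loghr - qnorm(0.975) * se),
                      ucl = exp(loghr + qnorm(0.975) * se))
  structure(list(curve = curve, p_nonlinear = p_nonlinear,
                 p_overall = p_overall, knots = knots, fit = fit),
            class = "ins_rcs")
}

#' Screen biomarkers: univariable C, Pearson collinearity, LASSO Cox
#'
#' Ranks every panel column by the concordance of its univariable Cox linear
#' predictor (so the direction of effect does not matter), reports the
#' pairwise Pearson correlation matrix, and retains the set selected by an
#' L1-penalized Cox fit with seeded cross-validation ([glmnet::cv.glmnet()],
#' `lambda.min`).
#'
#' @param panel an `ins_panel` or data.frame of biomarker columns (a
#'   `patient_id` column is ignored).
#' @param time,event survival outcome, aligned with the panel rows.
#' @param seed RNG seed for the cross-validation folds.
#' @param nfolds CV folds for the LASSO stage.
#' @return list of class `ins_screen`: `c_table` (index, group, c, lcl, ucl,
#'   n; sorted by C descending), `cor_matrix`, `lasso_retained`, `seed`.
#' @export
screen_biomarkers <- function(panel, time, event, seed = 1L, nfolds = 10L) {
  d <- as.data.frame(panel)
  d$patient_id <- NULL
  keep_col <- vapply(d, function(col) !all(is.na(col)), logical(1))
  if (any(!keep_col))
    warning("all-missing biomarker column(s) excluded: ",
            paste(names(d)[!keep_col], collapse = ", "))
  d <- d[keep_col]
  if (ncol(d) < 2L) stop("need at least 2 usable biomarkers")
  if (sum(event, na.rm = TRUE) < 20L) stop("need at least 20 events")
  groups <- attr(panel, "groups")
  if (is.null(groups))
    groups <- setNames(rep(NA_character_, ncol(d)), names(d))

  rows <- lapply(names(d), function(nm) {
    ok <- !(is.na(d[[nm]]) | is.na(time) | is.na(event))
    fit <- survival::coxph(survival::Surv(time[ok], event[ok]) ~ d[[nm]][ok])
    cc <- harrell_c(time[ok], event[ok],
                    drop(predict(fit, type = "lp")))
    data.frame(index = nm, group = unname(groups[nm]), c = cc$c,
               lcl = cc$lcl, ucl = cc$ucl, n = cc$n,
               stringsAsFactors = FALSE)
  })
  c_table <- do.call(rbind, rows)
  # stable sort: ties keep registry (input) order
  c_table <- c_table[order(-c_table$c), , drop = FALSE]
  rownames(c_table) <- NULL

  cm <- cor(as.matrix(d), use = "pairwise.complete.obs", method = "pearson")

  cc_rows <- stats::complete.cases(d) & !is.na(time) & !is.na(event)
  Xm <- as.matrix(d[cc_rows, , drop = FALSE])
  retained <- character(0)
  if (sum(event[cc_rows]) >= 2L && nrow(Xm) > nfolds) {
    set.seed(seed)
    cv <- glmnet::cv.glmnet(Xm, survival::Surv(time[cc_rows], event[cc_rows]),
                            family = "cox", nfolds = nfolds)
    b <- coef(cv, s = "lambda.min")
    retained <- rownames(b)[as.vector(b != 0)]
  }
  structure(list(c_table = c_table, cor_matrix = cm,
                 lasso_retained = retained, seed = seed),
            class = "ins_screen")
}

#' Select the top two biomarkers per group
#'
#' Picks the two highest-concordance indices from the inflammation group and
#' from the nutrition group. Exact C ties are broken by registry order (the
#' order of [index_registry()]), with a warning.
#'
#' @param c_table a ranked table as produced by [screen_biomarkers()], with
#'   columns `index`, `group`, `c`.
#' @return character vector of 4 index names (inflammation pair first).
#' @export
select_top2_per_group <- function(c_table) {
  reg <- index_registry()
  sel <- function(gr) {
    tab <- c_table[c_table$group == gr & !is.na(c_table$c), , drop = FALSE]
    if (nrow(tab) < 2L) stop("fewer than 2 usable biomarkers in group ", gr)
    ord <- order(-tab$c, match(tab$index, reg$index))
    tab <- tab[ord, , drop = FALSE]
    if (nrow(tab) > 2L && any(duplicated(tab$c[seq_len(3L)])))
      warning("C-statistic tie in group ", gr, "; registry order used")
    tab$index[1:2]
  }
  c(sel("inflammation"), sel("nutrition"))
}

#' Randomized internal split
#'
#' Disjoint, exhaustive partition of a cohort with `round(ratio * n)`
#' records in the first part, seeded and reproducible.
#'
#' @param cohort an `ins_cohort` (or data.frame).
#' @param ratio fraction in the first part; default 0.7.
#' @param seed RNG seed.
#' @return list with elements `a` and `b`.
#' @export
random_split <- function(cohort, ratio = 0.7, seed = 1L) {
  n <- nrow(cohort)
  if (n < 10L) stop("need at least 10 records to split")
  stopifnot(ratio > 0, ratio < 1)
  set.seed(seed)
  na <- round(ratio * n)
  idx <- sample.int(n, na)
  prov <- attr(cohort, "provenance")
  a <- cohort[sort(idx), , drop = FALSE]
  b <- cohort[sort(setdiff(seq_len(n), idx)), , drop = FALSE]
  if (inherits(cohort, "ins_cohort")) {
    a <- as_cohort(as.data.frame(a), provenance = paste0(prov, "#split-a"))
    b <- as_cohort(as.data.frame(b), provenance = paste0(prov, "#split-b"))
  }
  list(a = a, b = b)
}
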