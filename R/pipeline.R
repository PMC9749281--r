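# End-to-end pipeline: ingest or simulate -> panel -> screen -> cutpoints ->
# score -> evaluate -> split-validate, with a reproducible run manifest.
#
# One run-level seed is fanned out to per-stage seeds by fixed offsets so
# stages stay reproducible independently of each other.

.stage_seeds <- function(seed) {
  list(simulate = seed, screen = seed + 101L, cutpoint = seed + 211L,
       boot = seed + 307L, split = seed + 401L)
}

# polynomial rolling hash over a JSON serialization, for config fingerprints
.fingerprint <- function(x) {
  bytes <- utf8ToInt(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                      force = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2^31
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' @param input either `list(csv = path, schema = cohort_schema())` to read
#'   a cohort, or `list(simulate = sim_config())` to generate one.
#' @param seed run-level seed; per-stage seeds are derived by fixed offsets.
#' @param horizon evaluation horizon in months for cNRI/IDI and AUC(t).
#' @param derive_cutpoints if `TRUE`, screen the panel, select the top two
#'   indices per group, and derive their optimal cutpoints from the data; if
#'   `FALSE`, score with `score_config` as shipped.
#' @param score_config the [ins_config()] used when `derive_cutpoints` is
#'   `FALSE` (default [ins2022_config()]).
#' @param split_ratio internal validation split ratio.
#' @param n_boot bootstrap replicates for CIs inside the evaluation stage
#'   (kept moderate by default; raise for publication-grade intervals).
#' @param out_dir optional directory: intermediate artifacts (cohort, panel,
#'   scores, report JSON, manifest JSON) are written there.
#' @return list of class `ins_pipeline_config`.
#' @export
pipeline_config <- function(input, seed = 1L, horizon = 36,
                            derive_cutpoints = TRUE,
                            score_config = ins2022_config(),
                            split_ratio = 0.7, n_boot = 200L,
                            out_dir = NULL) {
  stopifnot(is.list(input),
            !is.null(input$csv) || !is.null(input$simulate))
  structure(list(input = input, seed = as.integer(seed), horizon = horizon,
                 derive_cutpoints = derive_cutpoints,
                 score_config = score_config, split_ratio = split_ratio,
                 n_boot = as.integer(n_boot), out_dir = out_dir),
            class = "ins_pipeline_config")
}

#' Run the full INS pipeline
#'
#' Executes the stages in order, halting with a stage-named error on any
#' failure: validate, panel, screen (univariable C + Pearson + LASSO),
#' top-2-per-group selection and optimal cutpoints (when
#' `derive_cutpoints`), scoring, evaluation (KM by stratum, Cox models a/b
#' with trend test, C-statistic of the score vs each component, cNRI/IDI and
#' AUC at the horizon), and the randomized internal split with per-part Cox
#' refits.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress stage progress messages.
#' @return list of class `ins_run`: `report` (evaluation results), `scored`,
#'   `screen`, `cutpoints`, `config_used` (the scoring configuration applied),
#'   `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "ins_pipeline_config"))
  seeds <- .stage_seeds(config$seed)
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  note <- function(stage) {
    timings[stage] <<- round(proc.time()[["elapsed"]] - t0, 2)
    t0 <<- proc.time()[["elapsed"]]
    if (!quiet) message("[", stage, "] done (", timings[stage], "s)")
  }
  stage <- function(name, expr) {
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
    note(name); r
  }

  cohort <- stage("input", {
    if (!is.null(config$input$csv)) {
      sch <- config$input$schema
      if (is.null(sch)) sch <- cohort_schema()
      read_cohort(config$input$csv, sch)
    } else {
      sc <- config$input$simulate
      if (!inherits(sc, "ins_simconfig")) sc <- do.call(sim_config, sc)
      sc$seed <- seeds$simulate
      simulate_cohort(sc)$cohort
    }
  })
  vrep <- stage("validate", {
    r <- validate_cohort(cohort)
    if (r$n_eligible == 0L) stop("no eligible records (all INS inputs or outcomes missing)")
    r
  })
  panel <- stage("panel", compute_panel(cohort))

  screen <- NULL; cuts <- NULL
  cfg_used <- config$score_config
  if (config$derive_cutpoints) {
    screen <- stage("screen",
                    screen_biomarkers(panel, cohort$os_time, cohort$event,
                                      seed = seeds$screen))
    cuts <- stage("cutpoints", {
      top4 <- select_top2_per_group(screen$c_table)
      lapply(setNames(top4, top4), function(nm)
        optimal_cutpoint(panel[[nm]], cohort$os_time, cohort$event))
    })
    cfg_used <- ins_config(lapply(names(cuts), function(nm)
      list(index = nm, threshold = cuts[[nm]]$threshold,
           direction = cuts[[nm]]$direction)),
      name = "derived")
  }

  scored <- stage("score", score_cohort(cohort, cfg_used))
  report <- stage("evaluate",
                  .evaluate_scored(cohort, panel, scored, cfg_used,
                                   horizon = config$horizon,
                                   B = config$n_boot, seed = seeds$boot))
  split <- stage("split_validate", {
    parts <- random_split(cohort, config$split_ratio, seed = seeds$split)
    lapply(parts, function(part) {
      sc <- score_cohort(part, cfg_used)
      d <- cbind(as.data.frame(part),
                 stratum = factor(sc$scores$stratum, levels = 1:(cfg_used$k + 1)))
      d <- d[!is.na(d$stratum) & table(d$stratum)[d$stratum] > 0, ]
      d$stratum <- droplevels(d$stratum)
      fit <- cox_model(d, "stratum", adjust = "model_b")
      list(n = nrow(d), hr_table = fit$hr_table, p_trend = fit$p_trend)
    })
  })

  manifest <- list(tool = "insmark",
                   version = as.character(packageVersion("insmark")),
                   seed = config$seed,
                   stage_seeds = seeds,
                   config_hash = .fingerprint(list(
                     horizon = config$horizon,
                     derive = config$derive_cutpoints,
                     ratio = config$split_ratio, n_boot = config$n_boot)),
                   input_fingerprint = attr(cohort, "provenance"),
                   n = nrow(cohort), n_eligible = vrep$n_eligible,
                   timings = as.list(timings),
                   outputs = character(0))
  run <- structure(list(report = report, scored = scored, screen = screen,
                        cutpoints = cuts, config_used = cfg_used,
                        split = split, validation = vrep,
                        manifest = manifest, cohort = cohort, panel = panel),
                   class = "ins_run")
  if (!is.null(config$out_dir)) run <- .write_run(run, config$out_dir)
  run
}

# the evaluation battery applied to a scored cohort
.evaluate_scored <- function(cohort, panel, scored, cfg, horizon, B, seed) {
  elig <- !is.na(scored$scores$stratum)
  d <- as.data.frame(cohort)[elig, , drop = FALSE]
  score <- scored$scores$raw_score[elig]
  stratum <- scored$scores$stratum[elig]

  km_by <- lapply(split(seq_along(stratum), stratum), function(idx)
    km_estimate(d$os_time[idx], d$event[idx]))
  death_prop <- vapply(split(d$event, stratum), mean, numeric(1))

  dd <- d
  dd$stratum <- factor(stratum)
  model_a <- cox_model(dd, "stratum", adjust = "model_a")
  model_b <- cox_model(dd, "stratum", adjust = "model_b")

  c_ins <- harrell_c(d$os_time, d$event, score)
  comp_names <- vapply(cfg$components, `[[`, "", "index")
  comparisons <- lapply(setNames(comp_names, comp_names), function(nm) {
    v <- panel[[nm]][elig]
    ok <- !is.na(v)
    fit <- survival::coxph(survival::Surv(d$os_time[ok], d$event[ok]) ~ v[ok])
    risk <- drop(predict(fit, type = "lp"))
    cc <- compare_c(d$os_time[ok], d$event[ok], risk, score[ok],
                    B = B, seed = seed)
    ni <- cnri_idi(d$os_time[ok], d$event[ok], risk, score[ok],
                   horizon = horizon, B = B, seed = seed)
    list(c_component = cc$c_a, delta_c = cc$delta, delta_c_p = cc$p_value,
         cnri = ni$cnri, cnri_ci = c(ni$cnri_lcl, ni$cnri_ucl),
         idi = ni$idi, idi_ci = c(ni$idi_lcl, ni$idi_ucl))
  })
  auc <- time_dependent_auc(d$os_time, d$event, score,
                            t = horizon)
  list(n = nrow(d), horizon = horizon, estimator = "IPCW at fixed horizon",
       death_prop_by_stratum = death_prop,
       km_by_stratum = km_by,
       cox_model_a = model_a, cox_model_b = model_b,
       c_ins = c_ins, component_comparisons = comparisons,
       auc_horizon = auc, seed = seed, n_boot = B)
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(cohort = file.path(out_dir, "cohort.csv"),
             scores = file.path(out_dir, "scores.csv"),
             report = file.path(out_dir, "report.json"),
             manifest = file.path(out_dir, "manifest.json"))
  write_cohort(run$cohort, paths["cohort"])
  write.csv(run$scored$scores, paths["scores"], row.names = FALSE)
  rep <- run$report
  rep$km_by_stratum <- NULL
  rep$cox_model_a <- rep$cox_model_a[c("hr_table", "p_trend")]
  rep$cox_model_b <- rep$cox_model_b[c("hr_table", "p_trend")]
  writeLines(jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA,
                              force = TRUE), paths["report"])
  run$manifest$outputs <- unname(paths)
  writeLines(jsonlite::toJSON(run$manifest, auto_unbox = TRUE, digits = NA,
                              force = TRUE), paths["manifest"])
  run
}

#' @export
print.ins_run <- function(x, ...) {
  cat("INS pipeline run (seed ", x$manifest$seed, ")\n", sep = "")
  cat("  n =", x$report$n, "eligible, configuration:", x$config_used$name, "\n")
  cat("  deaths by stratum:",
      paste(sprintf("%.1f%%", 100 * x$report$death_prop_by_stratum),
            collapse = " "), "\n")
  cat(sprintf("  C (INS) = %.3f (%.3f-%.3f); AUC(%g) = %.3f\n",
              x$report$c_ins$c, x$report$c_ins$lcl, x$report$c_ins$ucl,
              x$report$horizon, x$report$auc_horizon))
  cat(sprintf("  Cox model b, p-for-trend %.3g\n", x$report$cox_model_b$p_trend))
  invisible(x)
}
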