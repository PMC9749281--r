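# The 15 inflammation / nutrition indices.
#
# All formulas consume canonical units (counts x10^9/L, albumin g/L,
# CRP mg/L, glucose/cholesterol mmol/L) and rescale internally where a
# published formula is defined on another scale. Every formula lives in one
# registry keyed by index name, so a definitional correction touches the
# table, not scattered code paths.

#' Ideal body weight (Lorentz)
#'
#' Lorentz convention used by the NRI/GNRI family for the weight ratio:
#' males `height - 100 - (height - 150)/4`, females
#' `height - 100 - (height - 150)/2.5`, height in cm.
#'
#' @param height height in cm, positive.
#' @param sex `"male"` or `"female"` (recycled).
#' @return ideal weight in kg.
#' @examples
#' ideal_weight(170, "male")    # 65
#' ideal_weight(160, "female")  # 56
#' @export
ideal_weight <- function(height, sex) {
  if (any(!is.na(height) & height <= 0)) stop("height must be positive")
  sex <- rep_len(tolower(sex), length(height))
  if (any(!sex %in% c("male", "female"), na.rm = TRUE))
    stop("sex must be 'male' or 'female'")
  ifelse(sex == "male",
         height - 100 - (height - 150) / 4,
         height - 100 - (height - 150) / 2.5)
}

# CONUT subscores (original published scoring table):
#   albumin g/dL:      >=3.5 -> 0 | 3.0-3.49 -> 2 | 2.5-2.99 -> 4 | <2.5 -> 6
#   lymphocytes /uL:   >=1600 -> 0 | 1200-1599 -> 1 | 800-1199 -> 2 | <800 -> 3
#   cholesterol mg/dL: >180 -> 0 | 140-180 -> 1 | 100-139 -> 2 | <100 -> 3
.conut <- function(albumin, lymphocytes, cholesterol) {
  alb_dl <- albumin / 10
  lym_ul <- lymphocytes * 1000
  chol_mg <- cholesterol * 38.67
  a <- ifelse(alb_dl >= 3.5, 0, ifelse(alb_dl >= 3.0, 2,
       ifelse(alb_dl >= 2.5, 4, 6)))
  l <- ifelse(lym_ul >= 1600, 0, ifelse(lym_ul >= 1200, 1,
       ifelse(lym_ul >= 800, 2, 3)))
  c <- ifelse(chol_mg > 180, 0, ifelse(chol_mg >= 140, 1,
       ifelse(chol_mg >= 100, 2, 3)))
  a + l + c
}

# registry: name, group tag, formula on a canonical-unit data.frame.
# opts carries the configurable conventions (LCS cutoffs, mGPS thresholds).
.index_registry <- list(
  LCR = list(group = "inflammation", fun = function(d, o)
    (d$lymphocytes * 1000) / (d$crp / 10)),          # lymph /uL over CRP mg/dL
  CAR = list(group = "inflammation", fun = function(d, o)
    d$crp / d$albumin),
  NLR = list(group = "inflammation", fun = function(d, o)
    d$neutrophils / d$lymphocytes),
  SII = list(group = "inflammation", fun = function(d, o)
    d$platelets * d$neutrophils / d$lymphocytes),
  PLR = list(group = "inflammation", fun = function(d, o)
    d$platelets / d$lymphocytes),
  GLR = list(group = "inflammation", fun = function(d, o)
    d$glucose / d$lymphocytes),
  LCS = list(group = "inflammation", fun = function(d, o)
    (d$lymphocytes < o$lcs_lymph_cut) + (d$crp >= o$lcs_crp_cut)),
  mGNRI = list(group = "inflammation", fun = function(d, o)
    14.89 / (d$crp / 10) +
      41.7 * pmin(1, d$weight / ideal_weight(d$height, d$sex))),
  mGPS = list(group = "inflammation", fun = function(d, o)
    ifelse(d$crp > o$mgps_crp_cut & d$albumin < o$mgps_alb_cut, 2,
           ifelse(d$crp > o$mgps_crp_cut, 1, 0))),
  ALI = list(group = "nutrition", fun = function(d, o)
    d$bmi * (d$albumin / 10) / (d$neutrophils / d$lymphocytes)),
  PNI = list(group = "nutrition", fun = function(d, o)
    10 * (d$albumin / 10) + 0.005 * (d$lymphocytes * 1000)),
  NRI = list(group = "nutrition", fun = function(d, o)
    1.519 * d$albumin +
      41.7 * pmin(1, d$weight / ideal_weight(d$height, d$sex))),
  GNRI = list(group = "nutrition", fun = function(d, o)
    1.489 * d$albumin +
      41.7 * pmin(1, d$weight / ideal_weight(d$height, d$sex))),
  AGR = list(group = "nutrition", fun = function(d, o)
    d$albumin / (d$total_protein - d$albumin)),
  CONUT = list(group = "nutrition", fun = function(d, o)
    .conut(d$albumin, d$lymphocytes, d$cholesterol))
)

#' Names and group tags of the 15 indices
#'
#' @return data.frame with columns `index` and `group`
#'   (`"inflammation"` or `"nutrition"`), in registry order. Registry order
#'   is the declared tie-break order for top-2 selection.
#' @export
index_registry <- function() {
  data.frame(index = names(.index_registry),
             group = vapply(.index_registry, `[[`, "", "group"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default convention options for configurable indices
#'
#' LCS counts one point for lymphopenia and one for elevated CRP; mGPS uses
#' the standard CRP 10 mg/L and albumin 35 g/L thresholds.
#'
#' @param lcs_lymph_cut lymphocyte cutoff, x10^9/L (point when below).
#' @param lcs_crp_cut CRP cutoff, mg/L (point when at/above).
#' @param mgps_crp_cut mGPS CRP threshold, mg/L.
#' @param mgps_alb_cut mGPS albumin threshold, g/L.
#' @export
index_options <- function(lcs_lymph_cut = 1.0, lcs_crp_cut = 10,
                          mgps_crp_cut = 10, mgps_alb_cut = 35) {
  list(lcs_lymph_cut = lcs_lymph_cut, lcs_crp_cut = lcs_crp_cut,
       mgps_crp_cut = mgps_crp_cut, mgps_alb_cut = mgps_alb_cut)
}

#' Compute one index for one or more patients
#'
#' Missing inputs and zero denominators propagate as `NA` (with a message
#' for zero denominators), never as errors: AGR and CONUT depend on optional
#' labs and must degrade gracefully.
#'
#' @param record a one-row (or multi-row) canonical-unit data.frame, e.g. a
#'   cohort or a cohort subset.
#' @param index_name one of the 15 registry names.
#' @param opts convention options, see [index_options()].
#' @return numeric vector of index values, `NA` where not computable.
#' @examples
#' r <- data.frame(sex = "male", height = 170, weight = 65, bmi = 22.5,
#'                 neutrophils = 4.2, lymphocytes = 1.4, platelets = 250,
#'                 albumin = 40, crp = 8, glucose = 5.5,
#'                 total_protein = 70, cholesterol = 4.5)
#' compute_index(r, "NLR")  # 3
#' @export
compute_index <- function(record, index_name, opts = index_options()) {
  entry <- .index_registry[[index_name]]
  if (is.null(entry))
    stop("unknown index '", index_name, "'; see index_registry()")
  d <- as.data.frame(record)
  if (!"bmi" %in% names(d) && all(c("weight", "height") %in% names(d)))
    d$bmi <- d$weight / (d$height / 100)^2
  for (f in c(.canonical_labs, "sex", "height", "weight", "bmi"))
    if (!f %in% names(d)) d[[f]] <- NA
  v <- suppressWarnings(entry$fun(d, opts))
  nonfinite <- !is.finite(v) & !is.na(v)
  if (any(nonfinite, na.rm = TRUE))
    message(index_name, ": zero denominator in ", sum(nonfinite),
            " record(s); value set to NA")
  v[!is.finite(v)] <- NA_real_
  as.numeric(v)
}

#' Compute the full 15-index biomarker panel for a cohort
#'
#' @param cohort an `ins_cohort` (or any canonical-unit data.frame with a
#'   `patient_id` column).
#' @inheritParams compute_index
#' @return A data.frame of class `ins_panel`: `patient_id` plus one column
#'   per index, `NA` per cell where inputs are missing. Attribute `groups`
#'   carries the inflammation/nutrition tag per index.
#' @export
compute_panel <- function(cohort, opts = index_options()) {
  d <- as.data.frame(cohort)
  stopifnot("patient_id" %in% names(d))
  out <- data.frame(patient_id = d$patient_id, stringsAsFactors = FALSE)
  for (nm in names(.index_registry))
    out[[nm]] <- compute_index(d, nm, opts)
  structure(out, class = c("ins_panel", "data.frame"),
            groups = setNames(vapply(.index_registry, `[[`, "", "group"),
                              names(.index_registry)))
}
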