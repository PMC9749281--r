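# The INS: count of adverse dichotomized components, plus one.
#
# The shipped default ("INS-2022") is the four-component instance with the
# published thresholds: low LCR (< 2813), high CAR (>= 0.165), low ALI
# (< 33), low NRI (< 94). The scorer itself is generic in k.

#' INS component configuration
#'
#' @param components list of components, each a list with `index`
#'   (registry name), `threshold` (finite numeric) and `direction`
#'   (`"below"`: adverse when value < threshold, strict; `"at_or_above"`:
#'   adverse when value >= threshold).
#' @param name label recorded in outputs.
#' @return object of class `ins_config`.
#' @seealso [ins2022_config()] for the shipped default.
#' @export
ins_config <- function(components, name = "custom") {
  stopifnot(is.list(components), length(components) >= 1L)
  for (cmp in components) {
    stopifnot(is.character(cmp$index),
              is.finite(cmp$threshold),
              cmp$direction %in% c("below", "at_or_above"))
  }
  structure(list(components = components, name = name,
                 k = length(components)),
            class = "ins_config")
}

#' The shipped INS-2022 configuration
#'
#' Four components dichotomized at the published cutpoints: LCR < 2813,
#' CAR >= 0.165, ALI < 33, NRI < 94 score one adverse point each.
#'
#' @return an [ins_config()] with four components.
#' @export
ins2022_config <- function() {
  ins_config(list(
    list(index = "LCR", threshold = 2813,  direction = "below"),
    list(index = "CAR", threshold = 0.165, direction = "at_or_above"),
    list(index = "ALI", threshold = 33,    direction = "below"),
    list(index = "NRI", threshold = 94,    direction = "below")),
    name = "INS-2022")
}

#' @rdname ins_config
#' @param path path to a YAML file with keys `name` and `components`, each
#'   component holding `index`, `threshold`, `direction`.
#' @export
read_ins_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$components <- lapply(y$components, function(cmp) {
    cmp$threshold <- as.numeric(cmp$threshold)
    cmp
  })
  ins_config(y$components,
             name = if (is.null(y$name)) basename(path) else y$name)
}

#' Dichotomize an index value against a threshold
#'
#' `"below"` scores 1 iff `value < threshold` (strict: the boundary value is
#' not adverse); `"at_or_above"` scores 1 iff `value >= threshold`. Missing
#' values stay missing.
#'
#' @param value numeric vector.
#' @param threshold finite numeric scalar.
#' @param direction `"below"` or `"at_or_above"`.
#' @return integer vector of 0/1 with `NA` preserved.
#' @examples
#' dichotomize(2000, 2813, "below")      # 1: low LCR is adverse
#' dichotomize(0.10, 0.165, "at_or_above")  # 0
#' @export
dichotomize <- function(value, threshold, direction = c("below", "at_or_above")) {
  direction <- match.arg(direction)
  if (!is.finite(threshold)) stop("threshold must be finite")
  out <- if (direction == "below") value < threshold else value >= threshold
  as.integer(out)
}

#' Score one or more biomarker panels
#'
#' Sums the adverse indicator bits of the configured components; the INS
#' stratum is the raw score plus one (score 0 -> INS 1, ..., score k ->
#' INS k+1). A record missing any component index gets a missing score, with
#' the missing components listed, rather than an imputed one.
#'
#' @param panel an `ins_panel` (or data.frame holding the component index
#'   columns; `patient_id` optional).
#' @param config an [ins_config()]; default [ins2022_config()].
#' @return data.frame: `patient_id` (if present), one `bit_<index>` column
#'   per component, `raw_score`, `stratum`, `missing_components`.
#' @export
ins_score <- function(panel, config = ins2022_config()) {
  stopifnot(inherits(config, "ins_config"))
  d <- as.data.frame(panel)
  out <- if ("patient_id" %in% names(d))
    data.frame(patient_id = d$patient_id, stringsAsFactors = FALSE)
  else data.frame(row.names = seq_len(nrow(d)))
  bits <- matrix(NA_integer_, nrow(d), config$k)
  missnm <- rep("", nrow(d))
  for (j in seq_len(config$k)) {
    cmp <- config$components[[j]]
    if (!cmp$index %in% names(d))
      stop("panel lacks component index column '", cmp$index, "'")
    bits[, j] <- dichotomize(d[[cmp$index]], cmp$threshold, cmp$direction)
    out[[paste0("bit_", cmp$index)]] <- bits[, j]
    na <- is.na(bits[, j])
    missnm[na] <- ifelse(missnm[na] == "", cmp$index,
                         paste(missnm[na], cmp$index, sep = ","))
  }
  out$raw_score <- as.integer(rowSums(bits))
  out$stratum <- out$raw_score + 1L
  out$missing_components <- missnm
  out
}

#' Score an entire cohort
#'
#' Computes the biomarker panel, applies [ins_score()], and tabulates the
#' strata. Records whose score is not computable are reported separately,
#' never silently dropped.
#'
#' @param cohort an `ins_cohort`.
#' @param config an [ins_config()].
#' @param opts index convention options, see [index_options()].
#' @return list of class `ins_scored`: `scores` (per-patient table),
#'   `freq` (stratum frequency table over eligible patients),
#'   `ineligible` (patient ids with missing scores and the reason),
#'   `config_name`.
#' @export
score_cohort <- function(cohort, config = ins2022_config(),
                         opts = index_options()) {
  panel <- compute_panel(cohort, opts)
  scores <- ins_score(panel, config)
  elig <- !is.na(scores$stratum)
  freq <- table(factor(scores$stratum[elig], levels = seq_len(config$k + 1L)))
  names(dimnames(freq)) <- "stratum"
  ineligible <- data.frame(
    patient_id = scores$patient_id[!elig],
    missing_components = scores$missing_components[!elig],
    stringsAsFactors = FALSE)
  structure(list(scores = scores, freq = freq, ineligible = ineligible,
                 config_name = config$name),
            class = "ins_scored")
}

#' @export
print.ins_scored <- function(x, ...) {
  cat("INS scoring (", x$config_name, ")\n", sep = "")
  cat("  eligible:", sum(x$freq), " ineligible:", nrow(x$ineligible), "\n")
  print(x$freq)
  invisible(x)
}
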