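# Cohort data model: canonical fields, units, CSV ingestion and validation.
#
# Canonical units are fixed once here; every downstream formula consumes
# these units and performs any formula-specific rescaling internally:
#   wbc, neutrophils, lymphocytes, platelets  x10^9/L
#   rbc                                       x10^12/L
#   hemoglobin, albumin, total_protein        g/L
#   cholesterol, glucose                      mmol/L
#   crp                                       mg/L
#   height cm, weight kg, age years, os_time months

.canonical_labs <- c("wbc", "neutrophils", "lymphocytes", "platelets", "rbc",
                     "hemoglobin", "albumin", "total_protein", "cholesterol",
                     "crp", "glucose")

.required_fields <- c("patient_id", "sex", "age", "height", "weight",
                      "wbc", "neutrophils", "lymphocytes", "platelets",
                      "rbc", "hemoglobin", "albumin", "crp", "glucose",
                      "tnm_stage", "os_time", "event")

.optional_fields <- c("total_protein", "cholesterol", "tumor_type",
                      "surgery", "radiotherapy", "chemotherapy",
                      "hypertension", "diabetes", "smoking", "drinking",
                      "family_history")

# unit conversion factors into canonical units, per field
.unit_table <- list(
  albumin       = c("g/L" = 1, "g/dL" = 10),
  hemoglobin    = c("g/L" = 1, "g/dL" = 10),
  total_protein = c("g/L" = 1, "g/dL" = 10),
  crp           = c("mg/L" = 1, "mg/dL" = 10),
  glucose       = c("mmol/L" = 1, "mg/dL" = 1 / 18.016),
  cholesterol   = c("mmol/L" = 1, "mg/dL" = 1 / 38.67),
  wbc           = c("x10^9/L" = 1, "/uL" = 1e-3),
  neutrophils   = c("x10^9/L" = 1, "/uL" = 1e-3),
  lymphocytes   = c("x10^9/L" = 1, "/uL" = 1e-3),
  platelets     = c("x10^9/L" = 1, "/uL" = 1e-3),
  rbc           = c("x10^12/L" = 1),
  height        = c("cm" = 1, "m" = 100),
  weight        = c("kg" = 1),
  os_time       = c("months" = 1, "days" = 12 / 365.25, "years" = 12)
)

#' Column-mapping schema for cohort ingestion
#'
#' Maps user column names onto canonical fields and declares the source unit
#' of each lab column so that ingestion can convert explicitly rather than
#' guess. Fields not mentioned are assumed to use their canonical name and
#' canonical unit.
#'
#' @param columns named list or character vector: canonical field -> column
#'   name in the file.
#' @param units named character vector: canonical field -> source unit, one
#'   of the enumerated units for that field (see Details).
#' @details Recognised units: albumin/hemoglobin/total_protein `g/L`, `g/dL`;
#'   crp `mg/L`, `mg/dL`; glucose `mmol/L`, `mg/dL`; cholesterol `mmol/L`,
#'   `mg/dL`; cell counts `x10^9/L`, `/uL`; height `cm`, `m`; os_time
#'   `months`, `days`, `years`.
#' @return An object of class `ins_schema`.
#' @examples
#' cohort_schema(columns = c(albumin = "ALB"), units = c(albumin = "g/dL"))
#' @export
cohort_schema <- function(columns = list(), units = character()) {
  columns <- as.list(columns)
  bad <- setdiff(names(columns), c(.required_fields, .optional_fields))
  if (length(bad))
    stop("unknown canonical field(s) in schema: ", paste(bad, collapse = ", "))
  for (f in names(units)) {
    allowed <- names(.unit_table[[f]])
    if (is.null(allowed))
      stop("field '", f, "' has no unit options")
    if (!units[[f]] %in% allowed)
      stop("unit '", units[[f]], "' not recognised for '", f,
           "'; allowed: ", paste(allowed, collapse = ", "))
  }
  structure(list(columns = columns, units = units), class = "ins_schema")
}

#' @rdname cohort_schema
#' @param path path to a YAML file with optional top-level keys `columns`
#'   (canonical field -> column name) and `units` (canonical field ->
#'   source unit).
#' @export
read_schema <- function(path) {
  y <- yaml::read_yaml(path)
  cohort_schema(columns = if (is.null(y$columns)) list() else y$columns,
                units = unlist(if (is.null(y$units)) character() else y$units))
}

#' Read a patient-level cohort table
#'
#' Reads a CSV/TSV file, applies the schema's column mapping and unit
#' conversions, validates each row, and returns a cohort. Rows failing hard
#' validation (non-numeric labs, negative follow-up, event codes outside
#' \{0, 1\}) are dropped with a per-row message; records missing CRP are kept
#' but flagged ineligible for INS scoring, since all four INS components
#' depend on it directly or not at all (CRP feeds LCR and CAR).
#'
#' @param path path to a delimited text file with a header row.
#' @param schema an [cohort_schema()] object.
#' @param sep field separator; `NULL` (default) infers from the extension
#'   (`.tsv`/`.txt` tab, otherwise comma).
#' @return A `data.frame` of class `ins_cohort` in canonical units, with
#'   attributes `provenance` (the source path) and `dropped` (a data.frame of
#'   rejected rows with reasons).
#' @seealso [validate_cohort()], [write_cohort()]
#' @export
read_cohort <- function(path, schema = cohort_schema(), sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty cohort file: ", path)
  if (!inherits(schema, "ins_schema")) stop("schema must be a cohort_schema()")

  colmap <- schema$columns
  locate <- function(field) {
    nm <- if (!is.null(colmap[[field]])) colmap[[field]] else field
    if (nm %in% names(raw)) raw[[nm]] else NULL
  }
  for (f in .required_fields) {
    nm <- if (!is.null(colmap[[f]])) colmap[[f]] else f
    if (!nm %in% names(raw))
      stop("required column missing: '", nm, "' (canonical field '", f, "')")
  }

  n <- nrow(raw)
  out <- data.frame(patient_id = as.character(locate("patient_id")),
                    stringsAsFactors = FALSE)
  out$sex <- tolower(as.character(locate("sex")))

  numify <- function(field) {
    x <- locate(field)
    if (is.null(x)) return(rep(NA_real_, n))
    v <- suppressWarnings(as.numeric(x))
    v[!is.na(x) & x == ""] <- NA_real_
    fac <- 1
    if (field %in% names(schema$units))
      fac <- .unit_table[[field]][[schema$units[[field]]]]
    v * fac
  }
  for (f in c("age", "height", "weight", .canonical_labs, "os_time"))
    out[[f]] <- numify(f)
  out$tnm_stage <- toupper(as.character(locate("tnm_stage")))
  tt <- locate("tumor_type")
  out$tumor_type <- if (is.null(tt)) rep(NA_character_, n) else as.character(tt)
  for (f in c("surgery", "radiotherapy", "chemotherapy", "hypertension",
              "diabetes", "smoking", "drinking", "family_history")) {
    x <- locate(f)
    out[[f]] <- if (is.null(x)) rep(NA, n) else as.logical(as.integer(x))
  }
  ev <- locate("event")
  out$event <- suppressWarnings(as.numeric(ev))
  out$bmi <- out$weight / (out$height / 100)^2

  # hard row-level validation
  reasons <- character(n)
  flag <- function(bad, why) {
    bad[is.na(bad)] <- FALSE
    reasons[bad] <<- ifelse(reasons[bad] == "", why,
                            paste(reasons[bad], why, sep = "; "))
  }
  for (f in c("age", "height", "weight")) {
    orig <- locate(f)
    flag(!is.na(orig) & orig != "" & is.na(out[[f]]), paste0("non-numeric ", f))
    flag(out[[f]] <= 0, paste0("non-positive ", f))
    flag(is.na(out[[f]]) & (is.na(orig) | orig == ""), paste0("missing ", f))
  }
  for (f in .canonical_labs) {
    orig <- locate(f)
    if (!is.null(orig))
      flag(!is.na(orig) & orig != "" & is.na(out[[f]]), paste0("non-numeric ", f))
    flag(!is.na(out[[f]]) & out[[f]] <= 0, paste0("non-positive ", f))
  }
  flag(!out$sex %in% c("male", "female"), "sex not in {male, female}")
  flag(!out$tnm_stage %in% c("I", "II", "III", "IV"),
       "tnm_stage not in {I, II, III, IV}")
  flag(is.na(out$os_time) | out$os_time < 0, "os_time missing or negative")
  flag(is.na(out$event) | !out$event %in% c(0, 1),
       "event not in allowed codes {0, 1}")

  bad <- reasons != ""
  dropped <- data.frame(row = which(bad), reason = reasons[bad],
                        stringsAsFactors = FALSE)
  if (any(bad)) {
    for (i in seq_len(nrow(dropped)))
      message("row ", dropped$row[i], " dropped: ", dropped$reason[i])
  }
  out <- out[!bad, , drop = FALSE]
  if (nrow(out) == 0L) stop("no valid records after validation")
  if (anyDuplicated(out$patient_id))
    stop("duplicate patient_id values: ",
         paste(unique(out$patient_id[duplicated(out$patient_id)]), collapse = ", "))
  rownames(out) <- NULL
  as_cohort(out, provenance = path, dropped = dropped)
}

#' @rdname read_cohort
#' @param x a data.frame already in canonical units.
#' @param provenance source path or simulation descriptor.
#' @param dropped record of rejected rows (internal bookkeeping).
#' @export
as_cohort <- function(x, provenance = "in-memory", dropped = NULL) {
  stopifnot(is.data.frame(x), nrow(x) > 0)
  miss <- setdiff(.required_fields, names(x))
  if (length(miss)) stop("cohort lacks fields: ", paste(miss, collapse = ", "))
  if (anyDuplicated(x$patient_id)) stop("patient_id must be unique")
  for (f in .optional_fields) if (!f %in% names(x)) x[[f]] <- NA
  if (!"bmi" %in% names(x)) x$bmi <- x$weight / (x$height / 100)^2
  structure(x, class = c("ins_cohort", "data.frame"),
            provenance = provenance, dropped = dropped)
}

#' Write a cohort back to CSV in canonical units
#'
#' Inverse of [read_cohort()] under the identity schema: a written cohort
#' reads back with identical canonical values.
#'
#' @param cohort an `ins_cohort`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "ins_cohort"))
  df <- as.data.frame(cohort)
  df$bmi <- NULL
  lg <- vapply(df, is.logical, logical(1))
  df[lg] <- lapply(df[lg], as.integer)
  write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Validate a cohort and report eligibility
#'
#' Pure report: counts records eligible for INS scoring (all four component
#' inputs computable and survival outcome present), per-field missingness,
#' and outcome violations. Never mutates the cohort; repeated calls yield
#' identical reports.
#'
#' @param cohort an `ins_cohort`.
#' @return A list of class `ins_validation` with elements `n`, `n_eligible`,
#'   `n_ineligible`, `ineligible_ids`, `missingness` (named counts), and
#'   `outcome_violations` (row indices).
#' @export
validate_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "ins_cohort"))
  n <- nrow(cohort)
  fields <- c("age", "height", "weight", .canonical_labs, "os_time", "event")
  missingness <- vapply(fields, function(f) sum(is.na(cohort[[f]])), integer(1))
  # INS needs lymphocytes + crp (LCR), crp + albumin (CAR),
  # bmi + albumin + neutrophils + lymphocytes (ALI), albumin + weight + height (NRI)
  need <- c("crp", "albumin", "lymphocytes", "neutrophils",
            "weight", "height")
  ok <- !Reduce(`|`, lapply(need, function(f) is.na(cohort[[f]])))
  ok <- ok & !is.na(cohort$os_time) & cohort$os_time >= 0 &
    !is.na(cohort$event)
  viol <- which(is.na(cohort$os_time) | cohort$os_time < 0 |
                  is.na(cohort$event) | !cohort$event %in% c(0, 1))
  structure(list(n = n,
                 n_eligible = sum(ok),
                 n_ineligible = sum(!ok),
                 ineligible_ids = cohort$patient_id[!ok],
                 missingness = missingness,
                 outcome_violations = viol),
            class = "ins_validation")
}

#' @export
print.ins_validation <- function(x, ...) {
  cat("Cohort validation report\n")
  cat(sprintf("  records: %d  eligible for INS: %d  ineligible: %d\n",
              x$n, x$n_eligible, x$n_ineligible))
  mm <- x$missingness[x$missingness > 0]
  if (length(mm)) {
    cat("  missingness:\n")
    for (f in names(mm)) cat(sprintf("    %-14s %d\n", f, mm[f]))
  }
  if (length(x$outcome_violations))
    cat("  outcome violations at rows:",
        paste(x$outcome_violations, collapse = ", "), "\n")
  invisible(x)
}

#' @export
#' @rdname validate_cohort
#' @param report an `ins_validation` report.
#' @param path optional path; when given the JSON is written there.
validation_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "ins_validation"))
  j <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) writeLines(j, path)
  j
}
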