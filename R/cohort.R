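#' Cohort CSV schema
#'
#' One row per patient; paired CSF/serum panel with group label and
#' oligoclonal band (OCB) pattern. Empty cells are missing values; the
#' sentinel `"<LOD"` is accepted in the CSF FLC columns and means
#' "undetectable, substitute the detection limit".
#'
#' @return Data frame mapping CSV column names (with unit suffixes) to the
#'   internal column names used by [compute_panel()] and [run_pipeline()].
#' @export
cohort_schema <- function() {
  data.frame(
    csv = c("patient_id", "group", "ocb_pattern", "age", "sex",
            "serum_albumin_gL", "csf_albumin_mgL", "serum_igg_gL",
            "csf_igg_mgL", "serum_iga_gL", "csf_iga_mgL", "serum_igm_gL",
            "csf_igm_mgL", "serum_kflc_mgL", "csf_kflc_mgL",
            "serum_lflc_mgL", "csf_lflc_mgL"),
    internal = c("patient_id", "group", "ocb_pattern", "age", "sex",
                 "serum_albumin", "csf_albumin", "serum_igg", "csf_igg",
                 "serum_iga", "csf_iga", "serum_igm", "csf_igm",
                 "serum_kflc", "csf_kflc", "serum_lflc", "csf_lflc"),
    stringsAsFactors = FALSE
  )
}

.analyte_cols <- function() cohort_schema()$internal[-(1:5)]

#' Read a cohort CSV
#'
#' Parses the schema of [cohort_schema()], resolves `"<LOD"` sentinels in the
#' CSF FLC columns into the detection-limit value plus a `*_below_lod` flag,
#' and validates the result. A `"<LOD"` in a serum FLC column has no
#' substitution rule: the value is kept missing, flagged, and a warning is
#' raised.
#'
#' @param path Path to a CSV file.
#' @return Validated cohort data frame in the internal schema, with logical
#'   columns `csf_kflc_below_lod`, `csf_lflc_below_lod` (and serum analogues
#'   when sentinels occurred).
#' @export
read_cohort <- function(path) {
  sc <- cohort_schema()
  raw <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                  na.strings = c("", "NA"))
  missing_cols <- setdiff(sc$csv, names(raw))
  if (length(missing_cols))
    stop("cohort CSV lacks required columns: ", paste(missing_cols, collapse = ", "))
  out <- raw[sc$csv]
  names(out) <- sc$internal
  lods <- flc_lod()
  for (col in .analyte_cols()) {
    v <- out[[col]]
    sent <- !is.na(v) & trimws(v) == "<LOD"
    if (any(sent)) {
      if (col %in% names(lods)) {
        v[sent] <- lods[[col]]
        out[[paste0(col, "_below_lod")]] <- sent
      } else if (col %in% c("serum_kflc", "serum_lflc")) {
        warning("'<LOD' in ", col, ": no serum substitution rule, value kept missing")
        v[sent] <- NA
        out[[paste0(col, "_below_lod")]] <- sent
      } else {
        stop("'<LOD' sentinel is only valid in FLC columns, found in ", col)
      }
    }
    out[[col]] <- suppressWarnings(as.numeric(v))
    if (any(!is.na(v) & !sent & is.na(out[[col]])))
      stop("non-numeric value in column ", col)
  }
  for (flag in c("csf_kflc_below_lod", "csf_lflc_below_lod"))
    if (is.null(out[[flag]])) out[[flag]] <- FALSE
  out$age <- suppressWarnings(as.numeric(out$age))
  out$ocb_pattern <- suppressWarnings(as.integer(out$ocb_pattern))
  validate_cohort(out)
}

#' Validate a cohort data frame
#'
#' Checks the internal-schema invariants: known group labels, OCB pattern in
#' 1..5 (or missing), strictly positive concentrations, sex in F/M (or
#' missing), unique patient ids. Problems are collected and reported
#' together.
#'
#' @param cohort Data frame in the internal schema.
#' @return The cohort, invisibly classed `flc_cohort`, or an error listing
#'   every violation.
#' @export
validate_cohort <- function(cohort) {
  problems <- character()
  need <- c(cohort_schema()$internal)
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort lacks required columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(cohort$patient_id))
    problems <- c(problems, "duplicate patient_id values")
  g <- toupper(as.character(cohort$group))
  if (!all(g %in% c("MS", "CONTROL")))
    problems <- c(problems, "group must be 'MS' or 'CONTROL'")
  cohort$group <- g
  p <- cohort$ocb_pattern
  if (!all(is.na(p) | p %in% 1:5))
    problems <- c(problems, "ocb_pattern must be 1..5 or missing")
  s <- toupper(as.character(cohort$sex))
  if (!all(is.na(s) | s %in% c("F", "M")))
    problems <- c(problems, "sex must be 'F' or 'M' or missing")
  cohort$sex <- s
  for (col in .analyte_cols()) {
    v <- cohort[[col]]
    if (any(!is.na(v) & v <= 0))
      problems <- c(problems, paste0(col, " has non-positive values"))
  }
  if (any(!is.na(cohort$age) & (cohort$age < 0 | cohort$age > 120)))
    problems <- c(problems, "age out of plausible range")
  if (length(problems))
    stop("cohort validation failed:\n  - ", paste(problems, collapse = "\n  - "))
  class(cohort) <- unique(c("flc_cohort", class(cohort)))
  invisible(cohort)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort()]: internal columns are renamed to the unit-
#' suffixed CSV schema and `*_below_lod` flags are folded back into `"<LOD"`
#' sentinels, so a write/read round trip is lossless.
#'
#' @param cohort Cohort data frame in the internal schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  sc <- cohort_schema()
  out <- cohort[sc$internal]
  for (col in c("csf_kflc", "csf_lflc")) {
    flag <- cohort[[paste0(col, "_below_lod")]]
    if (!is.null(flag)) {
      v <- as.character(out[[col]])
      v[!is.na(flag) & flag] <- "<LOD"
      out[[col]] <- v
    }
  }
  names(out) <- sc$csv
  write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
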