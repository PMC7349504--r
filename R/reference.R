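# Published summary statistics of the 76-patient MS/control study cohort the
# synthetic generator emulates. These are calibration inputs and reference
# targets, not per-patient data (none were deposited).

#' Reference analyte summaries of the emulated study cohort
#'
#' Group medians and printed min-max ranges of the routine CSF/serum panel
#' (albumin and immunoglobulins in the study's Table-1 style), plus the FLC
#' medians reported in its text. FLC ranges were not published; the `min`
#' and `max` columns are `NA` there and the simulator uses its documented
#' default log-sigmas instead.
#'
#' A few published range bounds are internally impossible (a median outside
#' its own range, serum immunoglobulin maxima above total serum protein);
#' they are stored verbatim here and repaired by [calibrate_lognormal()] /
#' [analyte_models()] with explicit, warned rules.
#'
#' @return Data frame: `analyte`, `group`, `median`, `min`, `max`, `unit`.
#' @export
reference_analytes <- function() {
  ms <- rbind(
    c("serum_albumin", 43.90, 33.70, 57.40), c("csf_albumin", 187.95, 20.60, 487.70),
    c("serum_igg", 10.72, 6.35, 1320.00),    c("csf_igg", 43.19, 3.37, 20.47),
    c("serum_igm", 1.57, 0.57, 360.00),      c("csf_igm", 1.53, 0.31, 9.43),
    c("serum_iga", 2.18, 0.81, 263.00),      c("csf_iga", 3.47, 0.92, 24.20),
    c("serum_kflc", 13.480, NA, NA),         c("csf_kflc", 3.050, NA, NA),
    c("serum_lflc", 11.715, NA, NA),         c("csf_lflc", 2.050, NA, NA),
    c("age", 34, 20, 55))
  ct <- rbind(
    c("serum_albumin", 40.00, 17.80, 53.90), c("csf_albumin", 196.45, 16.50, 815.00),
    c("serum_igg", 10.00, 4.95, 1150.00),    c("csf_igg", 26.65, 2.14, 151.72),
    c("serum_igm", 1.19, 0.35, 249.00),      c("csf_igm", 0.58, 0.11, 103.00),
    c("serum_iga", 2.28, 0.02, 434.00),      c("csf_iga", 3.84, 0.88, 37.20),
    c("serum_kflc", 16.265, NA, NA),         c("csf_kflc", 0.310, NA, NA),
    c("serum_lflc", 13.220, NA, NA),         c("csf_lflc", 0.720, NA, NA),
    c("age", 48, 18, 78))
  out <- rbind(data.frame(analyte = ms[, 1], group = "MS",
                          median = as.numeric(ms[, 2]), min = as.numeric(ms[, 3]),
                          max = as.numeric(ms[, 4]), stringsAsFactors = FALSE),
               data.frame(analyte = ct[, 1], group = "CONTROL",
                          median = as.numeric(ct[, 2]), min = as.numeric(ct[, 3]),
                          max = as.numeric(ct[, 4]), stringsAsFactors = FALSE))
  out$unit <- ifelse(out$analyte == "age", "years",
                     ifelse(grepl("^serum", out$analyte), "g/L", "mg/L"))
  out$unit[out$analyte %in% c("serum_kflc", "serum_lflc")] <- "mg/L"
  out
}

#' Reference diagnostic performance of the four indices
#'
#' Published per-group index medians and ranges, ROC cut-offs and the five
#' diagnostic metrics (percent, printed at 1-decimal precision) with AUC,
#' for the kappa/lambda FLC and IgG indices in the emulated cohort. These
#' are the constraint inputs for [reconstruct_confusion()] and qualitative
#' targets for the simulator; note the kflc row's published PPV/NPV pair is
#' internally inconsistent with its sensitivity/specificity (see the
#' reconstruction vignette section).
#'
#' @return Data frame, one row per index.
#' @export
reference_performance <- function() {
  data.frame(
    index = c("kflc_index", "lflc_index", "kigg_index", "ligg_index"),
    median_ms = c(59.338, 35.070, 5.660, 3.571),
    min_ms = c(4.466, 6.336, 0.751, 0.330),
    max_ms = c(623.565, 792.533, 16.400, 10.374),
    median_control = c(6.196, 14.450, 0.956, 1.974),
    min_control = c(0.912, 1.015, 0.216, 0.241),
    max_control = c(91.081, 157.741, 9.581, 35.665),
    cutoff = c(9.417, 21.446, 1.929, 3.161),
    sensitivity = c(93.5, 71.9, 90.3, 65.6),
    specificity = c(68.3, 64.3, 80.5, 71.4),
    ppv = c(79.2, 60.5, 77.8, 63.6),
    npv = c(69.0, 75.0, 91.7, 73.2),
    accuracy = c(79.2, 67.6, 84.7, 68.9),
    auc = c(0.866, 0.693, 0.871, 0.632),
    stringsAsFactors = FALSE)
}

#' Reference OCB pattern composition and CSF kappa-FLC pattern medians
#'
#' Oligoclonal band pattern frequencies per group in the emulated cohort
#' (MS: 31 of type 2 and 3 of type 3; controls: 21/4/16/1 of types 1/3/4/5)
#' and the published per-pattern CSF kappa-FLC medians driving the
#' simulator's pattern-specific location shifts. No type-5 median was
#' published (a single patient); the control-group median stands in.
#'
#' @return List with `frequencies` (data frame `group`, `pattern`, `n`) and
#'   `csf_kflc_median` (named numeric, patterns 1-5, mg/L).
#' @export
reference_patterns <- function() {
  list(
    frequencies = data.frame(
      group = c("MS", "MS", "CONTROL", "CONTROL", "CONTROL", "CONTROL"),
      pattern = c(2L, 3L, 1L, 3L, 4L, 5L),
      n = c(31L, 3L, 21L, 4L, 16L, 1L),
      stringsAsFactors = FALSE),
    csf_kflc_median = c(`1` = 0.300, `2` = 2.905, `3` = 4.400,
                        `4` = 0.936, `5` = 0.310))
}

#' Reference Spearman correlation targets
#'
#' The published total-group Spearman correlations between age, the four
#' CSF/serum quotients, the two CSF FLC concentrations and the four indices.
#' The published table is not perfectly symmetric (a handful of cells differ
#' between the two triangles, one by sign); both readings are averaged here
#' and the result is a calibration target, not ground truth.
#'
#' @return Symmetric 11 x 11 matrix with unit diagonal; `NA` where no value
#'   was published (none, after symmetrization).
#' @export
reference_correlations <- function() {
  v <- c("age", "q_alb", "q_igg", "q_igm", "q_iga", "csf_kflc", "csf_lflc",
         "kflc_index", "lflc_index", "kigg_index", "ligg_index")
  m <- matrix(NA_real_, 11, 11, dimnames = list(v, v))
  put <- function(row, vals) {
    cols <- setdiff(v, row)
    m[row, cols] <<- vals
  }
  put("q_alb", c(0.403, 0.648, 0.268, 0.778, -0.120, 0.049, -0.253, -0.244, -0.472, -0.433))
  put("q_igg", c(0.010, 0.648, 0.553, 0.678, 0.405, 0.208, -0.197, -0.028, 0.034, -0.296))
  put("q_igm", c(-0.121, -0.268, 0.553, 0.547, 0.425, 0.302, 0.333, 0.164, 0.231, 0.015))
  put("q_iga", c(0.253, 0.778, 0.678, 0.547, 0.010, 0.078, -0.034, -0.101, -0.273, -0.335))
  put("csf_kflc", c(-0.309, -0.120, 0.405, 0.424, 0.010, 0.661, 0.802, 0.515, 0.843, 0.372))
  put("csf_lflc", c(-0.138, 0.049, 0.208, 0.302, 0.078, -0.126, 0.536, 0.720, 0.557, 0.686))
  put("kflc_index", c(-0.459, -0.253, 0.207, 0.333, -0.034, 0.802, 0.536, 0.784, 0.866, 0.495))
  put("lflc_index", c(-0.369, -0.244, -0.030, 0.164, -0.101, 0.371, 0.720, 0.784, 0.659, 0.809))
  put("kigg_index", c(-0.472, -0.472, 0.034, 0.231, -0.273, 0.843, 0.557, 0.867, 0.659, 0.647))
  put("ligg_index", c(-0.388, 0.432, -0.296, 0.015, -0.335, 0.372, 0.686, 0.495, 0.809, 0.647))
  sym <- (m + t(m))
  both <- !is.na(m) & !is.na(t(m))
  sym[both] <- sym[both] / 2
  one <- xor(is.na(m), is.na(t(m)))
  sym[one] <- pmax(m, t(m), na.rm = TRUE)[one]
  diag(sym) <- 1
  sym
}
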