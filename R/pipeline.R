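#' Run the full analysis pipeline on a cohort
#'
#' Reproduces the complete analysis on any cohort table: LOD handling and
#' index computation, MS-vs-control rank comparisons for every analyte,
#' quotient and index, OCB-pattern-stratified Kruskal-Wallis tests with
#' Dunn/Bonferroni post-hoc, the pairwise-complete Spearman correlation
#' matrix, and ROC diagnostics with Youden cut-off per index. A failure in
#' one index (e.g. a single-class ROC after missingness) skips that index
#' with a warning and never aborts the rest.
#'
#' @param cohort Cohort data frame or path to a cohort CSV
#'   (see [cohort_schema()]).
#' @param pattern_variables Variables tested across OCB patterns (default:
#'   CSF kappa-FLC and the four indices).
#' @return Object of class `flc_report`: list with elements
#'   `group_comparisons`, `pattern_tests`, `correlations`, `diagnostics`,
#'   `effective_n`, `provenance`.
#' @export
#' @examples
#' rep <- run_pipeline(generate_cohort(cohort_config(seed = 1)))
#' rep$diagnostics$kigg_index$performance
run_pipeline <- function(cohort,
                         pattern_variables = c("csf_kflc", "kflc_index",
                                               "lflc_index", "kigg_index",
                                               "ligg_index")) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  cohort <- validate_cohort(cohort)
  if (sum(cohort$group == "MS") < 2L || sum(cohort$group == "CONTROL") < 2L)
    stop("need at least 2 patients per compared group")
  panel <- compute_panel(cohort)
  index_cols <- c("kflc_index", "lflc_index", "kigg_index", "ligg_index")
  quot_cols <- c("q_alb", "q_igg", "q_iga", "q_igm")
  test_vars <- c("age", .analyte_cols(), quot_cols, index_cols)

  group_comparisons <- lapply(setNames(test_vars, test_vars), function(v) {
    x <- panel[[v]][panel$group == "MS"]
    y <- panel[[v]][panel$group == "CONTROL"]
    summ <- function(s) list(median = median(s, na.rm = TRUE),
                             min = suppressWarnings(min(s, na.rm = TRUE)),
                             max = suppressWarnings(max(s, na.rm = TRUE)),
                             n = sum(!is.na(s)))
    test <- tryCatch(mann_whitney_u(x, y), error = function(e) NULL)
    list(ms = summ(x), control = summ(y),
         u = if (!is.null(test)) test$statistic else NA_real_,
         p = if (!is.null(test)) test$p_value else NA_real_)
  })

  pattern_tests <- lapply(setNames(pattern_variables, pattern_variables), function(v) {
    ok <- !is.na(panel$ocb_pattern) & !is.na(panel[[v]])
    groups <- split(panel[[v]][ok], panel$ocb_pattern[ok])
    groups <- groups[lengths(groups) > 0L]
    if (length(groups) < 2L) return(NULL)
    kw <- kruskal_wallis(groups)
    list(h = kw$statistic, df = kw$df, p = kw$p_value,
         effective_n = as.list(kw$effective_n),
         posthoc = dunn_posthoc(groups))
  })

  correlations <- correlation_matrix(panel, c("age", quot_cols,
                                              "csf_kflc", "csf_lflc", index_cols))

  diagnostics <- lapply(setNames(index_cols, index_cols), function(v) {
    res <- tryCatch({
      curve <- roc_curve(panel[[v]], panel$group)
      cut <- youden_cutoff(curve)
      perf <- performance_at_cutoff(panel[[v]], panel$group, cut$cutoff)
      list(auc = curve$auc, cutoff = cut$cutoff, youden_j = cut$j,
           uninformative = cut$uninformative, performance = perf,
           roc = curve$points,
           n = c(ms = curve$n_pos, control = curve$n_neg))
    }, error = function(e) {
      warning("ROC skipped for ", v, ": ", conditionMessage(e))
      NULL
    })
    res
  })

  structure(list(
    group_comparisons = group_comparisons,
    pattern_tests = pattern_tests,
    correlations = correlations,
    diagnostics = diagnostics,
    effective_n = vapply(test_vars, function(v)
      sum(!is.na(panel[[v]])), integer(1)),
    provenance = c(list(n_patients = nrow(panel),
                        schema_version = "1.0",
                        package = paste0("flcindex ",
                                         as.character(utils::packageVersion("flcindex")))),
                   attr(cohort, "provenance"))),
    class = "flc_report")
}

#' Serialize an analysis report to JSON
#'
#' Writes the [run_pipeline()] report as versioned JSON (schema_version in
#' the provenance block). Matrices serialize with their dimnames; the output
#' contains no timestamps, so identical runs produce byte-identical files.
#'
#' @param report An `flc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "flc_report"))
  clean <- rapply(unclass(report), function(x) x, how = "replace")
  json <- jsonlite::toJSON(clean, auto_unbox = TRUE, digits = NA,
                           na = "null", pretty = TRUE, force = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @export
print.flc_report <- function(x, ...) {
  cat("flc_report:", x$provenance$n_patients, "patients\n")
  cat("  diagnostics (Youden cut-off):\n")
  for (v in names(x$diagnostics)) {
    d <- x$diagnostics[[v]]
    if (is.null(d)) { cat(sprintf("    %-11s skipped\n", v)); next }
    p <- d$performance
    cat(sprintf("    %-11s cutoff %7.3f  AUC %.3f  sens %5.1f  spec %5.1f\n",
                v, d$cutoff, d$auc, p$sensitivity, p$specificity))
  }
  invisible(x)
}
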