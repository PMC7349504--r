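#' CSF/serum quotient
#'
#' Conventional CSF/serum concentration quotient with the CSF value in mg/L
#' and the serum value in g/L, i.e. the result is on the usual x 10^-3
#' quotient scale (Q_Alb, Q_IgG, Q_IgA, Q_IgM).
#'
#' @param csf CSF concentration, mg/L.
#' @param serum Serum concentration, g/L.
#' @return `csf / serum` (dimensionally mg/g). `NA` inputs propagate.
#' @export
#' @examples
#' compute_quotient(187.95, 43.90)  # Q_Alb-style quotient
compute_quotient <- function(csf, serum) {
  bad <- !is.na(serum) & serum <= 0
  if (any(bad)) stop("serum concentration must be strictly positive")
  if (any(!is.na(csf) & csf <= 0)) stop("CSF concentration must be strictly positive")
  csf / serum
}

#' Free light chain index
#'
#' The FLC index relates the CSF/serum FLC ratio to the albumin ratio, the
#' latter acting as the individual blood-CSF barrier reference:
#' \deqn{\mathrm{FLC\ index} = \frac{\mathrm{CSF\ FLC} / \mathrm{serum\ FLC}}
#'   {\mathrm{CSF\ albumin} / \mathrm{serum\ albumin}}}
#' Both FLC concentrations are in mg/L; serum albumin arrives in g/L and is
#' converted to mg/L internally so the albumin ratio is fully unitless and
#' the index is dimensionless.
#'
#' @param csf_flc,serum_flc CSF and serum FLC, mg/L.
#' @param csf_alb CSF albumin, mg/L.
#' @param serum_alb Serum albumin, g/L.
#' @return Dimensionless index; `NA` if any constituent is missing.
#' @export
#' @examples
#' compute_flc_index(3.050, 13.480, 187.95, 43.90)
compute_flc_index <- function(csf_flc, serum_flc, csf_alb, serum_alb) {
  .check_positive(csf_flc, serum_flc, csf_alb, serum_alb)
  (csf_flc / serum_flc) / (csf_alb / (serum_alb * 1000))
}

#' IgG-quotient-based FLC index
#'
#' Variant index that replaces the albumin quotient denominator by the IgG
#' quotient, scaled by 100:
#' \deqn{\mathrm{IgG\ index} = 100 \cdot \frac{\mathrm{CSF\ FLC} /
#'   \mathrm{serum\ FLC}}{\mathrm{CSF\ IgG} / \mathrm{serum\ IgG}}}
#' with CSF IgG in mg/L and serum IgG in g/L exactly as reported by the
#' laboratory, so the denominator is the conventional Q_IgG scale and the
#' factor 100 brings the index to order unity.
#'
#' @param csf_flc,serum_flc CSF and serum FLC, mg/L.
#' @param csf_igg CSF IgG, mg/L.
#' @param serum_igg Serum IgG, g/L.
#' @return Dimensionless index; `NA` if any constituent is missing.
#' @export
#' @examples
#' compute_igg_index(3.050, 13.480, 43.19, 10.72)
compute_igg_index <- function(csf_flc, serum_flc, csf_igg, serum_igg) {
  .check_positive(csf_flc, serum_flc, csf_igg, serum_igg)
  100 * (csf_flc / serum_flc) / (csf_igg / serum_igg)
}

.check_positive <- function(...) {
  for (v in list(...))
    if (any(!is.na(v) & v <= 0)) stop("concentrations must be strictly positive")
  invisible(TRUE)
}

#' Quotients and indices for a whole cohort
#'
#' Applies LOD substitution to the CSF FLC columns, then computes the four
#' CSF/serum quotients (albumin, IgG, IgA, IgM) and the four diagnostic
#' indices (kappa/lambda FLC index, kappa/lambda IgG index) for every
#' patient. Any missing constituent makes the affected quotient/index `NA`;
#' no row ever errors out.
#'
#' @param cohort A cohort data frame in the internal schema of
#'   [read_cohort()] / [generate_cohort()] (columns `serum_albumin`,
#'   `csf_albumin`, `serum_igg`, `csf_igg`, ..., `csf_lflc`).
#' @return The input with columns added: `q_alb`, `q_igg`, `q_iga`, `q_igm`,
#'   `kflc_index`, `lflc_index`, `kigg_index`, `ligg_index`, and logical
#'   `csf_kflc_below_lod` / `csf_lflc_below_lod` flags (kept if already
#'   present, e.g. from `"<LOD"` sentinels in the CSV).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 1))
#' head(compute_panel(coh)[, c("patient_id", "q_alb", "kflc_index", "kigg_index")])
compute_panel <- function(cohort) {
  stopifnot(is.data.frame(cohort))
  lods <- flc_lod()
  for (col in names(lods)) {
    flag <- paste0(col, "_below_lod")
    if (is.null(cohort[[flag]])) cohort[[flag]] <- FALSE
    # substitute only observed sub-LOD values; plain NA here means missing,
    # not censored, and must stay missing
    low <- !is.na(cohort[[col]]) & cohort[[col]] < lods[[col]]
    cohort[[col]][low | cohort[[flag]]] <- lods[[col]]
    cohort[[flag]] <- cohort[[flag]] | low
  }
  for (s in c("kflc", "lflc")) {
    und <- cohort[[paste0("serum_", s, "_below_lod")]]
    if (!is.null(und) && any(und, na.rm = TRUE))
      warning("serum ", s, " flagged undetectable: no substitution rule, kept missing")
  }
  cohort$q_alb <- compute_quotient(cohort$csf_albumin, cohort$serum_albumin)
  cohort$q_igg <- compute_quotient(cohort$csf_igg, cohort$serum_igg)
  cohort$q_iga <- compute_quotient(cohort$csf_iga, cohort$serum_iga)
  cohort$q_igm <- compute_quotient(cohort$csf_igm, cohort$serum_igm)
  cohort$kflc_index <- compute_flc_index(cohort$csf_kflc, cohort$serum_kflc,
                                         cohort$csf_albumin, cohort$serum_albumin)
  cohort$lflc_index <- compute_flc_index(cohort$csf_lflc, cohort$serum_lflc,
                                         cohort$csf_albumin, cohort$serum_albumin)
  cohort$kigg_index <- compute_igg_index(cohort$csf_kflc, cohort$serum_kflc,
                                         cohort$csf_igg, cohort$serum_igg)
  cohort$ligg_index <- compute_igg_index(cohort$csf_lflc, cohort$serum_lflc,
                                         cohort$csf_igg, cohort$serum_igg)
  cohort
}
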