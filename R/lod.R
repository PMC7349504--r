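#' Detection limits for CSF free light chains
#'
#' Lower limits of detection (LOD) of the turbidimetric CSF FLC assays, in
#' mg/L. CSF values reported below these limits are substituted by the limit
#' itself before any quotient or index is computed; serum FLC assays have no
#' such substitution rule here and an undetectable serum value stays missing.
#'
#' @return Named numeric vector with elements `csf_kflc` (0.30) and
#'   `csf_lflc` (0.65), both mg/L.
#' @export
#' @examples
#' flc_lod()
flc_lod <- function() c(csf_kflc = 0.30, csf_lflc = 0.65)

#' Substitute values below the limit of detection
#'
#' Left-censored clinical chemistry convention: a measurement that is missing
#' because it was undetectable, or that lies below the assay's lower limit of
#' detection, is replaced by the limit itself and flagged. Values at or above
#' the limit pass through unchanged.
#'
#' @param value Numeric vector of concentrations (mg/L). `NA` is interpreted
#'   as "absent because undetectable" and is substituted; use this only for
#'   values known to be censored, not for generically missing data.
#' @param lod Single positive detection limit (mg/L).
#' @return List with components `value` (numeric, censored values replaced by
#'   `lod`) and `below_lod` (logical flag per element).
#' @export
#' @examples
#' apply_lod(c(0.10, 0.65, 2.05, NA), lod = 0.30)
apply_lod <- function(value, lod) {
  stopifnot(is.numeric(lod), length(lod) == 1L, is.finite(lod), lod > 0)
  if (any(value < 0, na.rm = TRUE))
    stop("negative concentrations are not valid inputs to apply_lod()")
  below <- is.na(value) | value < lod
  out <- value
  out[below] <- lod
  list(value = out, below_lod = below)
}
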