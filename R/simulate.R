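#' Log-normal calibration from median and range
#'
#' Clinical-chemistry analytes are strictly positive and right-skewed, so
#' each margin is modelled log-normally. The location is pinned to the
#' published median (`mu = log(median)`, since the log-normal median is
#' `exp(mu)`), and the published min-max range is read as roughly +/- 2
#' standard deviations on the log scale: `sigma = (log(max) - log(min)) / 4`.
#'
#' @param median,min,max Positive summaries with `min <= median <= max`.
#' @return Named numeric vector `c(mu, sigma)`.
#' @export
#' @examples
#' calibrate_lognormal(1, exp(-2), exp(2))  # mu 0, sigma 1
calibrate_lognormal <- function(median, min, max) {
  if (any(!is.finite(c(median, min, max))) || any(c(median, min, max) <= 0))
    stop("median, min and max must be positive and finite")
  if (min > median || median > max)
    stop("median must lie within [min, max]")
  c(mu = log(median), sigma = (log(max) - log(min)) / 4)
}

# Repair published ranges before calibration:
#  (a) median outside its own printed range -> widen the violated bound to
#      the median;
#  (b) serum immunoglobulin bounds above 50 g/L are decimal-shift misprints
#      (total serum protein is ~70 g/L) -> divide by 10 until plausible.
.repair_range <- function(analyte, median, min, max, quiet = FALSE) {
  if (grepl("^serum_ig", analyte)) {
    for (b in c("min", "max")) {
      v <- get(b)
      if (is.finite(v) && v > 50) {
        while (v > 50) v <- v / 10
        if (!quiet)
          warning(analyte, ": ", b, " above total serum protein, read as a ",
                  "decimal misprint and rescaled to ", v, " g/L")
        assign(b, v)
      }
    }
  }
  if (is.finite(min) && min > median) {
    if (!quiet) warning(analyte, ": published min exceeds median; widened to the median")
    min <- median
  }
  if (is.finite(max) && max < median) {
    if (!quiet) warning(analyte, ": published max below median; widened to the median")
    max <- median
  }
  c(min = min, max = max)
}

# Default log-sigmas where no range was published (FLC concentrations):
# serum FLC is tightly regulated, CSF FLC spans ~2 orders of magnitude in a
# mixed neurological cohort (cf. the published index ranges).
.default_sigma <- c(csf_kflc = 0.9, csf_lflc = 0.9,
                    serum_kflc = 0.35, serum_lflc = 0.35)

#' Per-analyte log-normal models for the simulator
#'
#' Turns [reference_analytes()] (or any table in the same shape) into
#' per-group `(mu, sigma)` log-normal parameters via [calibrate_lognormal()],
#' after repairing impossible published bounds (median outside range; serum
#' immunoglobulin bounds above total serum protein, read as decimal
#' misprints). Analytes without a published range get the package's default
#' log-sigmas (0.9 for CSF FLC, 0.35 for serum FLC).
#'
#' @param reference Data frame as returned by [reference_analytes()].
#' @param quiet Suppress repair warnings (used internally once the defaults
#'   have been documented).
#' @return Data frame: `analyte`, `group`, `mu`, `sigma`, `lod`.
#' @export
analyte_models <- function(reference = reference_analytes(), quiet = FALSE) {
  lods <- flc_lod()
  out <- reference[c("analyte", "group")]
  out$mu <- log(reference$median)
  out$sigma <- NA_real_
  for (i in seq_len(nrow(reference))) {
    r <- reference[i, ]
    if (is.finite(r$min) && is.finite(r$max)) {
      rng <- .repair_range(r$analyte, r$median, r$min, r$max, quiet = quiet)
      out$sigma[i] <- calibrate_lognormal(r$median, rng[["min"]], rng[["max"]])[["sigma"]]
    } else {
      if (!r$analyte %in% names(.default_sigma))
        stop("no range and no default sigma for ", r$analyte)
      out$sigma[i] <- .default_sigma[[r$analyte]]
    }
  }
  out$lod <- ifelse(out$analyte %in% names(lods), lods[out$analyte], NA_real_)
  out
}

# Latent Gaussian-copula correlation matrix over the 13 simulated margins.
# CSF-side pairs take the published total-group Spearman targets (quotient
# rows mapped onto their CSF analyte); within-analyte serum-CSF coupling and
# the serum kappa-lambda coupling are package calibration choices; the
# CSF IgG - CSF FLC pairs are raised above the diluted total-group values to
# reflect that intrathecal FLC and IgG are coupled B-cell products.
latent_correlations <- function() {
  v <- c("age", "serum_albumin", "csf_albumin", "serum_igg", "csf_igg",
         "serum_iga", "csf_iga", "serum_igm", "csf_igm",
         "serum_kflc", "csf_kflc", "serum_lflc", "csf_lflc")
  ref <- reference_correlations()
  map <- c(age = "age", csf_albumin = "q_alb", csf_igg = "q_igg",
           csf_igm = "q_igm", csf_iga = "q_iga",
           csf_kflc = "csf_kflc", csf_lflc = "csf_lflc")
  rho <- matrix(0, 13, 13, dimnames = list(v, v))
  mapped <- names(map)
  for (a in mapped) for (b in mapped)
    if (a != b) rho[a, b] <- ref[map[[a]], map[[b]]]
  rho["csf_igg", "csf_kflc"] <- rho["csf_kflc", "csf_igg"] <- 0.60
  rho["csf_igg", "csf_lflc"] <- rho["csf_lflc", "csf_igg"] <- 0.45
  pairs <- rbind(c("serum_albumin", "csf_albumin", 0.20),
                 c("serum_igg", "csf_igg", 0.30),
                 c("serum_iga", "csf_iga", 0.30),
                 c("serum_igm", "csf_igm", 0.30),
                 c("serum_kflc", "csf_kflc", 0.35),
                 c("serum_lflc", "csf_lflc", 0.35),
                 c("serum_kflc", "serum_lflc", 0.70))
  for (i in seq_len(nrow(pairs))) {
    val <- as.numeric(pairs[i, 3])
    rho[pairs[i, 1], pairs[i, 2]] <- rho[pairs[i, 2], pairs[i, 1]] <- val
  }
  diag(rho) <- 1
  r <- spearman_to_pearson(rho)
  nearest_psd(r)
}

#' Spearman-to-Pearson conversion for a Gaussian copula
#'
#' Under a Gaussian copula the latent Pearson correlation generating a given
#' Spearman rho is `r = 2 sin(pi rho / 6)`.
#'
#' @param rho Spearman correlation (scalar or matrix).
#' @return Latent Pearson correlation of the same shape.
#' @export
spearman_to_pearson <- function(rho) {
  r <- 2 * sin(pi * rho / 6)
  if (is.matrix(r)) diag(r) <- 1
  r
}

#' Nearest positive semi-definite correlation matrix
#'
#' Eigenvalue clipping: negative eigenvalues are raised to a small floor,
#' the matrix is reconstructed and rescaled to unit diagonal. Published
#' correlation tables assembled cell by cell are routinely slightly
#' indefinite; this repair keeps them usable as copula targets.
#'
#' @param m Symmetric matrix.
#' @param floor_eig Eigenvalue floor (default 1e-6).
#' @return PSD correlation matrix.
#' @export
nearest_psd <- function(m, floor_eig = 1e-6) {
  m <- (m + t(m)) / 2
  e <- eigen(m, symmetric = TRUE)
  if (all(e$values >= floor_eig)) return(m)
  v <- pmax(e$values, floor_eig)
  r <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- 1 / sqrt(diag(r))
  r <- r * outer(d, d)
  r <- (r + t(r)) / 2
  dimnames(r) <- dimnames(m)
  r
}

#' Simulator configuration
#'
#' All the knobs of [generate_cohort()] in one validated object. Defaults
#' reproduce the emulated study population: 34 MS / 42 control patients, OCB
#' pattern frequencies 31:3 (MS types 2:3) and 21/4/16/1 (control types
#' 1/3/4/5), log-normal margins calibrated by [analyte_models()], a Gaussian
#' copula with the documented latent correlation targets, CSF FLC detection
#' limits 0.30 / 0.65 mg/L, pattern-specific CSF kappa-FLC locations, and
#' 2% missingness on each FLC field.
#'
#' @param n_ms,n_control Group sizes.
#' @param pattern_frequencies Data frame `group`, `pattern`, `n`; counts are
#'   rescaled proportionally if the group sizes differ from their total.
#' @param models Output of [analyte_models()].
#' @param latent_corr 13 x 13 latent correlation matrix (see
#'   [spearman_to_pearson()]); repaired by [nearest_psd()] if needed.
#' @param missingness Named per-variable MCAR rates.
#' @param sigma_scale Multiplier on every log-sigma; 0 gives the
#'   deterministic cohort in which every analyte equals its group median.
#' @param pattern_shifts Give CSF kappa-FLC its per-pattern published median
#'   location instead of the group median (default `TRUE`).
#' @param p_female Named per-group probability of female sex.
#' @param seed Integer seed; generation is a pure function of (config, seed).
#' @return Object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_ms = 34L, n_control = 42L,
                          pattern_frequencies = reference_patterns()$frequencies,
                          models = analyte_models(quiet = TRUE),
                          latent_corr = latent_correlations(),
                          missingness = c(serum_kflc = 0.02, csf_kflc = 0.02,
                                          serum_lflc = 0.02, csf_lflc = 0.02),
                          sigma_scale = 1,
                          pattern_shifts = TRUE,
                          p_female = c(MS = 0.7, CONTROL = 29 / 42),
                          seed = 1L) {
  stopifnot(n_ms >= 1L, n_control >= 1L, sigma_scale >= 0,
            is.data.frame(pattern_frequencies),
            all(c("group", "pattern", "n") %in% names(pattern_frequencies)),
            is.matrix(latent_corr), nrow(latent_corr) == ncol(latent_corr))
  if (any(missingness < 0 | missingness > 1)) stop("missingness rates must be in [0, 1]")
  latent_corr <- nearest_psd(latent_corr)
  if (any(eigen(latent_corr, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
    stop("latent correlation matrix is not repairable to PSD")
  structure(list(n_ms = as.integer(n_ms), n_control = as.integer(n_control),
                 pattern_frequencies = pattern_frequencies, models = models,
                 latent_corr = latent_corr, missingness = missingness,
                 sigma_scale = sigma_scale, pattern_shifts = pattern_shifts,
                 p_female = p_female,
                 pattern_csf_kflc = .pattern_locations(),
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Latent (uncensored) per-pattern CSF kappa-FLC medians. A published
# pattern median exactly at the detection limit is a censored median and
# only upper-bounds the latent location; the conventional LOD/2 stands in.
.pattern_locations <- function() {
  pm <- reference_patterns()$csf_kflc_median
  lod <- flc_lod()[["csf_kflc"]]
  ifelse(pm <= lod, lod / 2, pm)
}

# integer pattern counts for a group of size n, proportional to the
# configured frequencies (largest-remainder rounding)
.pattern_counts <- function(freq, group, n) {
  f <- freq[freq$group == group, ]
  if (!nrow(f)) stop("no pattern frequencies configured for group ", group)
  raw <- f$n / sum(f$n) * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    o <- order(raw - base, decreasing = TRUE)
    base[o[seq_len(rem)]] <- base[o[seq_len(rem)]] + 1
  }
  setNames(base, f$pattern)
}

#' Generate a synthetic cohort
#'
#' Draws one cohort from the configured model: per patient a latent
#' multivariate normal with the configured copula correlations, transformed
#' margin-wise to the group's log-normal analyte distributions; CSF
#' kappa-FLC location shifted to its published per-pattern median when
#' `pattern_shifts` is on; CSF FLC values left-censored at the detection
#' limits via [apply_lod()]; missingness injected completely at random.
#' The same `(config, seed)` always yields a byte-identical cohort.
#'
#' @param config A [cohort_config()] object.
#' @return Validated cohort data frame (internal schema) with
#'   `csf_*_below_lod` flags and a `provenance` attribute.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_config(seed = 7))
#' table(coh$group, coh$ocb_pattern)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  vars <- colnames(config$latent_corr)
  analytes <- setdiff(vars, "age")
  groups <- list(MS = config$n_ms, CONTROL = config$n_control)
  rows <- list()
  for (g in names(groups)) {
    n <- groups[[g]]
    z <- MASS::mvrnorm(n, mu = rep(0, length(vars)), Sigma = config$latent_corr)
    z <- matrix(z, nrow = n, dimnames = list(NULL, vars))
    mods <- config$models[config$models$group == g, ]
    pat <- rep(as.integer(names(.pattern_counts(config$pattern_frequencies, g, n))),
               times = .pattern_counts(config$pattern_frequencies, g, n))
    pat <- sample(pat)   # shuffle pattern assignment across the group
    df <- data.frame(patient_id = sprintf("%s-%03d", ifelse(g == "MS", "MS", "CT"),
                                          seq_len(n)),
                     group = g, ocb_pattern = pat,
                     stringsAsFactors = FALSE)
    for (v in vars) {
      m <- mods[mods$analyte == v, ]
      if (!nrow(m)) stop("no model for ", v, " in group ", g)
      mu <- rep(m$mu, n)
      if (v == "csf_kflc" && isTRUE(config$pattern_shifts))
        mu <- log(config$pattern_csf_kflc[as.character(pat)])
      df[[v]] <- exp(mu + config$sigma_scale * m$sigma * z[, v])
    }
    # adult lumbar-puncture cohort: clamp the log-normal age tails
    df$age <- pmin(pmax(df$age, 16), 95)
    df$sex <- ifelse(runif(n) < config$p_female[[g]], "F", "M")
    rows[[g]] <- df
  }
  coh <- rbind(rows$MS, rows$CONTROL)
  # left-censor CSF FLC at the detection limits
  for (v in names(flc_lod())) {
    cens <- apply_lod(coh[[v]], flc_lod()[[v]])
    coh[[v]] <- cens$value
    coh[[paste0(v, "_below_lod")]] <- cens$below_lod
  }
  # MCAR missingness after censoring; a missing value carries no LOD flag
  for (v in names(config$missingness)) {
    drop <- runif(nrow(coh)) < config$missingness[[v]]
    coh[[v]][drop] <- NA
    flag <- paste0(v, "_below_lod")
    if (!is.null(coh[[flag]])) coh[[flag]][drop] <- FALSE
  }
  coh <- coh[c(cohort_schema()$internal, "csf_kflc_below_lod", "csf_lflc_below_lod")]
  out <- validate_cohort(coh)
  attr(out, "provenance") <- list(seed = config$seed, n_ms = config$n_ms,
                                  n_control = config$n_control,
                                  sigma_scale = config$sigma_scale,
                                  package = paste0("flcindex ",
                                                   as.character(utils::packageVersion("flcindex"))))
  out
}

#' Empirical medians of a generated cohort
#'
#' Round-trip check for the simulator: per-group empirical medians of every
#' analyte and of the four indices, for comparison against the configured
#' targets (the log-normal median is `exp(mu)`).
#'
#' @param cohort A cohort data frame (indices are computed if absent).
#' @return Data frame: `variable`, `group`, `median`, `n`.
#' @export
recover_parameters <- function(cohort) {
  if (is.null(cohort$kflc_index)) cohort <- compute_panel(cohort)
  vars <- c(.analyte_cols(), "kflc_index", "lflc_index", "kigg_index", "ligg_index")
  out <- expand.grid(variable = vars, group = c("MS", "CONTROL"),
                     stringsAsFactors = FALSE)
  out$median <- NA_real_
  out$n <- NA_integer_
  for (i in seq_len(nrow(out))) {
    v <- cohort[[out$variable[i]]][cohort$group == out$group[i]]
    out$median[i] <- median(v, na.rm = TRUE)
    out$n[i] <- sum(!is.na(v))
  }
  out
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("cohort_config: %d MS + %d control, sigma_scale %.2f, seed %d\n",
              x$n_ms, x$n_control, x$sigma_scale, x$seed))
  invisible(x)
}
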