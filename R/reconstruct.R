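#' Round half away from zero
#'
#' Commercial rounding as used by legacy statistics packages when printing
#' percentages (0.68293 -> 68.3, 0.9355 -> 93.5 at one decimal), as opposed
#' to R's banker's rounding. The reconstruction machinery matches published
#' tables under this convention by default.
#'
#' @param x Numeric vector.
#' @param decimals Number of decimal places.
#' @param convention `"half_away"` (default) or `"half_even"`
#'   (base [round()], with a warning: published clinical tables normally use
#'   half-away).
#' @return Rounded vector.
#' @export
round_half_away <- function(x, decimals = 1L, convention = c("half_away", "half_even")) {
  convention <- match.arg(convention)
  if (convention == "half_even") {
    warning("half-even rounding rarely matches published clinical tables")
    return(round(x, decimals))
  }
  s <- 10^decimals
  sign(x) * floor(abs(x) * s + 0.5) / s
}

#' Printed-style metrics of a confusion matrix
#'
#' Exact rational computation of sensitivity, specificity, PPV, NPV and
#' accuracy as percentages, then rounding to the stated number of decimals —
#' the forward direction of [reconstruct_confusion()]. A metric with a zero
#' denominator is returned `NA` (undefined), never NaN.
#'
#' @param tp,fn,tn,fp Nonnegative integer confusion counts.
#' @param decimals Decimals as printed (default 1).
#' @param convention Rounding convention, see [round_half_away()].
#' @return Named numeric vector `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy` (percent, rounded).
#' @export
#' @examples
#' derive_metrics(23, 9, 27, 15)  # sens 71.9, spec 64.3, ppv 60.5 ...
derive_metrics <- function(tp, fn, tn, fp, decimals = 1L,
                           convention = "half_away") {
  cm <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(cm < 0) || any(cm != floor(cm))) stop("counts must be nonnegative integers")
  round_half_away(.confusion_metrics(cm), decimals, convention)
}

#' Reconstruct confusion matrices from rounded published metrics
#'
#' Exhaustively searches every integer confusion matrix with `1 <= tp + fn
#' <= max_pos` and `1 <= tn + fp <= max_neg` and keeps those whose exactly
#' computed metrics, rounded half-away-from-zero to the stated decimals,
#' equal every supplied printed value. Totals below the caps are allowed:
#' the effective n of a published row may be smaller than the enrolled group
#' sizes when some patients have a missing index. An empty solution set is a
#' meaningful outcome — it proves the printed metrics are mutually
#' inconsistent at the stated group sizes.
#'
#' @param constraints Named list/vector of printed percentages; names among
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`.
#' @param max_pos,max_neg Caps on the diseased / control group sizes
#'   (defaults 34 and 42, the cohort composition the package's simulator
#'   emulates).
#' @param decimals Printed precision (default 1).
#' @param convention Rounding convention, see [round_half_away()].
#' @return Object of class `reconstruction`: data frame `solutions` with
#'   columns `tp`, `fn`, `tn`, `fp` plus the five derived (rounded) metrics,
#'   and flag `unique`.
#' @export
#' @examples
#' reconstruct_confusion(c(sensitivity = 90.3, specificity = 80.5))
reconstruct_confusion <- function(constraints, max_pos = 34L, max_neg = 42L,
                                  decimals = 1L, convention = "half_away") {
  constraints <- as.list(constraints)
  allowed <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
  if (!length(constraints) || is.null(names(constraints)) ||
      !all(names(constraints) %in% allowed))
    stop("constraints must be named among: ", paste(allowed, collapse = ", "))
  stopifnot(max_pos >= 1L, max_neg >= 1L)
  pos <- do.call(rbind, lapply(1:max_pos, function(P) cbind(tp = 0:P, fn = P - (0:P))))
  neg <- do.call(rbind, lapply(1:max_neg, function(N) cbind(tn = 0:N, fp = N - (0:N))))
  g <- cbind(pos[rep(seq_len(nrow(pos)), times = nrow(neg)), ],
             neg[rep(seq_len(nrow(neg)), each = nrow(pos)), ])
  g <- as.data.frame(g)
  fml <- list(
    sensitivity = function(g) 100 * g$tp / (g$tp + g$fn),
    specificity = function(g) 100 * g$tn / (g$tn + g$fp),
    ppv = function(g) 100 * g$tp / (g$tp + g$fp),
    npv = function(g) 100 * g$tn / (g$tn + g$fn),
    accuracy = function(g) 100 * (g$tp + g$tn) / (g$tp + g$fn + g$tn + g$fp))
  keep <- rep(TRUE, nrow(g))
  for (nm in names(constraints)) {
    v <- fml[[nm]](g)
    keep <- keep & !is.na(v) &
      round_half_away(v, decimals, convention) == constraints[[nm]]
  }
  sol <- g[keep, , drop = FALSE]
  if (nrow(sol)) {
    for (nm in allowed)
      sol[[nm]] <- round_half_away(fml[[nm]](sol), decimals, convention)
    sol <- sol[order(sol$tp + sol$fn + sol$tn + sol$fp), , drop = FALSE]
    rownames(sol) <- NULL
  }
  structure(list(solutions = sol, unique = nrow(sol) == 1L,
                 constraints = constraints,
                 caps = c(max_pos = max_pos, max_neg = max_neg)),
            class = "reconstruction")
}

#' @export
print.reconstruction <- function(x, ...) {
  cat(sprintf("constraints: %s  (caps %d/%d)\n",
              paste(names(x$constraints), unlist(x$constraints),
                    sep = "=", collapse = ", "),
              x$caps[["max_pos"]], x$caps[["max_neg"]]))
  if (!nrow(x$solutions)) {
    cat("no integer confusion matrix satisfies all constraints\n")
  } else {
    cat(nrow(x$solutions), if (x$unique) "solution (unique):\n" else "solutions:\n")
    print(x$solutions, row.names = FALSE)
  }
  invisible(x)
}
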