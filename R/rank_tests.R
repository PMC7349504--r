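#' Average ranks with midrank ties
#'
#' Ranks 1..n where tied values share the mean of the rank positions they
#' occupy (midranks). This is the shared primitive under every rank test in
#' the package; the rank sum is always n(n+1)/2.
#'
#' @param values Nonempty numeric vector without `NA`.
#' @return Numeric vector of ranks.
#' @export
#' @examples
#' rank_average_ties(c(3, 1, 3, 2))  # 3.5 1.0 3.5 2.0
rank_average_ties <- function(values) {
  n <- length(values)
  if (n == 0L) stop("cannot rank an empty vector")
  if (anyNA(values)) stop("NA values cannot be ranked")
  o <- order(values)
  sorted <- values[o]
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && sorted[j + 1L] == sorted[i]) j <- j + 1L
    r[o[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

# tie term sum(t^3 - t) over groups of tied values
.tie_term <- function(values) {
  t <- table(values)
  sum(t^3 - t)
}

#' Mann-Whitney U test
#'
#' Two-sample rank test for a location difference. The reported statistic is
#' `min(U_x, U_y)`. For small tie-free samples (`n1 + n2 <= 16`) the
#' two-sided p-value is exact, by full enumeration of all rank assignments;
#' otherwise the normal approximation with tie-corrected variance and an
#' optional 0.5 continuity correction is used.
#'
#' @param x,y Numeric samples, at least one observation each (`NA` dropped).
#' @param continuity Apply the 0.5 continuity correction in the normal
#'   approximation (default `TRUE`).
#' @param exact `NULL` (default) picks the exact enumeration automatically
#'   for tie-free pooled samples of at most 16; `TRUE` forces it (errors on
#'   ties); `FALSE` forces the normal approximation.
#' @return Object of class `rank_test`: list with `statistic_name = "U"`,
#'   `statistic`, `effective_n`, `p_value`, `tie_correction_applied`,
#'   `method` ("exact" or "normal").
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # exact p = 0.100
mann_whitney_u <- function(x, y, continuity = TRUE, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both samples must be nonempty")
  pooled <- c(x, y)
  r <- rank_average_ties(pooled)
  ux <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  uy <- n1 * n2 - ux
  u <- min(ux, uy)
  ties <- .tie_term(pooled) > 0
  n <- n1 + n2
  use_exact <- if (is.null(exact)) !ties && n <= 16L else isTRUE(exact)
  if (isTRUE(exact) && ties)
    stop("exact enumeration is only defined for tie-free samples")
  if (use_exact) {
    # exact: U distribution over all C(n, n1) assignments of ranks to x
    sets <- combn(n, n1)
    uall <- colSums(matrix(seq_len(n)[sets], nrow = n1)) - n1 * (n1 + 1) / 2
    umin <- pmin(uall, n1 * n2 - uall)
    p <- mean(umin <= u + 1e-9)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    sigma2 <- n1 * n2 / 12 * ((n + 1) - .tie_term(pooled) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      cc <- if (continuity) 0.5 else 0
      z <- (abs(u - mu) - cc) / sqrt(sigma2)
      z <- max(z, 0)
      p <- min(1, 2 * pnorm(-z))
    }
    method <- "normal"
  }
  structure(list(statistic_name = "U", statistic = u,
                 effective_n = c(n1 = n1, n2 = n2), p_value = p,
                 tie_correction_applied = ties, method = method),
            class = "rank_test")
}

#' Kruskal-Wallis rank test
#'
#' k-sample extension of the rank test, with the standard tie correction
#' `H / (1 - sum(t^3 - t) / (N^3 - N))` and a chi-square reference
#' distribution on k - 1 degrees of freedom. When every pooled value is
#' tied the statistic is defined as 0 with p = 1.
#'
#' @param groups List of at least two nonempty numeric samples (`NA` dropped).
#' @return Object of class `rank_test` with `statistic_name = "H"` and a
#'   `df` element.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2), c(3, 4), c(5, 6)))  # H = 4.571
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  k <- length(groups)
  if (k < 2L) stop("need at least two groups")
  if (any(lengths(groups) == 0L)) stop("every group must be nonempty")
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- rank_average_ties(pooled)
  idx <- rep(seq_len(k), lengths(groups))
  rsum <- tapply(r, idx, sum)
  h <- 12 / (n * (n + 1)) * sum(rsum^2 / lengths(groups)) - 3 * (n + 1)
  tt <- .tie_term(pooled)
  denom <- 1 - tt / (n^3 - n)
  ties <- tt > 0
  if (denom <= 0) {           # all values identical
    h <- 0; p <- 1
  } else {
    h <- h / denom
    h <- max(h, 0)            # guard tiny negative rounding
    p <- pchisq(h, df = k - 1, lower.tail = FALSE)
  }
  structure(list(statistic_name = "H", statistic = h, df = k - 1,
                 effective_n = lengths(groups), p_value = p,
                 tie_correction_applied = ties),
            class = "rank_test")
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Follow-up to [kruskal_wallis()]: pairwise z statistics on the pooled-rank
#' means with tie-corrected variance, two-sided p-values Bonferroni-adjusted
#' by the number of pairs k(k-1)/2 and capped at 1.
#'
#' @param groups Named list of numeric samples (`NA` dropped). Unnamed lists
#'   get labels `"1"`, `"2"`, ...
#' @return Data frame with columns `group_a`, `group_b`, `z`, `p_raw`,
#'   `adjusted_p`.
#' @export
dunn_posthoc <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  k <- length(groups)
  if (k < 2L) stop("need at least two groups")
  if (is.null(names(groups))) names(groups) <- as.character(seq_len(k))
  pooled <- unlist(groups, use.names = FALSE)
  n <- length(pooled)
  r <- rank_average_ties(pooled)
  idx <- rep(seq_len(k), lengths(groups))
  rmean <- tapply(r, idx, mean)
  sizes <- lengths(groups)
  tiev <- .tie_term(pooled) / (12 * (n - 1))
  base_var <- n * (n + 1) / 12 - tiev
  pairs <- combn(k, 2)
  m <- ncol(pairs)
  res <- data.frame(group_a = names(groups)[pairs[1, ]],
                    group_b = names(groups)[pairs[2, ]],
                    z = NA_real_, p_raw = NA_real_, adjusted_p = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(m)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(base_var * (1 / sizes[a] + 1 / sizes[b]))
    z <- if (se > 0) (rmean[a] - rmean[b]) / se else 0
    p <- 2 * pnorm(-abs(z))
    res$z[j] <- z
    res$p_raw[j] <- p
    res$adjusted_p[j] <- min(1, p * m)
  }
  res
}

#' Spearman rank correlation
#'
#' rho is the Pearson correlation of midranks; the p-value uses the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees
#' of freedom, with p = 0 when |rho| = 1. Pairs with a missing member are
#' dropped first (pairwise-complete).
#'
#' @param x,y Paired numeric samples; at least 3 complete pairs.
#' @return Object of class `rank_test` with `statistic_name = "rho"`.
#' @export
#' @examples
#' spearman(c(1, 2, 3, 4), c(8, 6, 4, 2))  # rho = -1
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  rx <- rank_average_ties(x); ry <- rank_average_ties(y)
  dx <- rx - mean(rx); dy <- ry - mean(ry)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) stop("a sample with all values tied has no rank correlation")
  rho <- sum(dx * dy) / den
  rho <- max(-1, min(1, rho))
  ties <- .tie_term(x) > 0 || .tie_term(y) > 0
  if (abs(rho) >= 1 - 1e-12) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(statistic_name = "rho", statistic = rho,
                 effective_n = c(n = n), p_value = p,
                 tie_correction_applied = ties),
            class = "rank_test")
}

#' Pairwise-complete Spearman correlation matrix
#'
#' Correlation structure of a set of cohort variables: for each pair of
#' columns, pairs with a missing member are dropped and [spearman()] is run
#' on the rest. Cells with fewer than `min_pairs` complete pairs are left
#' missing.
#'
#' @param data Data frame of numeric columns.
#' @param variables Character vector of column names (default: all columns).
#' @param min_pairs Minimum complete pairs per cell (default 3).
#' @return Object of class `correlation_matrix`: list of symmetric matrices
#'   `rho` (unit diagonal), `p`, and `n` (pairwise effective n).
#' @export
correlation_matrix <- function(data, variables = names(data), min_pairs = 3L) {
  stopifnot(all(variables %in% names(data)))
  k <- length(variables)
  rho <- p <- nn <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(rho) <- 1
  diag(p) <- 0
  for (v in variables) nn[v, v] <- sum(!is.na(data[[v]]))
  if (k >= 2) for (i in 1:(k - 1)) for (j in (i + 1):k) {
    x <- data[[variables[i]]]; y <- data[[variables[j]]]
    ok <- sum(!is.na(x) & !is.na(y))
    nn[i, j] <- nn[j, i] <- ok
    if (ok >= min_pairs) {
      st <- tryCatch(spearman(x, y), error = function(e) NULL)
      if (!is.null(st)) {
        rho[i, j] <- rho[j, i] <- st$statistic
        p[i, j] <- p[j, i] <- st$p_value
      }
    }
  }
  structure(list(rho = rho, p = p, n = nn), class = "correlation_matrix")
}

#' @export
print.rank_test <- function(x, ...) {
  cat(sprintf("%s = %.4g, n = [%s], p = %.4g%s\n", x$statistic_name,
              x$statistic, paste(x$effective_n, collapse = ", "), x$p_value,
              if (isTRUE(x$tie_correction_applied)) " (tie-corrected)" else ""))
  invisible(x)
}
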