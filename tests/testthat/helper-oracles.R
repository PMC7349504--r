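# Independent brute-force oracles used across the suite.

# Full-permutation two-sided Mann-Whitney p for tie-free samples:
# distribution of min(U_x, U_y) over all C(n1+n2, n1) rank assignments.
permutation_mw_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  stopifnot(!any(duplicated(r)))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  u_obs <- min(u_obs, n1 * (n - n1) - u_obs)
  sets <- combn(n, n1)
  u <- colSums(matrix(seq_len(n)[sets], nrow = n1)) - n1 * (n1 + 1) / 2
  u <- pmin(u, n1 * (n - n1) - u)
  mean(u <= u_obs + 1e-9)
}

# Two-step Spearman oracle: rank with base R, then Pearson with base R.
rank_pearson_rho <- function(x, y) {
  stats::cor(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# A tiny fully deterministic cohort for plumbing tests: the trivial values
# of the index formulas so every quotient/index is known in closed form.
trivial_cohort <- function() {
  data.frame(
    patient_id = c("P1", "P2"), group = c("MS", "CONTROL"),
    ocb_pattern = c(2L, 1L), age = c(30, 50), sex = c("F", "M"),
    serum_albumin = 1.0, csf_albumin = 1000.0,
    serum_igg = 1.0, csf_igg = 100.0,
    serum_iga = 2.0, csf_iga = 4.0,
    serum_igm = 1.0, csf_igm = 2.0,
    serum_kflc = 1.0, csf_kflc = 1.0,
    serum_lflc = 1.0, csf_lflc = 1.0,
    stringsAsFactors = FALSE)
}
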