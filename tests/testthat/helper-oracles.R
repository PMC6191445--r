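# Independent statistical oracles: full enumeration for the rank tests and
# the permutation t, definitional sums of squares for the ANOVA F.

enumerate_mw_p <- function(a, b) {
  # exact two-sided Mann-Whitney p by enumerating all group assignments
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  U_of <- function(idx) {
    av <- pooled[idx]; bv <- pooled[-idx]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  splits <- utils::combn(n, na)
  Us <- apply(splits, 2, U_of)
  U_obs <- U_of(seq_len(na))
  p_low <- mean(Us <= U_obs); p_high <- mean(Us >= U_obs)
  min(1, 2 * min(p_low, p_high))
}

perm_t <- function(a, b) {
  pooled <- c(a, b); na <- length(a)
  tstat <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sp <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    (mean(x) - mean(y)) / sqrt(sp * (1 / length(x) + 1 / length(y)))
  }
  splits <- utils::combn(length(pooled), na)
  ts <- apply(splits, 2, tstat)
  t_obs <- tstat(seq_len(na))
  list(t_obs = t_obs, p = mean(abs(ts) >= abs(t_obs) - 1e-12))
}

anova_F_oracle <- function(groups) {
  all <- unlist(groups); gm <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gm)^2, 0))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  dfb <- length(groups) - 1; dfw <- length(all) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}
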