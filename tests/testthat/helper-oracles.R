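# Independent brute-force oracles, kept deliberately naive and separate
# from the implementation paths they check.

# Exact Mann-Whitney p by enumerating every C(n+m, n) assignment of the
# pooled observations to the first group. Handles ties naturally.
enumerate_mw_p <- function(x, y, alternative = "two.sided") {
  n <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  u_all <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n * (n + 1) / 2
  })
  lower <- mean(u_all <= u_obs + 1e-9)
  upper <- mean(u_all >= u_obs - 1e-9)
  switch(alternative,
         greater = upper,
         less = lower,
         two.sided = min(1, 2 * min(lower, upper)))
}

# BH step-up by the textbook definition: q_(i) = min_{j >= i} p_(j) * m / j,
# computed with explicit loops over the sorted vector.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  out <- numeric(m)
  out[o] <- q
  out
}

# Spearman rho as Pearson on average ranks, straight from the definition.
spearman_oracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  stats::cor(rank(x[ok]), rank(y[ok]))
}

# Hypergeometric one-tailed p by summing the pmf over the support.
hyper_tail_oracle <- function(a, b, c, d) {
  k <- a + c
  support <- max(0, k - (c + d)):min(k, a + b)
  pmf <- choose(a + b, support) * choose(c + d, k - support) /
    choose(a + b + c + d, k)
  sum(pmf[support >= a])
}

# A tiny deterministic cohort with hand-placed effects, for unit tests that
# need full control over group values.
tiny_samples <- function(n_tumor = 4, n_normal = 4, tissues = "skin") {
  purrr::map_dfr(tissues, function(tis) {
    tibble::tibble(
      sample_id = sprintf("%s_%s%d", tis,
                          rep(c("t", "n"), c(n_tumor, n_normal)),
                          c(seq_len(n_tumor), seq_len(n_normal))),
      tissue = tis,
      condition = rep(c("tumor", "normal"), c(n_tumor, n_normal))
    )
  })
}

tiny_psi_matrix <- function(values, exon_ids, sample_ids) {
  m <- matrix(values, nrow = length(exon_ids), byrow = TRUE,
              dimnames = list(exon_ids, sample_ids))
  omics_matrix(m, "psi")
}
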