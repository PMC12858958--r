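# independent oracles used across test files

# brute-force AUC: all case-control pairs, ties counted one half
brute_force_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  s1 <- scores[labels]; s0 <- scores[!labels]
  tot <- 0
  for (a in s1) tot <- tot + sum(a > s0) + 0.5 * sum(a == s0)
  tot / (length(s1) * length(s0))
}

# Monte-Carlo draw from the bivariate-normal liability model
draw_liability <- function(n, rho, K, seed) {
  set.seed(seed)
  L <- rnorm(n)
  Z <- rho * L + sqrt(1 - rho^2) * rnorm(n)
  data.frame(z = Z, case = L > qnorm(1 - K))
}

# empirical AUC of z for case status (rank formula, independent of auc())
empirical_auc <- function(z, case) {
  r <- rank(z); n1 <- sum(case); n0 <- sum(!case)
  (sum(r[case]) - n1 * (n1 + 1) / 2) / (as.numeric(n1) * n0)
}

# one-band rate table shorthand
one_band <- function(lc, ld, lo = 0, hi = 100)
  rate_table(lo, hi, lc, ld)

# scores with a known true AUC under the binormal shift model
binormal_scores <- function(n1, n0, auc_true) {
  d <- sqrt(2) * qnorm(auc_true)
  list(scores = c(rnorm(n1, mean = d), rnorm(n0)),
       labels = c(rep(TRUE, n1), rep(FALSE, n0)))
}
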