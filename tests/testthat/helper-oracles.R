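# Independent brute-force oracles used to cross-check the statistical
# routines. These deliberately share no code with the implementation.

# Two-sided Fisher exact p for a 2x2 table by full hypergeometric
# enumeration: sum the probabilities of all tables with the same margins
# whose probability does not exceed (1 + eps) x that of the observed table.
fisher_enum_oracle <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)))
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lp <- function(a) {
    lchoose(r1, a) + lchoose(n - r1, c1 - a) - lchoose(n, c1)
  }
  a_range <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- exp(lp(a_range))
  obs <- exp(lp(tab[1, 1]))
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# One-sided exact binomial tail P(X >= k), X ~ Binomial(n, 1/2), by direct
# summation of the mass function.
binom_tail_oracle <- function(k, n) {
  sum(choose(n, k:n)) / 2^n
}

# Exact two-sided Mann-Whitney p for tie-free samples by enumerating every
# labeling of the pooled values.
mw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  stopifnot(!anyDuplicated(pooled))
  n1 <- length(x)
  u_stat <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_stat(x, y)
  m <- length(pooled)
  combs <- utils::combn(m, n1)
  u_all <- apply(combs, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  # two-sided: as extreme in either direction
  mu <- n1 * (m - n1) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Probability that the min-max intervals of two iid continuous samples are
# disjoint: the top n1 or top n2 order statistics must all come from one
# group.
null_deg_rate <- function(n1, n2) 2 / choose(n1 + n2, n1)

# Small six-phenotype count set used across tests.
toy_counts <- function(n_features = 60, reps = c(EQ = 3, EW = 3, MQ = 3,
                                                 MW = 2, LQ = 3, LW = 3),
                       seed = 42) {
  d <- sim_design(n_features = n_features, replicates = reps,
                  depth_range = c(2e4, 3e4),
                  de_spec = data.frame(stage = "mid", direction = "Q",
                                       n = 5, lfc = 4, dispersion = 0.05),
                  seed = seed)
  simulate_counts(d)
}
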