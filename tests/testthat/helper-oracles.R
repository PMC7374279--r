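# Independent brute-force oracles, coded directly from the defining
# formulas and kept free of any package internals.

# BH step-up from the definition: sort, take the running minimum of
# p_(j) * m / j from the largest rank downwards, clip at 1, restore order.
bh_brute <- function(p, m = length(p)) {
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- numeric(n)
  for (i in seq_len(n)) {
    q[i] <- min(1, min(ps[i:n] * m / (i:n)))
  }
  out <- numeric(n)
  out[o] <- q
  out
}

# Inverse-variance FEM, Cochran's Q, clamped I^2, DerSimonian-Laird tau^2
# and REM pool, written as plain loops over the textbook formulas.
meta_brute <- function(y, v) {
  k <- length(y)
  w <- 1 / v
  pooled_fem <- sum(w * y) / sum(w)
  var_fem <- 1 / sum(w)
  if (k == 1) {
    # single-study convention: no heterogeneity is estimable
    return(list(pooled_fem = pooled_fem, var_fem = var_fem, Q = 0, df = 0,
                ISq = 0, p_Q = 1, tau2 = 0, pooled_rem = pooled_fem,
                var_rem = var_fem))
  }
  Q <- 0
  for (i in seq_len(k)) Q <- Q + w[i] * (y[i] - pooled_fem)^2
  df <- k - 1
  ISq <- if (Q <= df) 0 else 100 * (Q - df) / Q
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (k < 2 || denom <= 0) 0 else max(0, (Q - df) / denom)
  ws <- 1 / (v + tau2)
  pooled_rem <- sum(ws * y) / sum(ws)
  var_rem <- 1 / sum(ws)
  list(pooled_fem = pooled_fem, var_fem = var_fem, Q = Q, df = df,
       ISq = ISq, p_Q = if (k < 2) 1 else pchisq(Q, df, lower.tail = FALSE),
       tau2 = tau2, pooled_rem = pooled_rem, var_rem = var_rem)
}

# Naive per-variant interval scan.
match_brute <- function(variants, locus) {
  hit <- logical(nrow(variants))
  for (i in seq_len(nrow(variants))) {
    hit[i] <- variants$CHR[i] == locus$chromosome &&
      variants$BP[i] >= locus$start_bp && variants$BP[i] <= locus$end_bp
  }
  variants[hit, , drop = FALSE]
}

# OLS through the normal equations, solved by explicit inversion.
ols_brute <- function(y, X) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Small simulated meta-analysis: k studies, per-group samples, true effect
# theta, homogeneous (tau2 = 0). Returns observed effects and estimated
# Welch variances.
simulate_meta_effects <- function(k, n_per_group, theta, sigma = 1) {
  case <- matrix(rnorm(k * n_per_group, theta, sigma), nrow = k)
  ctrl <- matrix(rnorm(k * n_per_group, 0, sigma), nrow = k)
  y <- rowMeans(case) - rowMeans(ctrl)
  v <- apply(case, 1, var) / n_per_group + apply(ctrl, 1, var) / n_per_group
  list(y = y, v = v)
}
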