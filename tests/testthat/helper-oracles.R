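# Independent oracles used across the suite. These deliberately re-derive
# each quantity with different code paths (explicit loops, enumeration,
# literal formula transcription) so they stay independent of the package
# implementation they check.

# Literal step-by-step RUV-III transcription: residualize replicates, SVD,
# loadings, control restriction, factor estimate, subtraction.
ruv3_oracle <- function(Y, M, ctl, k) {
  Y0 <- Y - M %*% solve(t(M) %*% M) %*% t(M) %*% Y
  U <- svd(Y0)$u[, seq_len(k), drop = FALSE]
  fullalpha <- t(U) %*% Y
  ac <- fullalpha[, ctl, drop = FALSE]
  W <- Y[, ctl, drop = FALSE] %*% t(ac) %*% solve(ac %*% t(ac))
  Y - W %*% fullalpha
}

# Brute-force between-unit variance of replicate-averaged expression.
between_unit_variance <- function(Y, sample_unit) {
  units <- unique(sample_unit)
  means <- sapply(seq_len(ncol(Y)), function(j)
    sapply(units, function(u) mean(Y[sample_unit == u, j])))
  apply(means, 2, var)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments.
signed_rank_enum_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  Vs <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(Vs >= V), mean(Vs <= V)))
}

# Exact two-sided rank-sum p by enumerating all group-1 rank subsets.
rank_sum_enum_p <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  W <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  idx <- utils::combn(m + n, m)
  Ws <- apply(idx, 2, function(i) sum(r[i])) - m * (m + 1) / 2
  min(1, 2 * min(mean(Ws >= W), mean(Ws <= W)))
}

# Exhaustive hypergeometric upper tail: enumerate every n-subset of the
# universe and count overlaps at least as large as observed.
hyper_enum_p <- function(N, K, n, x) {
  draws <- utils::combn(N, n)
  inset <- seq_len(K)
  overlaps <- apply(draws, 2, function(d) sum(d %in% inset))
  mean(overlaps >= x)
}

# A subtype_result built by hand (for call-level operations that do not
# need a trained classifier behind them).
make_subtype_result <- function(units, calls, scheme = "tcga") {
  res <- data.frame(unit = units, call = calls, row.names = NULL)
  attr(res, "scheme") <- scheme
  class(res) <- c("subtype_result", "data.frame")
  res
}

# Random RUV-III problem instance with replicated units.
random_ruv3_instance <- function(seed, n_max = 30, p_max = 120) {
  set.seed(seed)
  n <- sample(8:n_max, 1)
  p <- sample(20:p_max, 1)
  n_rep <- if (n %/% 3 <= 2) 2 else sample(2:(n %/% 3), 1)  # duplicated units
  units <- c(rep(seq_len(n_rep), each = 2),
             n_rep + seq_len(n - 2 * n_rep))
  samples <- sprintf("S%02d", seq_len(n))
  design <- replicate_design(samples, paste0("U", units))
  Y <- matrix(rnorm(n * p, 8, 1), n, p,
              dimnames = list(samples, sprintf("G%03d", seq_len(p))))
  ctl <- sort(sample(p, max(3, p %/% 5)))
  k <- sample(1:2, 1)
  list(Y = Y, design = design, ctl = ctl, k = k)
}
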