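# RUV-III, negative-control selection, replicate diagnostics and FSQN.

test_that("negative controls are the lowest between-unit-variance genes", {
  set.seed(21)
  n_units <- 10; p <- 100
  samples <- sprintf("S%02d", seq_len(2 * n_units))
  units <- rep(sprintf("U%02d", seq_len(n_units)), each = 2)
  design <- replicate_design(samples, units)
  # genes 1-10 carry a strong unit-level signal, genes 91-100 are flat
  unit_signal <- rnorm(n_units, 0, 3)
  Y <- matrix(rnorm(length(samples) * p, 8, 0.1), length(samples), p,
              dimnames = list(samples, sprintf("G%03d", seq_len(p))))
  Y[, 1:10] <- Y[, 1:10] + unit_signal[match(units, unique(units))]
  Y[, 11:90] <- Y[, 11:90] +
    0.5 * matrix(rnorm(length(samples) * 80), length(samples), 80)

  ctl <- select_negative_controls(Y, design, fraction = 0.1)
  expect_length(ctl, 10)
  expect_true(all(ctl > 10))  # never the signal genes

  # agrees with the brute-force between-unit variance ranking
  v <- between_unit_variance(Y, units)
  expect_setequal(unname(ctl), order(v)[1:10])
})

test_that("control selection handles ceilings, ties and filters", {
  samples <- paste0("s", 1:4)
  design <- replicate_design(samples, c("u1", "u1", "u2", "u2"))
  Y <- matrix(5, 4, 6, dimnames = list(samples, paste0("g", 6:1)))

  # ceiling(0.01 * 6) = 1 control; all-identical genes tie-break by name
  ctl <- select_negative_controls(Y, design, fraction = 0.16)
  expect_equal(names(ctl), "g1")

  expect_error(select_negative_controls(Y, design, fraction = 0),
               "fraction")
  expect_error(select_negative_controls(Y, design, fraction = 0.2, lod = 10),
               "lower the lod")
})

test_that("ruv3_normalize matches the step-by-step linear-algebra oracle", {
  for (seed in 31:35) {
    inst <- random_ruv3_instance(seed)
    fit <- ruv3_normalize(inst$Y, inst$design, inst$ctl, inst$k)
    M <- inst$design$M[rownames(inst$Y), ]
    M <- M[, colSums(M) > 0]
    expect_lt(max(abs(fit$Y - ruv3_oracle(inst$Y, M, inst$ctl, inst$k))),
              1e-8)
    expect_equal(dim(fit$Y), dim(inst$Y))
  }
})

test_that("ruv3 edge cases: k = 0 identity, identical replicates, bad k", {
  inst <- random_ruv3_instance(36)
  expect_identical(ruv3_normalize(inst$Y, inst$design, inst$ctl, 0)$Y,
                   inst$Y)

  # all samples identical replicates of one unit: Y0 = 0, data unchanged
  samples <- paste0("s", 1:4)
  one <- replicate_design(samples, rep("u", 4))
  Yc <- matrix(rep(rnorm(20, 8), each = 4), 4, 20,
               dimnames = list(samples, paste0("g", 1:20)))
  expect_equal(ruv3_normalize(Yc, one, 1:5, 1)$Y, Yc)

  expect_error(ruv3_normalize(inst$Y, inst$design, inst$ctl,
                              k = nrow(inst$Y)), "rank")
})

test_that("ruv3 shrinks technical-replicate disagreement on planted batches", {
  for (seed in 41:43) {
    cfg <- sim_config(seed = seed, n_units = 20, replicate_units = 6,
                      batch_magnitude = 1.5)
    run <- simulate_panel_run(cfg)
    Y <- log2_expression(run$pcm)
    ctl <- run$truth$flat_genes
    before <- replicate_log_difference(Y, run$design)
    after <- replicate_log_difference(
      ruv3_normalize(Y, run$design, match(ctl, colnames(Y)), 1)$Y,
      run$design)
    expect_lt(after$median_abs, before$median_abs)
    expect_lt(mean(abs(after$differences)),
              0.5 * mean(abs(before$differences)))
  }
})

test_that("replicate_log_difference reports exact pairwise differences", {
  samples <- c("a1", "a2", "b")
  design <- replicate_design(samples, c("u1", "u1", "u2"))
  Y <- matrix(c(5, 5, 7), 3, 4, dimnames = list(samples, paste0("g", 1:4)))
  d <- replicate_log_difference(Y, design)
  expect_true(all(d$differences == 0))

  Y["a2", ] <- Y["a2", ] + 1
  d2 <- replicate_log_difference(Y, design)
  expect_true(all(abs(d2$differences) == 1))
  expect_equal(d2$median_abs, 1)

  no_rep <- replicate_design(samples, c("u1", "u2", "u3"))
  expect_error(replicate_log_difference(Y, no_rep), "replicate")
})

test_that("the k sweep diagnostic covers k = 0 .. k_max", {
  inst <- random_ruv3_instance(44)
  sw <- ruv3_k_sweep(inst$Y, inst$design, inst$ctl, k_max = 2)
  expect_equal(sw$k, 0:2)
  expect_true(all(is.finite(sw$median_abs_diff)))
})

test_that("fsqn maps test values onto interpolated target quantiles", {
  test <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "g"))
  target <- matrix(c(10, 20, 30, 40), 4, 1, dimnames = list(NULL, "g"))
  out <- fsqn(test, target)
  # independent quantile oracle at probabilities {0, 0.5, 1}
  expect_equal(as.numeric(out), c(10, 25, 40))

  # constant target collapses the gene to that value
  const <- matrix(7, 4, 1, dimnames = list(NULL, "g"))
  expect_equal(as.numeric(fsqn(test, const)), c(7, 7, 7))

  expect_error(fsqn(matrix(1:4, 2, dimnames = list(NULL, c("g", "h"))),
                    target), "absent in target")
})

test_that("fsqn output multiset equals the target quantiles and is idempotent", {
  set.seed(45)
  for (rep in 1:10) {
    n <- sample(3:12, 1); N <- sample(5:30, 1); p <- sample(2:6, 1)
    test <- matrix(rnorm(n * p), n, p,
                   dimnames = list(NULL, paste0("g", 1:p)))
    target <- matrix(rnorm(N * p, 2, 3), N, p,
                     dimnames = list(NULL, paste0("g", 1:p)))
    out <- fsqn(test, target)
    for (j in seq_len(p)) {
      q <- unname(quantile(target[, j], probs = seq(0, 1, length.out = n),
                           type = 7))
      expect_lt(max(abs(sort(out[, j]) - q)), 1e-12)
      # rank preservation
      expect_equal(rank(out[, j]), rank(test[, j]))
    }
    expect_equal(fsqn(out, target), out)
  }
})

test_that("tied test values receive the mean of their mapped quantiles", {
  test <- matrix(c(1, 1, 2), 3, 1, dimnames = list(NULL, "g"))
  target <- matrix(c(0, 10, 20, 30), 4, 1, dimnames = list(NULL, "g"))
  out <- fsqn(test, target)
  # quantiles at {0, .5, 1} are 0, 15, 30; the tied pair shares (0+15)/2
  expect_equal(as.numeric(out), c(7.5, 7.5, 30))
})
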