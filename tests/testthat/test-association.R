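# Concordance, paired/rank tests, proportion comparisons and the
# drug-association pooling.

test_that("categorical concordance reproduces printed percentages", {
  parent <- c(rep("Low", 9), "Low", "High")
  organoid <- c(rep("Low", 9), "High", "Low")
  cc <- categorical_concordance(parent, organoid)
  expect_equal(cc$percent, 81.8)  # 9 of 11
  expect_equal(cc$n_matched, 9)

  parent2 <- c(rep("CIN", 7), rep("GS", 4))
  organoid2 <- c(rep("CIN", 7), rep("CIN", 4))
  expect_equal(categorical_concordance(parent2, organoid2)$percent, 63.6)

  expect_equal(categorical_concordance(parent, parent)$percent, 100.0)

  # symmetric in the pair
  sw <- categorical_concordance(organoid, parent)
  expect_equal(sw$percent, cc$percent)

  expect_error(categorical_concordance(character(0), character(0)),
               "non-empty")
})

test_that("paired signed-rank p matches exhaustive sign enumeration", {
  set.seed(81)
  for (rep in 1:5) {
    a <- rnorm(6); b <- a + rnorm(6, 0.3)
    while (any(b - a == 0) || anyDuplicated(abs(b - a)))
      b <- a + rnorm(6, 0.3)
    r <- paired_score_test(a, b)
    expect_true(r$exact)
    expect_equal(r$p, signed_rank_enum_p(b - a), tolerance = 1e-12)
  }

  # extreme ordering: all organoid scores larger, n = 11
  a <- 1:11 / 20
  b <- a + runif(11, 0.01, 0.05)
  r <- paired_score_test(a, b)
  expect_equal(r$p, 2 / 2^11, tolerance = 1e-12)

  # all-zero differences are degenerate, p = 1, flagged
  z <- paired_score_test(a, a)
  expect_true(z$degenerate)
  expect_equal(z$p, 1)
})

test_that("proportion comparison equals the closed-form 2x2 chi-square", {
  tab <- c(a = 30, b = 10)
  ref <- c(a = 45, b = 35)
  r <- proportion_comparison(tab, ref)
  # hand-computed Pearson chi-square for the 2x2 table
  m <- rbind(c(30, 10), c(45, 35))
  n <- sum(m)
  exp_m <- outer(rowSums(m), colSums(m)) / n
  chi2 <- sum((m - exp_m)^2 / exp_m)
  expect_equal(r$statistic, chi2, tolerance = 1e-12)
  expect_equal(r$df, 1)

  # identical proportions -> statistic 0, p = 1
  same <- proportion_comparison(c(a = 20, b = 10), c(a = 40, b = 20))
  expect_equal(same$statistic, 0, tolerance = 1e-12)
  expect_equal(same$p, 1)

  # zero-count category in one cohort only is retained
  zc <- proportion_comparison(c(a = 10, b = 0), c(a = 8, b = 4))
  expect_equal(ncol(zc$table), 2)

  expect_warning(proportion_comparison(c(a = 5, b = 0), c(a = 5, b = 0)),
                 "absent from both")
})

test_that("rank-sum tests and BH adjustment match exact references", {
  expect_equal(score_by_group_test(c(1, 2, 3, 4, 1, 2, 3, 4),
                                   rep(c("x", "y"), each = 4))$p, 1,
               tolerance = 0.05)

  # fully separated 4 vs 4: exact two-sided p = 2 * 4!4!/8!
  sep <- score_by_group_test(c(1, 2, 3, 4, 10, 11, 12, 13),
                             rep(c("x", "y"), each = 4))
  expect_equal(sep$p, 2 * factorial(4)^2 / factorial(8), tolerance = 1e-12)

  # enumeration oracle on random small groups
  set.seed(82)
  x <- rnorm(5); y <- rnorm(3, 1)
  r <- score_by_group_test(c(x, y), rep(c("x", "y"), c(5, 3)))
  expect_equal(r$p, rank_sum_enum_p(x, y), tolerance = 1e-12)

  # invariance under strictly monotone transformation
  r2 <- score_by_group_test(exp(c(x, y)), rep(c("x", "y"), c(5, 3)))
  expect_equal(r2$p, r$p)

  # multi-panel interface adds BH q-values
  panels <- list(p1 = c(x, y), p2 = exp(c(x, y)))
  grp <- list(rep(c("x", "y"), c(5, 3)), rep(c("x", "y"), c(5, 3)))
  multi <- score_by_group_test(panels, grp)
  expect_equal(multi$q, p.adjust(multi$p, "BH"))

  # BH on the worked vector
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04), "BH"),
               rep(0.04, 4))
  # BH never drops below p and is monotone
  p <- sort(runif(10))
  q <- p.adjust(p, "BH")
  expect_true(all(q >= p))
  expect_true(all(diff(q) >= 0))

  expect_error(score_by_group_test(c(1, 2), factor(c("x", "y"))),
               ">= 2")
})

test_that("drug association filters missingness and pools by pathway", {
  cfg <- sim_config(seed = 83)
  sim <- simulate_drug_table(cfg, n_lines = 30, n_drugs = 25)
  res <- drug_subtype_association(sim$auc, sim$pathways, sim$scores)

  # exactly the drugs with > 25% missing are excluded
  frac <- colMeans(is.na(sim$auc))
  expect_setequal(res$excluded_drugs, colnames(sim$auc)[frac > 0.25])
  expect_true(all(res$per_drug$n >= 3))

  # perfectly linear relation gives r = 1
  auc <- cbind(lin = sim$scores[, 1] * 2 + 1)
  one <- drug_subtype_association(
    cbind(auc, other = rev(sim$scores[, 1])),
    c(lin = "A", other = "B"), sim$scores)
  expect_equal(one$per_drug$r[one$per_drug$drug == "lin" &
                                one$per_drug$class == colnames(sim$scores)[1]],
               1, tolerance = 1e-12)

  expect_error(drug_subtype_association(
    sim$auc[, 1, drop = FALSE], sim$pathways, sim$scores),
    "2 target-pathway")
})

test_that("Kruskal-Wallis and Dunn match hand-computed statistics", {
  vals <- c(1, 3, 5, 2, 4, 9, 7, 8, 6)
  grp <- rep(c("a", "b", "c"), each = 3)
  kt <- kruskal.test(vals, factor(grp))
  # hand computation: H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1)
  r <- rank(vals)
  rbar <- tapply(r, grp, mean)
  H <- 12 / (9 * 10) * sum(3 * rbar^2) - 3 * 10
  expect_equal(unname(kt$statistic), H, tolerance = 1e-12)

  dn <- gastropanel:::dunn_posthoc(vals, grp)
  # independent recomputation for the a-b pair (no ties)
  z_ab <- (rbar["a"] - rbar["b"]) / sqrt(9 * 10 / 12 * (1 / 3 + 1 / 3))
  i <- which(dn$group1 == "a" & dn$group2 == "b")
  expect_equal(dn$z[i], unname(z_ab), tolerance = 1e-12)
  expect_equal(dn$p[i], unname(2 * pnorm(-abs(z_ab))), tolerance = 1e-12)
  expect_equal(dn$p_bonferroni, pmin(dn$p * 3, 1))
})

test_that("transition tables count class movements", {
  tt <- transition_table(c("CIN", "CIN", "GS"), c("CIN", "GS", "GS"))
  expect_equal(tt$n[tt$from == "CIN" & tt$to == "GS"], 1)
  expect_equal(sum(tt$n), 3)
})
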