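# 4PL fitting and drug sensitivity scores.

test_that("noise-free 4PL data are recovered essentially exactly", {
  conc <- dose_grid(800e-6, 8, "half-log")
  x <- log10(conc)
  truth <- c(a = 0, d = 100, h = 1, x50 = -6)
  inhib <- truth["a"] + (truth["d"] - truth["a"]) /
    (1 + 10^(truth["h"] * (truth["x50"] - x)))
  fit <- fit_4pl(dose_response_curve("drug", conc, 100 - inhib))
  expect_lt(max(abs(coef(fit) - truth)), 1e-6)
  expect_gt(fit$adj_r2, 1 - 1e-10)
  expect_false(fit$degenerate)
})

test_that("flat responses give a degenerate flagged fit with zero DSS", {
  conc <- dose_grid(800e-6, 8)
  fit <- fit_4pl(dose_response_curve("flat", conc, rep(100, 8)))
  expect_true(fit$degenerate)
  dss <- compute_dss(fit)
  expect_equal(c(dss$DSS1, dss$DSS2, dss$DSS3), c(0, 0, 0))
})

test_that("full inhibition across the window scores DSS1 = 100", {
  conc <- dose_grid(800e-6, 8)
  fit <- fit_4pl(dose_response_curve("max", conc, rep(0, 8)))
  dss <- compute_dss(fit, t = 10)
  expect_equal(dss$DSS1, 100)
  expect_equal(dss$DSS2, 100)
  expect_equal(dss$DSS3, 100)
})

test_that("curve data validate their invariants", {
  expect_error(dose_response_curve("d", c(1, 2, 3), c(50, 50, 50)),
               "4 distinct")
  expect_error(dose_response_curve("d", c(-1, 1, 2, 3), rep(50, 4)),
               "positive")
  expect_error(fit_4pl(dose_response_curve("d", 1:4, c(10, 20, 30, 40))),
               "more observations")
})

test_that("closed-form DSS integral agrees with quadrature on random fits", {
  set.seed(71)
  for (i in 1:30) {
    fit <- structure(list(a = runif(1, 0, 20), d = runif(1, 40, 100),
                          h = runif(1, 0.3, 3), x50 = runif(1, -7, -4),
                          window = c(-8, -3), degenerate = FALSE),
                     class = "pl4_fit")
    dss <- compute_dss(fit, t = 10)
    expect_lte(dss$quadrature_diff, 1e-6)
    # independent quadrature of the raw curve over the clipped window
    if (!is.na(dss$x1c) && dss$x1c < -3) {
      iq <- integrate(function(x)
        fit$a + (fit$d - fit$a) / (1 + 10^(fit$h * (fit$x50 - x))) - 10,
        dss$x1c, -3, rel.tol = 1e-10)$value
      expect_equal(dss$integral, iq, tolerance = 1e-8)
    }
  }
})

test_that("DSS never exceeds its bounds and responds monotonically to d", {
  base <- list(a = 0, h = 1, x50 = -5.5, window = c(-8, -3),
               degenerate = FALSE)
  tops <- seq(15, 100, by = 5)
  dss1 <- vapply(tops, function(d) {
    fit <- structure(c(base, list(d = d)), class = "pl4_fit")
    compute_dss(fit, t = 10)$DSS1
  }, numeric(1))
  expect_true(all(diff(dss1) >= 0))
  for (d in c(20, 60, 100)) {
    fit <- structure(c(base, list(d = d)), class = "pl4_fit")
    r <- compute_dss(fit, t = 10)
    expect_true(all(unlist(r[c("DSS1", "DSS2", "DSS3")]) >= 0))
    expect_true(all(unlist(r[c("DSS1", "DSS2", "DSS3")]) <= 100))
    expect_lte(r$DSS3, r$DSS2)  # window shrinkage factor <= 1
  }
  # a curve that never reaches the threshold scores zero, not an error
  low <- structure(c(base, list(d = 8)), class = "pl4_fit")
  expect_equal(compute_dss(low, t = 10)$DSS1, 0)
  expect_error(compute_dss(low, t = 101), "threshold")
  expect_error(compute_dss(low, t = 10, window = c(-3, -8)), "window")
})

test_that("noisy curves on the assay grids recover log10 IC50", {
  cfg <- sim_config(seed = 72)
  hits <- 0; total <- 0
  for (rep in 1:15) {
    sim <- simulate_dose_response(sim_config(seed = 72 + rep))
    for (drug in names(sim$curves)) {
      fit <- fit_4pl(sim$curves[[drug]])
      total <- total + 1
      if (abs(fit$x50 - sim$truth[[drug]]["x50"]) < 0.15) hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("assay grids reproduce the dilution designs", {
  g <- assay_dose_grids()
  expect_equal(g$`5-fluorouracil`[1], 800e-6)
  expect_equal(unique(round(g$`5-fluorouracil`[-8] /
                              g$`5-fluorouracil`[-1], 6)),
               round(sqrt(10), 6))
  expect_equal(g$docetaxel[1], 2400e-9)
  expect_equal(unique(g$docetaxel[-8] / g$docetaxel[-1]), 10)
  expect_error(dose_grid(-1), "top")
})

test_that("plate tables parse units and split sample:drug curves", {
  d <- expand.grid(concentration = c(800, 80, 8, 0.8, 0.08),
                   replicate = 1:2)
  d$sample <- "org1"; d$drug <- "5FU"; d$unit <- "uM"
  d$viability <- 100 - seq(10, 95, length.out = nrow(d))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(d, path, row.names = FALSE)
  curves <- read_plate_table(path)
  expect_length(curves, 1)
  expect_equal(sort(unique(curves[[1]]$concentration)),
               sort(c(800, 80, 8, 0.8, 0.08) * 1e-6))
})
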