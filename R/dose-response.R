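# Four-parameter logistic dose-response fitting and drug sensitivity
# scores (DSS) computed from the fitted inhibition curve.

#' Dose-response curve data
#'
#' Raw viability measurements for one drug on one sample: molar
#' concentrations (the working scale is x = log10 concentration) and
#' replicate viabilities as percent of vehicle control. Viability
#' normalization to vehicle is the caller's responsibility.
#'
#' @param drug Drug label.
#' @param concentration Strictly positive molar concentrations (repeated
#'   across replicates as needed).
#' @param viability Percent viability, same length as `concentration`.
#' @param sample_id Plate/sample identifier.
#' @return An object of class `dose_response_curve`.
#' @export
dose_response_curve <- function(drug, concentration, viability,
                                sample_id = "sample") {
  concentration <- as.numeric(concentration)
  viability <- as.numeric(viability)
  if (length(concentration) != length(viability))
    stop("concentration and viability must have equal length")
  if (any(!is.finite(concentration)) || any(concentration <= 0))
    stop("concentrations must be finite and strictly positive (molar)")
  if (any(!is.finite(viability)))
    stop("viabilities must be finite")
  if (length(unique(concentration)) < 4)
    stop("need >= 4 distinct concentrations to fit a 4PL curve")
  structure(list(drug = drug, concentration = concentration,
                 viability = viability, sample_id = sample_id),
            class = "dose_response_curve")
}

#' Standard panel dose grids
#'
#' Serial-dilution concentration grids matching the assay design: a top
#' concentration followed by half-log (sqrt(10)-fold) or ten-fold
#' dilutions.
#'
#' @param top Top concentration in molar.
#' @param n Number of concentrations (default 8).
#' @param dilution `"half-log"` or `"ten-fold"`.
#' @return Decreasing vector of molar concentrations.
#' @export
dose_grid <- function(top, n = 8, dilution = c("half-log", "ten-fold")) {
  dilution <- match.arg(dilution)
  stopifnot(top > 0, n >= 2)
  step <- if (dilution == "half-log") sqrt(10) else 10
  top / step^(0:(n - 1))
}

#' Built-in assay grids
#'
#' The three grids used by the organoid FLOT assay: 5-fluorouracil from
#' 800 uM and oxaliplatin from 2400 uM in 8 half-log dilutions, docetaxel
#' from 2400 nM in ten-fold dilutions.
#'
#' @return Named list of molar concentration vectors.
#' @export
assay_dose_grids <- function() {
  list(`5-fluorouracil` = dose_grid(800e-6, 8, "half-log"),
       oxaliplatin = dose_grid(2400e-6, 8, "half-log"),
       docetaxel = dose_grid(2400e-9, 8, "ten-fold"))
}

# 4PL inhibition curve: y(x) = a + (d - a) / (1 + 10^(h (x50 - x))),
# x = log10 molar concentration.
pl4_curve <- function(x, a, d, h, x50) {
  a + (d - a) / (1 + 10^(h * (x50 - x)))
}

# log10(1 + 10^z), overflow-safe.
log10_1p_pow10 <- function(z) {
  ifelse(z > 0,
         z + log1p(10^(-z)) / log(10),
         log1p(10^z) / log(10))
}

#' Fit a four-parameter logistic dose-response model
#'
#' Least-squares fit of the 4PL inhibition curve
#' `y(x) = a + (d - a)/(1 + 10^(h (x50 - x)))` to
#' `inhibition = 100 - viability` against x = log10 molar concentration,
#' using Levenberg-Marquardt with a deterministic grid of starting values
#' (multi-start over hill slope and IC50). Parameters are canonicalized to
#' bottom `a <= d` top. A response with (near-)zero variance is returned as
#' a degenerate flat fit rather than an error.
#'
#' @param curve A [dose_response_curve()].
#' @return An object of class `pl4_fit`: parameters `a`, `d`, `h`, `x50`
#'   (log10 IC50), `ic50` (molar), `r2` and `adj_r2`, residuals, and a
#'   `degenerate` flag.
#' @export
fit_4pl <- function(curve) {
  stopifnot(inherits(curve, "dose_response_curve"))
  x <- log10(curve$concentration)
  y <- 100 - curve$viability
  n <- length(y)
  if (n <= 4) stop("need more observations than the 4 model parameters")

  mk_fit <- function(a, d, h, x50, fitted, degenerate) {
    if (a > d) { tmp <- a; a <- d; d <- tmp; h <- -h }
    res <- y - fitted
    tss <- sum((y - mean(y))^2)
    r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
    adj <- if (is.na(r2)) NA_real_ else 1 - (1 - r2) * (n - 1) / (n - 4 - 1)
    structure(list(drug = curve$drug, sample_id = curve$sample_id,
                   a = a, d = d, h = h, x50 = x50, ic50 = 10^x50,
                   r2 = r2, adj_r2 = adj, residuals = res, x = x, y = y,
                   window = range(x), degenerate = degenerate),
              class = "pl4_fit")
  }

  if (stats::sd(y) < 1e-8) {
    flat <- mean(y)
    return(mk_fit(flat, flat, 1, NA_real_, rep(flat, n), degenerate = TRUE))
  }

  # inhibition is a percentage of the vehicle control: constrain the
  # asymptotes to the physical [0, 100] range (the unconstrained 4PL is
  # weakly identified when the plateaus are not sampled)
  lo <- c(a = 0, d = 10, h = 0.05, x50 = min(x) - 3)
  hi <- c(a = 90, d = 100, h = 10, x50 = max(x) + 3)
  # starts kept strictly inside the bounds: LM stalls when initialized on
  # a box constraint
  starts <- expand.grid(
    h = c(0.5, 1, 2, 4),
    x50 = stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE),
    d = unique(pmin(pmax(c(0.85, 1) * max(y), 15), 99.5)))
  best <- NULL; best_rss <- Inf
  for (i in seq_len(nrow(starts))) {
    st <- list(a = min(max(min(y), 0.5), 85), d = starts$d[i],
               h = starts$h[i], x50 = starts$x50[i])
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a + (d - a) / (1 + 10^(h * (x50 - x))),
                        start = st, lower = lo, upper = hi,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (rss < best_rss) { best <- fit; best_rss <- rss }
    }
  }
  if (is.null(best))
    stop("4PL fit failed to converge from all ", nrow(starts),
         " starting points")
  cf <- stats::coef(best)
  mk_fit(cf["a"], cf["d"], cf["h"], cf["x50"], stats::fitted(best),
         degenerate = FALSE)
}

#' @exportS3Method base::print
print.pl4_fit <- function(x, ...) {
  cat("pl4_fit:", x$drug, if (x$degenerate) "(degenerate flat fit)" else "", "\n")
  cat(sprintf("  bottom a = %.2f, top d = %.2f, hill h = %.3f, log10 IC50 = %s\n",
              x$a, x$d, x$h,
              if (is.na(x$x50)) "NA" else sprintf("%.3f", x$x50)))
  if (!is.na(x$adj_r2)) cat(sprintf("  adjusted R^2 = %.4f\n", x$adj_r2))
  invisible(x)
}

#' @export
coef.pl4_fit <- function(object, ...) {
  c(a = object$a, d = object$d, h = object$h, x50 = object$x50)
}

#' @export
residuals.pl4_fit <- function(object, ...) object$residuals

#' Predict inhibition from a fitted 4PL curve
#' @param object A `pl4_fit`.
#' @param newdata Numeric vector of log10 molar concentrations (defaults
#'   to the fitted x values).
#' @param ... Unused.
#' @return Predicted percent inhibition.
#' @export
predict.pl4_fit <- function(object, newdata = object$x, ...) {
  if (object$degenerate) return(rep(object$d, length(newdata)))
  pl4_curve(newdata, object$a, object$d, object$h, object$x50)
}

#' Plot a fitted dose-response curve
#' @param x A `pl4_fit`.
#' @param ... Passed to [plot()].
#' @export
plot.pl4_fit <- function(x, ...) {
  xs <- seq(min(x$x) - 0.5, max(x$x) + 0.5, length.out = 200)
  plot(x$x, x$y, xlab = "log10 concentration (M)",
       ylab = "inhibition (%)", main = x$drug, ...)
  graphics::lines(xs, predict(x, xs))
  invisible(x)
}

# Antiderivative of y(x) - t for the 4PL inhibition curve in log10 space:
# F(x) = (a - t) x + (d - a) [x + log10(1 + 10^(h (x50 - x))) / h]
pl4_antideriv <- function(x, a, d, h, x50, t) {
  (a - t) * x + (d - a) * (x + log10_1p_pow10(h * (x50 - x)) / h)
}

# Smallest x in [x1, x2] with y(x) >= t (h > 0 branch); NA if never.
pl4_threshold_crossing <- function(a, d, h, x50, t, x1) {
  if (t <= a) return(x1)
  if (t >= d) return(NA_real_)
  xt <- x50 - log10((d - t) / (t - a)) / h
  max(x1, xt)
}

#' Drug sensitivity scores from a fitted curve
#'
#' Integrates the fitted inhibition curve above an activity threshold t
#' over the tested concentration window [x1, x2] (log10 molar):
#' `I = integral from x1c to x2 of (y(x) - t) dx`, with x1c the larger of
#' x1 and the concentration where the curve first reaches t. The integral
#' is evaluated in closed form (the 4PL has an analytic antiderivative in
#' log10 space) and cross-checked against adaptive quadrature. Scores:
#' `DSS1 = 100 I / ((100 - t)(x2 - x1))`, `DSS2 = DSS1 * 100 / d`,
#' `DSS3 = DSS2 * (x2 - x1c)/(x2 - x1)`. A curve that never exceeds t
#' scores 0 on all three.
#'
#' @param fit A [fit_4pl()] result.
#' @param t Activity threshold in percent inhibition, in [0, 100)
#'   (default 10).
#' @param window Integration window `c(x1, x2)` in log10 molar; defaults
#'   to the fitted concentration range.
#' @param check_tol Maximum allowed |closed form - quadrature| (default
#'   1e-6).
#' @return A list with `DSS1`, `DSS2`, `DSS3`, `integral`, `x1c`, `window`
#'   and `quadrature_diff`.
#' @export
compute_dss <- function(fit, t = 10, window = NULL, check_tol = 1e-6) {
  stopifnot(inherits(fit, "pl4_fit"))
  if (t < 0 || t >= 100) stop("threshold t must be in [0, 100)")
  if (is.null(window)) window <- fit$window
  x1 <- window[1]; x2 <- window[2]
  if (!(is.finite(x1) && is.finite(x2)) || x1 >= x2)
    stop("invalid integration window: x1 must be < x2")

  zero <- list(DSS1 = 0, DSS2 = 0, DSS3 = 0, integral = 0, x1c = NA_real_,
               window = c(x1, x2), quadrature_diff = 0)
  a <- fit$a; d <- fit$d; h <- fit$h; x50 <- fit$x50

  if (fit$degenerate || !is.finite(x50)) {
    if (d <= t) return(zero)
    I <- (d - t) * (x2 - x1)
    x1c <- x1
    qdiff <- 0
  } else {
    x1c <- pl4_threshold_crossing(a, d, h, x50, t, x1)
    if (is.na(x1c) || x1c >= x2) return(zero)
    I <- pl4_antideriv(x2, a, d, h, x50, t) -
      pl4_antideriv(x1c, a, d, h, x50, t)
    Iq <- stats::integrate(function(x) pl4_curve(x, a, d, h, x50) - t,
                           x1c, x2, rel.tol = 1e-10, abs.tol = 1e-10)$value
    qdiff <- abs(I - Iq)
    if (qdiff > check_tol)
      stop(sprintf(
        "closed-form and quadrature DSS integrals disagree by %.3g", qdiff))
  }
  I <- max(I, 0)
  dss1 <- 100 * I / ((100 - t) * (x2 - x1))
  dss2 <- if (d > 0) dss1 * 100 / d else 0
  dss3 <- dss2 * (x2 - x1c) / (x2 - x1)
  clamp <- function(v) min(max(v, 0), 100)
  list(DSS1 = clamp(dss1), DSS2 = clamp(dss2), DSS3 = clamp(dss3),
       integral = I, x1c = x1c, window = c(x1, x2), quadrature_diff = qdiff)
}

#' Read a plate table of dose-response measurements
#'
#' @param path CSV with columns `sample`, `drug`, `concentration`, `unit`
#'   (`M`, `mM`, `uM` or `nM`) and `viability`.
#' @return Named list of [dose_response_curve()] objects, one per
#'   sample:drug combination.
#' @export
read_plate_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "drug", "concentration", "unit", "viability")
  if (!all(need %in% names(d)))
    stop("plate table needs columns: ", paste(need, collapse = ", "))
  scale <- c(M = 1, mM = 1e-3, uM = 1e-6, nM = 1e-9)
  if (!all(d$unit %in% names(scale)))
    stop("unknown concentration unit: ",
         paste(setdiff(d$unit, names(scale)), collapse = ", "))
  d$conc_m <- d$concentration * scale[d$unit]
  key <- paste(d$sample, d$drug, sep = ":")
  lapply(split(d, key), function(g)
    dose_response_curve(g$drug[1], g$conc_m, g$viability, g$sample[1]))
}
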