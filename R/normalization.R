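# RUV-III batch-effect removal with technical replicates, data-driven
# negative-control selection, and feature-specific quantile normalization
# (FSQN) onto a reference cohort.

#' Technical-replicate design
#'
#' Maps each assayed sample to its biological unit; samples sharing a unit
#' are technical replicates (e.g., the same RNA run on different
#' cartridges). The derived 0/1 membership matrix M (samples x units,
#' row sums 1) is the replicate structure RUV-III residualizes against.
#'
#' @param sample Character vector of sample names (unique).
#' @param unit Character vector of biological-unit IDs, same length.
#' @return An object of class `replicate_design` with elements `map`
#'   (data.frame sample/unit) and `M` (samples x units incidence matrix).
#' @export
replicate_design <- function(sample, unit) {
  sample <- as.character(sample); unit <- as.character(unit)
  if (length(sample) != length(unit) || length(sample) == 0)
    stop("sample and unit must be non-empty vectors of equal length")
  if (anyDuplicated(sample))
    stop("each sample maps to exactly one unit; duplicated: ",
         paste(unique(sample[duplicated(sample)]), collapse = ", "))
  units <- unique(unit)
  M <- matrix(0, length(sample), length(units),
              dimnames = list(sample, units))
  M[cbind(seq_along(sample), match(unit, units))] <- 1
  structure(list(map = data.frame(sample = sample, unit = unit), M = M),
            class = "replicate_design")
}

#' @exportS3Method base::print
print.replicate_design <- function(x, ...) {
  sizes <- table(x$map$unit)
  cat("replicate_design:", nrow(x$M), "sample(s),", ncol(x$M), "unit(s);",
      sum(sizes >= 2), "unit(s) with >= 2 replicates\n")
  invisible(x)
}

#' Read a replicate design from a two-column table
#' @param path TSV/CSV with columns `sample` and `unit`.
#' @return A `replicate_design`.
#' @export
read_replicate_design <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  d <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  if (!all(c("sample", "unit") %in% names(d)))
    stop("replicate design table needs columns: sample, unit")
  replicate_design(d$sample, d$unit)
}

align_design <- function(Y, design) {
  stopifnot(inherits(design, "replicate_design"))
  if (is.null(rownames(Y))) stop("Y must carry sample row names")
  miss <- setdiff(rownames(Y), rownames(design$M))
  if (length(miss))
    stop("samples absent from the replicate design: ", paste(miss, collapse = ", "))
  M <- design$M[rownames(Y), , drop = FALSE]
  M[, colSums(M) > 0, drop = FALSE]
}

#' Select data-driven negative-control genes
#'
#' Negative controls for RUV-III are genes expected to carry technical but
#' not biological variation. They are chosen as the `ceiling(fraction * p)`
#' genes with the lowest between-biological-unit variance of
#' replicate-averaged log expression, restricted to genes expressed above
#' `lod` in at least half the samples. Ties in variance are broken
#' deterministically by probe name.
#'
#' @param Y Log2-expression matrix, samples x genes.
#' @param design A [replicate_design()] covering the samples of `Y`.
#' @param fraction Proportion of genes to select, in (0, 1). Default 0.2.
#' @param lod Expression floor on the log2 scale (default 0).
#' @return Integer vector of selected gene column indices (named).
#' @export
select_negative_controls <- function(Y, design, fraction = 0.2, lod = 0) {
  if (!(fraction > 0 && fraction < 1)) stop("fraction must be in (0, 1)")
  M <- align_design(Y, design)
  if (ncol(M) < 2) stop("need >= 2 biological units to assess between-unit variance")
  expressed <- colMeans(Y > lod) >= 0.5
  if (!any(expressed))
    stop("no gene is expressed above lod = ", lod,
         " in >= 50% of samples; lower the lod filter")
  unit_means <- sweep(crossprod(M, Y), 1, colSums(M), "/")  # units x genes
  v <- apply(unit_means, 2, stats::var)
  v[!expressed] <- Inf
  n_ctrl <- ceiling(fraction * ncol(Y))
  n_ctrl <- min(n_ctrl, sum(expressed))
  ord <- order(v, colnames(Y))  # variance, then probe name for ties
  idx <- sort(ord[seq_len(n_ctrl)])
  stats::setNames(idx, colnames(Y)[idx])
}

#' RUV-III normalization
#'
#' Removes unwanted (cartridge/batch) variation from a log-expression
#' matrix using technical replicates and negative-control genes. The
#' estimator: residualize the replicate structure,
#' Y0 = Y - M (M'M)^-1 M' Y; take the first k left singular vectors U_k of
#' Y0; form loadings fullalpha = U_k' Y; restrict to the control genes
#' (alpha_c); estimate the unwanted factors
#' W = Y_c alpha_c' (alpha_c alpha_c')^-1; and subtract,
#' Y* = Y - W fullalpha. With k = 0 the data are returned unchanged.
#'
#' @param Y Log2-expression matrix, samples x genes.
#' @param design A [replicate_design()]; at least one unit must have two or
#'   more replicate samples.
#' @param controls Gene index vector (or names) of negative-control genes.
#' @param k Number of unwanted factors, `0 <= k <= n - rank(M)`.
#' @return A list with `Y` (normalized matrix, same dimensions) and
#'   `model`, a `ruv3_model` holding `k`, `controls`, `W` (samples x k) and
#'   `alpha` (k x genes).
#' @export
ruv3_normalize <- function(Y, design, controls, k = 1) {
  Y <- as.matrix(Y)
  M <- align_design(Y, design)
  if (!any(colSums(M) >= 2))
    stop("RUV-III needs at least one biological unit with >= 2 technical replicates")
  if (is.character(controls)) controls <- match(controls, colnames(Y))
  controls <- as.integer(controls)
  if (k > 0 && (length(controls) == 0 || anyNA(controls)))
    stop("controls must be a non-empty set of gene indices present in Y")
  n <- nrow(Y)
  rM <- qr(M)$rank
  if (k < 0 || k > n - rM)
    stop("k must satisfy 0 <= k <= n - rank(M) = ", n - rM)

  model <- structure(list(k = k, controls = controls,
                          control_genes = colnames(Y)[controls],
                          W = NULL, alpha = NULL),
                     class = "ruv3_model")
  if (k == 0) return(list(Y = Y, model = model))

  # (1) residualize replicate structure (within-unit deviations)
  Y0 <- Y - M %*% solve(crossprod(M), crossprod(M, Y))
  sv <- svd(Y0, nu = k, nv = 0)
  if (sv$d[1] < 1e-12 * max(1, max(abs(Y)))) {
    # identical replicates: no within-unit variation to learn from
    return(list(Y = Y, model = model))
  }
  Uk <- sv$u[, seq_len(k), drop = FALSE]
  # (3) loadings over all genes, (4) restricted to controls
  fullalpha <- crossprod(Uk, Y)                       # k x p
  alpha_c <- fullalpha[, controls, drop = FALSE]      # k x |c|
  gram <- tcrossprod(alpha_c)                         # k x k
  if (rcond(gram) < 1e-12)
    stop("alpha_c alpha_c' is numerically singular; ",
         "use more control genes or a smaller k")
  # (5) unwanted factors, (6) subtract
  W <- Y[, controls, drop = FALSE] %*% t(alpha_c) %*% solve(gram)
  Ystar <- Y - W %*% fullalpha
  dimnames(Ystar) <- dimnames(Y)
  model$W <- W
  model$alpha <- fullalpha
  list(Y = Ystar, model = model)
}

#' @exportS3Method base::print
print.ruv3_model <- function(x, ...) {
  cat("ruv3_model: k =", x$k, "with", length(x$controls),
      "negative-control gene(s)\n")
  invisible(x)
}

#' Serialize a RUV-III model to JSON
#' @param model A `ruv3_model`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_ruv3_model <- function(model, path) {
  stopifnot(inherits(model, "ruv3_model"))
  jsonlite::write_json(
    list(k = model$k, control_genes = model$control_genes,
         n_samples = if (is.null(model$W)) 0L else nrow(model$W)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Within-unit replicate log differences
#'
#' All pairwise differences of log expression between technical replicates
#' of the same biological unit, per gene. The median absolute difference is
#' the headline diagnostic: it should approach zero after successful
#' normalization.
#'
#' @param Y Log2-expression matrix, samples x genes.
#' @param design A [replicate_design()].
#' @return A list with `differences` (pairs x genes matrix, one row per
#'   within-unit sample pair), `pairs` (data.frame of the sample pairs) and
#'   `median_abs` (scalar median of |differences|).
#' @export
replicate_log_difference <- function(Y, design) {
  Y <- as.matrix(Y)
  M <- align_design(Y, design)
  units <- colnames(M)[colSums(M) >= 2]
  if (length(units) == 0)
    stop("no biological unit has >= 2 replicate samples")
  rows <- list(); a <- character(0); b <- character(0)
  for (u in units) {
    s <- rownames(M)[M[, u] == 1]
    cmb <- utils::combn(s, 2)
    for (j in seq_len(ncol(cmb))) {
      rows[[length(rows) + 1]] <- Y[cmb[1, j], ] - Y[cmb[2, j], ]
      a <- c(a, cmb[1, j]); b <- c(b, cmb[2, j])
    }
  }
  d <- do.call(rbind, rows)
  rownames(d) <- paste(a, b, sep = "|")
  list(differences = d, pairs = data.frame(sample1 = a, sample2 = b),
       median_abs = stats::median(abs(d)))
}

#' Replicate-agreement diagnostic over a range of k
#'
#' Runs [ruv3_normalize()] for `k = 0 .. k_max` and reports the median and
#' mean absolute replicate log difference at each k, to guide the choice of
#' the number of unwanted factors.
#'
#' @inheritParams ruv3_normalize
#' @param k_max Largest k to try; capped at `n - rank(M)` (default
#'   `min(5, n - rank(M))`).
#' @return A data.frame with columns `k`, `median_abs_diff`,
#'   `mean_abs_diff`.
#' @export
ruv3_k_sweep <- function(Y, design, controls, k_max = 5) {
  M <- align_design(as.matrix(Y), design)
  kk <- 0:min(k_max, nrow(Y) - qr(M)$rank)
  out <- lapply(kk, function(k) {
    Yk <- ruv3_normalize(Y, design, controls, k)$Y
    d <- replicate_log_difference(Yk, design)
    data.frame(k = k, median_abs_diff = d$median_abs,
               mean_abs_diff = mean(abs(d$differences)))
  })
  do.call(rbind, out)
}

# Type-7 (linear-interpolation) quantiles of `target` at n equally spaced
# probabilities in [0, 1].
interp_quantiles <- function(target, n) {
  if (n == 1) return(stats::median(target))
  unname(stats::quantile(target, probs = seq(0, 1, length.out = n), type = 7))
}

#' Feature-specific quantile normalization (FSQN)
#'
#' Maps each gene of a test matrix onto the corresponding gene's
#' distribution in a reference (target) cohort: for gene j, the n test
#' values are replaced, in rank order, by n linearly interpolated quantiles
#' of the target's gene-j values. Within each gene the output multiset
#' equals those quantiles and the test ranks are preserved; tied test
#' values receive the mean of their mapped quantiles. This transfers
#' panel-measured expression onto the scale of the cohort a classifier was
#' trained on.
#'
#' @param test Log-expression matrix, n x p (samples x genes).
#' @param target Reference expression matrix, N x p, with identical gene
#'   ordering (column names checked when present).
#' @return Normalized n x p matrix.
#' @export
fsqn <- function(test, target) {
  test <- as.matrix(test); target <- as.matrix(target)
  if (!is.null(colnames(test)) && !is.null(colnames(target))) {
    miss <- setdiff(colnames(test), colnames(target))
    if (length(miss))
      stop("genes present in test but absent in target: ",
           paste(miss, collapse = ", "))
    target <- target[, colnames(test), drop = FALSE]
  } else if (ncol(test) != ncol(target)) {
    stop("test and target must have the same genes in the same order")
  }
  n <- nrow(test)
  out <- test
  for (j in seq_len(ncol(test))) {
    q <- interp_quantiles(target[, j], n)
    r <- rank(test[, j], ties.method = "first")
    vals <- q[r]
    # tied inputs get the mean of their mapped quantiles
    if (anyDuplicated(test[, j])) {
      vals <- stats::ave(vals, match(test[, j], test[, j]))
    }
    out[, j] <- vals
  }
  out
}
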