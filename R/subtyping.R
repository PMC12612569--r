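# Probabilistic subtype classification: reference cohorts, an L2
# multinomial logistic classifier over the panel genes, replicate-averaged
# score assignment and joint TCGA x TME calls.

TCGA_CLASSES <- c("CIN", "EBV", "GS", "MSI")
TME_CLASSES <- c("High", "Low")
ACRG_CLASSES <- c("MSI", "MSS/TP53+", "MSS/TP53-", "EMT")

scheme_classes <- function(scheme) {
  switch(scheme,
         tcga = TCGA_CLASSES, tme = TME_CLASSES, acrg = ACRG_CLASSES,
         stop("unknown scheme '", scheme, "' (use tcga, tme or acrg)"))
}

#' Reference cohort for classifier training
#'
#' A gene-aligned expression matrix with per-sample subtype labels; serves
#' both as the FSQN target distribution and as the training set for the
#' subtype classifier.
#'
#' @param expression Samples x genes numeric matrix with dimnames.
#' @param labels Character vector of class labels, one per sample.
#' @param scheme Label scheme: `"tcga"` (CIN/EBV/GS/MSI), `"tme"`
#'   (High/Low) or `"acrg"`.
#' @param panel Optional character vector of panel genes (subset of the
#'   expression genes) the classifier is restricted to; defaults to all
#'   genes.
#' @return An object of class `reference_cohort`.
#' @export
reference_cohort <- function(expression, labels, scheme, panel = NULL) {
  expression <- as.matrix(expression)
  if (is.null(rownames(expression)) || is.null(colnames(expression)))
    stop("expression must have sample and gene dimnames")
  labels <- as.character(labels)
  if (length(labels) != nrow(expression))
    stop("one label per sample required")
  classes <- scheme_classes(scheme)
  if (!all(labels %in% classes))
    stop("labels outside the ", scheme, " label set: ",
         paste(setdiff(labels, classes), collapse = ", "))
  if (length(unique(labels)) < 2)
    stop("reference cohort must contain >= 2 classes")
  if (is.null(panel)) panel <- colnames(expression)
  if (!all(panel %in% colnames(expression)))
    stop("panel genes absent from expression: ",
         paste(setdiff(panel, colnames(expression)), collapse = ", "))
  structure(list(expression = expression, labels = labels,
                 scheme = scheme, panel = panel),
            class = "reference_cohort")
}

#' @exportS3Method base::print
print.reference_cohort <- function(x, ...) {
  cat("reference_cohort (", x$scheme, "): ", nrow(x$expression),
      " sample(s) x ", ncol(x$expression), " gene(s); panel ",
      length(x$panel), " gene(s)\n", sep = "")
  print(round(100 * prop.table(table(x$labels)), 1))
  invisible(x)
}

#' Train a probabilistic subtype classifier
#'
#' Fits an L2-regularized (ridge) multinomial logistic regression on the
#' reference cohort's panel genes, with the regularization strength chosen
#' by cross-validation and inverse-frequency class weights to counter
#' imbalance (EBV-type tumours are only a few percent of gastric cancers).
#' The softmax link yields calibrated per-class probabilities — the
#' "subtype scores". The binary TME scheme is the two-class special case.
#'
#' @param ref A [reference_cohort()].
#' @param nfolds Cross-validation folds for the regularization path
#'   (default 5).
#' @param seed Integer seed making the fold assignment (and hence the fit)
#'   deterministic.
#' @return An object of class `subtype_model` with a
#'   [predict.subtype_model()] method.
#' @export
train_subtype_classifier <- function(ref, nfolds = 5, seed = 1) {
  stopifnot(inherits(ref, "reference_cohort"))
  x <- ref$expression[, ref$panel, drop = FALSE]
  y <- factor(ref$labels)
  sizes <- table(y)
  if (any(sizes < 3))
    stop("every class needs >= 3 training samples to cross-validate; too small: ",
         paste(names(sizes)[sizes < 3], collapse = ", "))
  w <- as.numeric(1 / (sizes[y] / length(y)))  # inverse frequency
  set.seed(seed)
  # stratified folds: rare classes (EBV is ~5% prevalent) must appear in
  # every training fold
  foldid <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  cv <- glmnet::cv.glmnet(x, y, family = "multinomial", alpha = 0,
                          weights = w, foldid = foldid,
                          type.measure = "deviance")
  structure(list(cv = cv, panel = ref$panel, classes = levels(y),
                 scheme = ref$scheme, seed = seed, nfolds = nfolds,
                 lambda = cv$lambda.min),
            class = "subtype_model")
}

#' @exportS3Method base::print
print.subtype_model <- function(x, ...) {
  cat("subtype_model (", x$scheme, "): ridge multinomial logistic, ",
      length(x$panel), " gene(s), classes {",
      paste(x$classes, collapse = ", "), "}, lambda = ",
      signif(x$lambda, 3), "\n", sep = "")
  invisible(x)
}

#' Per-class subtype probabilities for new samples
#'
#' @param object A `subtype_model`.
#' @param newdata Samples x genes matrix covering the model's panel genes.
#' @param ... Unused.
#' @return Samples x classes matrix of probabilities (rows sum to 1).
#' @export
predict.subtype_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  miss <- setdiff(object$panel, colnames(newdata))
  if (length(miss))
    stop("newdata lacks panel genes: ", paste(miss, collapse = ", "))
  x <- newdata[, object$panel, drop = FALSE]
  p <- predict(object$cv, newx = x, s = "lambda.min", type = "response")
  p <- p[, , 1]
  if (is.null(dim(p))) p <- matrix(p, nrow = 1, dimnames = list(rownames(x), names(p)))
  p[, object$classes, drop = FALSE]
}

#' Held-out accuracy of a subtype classifier by cross-validation
#'
#' Simple k-fold cross-validated accuracy on the reference cohort, used as
#' a training diagnostic.
#'
#' @inheritParams train_subtype_classifier
#' @return Scalar accuracy in [0, 1].
#' @export
cv_accuracy <- function(ref, nfolds = 5, seed = 1) {
  stopifnot(inherits(ref, "reference_cohort"))
  y <- factor(ref$labels)
  set.seed(seed)
  foldid <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(nfolds), length(idx)))
  }
  correct <- 0L
  for (f in seq_len(nfolds)) {
    tr <- foldid != f
    ref_tr <- reference_cohort(ref$expression[tr, , drop = FALSE],
                               ref$labels[tr], ref$scheme, ref$panel)
    m <- train_subtype_classifier(ref_tr, nfolds = nfolds, seed = seed + f)
    p <- predict(m, ref$expression[!tr, , drop = FALSE])
    correct <- correct + sum(colnames(p)[max.col(p, "first")] == ref$labels[!tr])
  }
  correct / length(y)
}

#' Assign subtype scores and calls with replicate averaging
#'
#' Computes per-sample class probabilities from a trained model, then
#' averages the scores of technical replicates within each biological unit
#' (the replicate rule); the discrete call is the argmax of the averaged
#' scores, with a deterministic tie-break by class-name order (ties are
#' reported via a message).
#'
#' @param model A `subtype_model`.
#' @param Y_fsqn FSQN-normalized samples x genes matrix aligned to the
#'   model's panel.
#' @param design A [replicate_design()] covering every sample.
#' @return An object of class `subtype_result`: data.frame with `unit`,
#'   one score column per class, and `call`.
#' @export
assign_subtypes <- function(model, Y_fsqn, design) {
  stopifnot(inherits(model, "subtype_model"))
  p <- predict(model, Y_fsqn)
  M <- align_design(Y_fsqn, design)
  scores <- sweep(crossprod(M, p), 1, colSums(M), "/")  # units x classes
  calls <- apply(scores, 1, function(s) {
    top <- which(s == max(s))
    if (length(top) > 1)
      message("score tie for a unit; broken by class-name order: ",
              paste(colnames(scores)[top], collapse = ", "))
    colnames(scores)[min(top)]
  })
  res <- data.frame(unit = rownames(scores), scores, call = calls,
                    row.names = NULL, check.names = FALSE)
  attr(res, "scheme") <- model$scheme
  attr(res, "classes") <- model$classes
  class(res) <- c("subtype_result", "data.frame")
  res
}

#' @exportS3Method base::print
print.subtype_result <- function(x, ...) {
  cat("subtype_result (", attr(x, "scheme"), "): ", nrow(x),
      " unit(s)\n", sep = "")
  print(round(100 * prop.table(table(x$call)), 1))
  invisible(x)
}

#' Joint TCGA x TME call table and prevalences
#'
#' Combines two subtype results over the same biological units into joint
#' labels (e.g., `"CIN-TME Low"`) and reports per-class prevalence
#' percentages rounded to one decimal.
#'
#' @param tcga,tme `subtype_result` objects sharing the same units.
#' @return A list with `table` (unit, tcga, tme, joint label) and
#'   `prevalence` (data.frames of percent prevalence for tcga, tme and the
#'   joint labels).
#' @export
combined_call <- function(tcga, tme) {
  stopifnot(inherits(tcga, "subtype_result"), inherits(tme, "subtype_result"))
  common <- intersect(tcga$unit, tme$unit)
  if (!setequal(tcga$unit, tme$unit))
    stop("unit mismatch between the two subtype results")
  if (length(common) == 0) stop("no shared units")
  a <- tcga[match(common, tcga$unit), ]
  b <- tme[match(common, tme$unit), ]
  joint <- paste0(a$call, "-TME ", b$call)
  pct <- function(x) {
    t <- table(x)
    data.frame(class = names(t), n = as.integer(t),
               percent = round(100 * as.integer(t) / length(x), 1),
               row.names = NULL)
  }
  list(table = data.frame(unit = common, tcga = a$call, tme = b$call,
                          joint = joint, row.names = NULL),
       prevalence = list(tcga = pct(a$call), tme = pct(b$call),
                         joint = pct(joint)))
}

#' Write a subtype result as TSV
#' @param result A `subtype_result`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_subtype_result <- function(result, path) {
  out <- as.data.frame(result)
  out$scheme <- attr(result, "scheme")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
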