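# Classifier training, score assignment with the replicate-mean rule, and
# joint TCGA x TME calls.

make_two_class_ref <- function(n_per_class, delta, seed, noise = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  labels <- rep(c("High", "Low"), each = n_per_class)
  x <- matrix(rnorm(n * 2, 0, noise), n, 2,
              dimnames = list(sprintf("s%03d", 1:n), c("g1", "g2")))
  x[labels == "High", 1] <- x[labels == "High", 1] + delta
  reference_cohort(x, labels, "tme")
}

test_that("a separating gene yields perfect held-out accuracy", {
  ref <- make_two_class_ref(15, delta = 30, seed = 51, noise = 0.5)
  expect_equal(cv_accuracy(ref, seed = 1), 1.0)
})

test_that("identical class distributions stay near chance accuracy", {
  ref <- make_two_class_ref(50, delta = 0, seed = 52)
  acc <- cv_accuracy(ref, seed = 1)
  expect_gt(acc, 0.4)
  expect_lt(acc, 0.6)
})

test_that("training validates class sizes and scores sum to one", {
  set.seed(53)
  x <- matrix(rnorm(12 * 3), 12, 3,
              dimnames = list(paste0("s", 1:12), paste0("g", 1:3)))
  expect_error(
    train_subtype_classifier(
      reference_cohort(x, c(rep("CIN", 10), "EBV", "EBV"), "tcga")),
    ">= 3 training samples")

  ref <- make_two_class_ref(10, delta = 3, seed = 53)
  model <- train_subtype_classifier(ref, seed = 7)
  p <- predict(model, ref$expression)
  expect_equal(unname(rowSums(p)), rep(1, nrow(p)), tolerance = 1e-9)
  expect_true(all(p >= 0 & p <= 1))

  # deterministic given seed
  model2 <- train_subtype_classifier(ref, seed = 7)
  expect_identical(predict(model2, ref$expression), p)
})

# a stub model whose predictions are dictated by the test, so the
# replicate-averaging rule can be checked in isolation
stub_model <- function(scores, classes = colnames(scores)) {
  structure(list(panel = "g1", classes = classes, scheme = "tme",
                 scores = scores),
            class = c("stub_model", "subtype_model"))
}

predict.stub_model <- function(object, newdata, ...) {
  object$scores[rownames(newdata), , drop = FALSE]
}

test_that("technical replicates are averaged and singletons pass through", {
  .S3method("predict", "stub_model", predict.stub_model)
  scores <- matrix(c(0.4, 0.6, 0.9,
                     0.6, 0.4, 0.1), 3, 2,
                   dimnames = list(c("a1", "a2", "b"), c("High", "Low")))
  Y <- matrix(0, 3, 1, dimnames = list(c("a1", "a2", "b"), "g1"))
  design <- replicate_design(c("a1", "a2", "b"), c("A", "A", "B"))
  res <- assign_subtypes(stub_model(scores), Y, design)
  expect_equal(res$High[res$unit == "A"], 0.5)  # mean of 0.4 and 0.6
  expect_equal(res$High[res$unit == "B"], 0.9)
  expect_equal(res$call, c("High", "High"))

  # order invariance: permuting samples leaves unit scores unchanged
  perm <- c("b", "a2", "a1")
  res2 <- assign_subtypes(stub_model(scores), Y[perm, , drop = FALSE],
                          design)
  expect_equal(res2[order(res2$unit), ], res[order(res$unit), ],
               ignore_attr = TRUE)

  # exact ties break deterministically by class-name order, with a note
  tie <- matrix(c(0.5, 0.5), 1, 2,
                dimnames = list("b", c("High", "Low")))
  expect_message(
    res3 <- assign_subtypes(stub_model(tie), Y["b", , drop = FALSE],
                            replicate_design("b", "B")),
    "tie")
  expect_equal(res3$call, "High")

  expect_error(
    assign_subtypes(stub_model(scores), Y,
                    replicate_design(c("a1", "a2"), c("A", "A"))),
    "absent from the replicate design")
})

test_that("combined calls cross TCGA and TME with printed prevalences", {
  units <- sprintf("u%02d", 1:38)
  tcga <- make_subtype_result(units, c(rep("CIN", 27), rep("MSI", 6),
                                       rep("GS", 3), rep("EBV", 2)))
  tme <- make_subtype_result(units, c(rep("Low", 33), rep("High", 5)),
                             scheme = "tme")
  cc <- combined_call(tcga, tme)
  prev <- cc$prevalence$tcga
  expect_equal(prev$percent[prev$class == "CIN"], 71.1)  # 27 of 38
  expect_equal(cc$table$joint[1], "CIN-TME Low")
  expect_equal(sum(cc$prevalence$joint$n), 38)

  # all one class -> 100%
  allc <- make_subtype_result(units[1:5], rep("CIN", 5))
  allt <- make_subtype_result(units[1:5], rep("Low", 5), scheme = "tme")
  expect_equal(combined_call(allc, allt)$prevalence$tcga$percent, 100)

  expect_error(combined_call(tcga, make_subtype_result("other", "Low",
                                                       scheme = "tme")),
               "unit mismatch")
})

test_that("planted class shifts are recovered monotonically in effect size", {
  accs <- vapply(c(0.5, 1, 2), function(eff) {
    cfg <- sim_config(seed = 55, n_units = 24, replicate_units = 4,
                      effect = eff, ref_n = 120)
    run <- run_simulated_pipeline(cfg)
    run$accuracy
  }, numeric(1))
  expect_true(all(diff(accs) >= 0))
  expect_gte(accs[3], 0.9)
})
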