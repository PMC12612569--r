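# End-to-end convenience wrapper: simulated panel run -> QC -> RUV-III ->
# FSQN -> subtype assignment, with recovery scoring against the planted
# truth. This is the programmatic equivalent of chaining the CLI
# subcommands simulate / qc / normalize / classify.

#' Run the full subtyping pipeline on simulated data
#'
#' Generates a panel run and a reference cohort from one configuration,
#' gates samples by QC, selects negative-control genes, removes cartridge
#' variation with RUV-III, maps onto the reference with FSQN, trains the
#' subtype classifier and assigns replicate-averaged scores and calls.
#'
#' @param cfg A [sim_config()].
#' @param k Number of unwanted factors for RUV-III (default 1).
#' @param control_fraction Negative-control gene fraction (default 0.2).
#' @return A list with `result` (a `subtype_result`), `truth` (planted
#'   unit labels), `accuracy` (fraction of units called correctly),
#'   `replicate_diff` (median absolute replicate log difference before and
#'   after RUV-III) and the intermediate `model` objects.
#' @export
run_simulated_pipeline <- function(cfg, k = 1, control_fraction = 0.2) {
  stopifnot(inherits(cfg, "sim_config"))
  run <- simulate_panel_run(cfg)
  ref <- simulate_reference_cohort(cfg)
  gated <- qc_gate(run$pcm)
  Y <- log2_expression(gated$pcm)
  controls <- select_negative_controls(Y, run$design,
                                       fraction = control_fraction)
  before <- replicate_log_difference(Y, run$design)$median_abs
  norm <- ruv3_normalize(Y, run$design, controls, k)
  after <- replicate_log_difference(norm$Y, run$design)$median_abs
  Yf <- fsqn(norm$Y, ref$expression)
  model <- train_subtype_classifier(ref, seed = cfg$seed)
  res <- assign_subtypes(model, Yf, run$design)
  truth <- run$truth$labels[res$unit]
  list(result = res, truth = truth,
       accuracy = mean(res$call == truth),
       replicate_diff = c(before = before, after = after),
       ruv3_model = norm$model, classifier = model,
       controls = controls)
}
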