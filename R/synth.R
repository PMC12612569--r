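# Synthetic-data generators: panel runs with planted cartridge effects and
# subtype shifts, reference cohorts, dose-response plates, MSI profiles,
# gene-set collections and drug-sensitivity tables. Everything is
# deterministic under the configured seed and returns its ground truth so
# recovery properties can be scored.

#' Simulation configuration
#'
#' Study-shaped defaults: 38 biological units on a 107-endogenous-gene
#' panel (6 positive, 8 negative control probes), 7 units run in technical
#' duplicate across cartridges, a one-dimensional cartridge batch effect of
#' 1 log2 unit, subtype-specific mean shifts of 2 log2 units on
#' class-marker gene blocks, log-normal count noise (sd 0.25 on the log2
#' scale), a 400-sample reference cohort with the public-cohort TCGA class
#' mix (CIN 74.1, EBV 5.6, GS 8.6, MSI 11.7 percent, renormalized), and
#' 5-percent viability noise on the assay dose grids.
#'
#' @param seed Integer seed; all generators derive their randomness from
#'   it.
#' @param n_units Number of biological units (patients/organoids) in a
#'   panel run.
#' @param replicate_units Number of units assayed in technical duplicate,
#'   with the duplicate placed on a different cartridge.
#' @param n_cartridges Number of cartridges (batches).
#' @param batch_magnitude Cartridge effect size in log2 units (0 disables).
#' @param noise_sd Gene-wise noise sd on the log2 scale.
#' @param scheme Subtype scheme for planted classes (`"tcga"` or `"tme"`).
#' @param effect Planted class-shift magnitude in log2 units.
#' @param n_genes Endogenous probe count.
#' @param ref_n Reference-cohort size.
#' @param prevalence Named class prevalence vector for the reference
#'   cohort (defaults to the public-cohort mix for the scheme).
#' @param viability_sd Dose-response viability noise sd (percent).
#' @param n_markers MSI marker count (pentaplex default 5).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1, n_units = 38, replicate_units = 7,
                       n_cartridges = 3, batch_magnitude = 1,
                       noise_sd = 0.25, scheme = "tcga", effect = 2,
                       n_genes = 107, ref_n = 400, prevalence = NULL,
                       viability_sd = 5, n_markers = 5) {
  stopifnot(seed == round(seed), n_units >= 2,
            replicate_units >= 0, replicate_units <= n_units,
            n_cartridges >= 1, batch_magnitude >= 0, noise_sd >= 0,
            effect >= 0, n_genes >= 8, ref_n >= 20, viability_sd >= 0,
            n_markers >= 1)
  classes <- scheme_classes(scheme)
  if (is.null(prevalence)) {
    prevalence <- switch(scheme,
      tcga = c(CIN = 0.741, EBV = 0.056, GS = 0.086, MSI = 0.117),
      tme = c(High = 0.334, Low = 0.666),
      acrg = c(`MSI` = 0.23, `MSS/TP53+` = 0.26, `MSS/TP53-` = 0.36,
               EMT = 0.15))
  }
  if (!setequal(names(prevalence), classes))
    stop("prevalence must name every class of the ", scheme, " scheme")
  if (any(prevalence <= 0))
    stop("degenerate prevalence: every class needs positive probability")
  prevalence <- prevalence / sum(prevalence)
  structure(list(seed = as.integer(seed), n_units = n_units,
                 replicate_units = replicate_units,
                 n_cartridges = n_cartridges,
                 batch_magnitude = batch_magnitude, noise_sd = noise_sd,
                 scheme = scheme, effect = effect, n_genes = n_genes,
                 ref_n = ref_n, prevalence = prevalence[classes],
                 viability_sd = viability_sd, n_markers = n_markers),
            class = "sim_config")
}

# Shared gene design: baselines, per-class shift matrix and the planted
# flat (control-eligible) genes. Deterministic in cfg$seed so the panel
# run and the reference cohort share the same biology.
panel_gene_design <- function(cfg) {
  set.seed(cfg$seed)
  p <- cfg$n_genes
  genes <- sprintf("GENE%03d", seq_len(p))
  baseline <- stats::runif(p, 5, 10)
  classes <- scheme_classes(cfg$scheme)
  n_flat <- ceiling(0.2 * p)
  flat <- genes[(p - n_flat + 1):p]
  block <- 10
  shifts <- matrix(0, length(classes), p, dimnames = list(classes, genes))
  for (i in seq_along(classes)) {
    idx <- ((i - 1) * block + 1):(i * block)
    idx <- idx[idx <= p - n_flat]
    shifts[i, idx] <- cfg$effect
  }
  # a one-dimensional unwanted factor loading, shared by all samples on a
  # cartridge
  batch_loading <- stats::runif(p, 0.5, 1.5)
  list(genes = genes, baseline = baseline, shifts = shifts, flat = flat,
       batch_loading = batch_loading, classes = classes)
}

#' Simulate a panel run
#'
#' Generates a raw count matrix on the configured panel:
#' `counts = round(2^(baseline + class shift + cartridge effect +
#' noise)) - 1` per endogenous probe, with positive-control probes on the
#' standard spike ladder, negative-control probes at background level, and
#' imaging metadata within QC bounds. Technical duplicates are placed on a
#' different cartridge than their first sample. Ground truth (unit labels,
#' per-sample cartridge scores, planted flat genes) is returned for
#' recovery tests.
#'
#' @param cfg A [sim_config()].
#' @return A list with `pcm` ([panel_count_matrix()]), `design`
#'   ([replicate_design()]), `truth` (unit labels, cartridge scores, flat
#'   genes, shift matrix) and `log2_true` (noise-free log2 expression).
#' @export
simulate_panel_run <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$replicate_units > cfg$n_units)
    stop("cannot replicate more units than exist")
  des <- panel_gene_design(cfg)
  set.seed(cfg$seed + 1L)

  units <- sprintf("U%02d", seq_len(cfg$n_units))
  labels <- sample(des$classes, cfg$n_units, replace = TRUE,
                   prob = cfg$prevalence)
  # guarantee every class occurs at least once when feasible
  if (cfg$n_units >= length(des$classes))
    labels[seq_along(des$classes)] <- des$classes
  names(labels) <- units

  sample_unit <- c(units, units[seq_len(cfg$replicate_units)])
  samples <- c(units,
               if (cfg$replicate_units > 0)
                 paste0(units[seq_len(cfg$replicate_units)], "_rep"))
  cart <- (seq_along(units) - 1L) %% cfg$n_cartridges + 1L
  cart_rep <- (cart[seq_len(cfg$replicate_units)]) %% cfg$n_cartridges + 1L
  cart_all <- c(cart, cart_rep)
  # centred per-cartridge scores scaled to the requested magnitude
  cart_score <- if (cfg$n_cartridges == 1) rep(0, 1) else {
    s <- seq_len(cfg$n_cartridges) - (cfg$n_cartridges + 1) / 2
    cfg$batch_magnitude * s / max(abs(s))
  }

  p <- cfg$n_genes
  n <- length(samples)
  log2_true <- matrix(0, n, p, dimnames = list(samples, des$genes))
  for (i in seq_len(n)) {
    u <- sample_unit[i]
    log2_true[i, ] <- des$baseline + des$shifts[labels[u], ] +
      cart_score[cart_all[i]] * des$batch_loading
  }
  noisy <- log2_true + matrix(stats::rnorm(n * p, 0, cfg$noise_sd), n, p)
  endo <- pmax(round(2^noisy) - 1, 0)

  pos_conc <- c(128, 32, 8, 2, 0.5, 0.125)
  pos_names <- sprintf("POS_%s(%s)", LETTERS[1:6], as.character(pos_conc))
  pos <- t(vapply(seq_len(n), function(i)
    round(pos_conc * 60 * stats::runif(1, 0.9, 1.1)), numeric(6)))
  neg <- matrix(stats::rpois(n * 8, 4), n, 8)
  colnames(neg) <- paste0("NEG_", LETTERS[1:8])
  colnames(pos) <- pos_names

  counts <- cbind(endo, pos, neg)
  rownames(counts) <- samples
  probe_class <- c(rep("endogenous", p), rep("positive", 6),
                   rep("negative", 8))
  meta <- data.frame(
    fov_count = rep(555, n),
    fov_counted = round(555 * stats::runif(n, 0.9, 1)),
    binding_density = stats::runif(n, 0.5, 1.8),
    tissue = rep("FFPE", n),
    row.names = samples)
  pcm <- panel_count_matrix(counts, probe_class,
                            paste0("CART", cart_all), meta)
  design <- replicate_design(samples, sample_unit)
  list(pcm = pcm, design = design,
       truth = list(labels = labels,
                    cartridge_score = stats::setNames(
                      cart_score[cart_all], samples),
                    flat_genes = des$flat, shifts = des$shifts,
                    batch_loading = des$batch_loading),
       log2_true = log2_true)
}

#' Simulate a reference cohort
#'
#' Batch-free expression for `ref_n` samples drawn from the configured
#' class prevalences, sharing the gene design (baselines and class shifts)
#' of [simulate_panel_run()] under the same seed, so a classifier trained
#' on the cohort transfers to the simulated panel.
#'
#' @param cfg A [sim_config()].
#' @return A [reference_cohort()].
#' @export
simulate_reference_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  des <- panel_gene_design(cfg)
  set.seed(cfg$seed + 2L)
  n <- cfg$ref_n
  labels <- sample(des$classes, n, replace = TRUE, prob = cfg$prevalence)
  # every class needs enough members to train on
  labels[seq_len(3 * length(des$classes))] <- rep(des$classes, 3)
  expr <- t(vapply(labels, function(cl)
    des$baseline + des$shifts[cl, ], numeric(cfg$n_genes)))
  expr <- expr + matrix(stats::rnorm(n * cfg$n_genes, 0, cfg$noise_sd),
                        n, cfg$n_genes)
  dimnames(expr) <- list(sprintf("REF%04d", seq_len(n)), des$genes)
  reference_cohort(expr, labels, cfg$scheme)
}

#' Simulate dose-response plates
#'
#' One curve per assay drug on its standard grid, generated from known
#' 4PL parameters with Gaussian viability noise, in triplicate.
#'
#' @param cfg A [sim_config()].
#' @param params Optional named list of true parameter vectors
#'   `c(a, d, h, x50)` per drug; defaults are drawn per drug from
#'   realistic ranges (a = 0, d in [80, 100], h in [0.7, 2], x50 inside
#'   the grid).
#' @param replicates Technical replicates per concentration (default 3).
#' @return A list with `curves` (named list of
#'   [dose_response_curve()]) and `truth` (per-drug parameter vectors).
#' @export
simulate_dose_response <- function(cfg, params = NULL, replicates = 3) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 3L)
  grids <- assay_dose_grids()
  curves <- list(); truth <- list()
  for (drug in names(grids)) {
    conc <- grids[[drug]]
    if (any(conc <= 0)) stop("concentrations must be positive")
    x <- log10(conc)
    th <- if (!is.null(params) && drug %in% names(params)) params[[drug]]
    else c(a = 0, d = stats::runif(1, 80, 100),
           h = stats::runif(1, 0.7, 2),
           x50 = stats::runif(1, min(x) + 0.5, max(x) - 0.5))
    xx <- rep(x, each = replicates)
    inhib <- pl4_curve(xx, th["a"], th["d"], th["h"], th["x50"])
    viab <- 100 - inhib + stats::rnorm(length(xx), 0, cfg$viability_sd)
    curves[[drug]] <- dose_response_curve(drug, rep(conc, each = replicates),
                                          viab, "simulated")
    truth[[drug]] <- th
  }
  list(curves = curves, truth = truth)
}

#' Simulate MSI marker profiles consistent with subtype labels
#'
#' Samples labelled MSI receive 2-5 unstable markers (MSI-High under the
#' pentaplex rule); all other classes receive 0 (MSS), so the generated
#' gold standard agrees with the planted truth.
#'
#' @param labels Named character vector of subtype labels (names = sample
#'   IDs).
#' @param cfg A [sim_config()] (supplies marker count and seed).
#' @return Named list of [msi_profile()] objects.
#' @export
simulate_msi_profiles <- function(labels, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 4L)
  m <- cfg$n_markers
  out <- lapply(names(labels), function(s) {
    k <- if (labels[[s]] == "MSI") sample(2:max(2, m), 1) else 0
    unstable <- rep(FALSE, m)
    if (k > 0) unstable[sample.int(m, min(k, m))] <- TRUE
    msi_profile(stats::setNames(unstable, c("BAT-25", "BAT-26", "NR-21",
                                            "NR-24", "MONO-27",
                                            paste0("M", seq_len(max(0, m - 5))))[seq_len(m)]),
                s)
  })
  stats::setNames(out, names(labels))
}

#' Simulate paired parent-tumour / organoid subtype assignments
#'
#' Twelve patients yield eleven evaluable pairs in the study design; the
#' default fixture has 9 of 11 TME-concordant and 7 of 11 TCGA-concordant
#' pairs, with discordant organoids transitioning to CIN / TME Low (the
#' drift seen in culture). Per-member subtype scores consistent with the
#' calls are attached.
#'
#' @param cfg A [sim_config()].
#' @param n_pairs Number of pairs (default 11).
#' @param tcga_matches,tme_matches Concordant pair counts (defaults 7
#'   and 9).
#' @return data.frame with `patient`, `parent_tcga`, `organoid_tcga`,
#'   `parent_tme`, `organoid_tme`, and per-member MSI score columns.
#' @export
simulate_paired_assignments <- function(cfg, n_pairs = 11,
                                        tcga_matches = 7, tme_matches = 9) {
  stopifnot(inherits(cfg, "sim_config"),
            tcga_matches <= n_pairs, tme_matches <= n_pairs)
  set.seed(cfg$seed + 5L)
  patients <- sprintf("P%02d", seq_len(n_pairs))
  parent_tcga <- sample(TCGA_CLASSES, n_pairs, replace = TRUE,
                        prob = c(0.6, 0.1, 0.1, 0.2))
  organoid_tcga <- parent_tcga
  flip <- utils::tail(seq_len(n_pairs), n_pairs - tcga_matches)
  organoid_tcga[flip] <- ifelse(parent_tcga[flip] == "CIN", "GS", "CIN")
  parent_tme <- ifelse(parent_tcga %in% c("EBV", "MSI"), "High", "Low")
  organoid_tme <- parent_tme
  flip2 <- utils::tail(seq_len(n_pairs), n_pairs - tme_matches)
  organoid_tme[flip2] <- ifelse(parent_tme[flip2] == "High", "Low", "High")
  parent_msi_score <- ifelse(parent_tcga == "MSI",
                             stats::runif(n_pairs, 0.6, 0.9),
                             stats::runif(n_pairs, 0.02, 0.2))
  organoid_msi_score <- pmax(0, parent_msi_score -
                               stats::runif(n_pairs, 0, 0.15))
  data.frame(patient = patients, parent_tcga = parent_tcga,
             organoid_tcga = organoid_tcga, parent_tme = parent_tme,
             organoid_tme = organoid_tme,
             parent_msi_score = parent_msi_score,
             organoid_msi_score = organoid_msi_score)
}

#' Simulate a gene-set collection
#'
#' Random sets over a universe, optionally with a planted hub gene that is
#' a member of `hub_sets` of the first sets (so degree ranking must
#' recover it).
#'
#' @param universe Character vector of universe genes.
#' @param n_sets Number of sets (default 10).
#' @param set_size Range of set sizes (default 5 to 15).
#' @param hub_gene Optional gene symbol to plant.
#' @param hub_sets Number of sets the hub joins (default 3).
#' @param seed Seed.
#' @return A [gene_set_collection()].
#' @export
simulate_gene_sets <- function(universe, n_sets = 10, set_size = c(5, 15),
                               hub_gene = NULL, hub_sets = 3, seed = 1) {
  set.seed(seed)
  sets <- lapply(seq_len(n_sets), function(i) {
    k <- sample(set_size[1]:set_size[2], 1)
    sample(universe, min(k, length(universe)))
  })
  names(sets) <- sprintf("SET_%02d", seq_len(n_sets))
  if (!is.null(hub_gene)) {
    for (i in seq_len(min(hub_sets, n_sets)))
      sets[[i]] <- unique(c(sets[[i]], hub_gene))
  }
  gene_set_collection(sets, unique(c(universe, hub_gene)), "simulated")
}

#' Simulate a drug-sensitivity association table
#'
#' Cell-line AUC values for a drug screen with pathway annotations and a
#' controllable missingness pattern, plus per-line subtype scores. Drugs
#' in pathways listed in `linked_pathways` have AUC correlated with the
#' first subtype score so pathway pooling has signal to find.
#'
#' @param cfg A [sim_config()].
#' @param n_lines Cell lines (default 37, the gastric screen size).
#' @param n_drugs Drugs (default 111).
#' @param pathways Pathway label pool.
#' @param missing_fracs Missingness fractions cycled over drugs (default
#'   mostly complete with some drugs above the 25-percent filter).
#' @param linked_pathways Pathways whose drugs correlate with the first
#'   score column.
#' @return A list with `auc` (lines x drugs), `pathways` (named vector),
#'   `scores` (lines x classes).
#' @export
simulate_drug_table <- function(cfg, n_lines = 37, n_drugs = 111,
                                pathways = c("PI3K/MTOR", "ERK MAPK",
                                             "DNA replication", "EGFR",
                                             "Cell cycle", "Apoptosis",
                                             "Chromatin", "Other"),
                                missing_fracs = c(0, 0, 0.1, 0, 0.3),
                                linked_pathways = "PI3K/MTOR") {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 6L)
  classes <- scheme_classes(cfg$scheme)
  raw <- matrix(stats::rexp(n_lines * length(classes)), n_lines)
  scores <- raw / rowSums(raw)
  dimnames(scores) <- list(sprintf("LINE%02d", seq_len(n_lines)), classes)
  drugs <- sprintf("DRUG%03d", seq_len(n_drugs))
  path <- stats::setNames(sample(pathways, n_drugs, replace = TRUE), drugs)
  auc <- matrix(NA_real_, n_lines, n_drugs,
                dimnames = list(rownames(scores), drugs))
  mf <- rep_len(missing_fracs, n_drugs)
  for (j in seq_len(n_drugs)) {
    base <- stats::rnorm(n_lines, 0.7, 0.1)
    if (path[j] %in% linked_pathways)
      base <- base - 0.5 * scores[, 1]  # sensitive where score is high
    n_miss <- round(mf[j] * n_lines)
    if (n_miss > 0) base[sample.int(n_lines, n_miss)] <- NA
    auc[, j] <- base
  }
  list(auc = auc, pathways = path, scores = scores)
}
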