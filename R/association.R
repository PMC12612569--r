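# Comparison statistics: paired tumour-organoid concordance, cohort
# proportion/score comparisons, and subtype-score vs drug-sensitivity
# association with target-pathway pooling.

#' Categorical concordance between paired assignments
#'
#' Percent of pairs (e.g., parent tumour vs derived organoid) assigned the
#' same class, with a chi-square test comparing the two class frequency
#' distributions. The measure is symmetric in the pair.
#'
#' @param parent,organoid Character vectors of class calls, equal length.
#' @return A list with `percent` (1 decimal), `n_matched`, `n`,
#'   `chisq_p` and the frequency `table`.
#' @export
categorical_concordance <- function(parent, organoid) {
  parent <- as.character(parent); organoid <- as.character(organoid)
  if (length(parent) == 0 || length(parent) != length(organoid))
    stop("need a non-empty set of pairs with both members present")
  n <- length(parent)
  matched <- sum(parent == organoid)
  classes <- sort(unique(c(parent, organoid)))
  freq <- rbind(parent = table(factor(parent, classes)),
                organoid = table(factor(organoid, classes)))
  p <- if (ncol(freq) < 2) 1 else
    suppressWarnings(stats::chisq.test(freq, correct = FALSE)$p.value)
  list(percent = round(100 * matched / n, 1), n_matched = matched, n = n,
       chisq_p = p, table = freq)
}

#' Paired Wilcoxon signed-rank test on subtype scores
#'
#' Two-sided signed-rank test of paired scores (parent vs organoid). Zero
#' differences are dropped (signed-rank convention); with 25 or fewer
#' untied non-zero differences the exact distribution is used, otherwise a
#' normal approximation with continuity correction. If every difference is
#' zero the test is degenerate and reported as p = 1 with a flag.
#'
#' @param a,b Paired numeric score vectors.
#' @return A list with `statistic` (V), `p`, `n_effective`, `exact` and
#'   `degenerate`.
#' @export
paired_score_test <- function(a, b) {
  if (length(a) != length(b) || length(a) == 0)
    stop("paired vectors must be non-empty and of equal length")
  d <- b - a
  nz <- d[d != 0]
  if (length(nz) == 0)
    return(list(statistic = NA_real_, p = 1, n_effective = 0L,
                exact = FALSE, degenerate = TRUE))
  use_exact <- length(nz) <= 25 && !anyDuplicated(abs(nz))
  wt <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value,
       n_effective = length(nz), exact = use_exact, degenerate = FALSE)
}

#' Chi-square comparison of subtype proportions between cohorts
#'
#' Pearson chi-square (no continuity correction) on the 2 x K table of
#' class counts in a study cohort vs a reference cohort. Categories absent
#' from both are dropped with a warning; a zero count in one cohort only
#' is retained.
#'
#' @param cohort_counts,reference_counts Named integer vectors of class
#'   counts.
#' @return A list with `statistic`, `df`, `p`, the `table` used, and
#'   `expected_ok` (all expected counts >= 5).
#' @export
proportion_comparison <- function(cohort_counts, reference_counts) {
  classes <- union(names(cohort_counts), names(reference_counts))
  get <- function(v) {
    out <- stats::setNames(rep(0, length(classes)), classes)
    out[names(v)] <- v
    out
  }
  a <- get(cohort_counts); b <- get(reference_counts)
  empty <- a + b == 0
  if (any(empty)) {
    warning("dropping categories absent from both cohorts: ",
            paste(classes[empty], collapse = ", "))
    a <- a[!empty]; b <- b[!empty]
  }
  tab <- rbind(cohort = a, reference = b)
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, table = tab, expected_ok = all(ct$expected >= 5))
}

#' Rank-sum comparison of scores between two groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test of a score between two
#' groups, e.g., genomically-stable score in diffuse vs intestinal-type
#' tumours. When several panels are tested at once, supply a list and
#' Benjamini-Hochberg adjusted q-values are returned alongside.
#'
#' @param scores Numeric vector (or, for multi-panel use, a named list of
#'   vectors).
#' @param grouping Factor-like with exactly two levels (or list parallel
#'   to `scores`).
#' @return For vectors: list with `statistic`, `p`. For lists: data.frame
#'   with `panel`, `statistic`, `p`, `q` (BH).
#' @export
score_by_group_test <- function(scores, grouping) {
  one <- function(s, g) {
    g <- factor(g)
    if (nlevels(g) != 2) stop("grouping must have exactly two levels")
    ns <- table(g)
    if (any(ns < 2)) stop("each group needs >= 2 observations")
    use_exact <- length(s) <= 25 && !anyDuplicated(s)
    wt <- suppressWarnings(
      stats::wilcox.test(s[g == levels(g)[1]], s[g == levels(g)[2]],
                         alternative = "two.sided", exact = use_exact,
                         correct = TRUE))
    list(statistic = unname(wt$statistic), p = wt$p.value)
  }
  if (is.list(scores) && !is.data.frame(scores)) {
    res <- Map(one, scores, grouping)
    out <- data.frame(panel = names(res),
                      statistic = vapply(res, `[[`, numeric(1), "statistic"),
                      p = vapply(res, `[[`, numeric(1), "p"),
                      row.names = NULL)
    out$q <- stats::p.adjust(out$p, method = "BH")
    out
  } else {
    one(scores, grouping)
  }
}

# Dunn's post hoc pairwise z-tests after Kruskal-Wallis, with tie
# correction on the pooled ranking and Bonferroni adjustment.
dunn_posthoc <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  tie_tab <- table(r)
  tie_corr <- sum(tie_tab^3 - tie_tab) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- table(groups)
  lv <- levels(groups)
  comps <- utils::combn(lv, 2)
  m <- ncol(comps)
  out <- data.frame(group1 = comps[1, ], group2 = comps[2, ],
                    z = NA_real_, p = NA_real_, p_bonferroni = NA_real_)
  for (j in seq_len(m)) {
    i1 <- comps[1, j]; i2 <- comps[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[i1] + 1 / ns[i2]))
    z <- (rbar[i1] - rbar[i2]) / se
    out$z[j] <- z
    out$p[j] <- 2 * stats::pnorm(-abs(z))
  }
  out$p_bonferroni <- pmin(out$p * m, 1)
  out
}

#' Subtype-score vs drug-sensitivity association
#'
#' The cell-line association analysis: drugs with more than `max_missing`
#' missing sensitivity values are removed; for each remaining drug and
#' each subtype score, Pearson's correlation (pairwise-complete, two-sided
#' t-approximation p, plus BH-adjusted q across the drug screen) is
#' computed between the score and sensitivity (area under the curve, where
#' lower usually means more sensitive). Correlations are then pooled by
#' the drug's target pathway and compared across pathways with a
#' Kruskal-Wallis test followed by Dunn's post hoc z-tests with Bonferroni
#' correction.
#'
#' @param auc Cell-lines x drugs numeric matrix of sensitivity values (NA
#'   for missing).
#' @param pathways Named character vector: target pathway per drug.
#' @param scores Cell-lines x classes matrix of subtype scores (rows
#'   aligned with `auc`).
#' @param max_missing Maximum tolerated missing fraction per drug
#'   (default 0.25).
#' @return A list with `per_drug` (drug, class, pathway, n, r, p, q),
#'   `kruskal` (per class: statistic, df, p) and `dunn` (per class
#'   pairwise table), plus `excluded_drugs`.
#' @export
drug_subtype_association <- function(auc, pathways, scores,
                                     max_missing = 0.25) {
  auc <- as.matrix(auc); scores <- as.matrix(scores)
  if (nrow(auc) != nrow(scores))
    stop("auc and scores must cover the same cell lines")
  if (is.null(colnames(auc))) stop("auc needs drug column names")
  miss <- setdiff(colnames(auc), names(pathways))
  if (length(miss)) stop("drugs without a pathway label: ",
                         paste(miss, collapse = ", "))
  frac_missing <- colMeans(is.na(auc))
  excluded <- colnames(auc)[frac_missing > max_missing]
  keep <- setdiff(colnames(auc), excluded)
  if (length(keep) == 0) stop("all drugs exceed the missing-data filter")

  rows <- list()
  for (drug in keep) {
    for (cls in colnames(scores)) {
      ok <- stats::complete.cases(auc[, drug], scores[, cls])
      if (sum(ok) < 3)
        stop("drug ", drug, " has fewer than 3 complete observations")
      ct <- stats::cor.test(auc[ok, drug], scores[ok, cls],
                            method = "pearson")
      rows[[length(rows) + 1]] <-
        data.frame(drug = drug, class = cls,
                   pathway = unname(pathways[drug]), n = sum(ok),
                   r = unname(ct$estimate), p = ct$p.value)
    }
  }
  per_drug <- do.call(rbind, rows)
  per_drug$q <- stats::p.adjust(per_drug$p, method = "BH")

  kruskal <- list(); dunn <- list()
  for (cls in colnames(scores)) {
    sub <- per_drug[per_drug$class == cls, ]
    groups <- factor(sub$pathway)
    if (nlevels(groups) < 2)
      stop("fewer than 2 target-pathway groups remain after filtering")
    kt <- stats::kruskal.test(sub$r, groups)
    kruskal[[cls]] <- list(statistic = unname(kt$statistic),
                           df = unname(kt$parameter), p = kt$p.value)
    dunn[[cls]] <- dunn_posthoc(sub$r, groups)
  }
  list(per_drug = per_drug, kruskal = kruskal, dunn = dunn,
       excluded_drugs = excluded)
}

#' Class-transition edge list for paired assignments
#'
#' Sankey-style edge list counting transitions from parent class to
#' organoid class.
#'
#' @inheritParams categorical_concordance
#' @return data.frame with `from`, `to`, `n`.
#' @export
transition_table <- function(parent, organoid) {
  t <- table(from = parent, to = organoid)
  d <- as.data.frame(t, responseName = "n", stringsAsFactors = FALSE)
  d[d$n > 0, ]
}
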