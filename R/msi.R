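# Pentaplex microsatellite-instability calling and its concordance with
# the expression-based classifier.

#' MSI marker profile
#'
#' Per-marker tumour-vs-matched-normal instability indicators for one
#' sample, from the pentaplex mononucleotide-marker PCR assay (allele
#' calling is performed upstream; this consumes marker-level booleans).
#'
#' @param unstable Named logical vector: `TRUE` where allelic variation is
#'   present at that marker.
#' @param sample_id Sample identifier.
#' @return An object of class `msi_profile`.
#' @export
msi_profile <- function(unstable, sample_id = "sample") {
  if (length(unstable) < 1) stop("profile must contain >= 1 marker")
  if (!is.logical(unstable) || anyNA(unstable))
    stop("marker instability must be non-missing logical values")
  if (is.null(names(unstable)))
    names(unstable) <- paste0("marker", seq_along(unstable))
  structure(list(unstable = unstable, sample_id = sample_id),
            class = "msi_profile")
}

#' Call MSI status from a marker profile
#'
#' The pentaplex rule: allelic variation in two or more microsatellite
#' markers is MSI-High, exactly one is MSI-Low, none is microsatellite
#' stable (MSS). The call is a pure function of the unstable-marker count.
#'
#' @param profile An [msi_profile()].
#' @return A list with `call` in {`"MSI-High"`, `"MSI-Low"`, `"MSS"`} and
#'   `n_unstable`.
#' @export
call_msi <- function(profile) {
  stopifnot(inherits(profile, "msi_profile"))
  n <- sum(profile$unstable)
  call <- if (n >= 2) "MSI-High" else if (n == 1) "MSI-Low" else "MSS"
  list(call = call, n_unstable = n, sample_id = profile$sample_id)
}

#' Read marker profiles from a long TSV
#'
#' @param path TSV with columns `sample`, `marker`, `unstable`
#'   (TRUE/FALSE or 0/1).
#' @return Named list of [msi_profile()] objects, one per sample.
#' @export
read_msi_profiles <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  if (!all(c("sample", "marker", "unstable") %in% names(d)))
    stop("marker table needs columns: sample, marker, unstable")
  out <- lapply(split(d, d$sample), function(g)
    msi_profile(stats::setNames(as.logical(g$unstable), g$marker),
                g$sample[1]))
  out[unique(d$sample)]
}

#' Concordance of PCR MSI calls with the expression classifier
#'
#' Binarizes both sides — gold standard positive = MSI-High (MSI-Low maps
#' to "not MSI", since the TCGA scheme has a single MSI class); classifier
#' positive = a TCGA call of MSI — and tabulates the 2x2 contingency with
#' accuracy (TP + TN) / n over the shared samples.
#'
#' @param msi_calls Named character vector of pentaplex calls
#'   (`"MSI-High"`, `"MSI-Low"`, `"MSS"`), names = sample IDs.
#' @param subtype_calls Named character vector of classifier calls (TCGA
#'   classes), names = sample IDs.
#' @return A list with `table` (2x2 contingency), `accuracy` (percent) and
#'   `n`.
#' @export
concordance_with_classifier <- function(msi_calls, subtype_calls) {
  shared <- intersect(names(msi_calls), names(subtype_calls))
  if (length(shared) == 0) stop("no shared sample IDs between the two call sets")
  gold <- factor(msi_calls[shared] == "MSI-High", levels = c(TRUE, FALSE),
                 labels = c("MSI-High", "not MSI-High"))
  pred <- factor(subtype_calls[shared] == "MSI", levels = c(TRUE, FALSE),
                 labels = c("MSI", "not MSI"))
  tab <- table(classifier = pred, pcr = gold)
  acc <- 100 * (tab["MSI", "MSI-High"] + tab["not MSI", "not MSI-High"]) /
    length(shared)
  list(table = tab, accuracy = acc, n = length(shared))
}
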