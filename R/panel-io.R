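# Panel count containers, RCC reading/writing and sample-level QC.

PROBE_CLASSES <- c("endogenous", "positive", "negative", "housekeeping")

#' Panel count matrix
#'
#' Container for raw targeted-panel counts: a samples x probes matrix of
#' non-negative integers together with per-probe classes (endogenous,
#' positive control, negative control, housekeeping), per-sample cartridge
#' identifiers and free-form sample metadata.
#'
#' @param counts Integer-valued matrix, samples in rows, probes in columns.
#'   Row and column names are required and must be unique.
#' @param probe_class Character vector, one of `"endogenous"`, `"positive"`,
#'   `"negative"`, `"housekeeping"` per probe (recycled names checked
#'   against `colnames(counts)`).
#' @param cartridge_id Character vector of per-sample cartridge (batch)
#'   labels.
#' @param sample_meta Optional data.frame of per-sample annotations (row
#'   names matching samples). Columns `fov_count`, `fov_counted` and
#'   `binding_density`, when present, feed the imaging and binding-density
#'   QC checks.
#' @return An object of class `panel_count_matrix`.
#' @export
panel_count_matrix <- function(counts, probe_class, cartridge_id,
                               sample_meta = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have sample row names and probe column names")
  if (anyDuplicated(colnames(counts)))
    stop("probe names must be unique")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample names: ", paste(
      unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("counts must be finite and non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integer-valued")
  storage.mode(counts) <- "double"

  probe_class <- as.character(probe_class)
  if (length(probe_class) != ncol(counts))
    stop("probe_class must have one entry per probe")
  if (!all(probe_class %in% PROBE_CLASSES))
    stop("probe_class values must be in: ", paste(PROBE_CLASSES, collapse = ", "))
  names(probe_class) <- colnames(counts)
  if (!any(probe_class == "endogenous"))
    stop("at least one endogenous probe is required")

  cartridge_id <- as.character(cartridge_id)
  if (length(cartridge_id) != nrow(counts))
    stop("every sample needs a cartridge_id")
  if (anyNA(cartridge_id) || any(cartridge_id == ""))
    stop("cartridge_id entries must be non-empty")
  names(cartridge_id) <- rownames(counts)

  if (is.null(sample_meta)) {
    sample_meta <- data.frame(row.names = rownames(counts))
  } else {
    sample_meta <- as.data.frame(sample_meta)
    if (nrow(sample_meta) != nrow(counts))
      stop("sample_meta must have one row per sample")
    rownames(sample_meta) <- rownames(counts)
  }

  structure(
    list(counts = counts, probe_class = probe_class,
         cartridge_id = cartridge_id, sample_meta = sample_meta),
    class = "panel_count_matrix")
}

#' @exportS3Method base::print
print.panel_count_matrix <- function(x, ...) {
  tab <- table(factor(x$probe_class, levels = PROBE_CLASSES))
  cat("panel_count_matrix:", nrow(x$counts), "sample(s) x",
      ncol(x$counts), "probe(s)\n")
  cat("  probes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  cartridges:", paste(unique(x$cartridge_id), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / probes in a panel count matrix
#' @param x A `panel_count_matrix`.
#' @return `dim` returns `c(samples, probes)`.
#' @export
dim.panel_count_matrix <- function(x) dim(x$counts)

#' Subset samples of a panel count matrix
#' @param x A `panel_count_matrix`.
#' @param samples Character or integer index of samples to keep.
#' @return A `panel_count_matrix` restricted to `samples`.
#' @export
subset_samples <- function(x, samples) {
  stopifnot(inherits(x, "panel_count_matrix"))
  panel_count_matrix(x$counts[samples, , drop = FALSE], x$probe_class,
                     x$cartridge_id[samples],
                     x$sample_meta[samples, , drop = FALSE])
}

# nCounter positive-control probes carry their spike concentration (fM) in
# the probe name, e.g. "POS_A(128)".
parse_positive_conc <- function(probe_names) {
  m <- regmatches(probe_names, regexpr("\\(([0-9.]+)\\)", probe_names))
  out <- rep(NA_real_, length(probe_names))
  has <- lengths(regmatches(probe_names, gregexpr("\\(([0-9.]+)\\)", probe_names))) > 0
  out[has] <- as.numeric(gsub("[()]", "", m))
  out
}

rcc_class_map <- c(Endogenous = "endogenous", Positive = "positive",
                   Negative = "negative", Housekeeping = "housekeeping")

#' Read a single-sample RCC file
#'
#' Parses the nCounter instrument's sectioned text output (Header,
#' Sample_Attributes, Lane_Attributes, Code_Summary) into a one-sample
#' [panel_count_matrix()]. The cartridge ID is taken from the lane
#' attributes; imaging fields (`FovCount`, `FovCounted`, `BindingDensity`)
#' are carried into `sample_meta` for QC.
#'
#' @param path Path to an RCC file.
#' @return A `panel_count_matrix` with one sample.
#' @export
read_rcc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  section_of <- function(name) {
    open <- match(paste0("<", name, ">"), lines)
    close <- match(paste0("</", name, ">"), lines)
    if (is.na(open) || is.na(close) || close <= open)
      stop("malformed RCC file '", basename(path), "': missing or unclosed section <",
           name, ">")
    lines[(open + 1):(close - 1)]
  }
  kv <- function(sec) {
    parts <- strsplit(sec, ",", fixed = TRUE)
    stats::setNames(vapply(parts, function(p) if (length(p) > 1) p[2] else "",
                           character(1)),
                    vapply(parts, `[`, character(1), 1))
  }
  section_of("Header")  # presence check only
  samp <- kv(section_of("Sample_Attributes"))
  lane <- kv(section_of("Lane_Attributes"))
  code <- section_of("Code_Summary")

  hdr <- strsplit(code[1], ",", fixed = TRUE)[[1]]
  if (!identical(hdr[1:4], c("CodeClass", "Name", "Accession", "Count")))
    stop("malformed RCC file '", basename(path),
         "': Code_Summary header must be CodeClass,Name,Accession,Count")
  body <- strsplit(code[-1], ",", fixed = TRUE)
  body <- body[lengths(body) >= 4]
  cls_raw <- vapply(body, `[`, character(1), 1)
  probe <- vapply(body, `[`, character(1), 2)
  cnt <- suppressWarnings(as.numeric(vapply(body, `[`, character(1), 4)))
  if (anyNA(cnt))
    stop("malformed RCC file '", basename(path), "': non-numeric count in Code_Summary")
  if (any(cnt < 0))
    stop("negative count in '", basename(path), "'")
  if (!all(cls_raw %in% names(rcc_class_map)))
    stop("unknown CodeClass in '", basename(path), "': ",
         paste(setdiff(cls_raw, names(rcc_class_map)), collapse = ", "))

  sample_id <- if (!is.na(samp["ID"]) && nzchar(samp["ID"])) unname(samp["ID"])
               else sub("\\.rcc$", "", basename(path), ignore.case = TRUE)
  cart <- if (!is.na(lane["CartridgeID"]) && nzchar(lane["CartridgeID"]))
    unname(lane["CartridgeID"]) else stop("RCC lane attributes lack CartridgeID")

  counts <- matrix(cnt, nrow = 1, dimnames = list(sample_id, probe))
  meta <- data.frame(
    fov_count = suppressWarnings(as.numeric(lane["FovCount"])),
    fov_counted = suppressWarnings(as.numeric(lane["FovCounted"])),
    binding_density = suppressWarnings(as.numeric(lane["BindingDensity"])),
    row.names = sample_id)
  panel_count_matrix(counts, unname(rcc_class_map[cls_raw]), cart, meta)
}

#' Write samples of a panel count matrix as RCC files
#'
#' Inverse of [read_rcc()]: one sectioned RCC text file per sample.
#'
#' @param pcm A `panel_count_matrix`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_rcc <- function(pcm, dir) {
  stopifnot(inherits(pcm, "panel_count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  inv_map <- stats::setNames(names(rcc_class_map), rcc_class_map)
  paths <- character(0)
  for (s in rownames(pcm$counts)) {
    meta <- pcm$sample_meta[s, , drop = FALSE]
    num_or <- function(col, default) {
      if (col %in% names(meta) && is.finite(meta[[col]])) meta[[col]] else default
    }
    lines <- c(
      "<Header>", "FileVersion,3.0", "SoftwareVersion,4.0", "</Header>",
      "<Sample_Attributes>", paste0("ID,", s), "Owner,", "Comments,",
      "Date,20240101", "GeneRLF,GP107", "SystemAPF,n.a.",
      "</Sample_Attributes>",
      "<Lane_Attributes>", "ID,1",
      paste0("FovCount,", format(num_or("fov_count", 555))),
      paste0("FovCounted,", format(num_or("fov_counted", 555))),
      "ScannerID,SIM", "StagePosition,1",
      paste0("BindingDensity,", format(num_or("binding_density", 1))),
      paste0("CartridgeID,", pcm$cartridge_id[[s]]),
      "</Lane_Attributes>",
      "<Code_Summary>", "CodeClass,Name,Accession,Count",
      sprintf("%s,%s,NA,%d", inv_map[pcm$probe_class], colnames(pcm$counts),
              as.integer(round(pcm$counts[s, ]))),
      "</Code_Summary>", "<Messages>", "</Messages>")
    p <- file.path(dir, paste0(s, ".rcc"))
    writeLines(lines, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read a set of RCC files into one panel count matrix
#'
#' Concatenates per-file samples. Files must share the same probe set;
#' duplicate sample names across files are an error rather than being
#' silently suffixed.
#'
#' @param paths Character vector of RCC file paths.
#' @return A `panel_count_matrix`.
#' @export
read_rcc_set <- function(paths) {
  if (length(paths) == 0) stop("no RCC files given")
  parts <- lapply(paths, read_rcc)
  probes <- colnames(parts[[1]]$counts)
  for (p in parts[-1]) {
    if (!identical(colnames(p$counts), probes))
      stop("RCC files do not share a common probe set")
  }
  samples <- unlist(lapply(parts, function(p) rownames(p$counts)))
  if (anyDuplicated(samples))
    stop("duplicate sample names across RCC files: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  panel_count_matrix(
    do.call(rbind, lapply(parts, function(p) p$counts)),
    parts[[1]]$probe_class,
    unlist(lapply(parts, function(p) p$cartridge_id)),
    do.call(rbind, lapply(parts, function(p) p$sample_meta)))
}

#' Read / write a plain sample x gene count table
#'
#' Plain-table alternative to RCC ingestion: a counts matrix (CSV/TSV,
#' samples in rows) with a sidecar probe table (`probe`, `class`) and a
#' sample metadata table (`sample`, `cartridge_id`, further columns kept as
#' metadata).
#'
#' @param counts_file,probe_file,meta_file File paths; separator inferred
#'   from the extension (`.csv` comma, otherwise tab).
#' @return A `panel_count_matrix`.
#' @export
read_count_table <- function(counts_file, probe_file, meta_file) {
  sep_of <- function(f) if (grepl("\\.csv$", f, ignore.case = TRUE)) "," else "\t"
  cnt <- as.matrix(utils::read.table(counts_file, header = TRUE, sep = sep_of(counts_file),
                                     row.names = 1, check.names = FALSE))
  probes <- utils::read.table(probe_file, header = TRUE, sep = sep_of(probe_file),
                              stringsAsFactors = FALSE)
  meta <- utils::read.table(meta_file, header = TRUE, sep = sep_of(meta_file),
                            stringsAsFactors = FALSE)
  if (!all(c("probe", "class") %in% names(probes)))
    stop("probe table needs columns: probe, class")
  if (!all(c("sample", "cartridge_id") %in% names(meta)))
    stop("sample metadata table needs columns: sample, cartridge_id")
  cls <- stats::setNames(probes$class, probes$probe)[colnames(cnt)]
  if (anyNA(cls)) stop("probes missing from probe table: ",
                       paste(colnames(cnt)[is.na(cls)], collapse = ", "))
  rownames(meta) <- meta$sample
  meta <- meta[rownames(cnt), , drop = FALSE]
  panel_count_matrix(cnt, unname(cls), meta$cartridge_id,
                     meta[, setdiff(names(meta), c("sample", "cartridge_id")),
                          drop = FALSE])
}

#' @rdname read_count_table
#' @param pcm A `panel_count_matrix` to write.
#' @param dir Output directory; writes `counts.tsv`, `probes.tsv`,
#'   `samples.tsv`.
#' @export
write_count_table <- function(pcm, dir) {
  stopifnot(inherits(pcm, "panel_count_matrix"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(data.frame(sample = rownames(pcm$counts), pcm$counts,
                                check.names = FALSE),
                     file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(probe = names(pcm$probe_class),
                                class = unname(pcm$probe_class)),
                     file.path(dir, "probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cbind(data.frame(sample = rownames(pcm$counts),
                                      cartridge_id = unname(pcm$cartridge_id)),
                           pcm$sample_meta),
                     file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Default QC thresholds
#'
#' Instrument-default sample QC gates: imaging field-of-view fraction,
#' binding density window, positive-control log-linearity and a limit of
#' detection derived from negative probes (mean + 2 sd).
#'
#' @param fov_min Minimum fraction of fields of view counted.
#' @param bd_range Allowed binding-density interval.
#' @param pos_r2_min Minimum R^2 of log2 positive-control counts against
#'   log2 spike concentration.
#' @param lod_sd Number of negative-probe standard deviations above the
#'   negative-probe mean defining the limit of detection.
#' @return A list of thresholds for [qc_gate()].
#' @export
qc_thresholds <- function(fov_min = 0.75, bd_range = c(0.1, 2.25),
                          pos_r2_min = 0.95, lod_sd = 2) {
  stopifnot(fov_min > 0, fov_min <= 1, length(bd_range) == 2,
            bd_range[1] < bd_range[2], pos_r2_min >= 0, pos_r2_min <= 1,
            lod_sd >= 0)
  list(fov_min = fov_min, bd_range = bd_range, pos_r2_min = pos_r2_min,
       lod_sd = lod_sd)
}

# Limit of detection on the count scale from a sample's negative probes.
sample_lod <- function(neg_counts, lod_sd = 2) {
  mean(neg_counts) + lod_sd * stats::sd(neg_counts)
}

#' Sample-level QC gating
#'
#' Applies per-sample flags (imaging, binding density, positive-control
#' linearity, limit of detection) and drops failing samples before
#' normalization. The LOD flag fails when the 0.5 fM positive-control probe
#' or the mean endogenous count falls below mean + `lod_sd` x sd of the
#' negative probes. Missing imaging metadata leaves the corresponding flag
#' passing; a sample with constant positive-control counts fails linearity.
#'
#' @param pcm A `panel_count_matrix`.
#' @param thresholds Output of [qc_thresholds()].
#' @return A list with `pcm` (passing samples only) and `report`, a
#'   `qc_report` data.frame of per-sample flags and failure reasons.
#' @export
qc_gate <- function(pcm, thresholds = qc_thresholds()) {
  stopifnot(inherits(pcm, "panel_count_matrix"))
  th <- thresholds
  samples <- rownames(pcm$counts)
  pos <- pcm$probe_class == "positive"
  neg <- pcm$probe_class == "negative"
  endo <- pcm$probe_class == "endogenous"
  pos_conc <- parse_positive_conc(colnames(pcm$counts)[pos])

  meta_num <- function(col) {
    if (col %in% names(pcm$sample_meta)) as.numeric(pcm$sample_meta[[col]])
    else rep(NA_real_, length(samples))
  }
  fovn <- meta_num("fov_count"); fovc <- meta_num("fov_counted")
  bd <- meta_num("binding_density")

  imaging <- ifelse(is.na(fovn) | is.na(fovc), TRUE, fovc / fovn >= th$fov_min)
  density <- ifelse(is.na(bd), TRUE, bd >= th$bd_range[1] & bd <= th$bd_range[2])

  linearity <- rep(TRUE, length(samples))
  lod_pass <- rep(TRUE, length(samples))
  if (any(pos) && sum(is.finite(pos_conc)) >= 3) {
    for (i in seq_along(samples)) {
      y <- log2(pcm$counts[i, pos][is.finite(pos_conc)] + 1)
      x <- log2(pos_conc[is.finite(pos_conc)])
      linearity[i] <- if (stats::sd(y) == 0) FALSE else stats::cor(x, y)^2 >= th$pos_r2_min
    }
  }
  if (any(neg) && sum(neg) >= 2) {
    half_fm <- which(pos)[which(abs(pos_conc - 0.5) < 1e-9)]
    for (i in seq_along(samples)) {
      lod <- sample_lod(pcm$counts[i, neg], th$lod_sd)
      ok <- mean(pcm$counts[i, endo]) >= lod
      if (length(half_fm) == 1) ok <- ok && pcm$counts[i, half_fm] >= lod
      lod_pass[i] <- ok
    }
  }

  overall <- imaging & density & linearity & lod_pass
  reason <- vapply(seq_along(samples), function(i) {
    f <- c("imaging", "binding-density", "positive-control-linearity",
           "limit-of-detection")[!c(imaging[i], density[i], linearity[i], lod_pass[i])]
    paste(f, collapse = ";")
  }, character(1))
  report <- data.frame(sample = samples, imaging = imaging,
                       binding_density = density,
                       pos_control_linearity = linearity,
                       limit_of_detection = lod_pass,
                       pass = overall, failed_flags = reason,
                       row.names = NULL)
  class(report) <- c("qc_report", "data.frame")
  if (!any(overall))
    stop("all samples failed QC; no cohort remains (see the QC report flags)")
  list(pcm = subset_samples(pcm, samples[overall]), report = report)
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat("qc_report:", sum(x$pass), "of", nrow(x), "sample(s) pass\n")
  failed <- x[!x$pass, c("sample", "failed_flags")]
  if (nrow(failed)) {
    cat("excluded:\n")
    for (i in seq_len(nrow(failed)))
      cat("  ", failed$sample[i], "->", failed$failed_flags[i], "\n")
  }
  invisible(x)
}

#' Log2 expression from a panel count matrix
#'
#' Extracts the endogenous probes as `log2(count + 1)`, the working scale
#' of the normalization stage.
#'
#' @param pcm A `panel_count_matrix`.
#' @param classes Probe classes to keep (default endogenous only).
#' @return A samples x genes numeric matrix.
#' @export
log2_expression <- function(pcm, classes = "endogenous") {
  stopifnot(inherits(pcm, "panel_count_matrix"))
  keep <- pcm$probe_class %in% classes
  log2(pcm$counts[, keep, drop = FALSE] + 1)
}
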