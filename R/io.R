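# Readers and writers for the plain-text interchange formats:
# beta matrix (TSV/CSV, probes x samples), sample sheet (CSV),
# probe annotation (CSV). All UTF-8, decimal point.

.sepFor <- function(dialect) switch(match.arg(dialect, c("tsv", "csv")),
                                    tsv = "\t", csv = ",")

#' Read a beta-value matrix
#'
#' Reads a probe-by-sample table of methylation beta fractions. The first
#' column holds probe ids (header \code{probe_id}); remaining columns are
#' samples. Empty cells become \code{NA} (the missing marker). Any non-missing
#' value outside [0,1] is an error naming the offending cell.
#'
#' @param path file path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @return numeric matrix with probe rownames and sample colnames.
#' @export
readBetaMatrix <- function(path, dialect = c("tsv", "csv")) {
  if (!file.exists(path))
    .stopc("episcreen_io_error", "file not found: %s", path)
  sep <- .sepFor(dialect)
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, na.strings = c("", "NA"),
                          comment.char = "", quote = "\"")
  if (ncol(df) < 2 || tolower(colnames(df)[1]) != "probe_id")
    .stopc("episcreen_format_error",
           "malformed header: first column must be 'probe_id' (got '%s')",
           colnames(df)[1])
  probes <- as.character(df[[1]])
  if (anyDuplicated(probes))
    .stopc("episcreen_format_error", "duplicate probe ids in %s", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    m <- suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))
    if (anyNA(m) && !anyNA(df[, -1]))
      .stopc("episcreen_format_error", "non-numeric beta values in %s", path)
  }
  rownames(m) <- probes
  bad <- which(!is.na(m) & (m < 0 | m > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(m))
    .stopc("episcreen_range_error",
           "beta value out of [0,1] at probe %s, sample %s: %g",
           probes[i[1]], colnames(m)[i[2]], m[bad[1]])
  }
  m
}

#' Write a beta-value matrix
#'
#' Inverse of \code{\link{readBetaMatrix}}; round-trips values to better than
#' 1e-9. Missing values are written as empty cells.
#'
#' @param beta numeric matrix (probes x samples) or a \linkS4class{MethylCohort}.
#' @param path output file path.
#' @param dialect \code{"tsv"} or \code{"csv"}.
#' @return \code{path}, invisibly.
#' @export
writeBetaMatrix <- function(beta, path, dialect = c("tsv", "csv")) {
  if (methods::is(beta, "MethylCohort")) beta <- betaValues(beta)
  sep <- .sepFor(dialect)
  txt <- format(beta, digits = 15, trim = TRUE, scientific = FALSE)
  txt[is.na(beta)] <- ""
  out <- cbind(probe_id = rownames(beta), txt)
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE,
                     col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read or write a sample sheet
#'
#' CSV with columns sample_id, sex, age, batch, role, replicate_of,
#' disorder_label, cohort. \code{role} must be one of reference_case,
#' reference_control, test, replicate; \code{disorder_label} is required
#' exactly for reference cases and \code{replicate_of} exactly for replicates.
#'
#' @param path file path.
#' @return data.frame with the sheet columns.
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path))
    .stopc("episcreen_io_error", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), colClasses = "character")
  missing <- setdiff(.SHEET_COLS, colnames(df))
  if (length(missing))
    .stopc("episcreen_schema_error", "sample sheet missing column(s): %s",
           paste(missing, collapse = ", "))
  df$age <- suppressWarnings(as.numeric(df$age))
  for (col in c("replicate_of", "disorder_label"))
    df[[col]][is.na(df[[col]])] <- ""
  df$sex[is.na(df$sex)] <- "unknown"
  .checkSheet(df)
  df[, .SHEET_COLS]
}

.checkSheet <- function(df) {
  if (!all(df$role %in% .ROLES))
    .stopc("episcreen_schema_error", "invalid role value(s): %s",
           paste(unique(setdiff(df$role, .ROLES)), collapse = ", "))
  if (!all(df$sex %in% .SEXES))
    .stopc("episcreen_schema_error", "invalid sex value(s)")
  isCase <- df$role == "reference_case"
  if (any(isCase & !nzchar(df$disorder_label)))
    .stopc("episcreen_schema_error",
           "reference_case without disorder_label: %s",
           paste(df$sample_id[isCase & !nzchar(df$disorder_label)], collapse = ", "))
  invisible(df)
}

#' @rdname readSampleSheet
#' @param sheet data.frame as returned by \code{readSampleSheet}.
#' @export
writeSampleSheet <- function(sheet, path) {
  utils::write.csv(sheet[, .SHEET_COLS], path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Read or write a probe annotation table
#'
#' CSV with columns probe_id, chrom, pos (1-based), gene, region_tag
#' (\code{none}, \code{imprinted_dmr:<name>} or \code{repeat_locus:<name>})
#' and on_chrX (TRUE/FALSE).
#'
#' @param path file path.
#' @return data.frame of probe annotation.
#' @export
readProbeAnnotation <- function(path) {
  if (!file.exists(path))
    .stopc("episcreen_io_error", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA"))
  missing <- setdiff(.ANNOT_COLS, colnames(df))
  if (length(missing))
    .stopc("episcreen_schema_error", "annotation missing column(s): %s",
           paste(missing, collapse = ", "))
  df$pos <- as.integer(df$pos)
  if (any(!is.na(df$pos) & df$pos < 1))
    .stopc("episcreen_range_error", "probe position < 1")
  df$on_chrX <- as.logical(df$on_chrX)
  df$region_tag[is.na(df$region_tag) | !nzchar(df$region_tag)] <- "none"
  badTag <- !grepl("^(none|imprinted_dmr:.+|repeat_locus:.+)$", df$region_tag)
  if (any(badTag))
    .stopc("episcreen_schema_error", "invalid region_tag(s): %s",
           paste(unique(df$region_tag[badTag]), collapse = ", "))
  df[, .ANNOT_COLS]
}

#' @rdname readProbeAnnotation
#' @param annotation data.frame as returned by \code{readProbeAnnotation}.
#' @export
writeProbeAnnotation <- function(annotation, path) {
  utils::write.csv(annotation[, .ANNOT_COLS], path, row.names = FALSE,
                   quote = FALSE, na = "")
  invisible(path)
}

#' Validate a cohort (beta matrix + sample sheet)
#'
#' Reconciles a beta matrix against a sample sheet: every sheet sample must be
#' a matrix column and vice versa, replicate links must resolve, and reference
#' cases must carry a disorder label. Returns a \linkS4class{MethylCohort}
#' whose \code{colData} carries the per-sample missing-probe fraction.
#' Validating an already-validated cohort is a no-op.
#'
#' @param beta numeric matrix or \linkS4class{MethylCohort}.
#' @param sheet sample sheet data.frame (ignored when \code{beta} is already
#'   a cohort).
#' @param annotation optional probe annotation data.frame.
#' @return a validated \linkS4class{MethylCohort}.
#' @export
validateCohort <- function(beta, sheet = NULL, annotation = NULL) {
  if (methods::is(beta, "MethylCohort")) {
    methods::validObject(beta)
    return(beta)
  }
  if (is.null(sheet))
    .stopc("episcreen_schema_error", "a sample sheet is required")
  .checkSheet(sheet)
  MethylCohort(beta, sheet, annotation)
}

#' Write a full cohort to a directory
#'
#' Writes \code{beta.tsv}, \code{samples.csv}, \code{annotation.csv} and, if
#' simulation truth is attached, \code{truth.csv}.
#'
#' @param cohort a \linkS4class{MethylCohort}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeBetaMatrix(betaValues(cohort), file.path(dir, "beta.tsv"), "tsv")
  sheet <- sampleSheet(cohort)
  writeSampleSheet(sheet, file.path(dir, "samples.csv"))
  writeProbeAnnotation(probeAnnotation(cohort), file.path(dir, "annotation.csv"))
  tt <- truthTable(cohort)
  if (nrow(tt)) utils::write.csv(tt, file.path(dir, "truth.csv"),
                                 row.names = FALSE, quote = FALSE, na = "")
  invisible(dir)
}

#' Read a cohort directory written by \code{\link{writeCohort}}
#'
#' @param dir directory containing \code{beta.tsv}, \code{samples.csv} and
#'   optionally \code{annotation.csv}.
#' @return a validated \linkS4class{MethylCohort}.
#' @export
readCohort <- function(dir) {
  beta <- readBetaMatrix(file.path(dir, "beta.tsv"), "tsv")
  sheet <- readSampleSheet(file.path(dir, "samples.csv"))
  annPath <- file.path(dir, "annotation.csv")
  ann <- if (file.exists(annPath)) readProbeAnnotation(annPath) else NULL
  validateCohort(beta, sheet, ann)
}
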