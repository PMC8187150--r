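# Constructors, generics, accessors and show methods.

#' Construct a MethylCohort
#'
#' Bundles a beta matrix, a sample sheet and (optionally) a probe annotation
#' into a validated \linkS4class{MethylCohort}. Columns are reordered to the
#' sample-sheet order; annotation rows to the probe order.
#'
#' @param beta numeric matrix, probes in rows (rownames = probe ids), samples
#'   in columns (colnames = sample ids); values in [0,1], \code{NA} = missing.
#' @param sheet data.frame with columns sample_id, sex, age, batch, role,
#'   replicate_of, disorder_label, cohort.
#' @param annotation optional data.frame with columns probe_id, chrom, pos,
#'   gene, region_tag, on_chrX.
#' @param metadata optional list stored in the object metadata.
#' @return a \linkS4class{MethylCohort}.
#' @export
MethylCohort <- function(beta, sheet, annotation = NULL, metadata = list()) {
  if (is.null(rownames(beta)) || is.null(colnames(beta)))
    .stopc("episcreen_format_error", "beta matrix needs probe rownames and sample colnames")
  sheet <- as.data.frame(sheet, stringsAsFactors = FALSE)
  missingSheet <- setdiff(.SHEET_COLS, colnames(sheet))
  if (length(missingSheet))
    .stopc("episcreen_schema_error", "sample sheet missing column(s): %s",
           paste(missingSheet, collapse = ", "))
  extraB <- setdiff(colnames(beta), sheet$sample_id)
  extraS <- setdiff(sheet$sample_id, colnames(beta))
  if (length(extraB) || length(extraS))
    .stopc("episcreen_reconciliation_error",
           "sample mismatch between beta matrix and sheet; only in matrix: [%s]; only in sheet: [%s]",
           paste(extraB, collapse = ", "), paste(extraS, collapse = ", "))
  beta <- beta[, sheet$sample_id, drop = FALSE]
  if (is.null(annotation)) {
    annotation <- data.frame(probe_id = rownames(beta), chrom = NA_character_,
                             pos = NA_integer_, gene = NA_character_,
                             region_tag = "none", on_chrX = FALSE,
                             stringsAsFactors = FALSE)
  } else {
    annotation <- as.data.frame(annotation, stringsAsFactors = FALSE)
    missingA <- setdiff(.ANNOT_COLS, colnames(annotation))
    if (length(missingA))
      .stopc("episcreen_schema_error", "probe annotation missing column(s): %s",
             paste(missingA, collapse = ", "))
    if (!all(rownames(beta) %in% annotation$probe_id))
      .stopc("episcreen_reconciliation_error",
             "probe(s) in beta matrix absent from annotation")
    annotation <- annotation[match(rownames(beta), annotation$probe_id), , drop = FALSE]
  }
  rd <- S4Vectors::DataFrame(annotation, row.names = rownames(beta))
  cd <- S4Vectors::DataFrame(sheet, row.names = sheet$sample_id)
  cd$missing_fraction <- colMeans(is.na(beta))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = S4Vectors::SimpleList(beta = beta),
    rowData = rd, colData = cd, metadata = metadata)
  methods::new("MethylCohort", se)
}

#' @rdname MethylCohort-accessors
#' @export
setGeneric("betaValues", function(x) standardGeneric("betaValues"))
#' @rdname MethylCohort-accessors
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))
#' @rdname MethylCohort-accessors
#' @export
setGeneric("probeAnnotation", function(x) standardGeneric("probeAnnotation"))
#' @rdname MethylCohort-accessors
#' @export
setGeneric("missingFraction", function(x) standardGeneric("missingFraction"))
#' @rdname MethylCohort-accessors
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))

#' Accessors for MethylCohort
#'
#' \code{betaValues} returns the probe-by-sample beta matrix;
#' \code{sampleSheet} and \code{probeAnnotation} return plain data.frames;
#' \code{missingFraction} the per-sample fraction of missing probes;
#' \code{truthTable} the simulation ground truth (empty for real cohorts).
#'
#' @param x a \linkS4class{MethylCohort}.
#' @name MethylCohort-accessors
#' @aliases betaValues sampleSheet probeAnnotation missingFraction truthTable
NULL

#' @rdname MethylCohort-accessors
#' @export
setMethod("betaValues", "MethylCohort",
          function(x) SummarizedExperiment::assay(x, "beta"))
#' @rdname MethylCohort-accessors
#' @export
setMethod("sampleSheet", "MethylCohort", function(x) {
  df <- as.data.frame(SummarizedExperiment::colData(x))
  rownames(df) <- NULL
  df
})
#' @rdname MethylCohort-accessors
#' @export
setMethod("probeAnnotation", "MethylCohort", function(x) {
  df <- as.data.frame(SummarizedExperiment::rowData(x))
  rownames(df) <- NULL
  df
})
#' @rdname MethylCohort-accessors
#' @export
setMethod("missingFraction", "MethylCohort", function(x) {
  mf <- SummarizedExperiment::colData(x)$missing_fraction
  names(mf) <- colnames(x)
  mf
})
#' @rdname MethylCohort-accessors
#' @export
setMethod("truthTable", "MethylCohort", function(x) {
  tt <- S4Vectors::metadata(x)$truth
  if (is.null(tt)) data.frame(sample_id = character(), disorder_id = character())
  else tt
})

#' @rdname kdb-accessors
#' @export
setGeneric("kdbVersion", function(x) standardGeneric("kdbVersion"))
#' @rdname kdb-accessors
#' @export
setGeneric("signatures", function(x) standardGeneric("signatures"))
#' @rdname kdb-accessors
#' @export
setGeneric("classifiers", function(x) standardGeneric("classifiers"))
#' @rdname kdb-accessors
#' @export
setGeneric("controlReference", function(x) standardGeneric("controlReference"))
#' @rdname kdb-accessors
#' @export
setGeneric("locusRegistry", function(x) standardGeneric("locusRegistry"))

#' Accessors for the knowledge database
#'
#' @param x a \linkS4class{KnowledgeDatabase}.
#' @name kdb-accessors
#' @aliases kdbVersion signatures classifiers controlReference locusRegistry
NULL

#' @rdname kdb-accessors
#' @export
setMethod("kdbVersion", "KnowledgeDatabase", function(x) x@version)
#' @rdname kdb-accessors
#' @export
setMethod("signatures", "KnowledgeDatabase", function(x) x@signatures)
#' @rdname kdb-accessors
#' @export
setMethod("classifiers", "KnowledgeDatabase", function(x) x@classifiers)
#' @rdname kdb-accessors
#' @export
setMethod("controlReference", "KnowledgeDatabase", function(x) x@controlReference)
#' @rdname kdb-accessors
#' @export
setMethod("locusRegistry", "KnowledgeDatabase", function(x) x@locusRegistry)

#' @rdname episignature-accessors
#' @export
setGeneric("disorderId", function(x) standardGeneric("disorderId"))
#' @rdname episignature-accessors
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))
#' @rdname episignature-accessors
#' @export
setGeneric("signatureDelta", function(x) standardGeneric("signatureDelta"))

#' Accessors for signatures and classifiers
#'
#' @param x an \linkS4class{Episignature} or \linkS4class{TrainedClassifier}.
#' @name episignature-accessors
#' @aliases disorderId probeIds signatureDelta
NULL

#' @rdname episignature-accessors
#' @export
setMethod("disorderId", "Episignature", function(x) x@disorderId)
#' @rdname episignature-accessors
#' @export
setMethod("disorderId", "TrainedClassifier", function(x) x@disorderId)
#' @rdname episignature-accessors
#' @export
setMethod("probeIds", "Episignature", function(x) x@probeIds)
#' @rdname episignature-accessors
#' @export
setMethod("probeIds", "TrainedClassifier", function(x) x@probeIds)
#' @rdname episignature-accessors
#' @export
setMethod("signatureDelta", "Episignature", function(x) {
  d <- x@delta
  names(d) <- x@probeIds
  d
})

#' @rdname report-accessors
#' @export
setGeneric("finalStatus", function(x) standardGeneric("finalStatus"))
#' @rdname report-accessors
#' @export
setGeneric("matchedDisorders", function(x) standardGeneric("matchedDisorders"))
#' @rdname report-accessors
#' @export
setGeneric("reviewFlags", function(x) standardGeneric("reviewFlags"))
#' @rdname report-accessors
#' @export
setGeneric("mvpScores", function(x) standardGeneric("mvpScores"))

#' Accessors for screening reports
#'
#' @param x an \linkS4class{EpisignReport}.
#' @name report-accessors
#' @aliases finalStatus matchedDisorders reviewFlags mvpScores
NULL

#' @rdname report-accessors
#' @export
setMethod("finalStatus", "EpisignReport", function(x) x@finalStatus)
#' @rdname report-accessors
#' @export
setMethod("matchedDisorders", "EpisignReport", function(x) x@matchedDisorders)
#' @rdname report-accessors
#' @export
setMethod("reviewFlags", "EpisignReport", function(x) x@reviewFlags)
#' @rdname report-accessors
#' @export
setMethod("mvpScores", "EpisignReport", function(x) x@scores)

setMethod("show", "Episignature", function(object) {
  cat(sprintf("Episignature '%s' (v%s): %d probes, granularity %s, %s\n",
              object@disorderId, object@version, length(object@probeIds),
              object@granularity, object@sensitivityClass))
  cat(sprintf("  mean |delta| %.3f (range %.3f..%.3f); %d cases / %d controls\n",
              mean(abs(object@delta)), min(object@delta), max(object@delta),
              object@nCases, object@nControls))
})

setMethod("show", "PlattParams", function(object) {
  cat(sprintf("PlattParams: P(f) = 1/(1 + exp(%.4g * f + %.4g))\n",
              object@A, object@B))
})

setMethod("show", "TrainedClassifier", function(object) {
  cat(sprintf("TrainedClassifier '%s': %d probes, bias %.4g\n",
              object@disorderId, length(object@probeIds), object@bias))
  cat(sprintf("  Platt A=%.4g B=%.4g; thresholds >%.2g pos, <%.2g neg\n",
              object@platt@A, object@platt@B,
              object@thresholds@tPos, object@thresholds@tNeg))
})

setMethod("show", "KnowledgeDatabase", function(object) {
  cat(sprintf("KnowledgeDatabase v%s: %d signatures, %d classifiers, %d loci\n",
              object@version, length(object@signatures),
              length(object@classifiers), nrow(object@locusRegistry)))
})

setMethod("show", "ClusterEvidence", function(object) {
  cat(sprintf("ClusterEvidence %s / %s: %s (margin %.3f, floor %.2f, %s)\n",
              object@sampleId, object@disorderId, object@call,
              object@margin, object@marginFloor, object@assignment))
})

setMethod("show", "EpisignReport", function(object) {
  cat(sprintf("EpisignReport %s [KDB v%s]: %s\n", object@sampleId,
              object@kdbVersion, toupper(object@finalStatus)))
  if (length(object@matchedDisorders))
    cat("  matched:", paste(object@matchedDisorders, collapse = ", "), "\n")
  for (f in object@reviewFlags) cat("  flag:", f, "\n")
})
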