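#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata SimpleList
NULL

.ROLES <- c("reference_case", "reference_control", "test", "replicate")
.SEXES <- c("M", "F", "unknown")
.COHORTS <- c("targeted", "screening", "validation", "simulated")
.GRANULARITIES <- c("gene", "gene_domain", "complex", "region")
.SENSITIVITY_CLASSES <- c("robust", "moderate")
.LOCUS_TYPES <- c("imprinted_dmr", "repeat_locus")

.SHEET_COLS <- c("sample_id", "sex", "age", "batch", "role",
                 "replicate_of", "disorder_label", "cohort")
.ANNOT_COLS <- c("probe_id", "chrom", "pos", "gene", "region_tag", "on_chrX")

#' MethylCohort: beta values plus sample sheet and probe annotation
#'
#' A \linkS4class{SummarizedExperiment} with a single \code{"beta"} assay
#' (probes in rows, samples in columns, values in [0,1] with \code{NA} as the
#' missing marker), the sample sheet as \code{colData} and the probe
#' annotation as \code{rowData}. Construct with \code{\link{MethylCohort}} or
#' \code{\link{validateCohort}}; both enforce the cohort invariants.
#'
#' @export
setClass("MethylCohort", contains = "SummarizedExperiment")

.validMethylCohort <- function(object) {
  msgs <- character()
  if (!"beta" %in% SummarizedExperiment::assayNames(object))
    return("assay 'beta' is required")
  b <- SummarizedExperiment::assay(object, "beta")
  bad <- which(!is.na(b) & (b < 0 | b > 1))
  if (length(bad)) {
    i <- arrayInd(bad[1], dim(b))
    msgs <- c(msgs, sprintf("beta value out of [0,1]: probe %s, sample %s, value %g",
                            rownames(b)[i[1]], colnames(b)[i[2]], b[bad[1]]))
  }
  if (anyDuplicated(rownames(b))) msgs <- c(msgs, "duplicate probe ids")
  if (anyDuplicated(colnames(b))) msgs <- c(msgs, "duplicate sample ids")
  cd <- SummarizedExperiment::colData(object)
  if (!all(.SHEET_COLS %in% colnames(cd))) {
    msgs <- c(msgs, paste("sample sheet columns missing:",
                          paste(setdiff(.SHEET_COLS, colnames(cd)), collapse = ", ")))
  } else {
    if (!all(cd$role %in% .ROLES)) msgs <- c(msgs, "invalid role value")
    if (!all(cd$sex %in% .SEXES)) msgs <- c(msgs, "invalid sex value")
    isCase <- cd$role == "reference_case"
    hasLab <- !is.na(cd$disorder_label) & nzchar(cd$disorder_label)
    if (any(isCase & !hasLab))
      msgs <- c(msgs, "reference_case sample without disorder_label")
    if (any(!isCase & hasLab))
      msgs <- c(msgs, "disorder_label set for a non-reference_case sample")
    isRep <- cd$role == "replicate"
    hasRef <- !is.na(cd$replicate_of) & nzchar(cd$replicate_of)
    if (any(isRep & !hasRef)) msgs <- c(msgs, "replicate without replicate_of")
    if (any(!isRep & hasRef)) msgs <- c(msgs, "replicate_of set for a non-replicate")
    if (any(isRep) && !all(cd$replicate_of[isRep] %in% cd$sample_id))
      msgs <- c(msgs, "replicate_of refers to an unknown sample_id")
  }
  if (length(msgs)) msgs else TRUE
}
setValidity("MethylCohort", .validMethylCohort)

#' Episignature: a disorder's probe set with reference means
#'
#' The unit of the knowledge database: the ordered probe set selected for one
#' disorder together with the per-probe reference case/control means, their
#' difference (\code{delta}), the selection statistic, the signature
#' granularity (gene, gene domain, protein complex, or region) and a
#' sensitivity class (\code{"moderate"} marks small probe sets or small
#' reference cohorts, which yield reduced-intensity signatures).
#'
#' @slot disorderId disorder identifier.
#' @slot version knowledge-database version string.
#' @slot probeIds ordered probe identifiers.
#' @slot controlMean,caseMean per-probe reference beta means in [0,1].
#' @slot delta per-probe \code{caseMean - controlMean}.
#' @slot selectionStat per-probe ranking statistic used at selection time.
#' @slot granularity one of gene, gene_domain, complex, region.
#' @slot sensitivityClass "robust" or "moderate".
#' @slot nCases,nControls reference cohort sizes behind the means.
#' @export
setClass("Episignature",
  representation(disorderId = "character", version = "character",
                 probeIds = "character", controlMean = "numeric",
                 caseMean = "numeric", delta = "numeric",
                 selectionStat = "numeric", granularity = "character",
                 sensitivityClass = "character",
                 nCases = "integer", nControls = "integer"))

setValidity("Episignature", function(object) {
  n <- length(object@probeIds)
  msgs <- character()
  if (n < 1) msgs <- c(msgs, "a signature needs at least one probe")
  if (anyDuplicated(object@probeIds)) msgs <- c(msgs, "duplicate probe ids")
  for (s in c("controlMean", "caseMean", "delta", "selectionStat"))
    if (length(slot(object, s)) != n)
      msgs <- c(msgs, sprintf("length(%s) != length(probeIds)", s))
  if (length(object@controlMean) == n && length(object@caseMean) == n) {
    if (any(object@controlMean < 0 | object@controlMean > 1 |
            object@caseMean < 0 | object@caseMean > 1, na.rm = TRUE))
      msgs <- c(msgs, "reference means outside [0,1]")
    if (length(object@delta) == n &&
        max(abs(object@delta - (object@caseMean - object@controlMean))) > 1e-12)
      msgs <- c(msgs, "delta != caseMean - controlMean (tolerance 1e-12)")
  }
  if (!object@granularity %in% .GRANULARITIES) msgs <- c(msgs, "invalid granularity")
  if (!object@sensitivityClass %in% .SENSITIVITY_CLASSES)
    msgs <- c(msgs, "invalid sensitivityClass")
  if (length(msgs)) msgs else TRUE
})

#' Platt calibration parameters
#'
#' Parameters of the logistic link \eqn{P(f) = 1 / (1 + exp(A f + B))} mapping
#' a classifier decision value \eqn{f} to a calibrated probability. \code{A}
#' is negative whenever the positive class has the larger decision values.
#'
#' @slot A slope of the logistic link.
#' @slot B offset of the logistic link.
#' @export
setClass("PlattParams", representation(A = "numeric", B = "numeric"))

setValidity("PlattParams", function(object) {
  if (length(object@A) != 1L || length(object@B) != 1L ||
      !is.finite(object@A) || !is.finite(object@B))
    "A and B must be finite scalars" else TRUE
})

#' MVP score thresholds
#'
#' The reporting thresholds on the MVP score scale: \code{tPos} (scores
#' strictly above are positive), \code{tNeg} (strictly below are negative;
#' the closed band between them is inconclusive) and \code{replicateTol},
#' the maximum score difference tolerated between technical replicates.
#'
#' @slot tPos positive threshold (default 0.5).
#' @slot tNeg negative threshold (default 0.1).
#' @slot replicateTol replicate concordance tolerance (default 0.05).
#' @export
setClass("ThresholdConfig",
  representation(tPos = "numeric", tNeg = "numeric", replicateTol = "numeric"))

setValidity("ThresholdConfig", function(object) {
  if (!(object@tNeg >= 0 && object@tNeg < object@tPos && object@tPos <= 1))
    return("need 0 <= tNeg < tPos <= 1")
  if (object@replicateTol <= 0) return("replicateTol must be > 0")
  TRUE
})

#' A trained one-vs-rest disorder classifier
#'
#' Linear decision function over a signature's probes,
#' \eqn{f = w \cdot \beta + b}, with Platt parameters mapping \eqn{f} to an
#' MVP score and the reporting thresholds. \code{trainingMeta} records
#' cohort sizes, cross-validation folds, the seed and the KDB version.
#'
#' @slot disorderId disorder identifier.
#' @slot probeIds signature probes, in weight order.
#' @slot weights per-probe weights.
#' @slot bias intercept of the decision function.
#' @slot platt \linkS4class{PlattParams}.
#' @slot thresholds \linkS4class{ThresholdConfig}.
#' @slot trainingMeta list of training metadata.
#' @export
setClass("TrainedClassifier",
  representation(disorderId = "character", probeIds = "character",
                 weights = "numeric", bias = "numeric",
                 platt = "PlattParams", thresholds = "ThresholdConfig",
                 trainingMeta = "list"))

setValidity("TrainedClassifier", function(object) {
  msgs <- character()
  if (length(object@weights) != length(object@probeIds))
    msgs <- c(msgs, "length(weights) != length(probeIds)")
  if (length(object@bias) != 1L || !is.finite(object@bias))
    msgs <- c(msgs, "bias must be a finite scalar")
  if (length(msgs)) msgs else TRUE
})

#' Knowledge database of signatures and classifiers
#'
#' A versioned store of \linkS4class{Episignature}s, their
#' \linkS4class{TrainedClassifier}s, a per-probe control reference summary
#' (mean/SD over reference controls for every signature probe and registered
#' locus probe) and the registry of imprinted/repeat loci with their control
#' locus-mean statistics. Every classifier must reference a signature present
#' in the store.
#'
#' @slot version version string, propagated into every report.
#' @slot signatures named list of \linkS4class{Episignature}.
#' @slot classifiers named list of \linkS4class{TrainedClassifier}.
#' @slot controlReference data.frame (probe_id, mean, sd).
#' @slot locusRegistry data.frame (name, type, n_probes, control_mean, control_sd).
#' @export
setClass("KnowledgeDatabase",
  representation(version = "character", signatures = "list",
                 classifiers = "list", controlReference = "data.frame",
                 locusRegistry = "data.frame"))

setValidity("KnowledgeDatabase", function(object) {
  msgs <- character()
  sid <- vapply(object@signatures, function(s) s@disorderId, "")
  cid <- vapply(object@classifiers, function(c) c@disorderId, "")
  if (!all(cid %in% sid))
    msgs <- c(msgs, sprintf("classifier(s) without a matching signature: %s",
                            paste(setdiff(cid, sid), collapse = ", ")))
  sv <- vapply(object@signatures, function(s) s@version, "")
  if (length(sv) && !all(sv == object@version))
    msgs <- c(msgs, "signature version differs from KDB version")
  cv <- vapply(object@classifiers,
               function(c) as.character(c@trainingMeta$kdb_version %||% object@version), "")
  if (length(cv) && !all(cv == object@version))
    msgs <- c(msgs, "classifier KDB version differs from store version")
  if (length(msgs)) msgs else TRUE
})

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Clustering/MDS evidence for one sample against one disorder
#'
#' Secondary evidence from unsupervised analysis over a signature's probes:
#' the 2-D principal-coordinate embedding of the test sample with the
#' disorder's reference cases and controls, the side of the k=2 dendrogram
#' cut the test sample lands on, and a centroid-separation margin in [-1,1]
#' (positive = nearer the case centroid). \code{call} is \code{"with_cases"},
#' \code{"with_controls"} or \code{"intermediate"} (|margin| below the floor).
#'
#' @slot disorderId,sampleId identifiers.
#' @slot embedding matrix (samples x 2) of embedding coordinates.
#' @slot assignment "case_side" or "control_side" at the k=2 cut.
#' @slot margin centroid-separation margin in [-1,1].
#' @slot marginFloor threshold below which the call is intermediate.
#' @slot call with_cases / with_controls / intermediate.
#' @export
setClass("ClusterEvidence",
  representation(disorderId = "character", sampleId = "character",
                 embedding = "matrix", assignment = "character",
                 margin = "numeric", marginFloor = "numeric",
                 call = "character"))

setValidity("ClusterEvidence", function(object) {
  msgs <- character()
  if (!object@assignment %in% c("case_side", "control_side"))
    msgs <- c(msgs, "invalid assignment")
  if (!object@call %in% c("with_cases", "with_controls", "intermediate"))
    msgs <- c(msgs, "invalid call")
  if (abs(object@margin) > 1 + 1e-9) msgs <- c(msgs, "margin outside [-1,1]")
  if (abs(object@margin) < object@marginFloor && object@call != "intermediate")
    msgs <- c(msgs, "call must be intermediate when |margin| < marginFloor")
  if (object@call == "with_cases" &&
      !(object@assignment == "case_side" && object@margin >= object@marginFloor))
    msgs <- c(msgs, "with_cases requires case_side assignment and margin >= floor")
  if (length(msgs)) msgs else TRUE
})

#' Final screening report for one sample
#'
#' The three-way call (\code{positive}/\code{negative}/\code{inconclusive})
#' with its full evidence bundle: per-disorder MVP scores and categories,
#' clustering evidence, locus screening results, and human-readable review
#' flags. \code{matchedDisorders} is non-empty exactly when the status is
#' positive.
#'
#' @slot sampleId sample identifier.
#' @slot kdbVersion knowledge-database version the evidence came from.
#' @slot finalStatus positive / negative / inconclusive.
#' @slot matchedDisorders matched disorder or locus identifiers.
#' @slot scores data.frame of per-disorder MVP results.
#' @slot clusterEvidence list of \linkS4class{ClusterEvidence}.
#' @slot locusResults data.frame of locus screening results.
#' @slot reviewFlags character flags, each referencing an evidence item.
#' @slot timestamp creation time.
#' @export
setClass("EpisignReport",
  representation(sampleId = "character", kdbVersion = "character",
                 finalStatus = "character", matchedDisorders = "character",
                 scores = "data.frame", clusterEvidence = "list",
                 locusResults = "data.frame", reviewFlags = "character",
                 timestamp = "POSIXct"))

setValidity("EpisignReport", function(object) {
  msgs <- character()
  if (!object@finalStatus %in% c("positive", "negative", "inconclusive"))
    msgs <- c(msgs, "invalid finalStatus")
  if ((object@finalStatus == "positive") != (length(object@matchedDisorders) > 0))
    msgs <- c(msgs, "finalStatus positive iff matchedDisorders non-empty")
  if (length(msgs)) msgs else TRUE
})
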