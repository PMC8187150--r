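# Secondary evidence: clustering and low-dimensional embedding of a test
# sample against a disorder's reference cases and controls over the
# signature's probes. The visual pattern used in expert review is made
# machine-checkable through a centroid-separation margin.

# beta matrix restricted to signature probes for refs + test, NA-imputed
# column-wise to the control means of the restricted matrix
.evidenceMatrix <- function(cohort, signature, caseIds, ctrlIds, testId) {
  b <- betaValues(cohort)
  probes <- intersect(probeIds(signature), rownames(b))
  ids <- c(caseIds, ctrlIds, testId)
  X <- b[probes, ids, drop = FALSE]
  if (anyNA(X)) {
    cm <- rowMeans(X[, ctrlIds, drop = FALSE], na.rm = TRUE)
    for (j in seq_len(ncol(X))) {
      miss <- is.na(X[, j])
      X[miss, j] <- cm[miss]
    }
  }
  X
}

#' Classical MDS embedding over signature probes
#'
#' Principal-coordinate (classical metric MDS) embedding of samples on
#' Euclidean distances over a signature's probes. The sign of the first axis
#' is fixed by forcing the reference-case centroid positive, so the
#' embedding is deterministic.
#'
#' @param X numeric matrix, signature probes x samples.
#' @param caseIds sample ids of the reference cases (used for the sign fix;
#'   optional).
#' @return matrix (samples x 2) of coordinates.
#' @export
mdsEmbed <- function(X, caseIds = NULL) {
  if (ncol(X) < 3)
    .stopc("episcreen_embedding_error",
           "need >= 3 samples to embed, have %d", ncol(X))
  d <- stats::dist(t(X))
  coords <- stats::cmdscale(d, k = 2)
  if (ncol(coords) < 2)  # degenerate geometry: pad the missing axis
    coords <- cbind(coords, matrix(0, nrow(coords), 2 - ncol(coords)))
  colnames(coords) <- c("MDS1", "MDS2")
  if (!is.null(caseIds) && length(intersect(caseIds, rownames(coords)))) {
    cc <- colMeans(coords[intersect(caseIds, rownames(coords)), , drop = FALSE])
    if (cc[1] < 0) coords[, 1] <- -coords[, 1]
  }
  coords
}

#' Cluster a test sample with a disorder's references
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances) of the
#' reference cases, reference controls and the test sample over the
#' signature probes, cut at k = 2. The test sample is assigned to the side
#' holding the majority of reference cases or controls, and a margin
#' \eqn{(d_{control} - d_{case}) / max(d_{control}, d_{case})} quantifies its
#' position between the two reference centroids (+1 = on the case centroid,
#' -1 = on the control centroid). Calls: \code{with_cases} /
#' \code{with_controls} when the assignment and a margin beyond
#' \code{marginFloor} agree, otherwise \code{intermediate} — the pattern of
#' a sample plotting between the references.
#'
#' @param cohort a \linkS4class{MethylCohort}.
#' @param signature an \linkS4class{Episignature}.
#' @param testId sample id to assess.
#' @param marginFloor margin magnitude below which the call is
#'   \code{intermediate} (default 0.2).
#' @param caseIds,ctrlIds reference sample ids; default: the cohort's
#'   reference cases of the signature's disorder and all reference controls.
#' @return a \linkS4class{ClusterEvidence}.
#' @export
clusterAssign <- function(cohort, signature, testId, marginFloor = 0.2,
                          caseIds = NULL, ctrlIds = NULL) {
  cohort <- validateCohort(cohort)
  sheet <- sampleSheet(cohort)
  if (is.null(caseIds))
    caseIds <- sheet$sample_id[sheet$role == "reference_case" &
                               sheet$disorder_label == disorderId(signature)]
  if (is.null(ctrlIds))
    ctrlIds <- sheet$sample_id[sheet$role == "reference_control"]
  caseIds <- setdiff(caseIds, testId)
  ctrlIds <- setdiff(ctrlIds, testId)
  if (length(caseIds) < 3 || length(ctrlIds) < 3)
    .stopc("episcreen_cohort_size_error",
           "need >= 3 reference cases and >= 3 controls (have %d / %d)",
           length(caseIds), length(ctrlIds))
  X <- .evidenceMatrix(cohort, signature, caseIds, ctrlIds, testId)
  hc <- stats::hclust(stats::dist(t(X)), method = "ward.D2")
  grp <- stats::cutree(hc, k = 2)
  caseMaj <- as.integer(names(which.max(table(grp[caseIds]))))
  ctrlMaj <- as.integer(names(which.max(table(grp[ctrlIds]))))
  if (caseMaj == ctrlMaj)
    .stopc("episcreen_separability_error",
           "reference cases and controls fall on one side of the k=2 cut for %s",
           disorderId(signature))
  assignment <- if (grp[testId] == caseMaj) "case_side" else "control_side"
  caseCentroid <- rowMeans(X[, caseIds, drop = FALSE])
  ctrlCentroid <- rowMeans(X[, ctrlIds, drop = FALSE])
  dCase <- sqrt(sum((X[, testId] - caseCentroid)^2))
  dCtrl <- sqrt(sum((X[, testId] - ctrlCentroid)^2))
  margin <- if (max(dCase, dCtrl) == 0) 0 else (dCtrl - dCase) / max(dCtrl, dCase)
  call <- if (abs(margin) < marginFloor) "intermediate"
          else if (margin > 0 && assignment == "case_side") "with_cases"
          else if (margin < 0 && assignment == "control_side") "with_controls"
          else "intermediate"  # geometry and tree disagree: needs review
  emb <- mdsEmbed(X, caseIds = caseIds)
  methods::new("ClusterEvidence", disorderId = disorderId(signature),
               sampleId = testId, embedding = emb, assignment = assignment,
               margin = margin, marginFloor = marginFloor, call = call)
}
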