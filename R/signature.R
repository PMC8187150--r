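# Episignature discovery: probe selection from reference cases vs controls.

#' Probe-selection parameters
#'
#' Defaults: absolute beta-difference floor 0.10, Benjamini-Hochberg adjusted
#' two-sided Welch-test level 0.01, at most 500 probes, at least 5 reference
#' cases.
#'
#' @param minAbsDelta minimum |case mean - control mean| in beta units.
#' @param alpha BH-adjusted significance level.
#' @param maxProbes cap on the signature size.
#' @param minCases minimum reference case count.
#' @return a \code{SelectionParams} list.
#' @export
selectionParams <- function(minAbsDelta = 0.10, alpha = 0.01,
                            maxProbes = 500, minCases = 5) {
  stopifnot(minAbsDelta > 0, minAbsDelta < 1, alpha > 0, alpha < 1,
            maxProbes >= 1, minCases >= 1)
  structure(list(minAbsDelta = minAbsDelta, alpha = alpha,
                 maxProbes = maxProbes, minCases = minCases),
            class = "SelectionParams")
}

#' Derive an episignature for one disorder
#'
#' Compares the disorder's reference cases against all reference controls
#' probe-by-probe (Welch two-sample test on beta values, Benjamini-Hochberg
#' corrected) and keeps probes with \code{|delta| >= minAbsDelta} and adjusted
#' p-value at most \code{alpha}. Probes are ranked by
#' \code{|delta| * (-log10 p)}, ties broken by probe id, and truncated to
#' \code{maxProbes}, so selection is fully deterministic. The signature is
#' classed \code{"moderate"} when fewer than 50 probes survive or fewer than
#' 10 cases were available (small cohorts and small probe sets give reduced
#' signature intensity), else \code{"robust"}.
#'
#' @param cohort a \linkS4class{MethylCohort} with reference cases/controls.
#' @param disorderId disorder to derive the signature for.
#' @param params a \code{\link{selectionParams}}.
#' @param version KDB version string stamped on the signature.
#' @param granularity signature granularity (default \code{"gene"}).
#' @return an \linkS4class{Episignature}.
#' @export
selectSignatureProbes <- function(cohort, disorderId,
                                  params = selectionParams(),
                                  version = "1", granularity = "gene") {
  cohort <- validateCohort(cohort)
  sheet <- sampleSheet(cohort)
  caseIds <- sheet$sample_id[sheet$role == "reference_case" &
                             sheet$disorder_label == disorderId]
  ctrlIds <- sheet$sample_id[sheet$role == "reference_control"]
  if (length(caseIds) < params$minCases)
    .stopc("episcreen_cohort_size_error",
           "disorder %s has %d reference cases; need >= %d",
           disorderId, length(caseIds), params$minCases)
  if (length(ctrlIds) < 10)
    .stopc("episcreen_cohort_size_error",
           "need >= 10 reference controls, have %d", length(ctrlIds))
  b <- betaValues(cohort)
  w <- .rowWelch(b[, caseIds, drop = FALSE], b[, ctrlIds, drop = FALSE])
  padj <- stats::p.adjust(w$p, method = "BH")
  keep <- which(abs(w$delta) >= params$minAbsDelta & padj <= params$alpha)
  if (!length(keep))
    .stopc("episcreen_empty_signature_error",
           "no probe passed selection for %s (|delta| >= %g, BH p <= %g)",
           disorderId, params$minAbsDelta, params$alpha)
  stat <- abs(w$delta[keep]) * w$neglog10p[keep]
  ord <- order(-stat, rownames(b)[keep])
  keep <- keep[ord][seq_len(min(length(keep), params$maxProbes))]
  stat <- abs(w$delta[keep]) * w$neglog10p[keep]
  sens <- if (length(keep) < 50 || length(caseIds) < 10) "moderate" else "robust"
  methods::new("Episignature",
               disorderId = disorderId, version = version,
               probeIds = rownames(b)[keep],
               controlMean = unname(w$meanControl[keep]),
               caseMean = unname(w$meanCase[keep]),
               delta = unname(w$delta[keep]),
               selectionStat = unname(stat),
               granularity = granularity, sensitivityClass = sens,
               nCases = length(caseIds), nControls = length(ctrlIds))
}

#' Merge episignatures into a coarser-granularity signature
#'
#' Builds the probe union of the parts (e.g. the per-gene signatures of one
#' protein complex) and recomputes per-probe reference means as the
#' sample-count-weighted average of the parts that carry each probe —
#' equivalent to recomputing means on the pooled reference samples when the
#' parts' cohorts are disjoint. Merging a signature with itself is the
#' identity.
#'
#' @param parts list of \linkS4class{Episignature} sharing a version.
#' @param granularity granularity recorded on the merged signature
#'   (default \code{"complex"}).
#' @param disorderId identifier for the merged signature; default joins the
#'   part ids with \code{"+"}.
#' @return an \linkS4class{Episignature}.
#' @export
mergeSignatures <- function(parts, granularity = "complex", disorderId = NULL) {
  if (!length(parts)) .stopc("episcreen_merge_error", "no signatures to merge")
  vs <- unique(vapply(parts, function(s) s@version, ""))
  if (length(vs) != 1)
    .stopc("episcreen_merge_error", "parts span versions: %s",
           paste(vs, collapse = ", "))
  ids <- unique(vapply(parts, function(s) s@disorderId, ""))
  if (is.null(disorderId))
    disorderId <- paste(ids, collapse = "+")
  probes <- unique(unlist(lapply(parts, probeIds)))
  wsum <- function(field, weightField) {
    num <- den <- stats::setNames(numeric(length(probes)), probes)
    for (s in parts) {
      wgt <- as.numeric(methods::slot(s, weightField))
      num[s@probeIds] <- num[s@probeIds] + slot(s, field) * wgt
      den[s@probeIds] <- den[s@probeIds] + wgt
    }
    unname(num / den)
  }
  caseMean <- wsum("caseMean", "nCases")
  ctrlMean <- wsum("controlMean", "nControls")
  stat <- wsum("selectionStat", "nCases")
  methods::new("Episignature",
               disorderId = disorderId, version = vs,
               probeIds = probes, controlMean = ctrlMean, caseMean = caseMean,
               delta = caseMean - ctrlMean, selectionStat = stat,
               granularity = granularity,
               sensitivityClass = if (length(probes) < 50) "moderate" else "robust",
               nCases = sum(vapply(parts, function(s) s@nCases, 1L)),
               nControls = max(vapply(parts, function(s) s@nControls, 1L)))
}
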