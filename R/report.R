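# Final report composition: MVP scores + clustering evidence + locus
# screening -> positive / negative / inconclusive, with review flags.
#
# Rules, applied strictly in order (first match decides the status):
#   1. a positive-score disorder whose cluster call is with_cases -> POSITIVE
#      for those disorders;
#   2. a positive-score disorder whose cluster call is with_controls ->
#      INCONCLUSIVE, flagged score/cluster discordant;
#   3. all scores negative but a cluster call intermediate trending case-ward
#      (margin > 0) -> INCONCLUSIVE, flagged;
#   4. any score in the inconclusive band -> INCONCLUSIVE, flagged;
#   5. any non-normal locus call -> POSITIVE for that locus;
#   6. otherwise NEGATIVE.

#' Compose the final screening report for one sample
#'
#' @param scores data.frame from \code{\link{scoreSample}} (one row per
#'   disorder).
#' @param evidence list of \linkS4class{ClusterEvidence} for the same sample
#'   (typically for the positively scoring disorders; may be empty).
#' @param loci data.frame from \code{\link{screenLoci}} (may be zero-row).
#' @param thresholds a \linkS4class{ThresholdConfig}.
#' @param sampleId sample identifier; defaults to the one in the evidence.
#' @param kdbVersion knowledge-database version string recorded on the report.
#' @return an \linkS4class{EpisignReport}.
#' @export
composeReport <- function(scores, evidence = list(), loci = NULL,
                          thresholds = thresholdConfig(), sampleId = NULL,
                          kdbVersion = "1") {
  if (is.null(loci))
    loci <- data.frame(locus = character(), call = character())
  evIds <- unique(vapply(evidence, function(e) e@sampleId, ""))
  if (is.null(sampleId)) {
    sampleId <- if (length(evIds)) evIds[1]
                else scores$sample_id[1] %||% "sample"
  }
  if (length(evIds) && any(evIds != sampleId))
    .stopc("episcreen_composition_error",
           "evidence refers to sample(s) %s, expected %s",
           paste(setdiff(evIds, sampleId), collapse = ", "), sampleId)
  clusterCall <- vapply(evidence, function(e) e@call, "")
  names(clusterCall) <- vapply(evidence, function(e) e@disorderId, "")
  margins <- vapply(evidence, function(e) e@margin, 0)
  names(margins) <- names(clusterCall)

  scored <- scores[scores$category != "coverage_error", , drop = FALSE]
  posD <- scored$disorder_id[scored$category == "positive"]
  bandD <- scored$disorder_id[scored$category == "inconclusive"]
  flags <- character()
  for (d in scores$disorder_id[scores$category == "coverage_error"])
    flags <- c(flags, sprintf("%s: signature coverage below floor, not scored", d))

  # rule 1: positive score confirmed by clustering (or unchallenged by it)
  confirmed <- posD[!(posD %in% names(clusterCall)) |
                    clusterCall[posD] == "with_cases"]
  unconfirmedNoEv <- setdiff(confirmed, names(clusterCall))
  status <- NULL; matched <- character()
  if (length(confirmed)) {
    status <- "positive"; matched <- confirmed
    for (d in unconfirmedNoEv)
      flags <- c(flags, sprintf("%s: positive MVP score without clustering evidence", d))
    if (length(confirmed) > 1)
      flags <- c(flags, sprintf("multiple simultaneous positives (%s): review",
                                paste(confirmed, collapse = ", ")))
  } else if (length(posD) &&
             any(clusterCall[intersect(posD, names(clusterCall))] == "with_controls")) {
    # rule 2
    d <- posD[clusterCall[posD] == "with_controls"]
    status <- "inconclusive"
    flags <- c(flags, sprintf("%s: score/cluster discordant (positive MVP, clusters with controls)", d))
  } else if (length(posD)) {
    # positive score, clustering intermediate
    status <- "inconclusive"
    d <- posD[clusterCall[posD] == "intermediate"]
    flags <- c(flags, sprintf("%s: positive MVP but intermediate clustering position", d))
  } else if (!length(bandD) && length(clusterCall) &&
             any(clusterCall == "intermediate" & margins > 0)) {
    # rule 3: scores negative, clustering trends case-ward
    d <- names(clusterCall)[clusterCall == "intermediate" & margins > 0]
    status <- "inconclusive"
    flags <- c(flags, sprintf(
      "%s: negative MVP score but sample plots between cases and controls (margin %.2f)",
      d, margins[d]))
  } else if (length(bandD)) {
    # rule 4: score in the inconclusive band
    status <- "inconclusive"
    for (d in bandD) {
      s <- scored$mvp[scored$disorder_id == d]
      flags <- c(flags, sprintf(
        "%s: MVP score %.2f in the inconclusive band [%g, %g]",
        d, s, thresholds@tNeg, thresholds@tPos))
    }
  }
  aberrLoci <- loci$locus[!loci$call %in% c("normal", "coverage_error", "indeterminate")]
  if (is.null(status) && length(aberrLoci)) {
    # rule 5
    status <- "positive"
    matched <- as.character(aberrLoci)
    for (i in which(loci$locus %in% aberrLoci))
      flags <- c(flags, sprintf("%s: locus %s (z = %.1f)", loci$locus[i],
                                loci$call[i], loci$z[i]))
  }
  for (i in which(loci$call == "indeterminate"))
    flags <- c(flags, sprintf("%s: locus screening indeterminate", loci$locus[i]))
  if (is.null(status)) status <- "negative"  # rule 6
  methods::new("EpisignReport", sampleId = sampleId, kdbVersion = kdbVersion,
               finalStatus = status, matchedDisorders = matched,
               scores = scores, clusterEvidence = evidence,
               locusResults = loci, reviewFlags = flags,
               timestamp = Sys.time())
}

#' Check technical-replicate concordance
#'
#' Two replicate score sets are concordant when the largest per-disorder MVP
#' difference is at most \code{tol} and every disorder's category agrees.
#'
#' @param r1,r2 data.frames from \code{\link{scoreSample}} over the same
#'   disorder panel.
#' @param tol maximum tolerated MVP difference (default 0.05).
#' @return list with \code{concordant} (logical), \code{maxDelta}, and
#'   \code{offenders} (disorders exceeding tol or flipping category).
#' @export
checkReplicateConcordance <- function(r1, r2, tol = 0.05) {
  if (!setequal(r1$disorder_id, r2$disorder_id))
    .stopc("episcreen_comparison_error", "disorder panels differ")
  m <- match(r1$disorder_id, r2$disorder_id)
  dmvp <- abs(r1$mvp - r2$mvp[m])
  flip <- r1$category != r2$category[m]
  off <- r1$disorder_id[(!is.na(dmvp) & dmvp > tol) | flip]
  list(concordant = length(off) == 0,
       maxDelta = if (all(is.na(dmvp))) NA_real_ else max(dmvp, na.rm = TRUE),
       offenders = off)
}

#' Summarize screening outcomes over a cohort
#'
#' Counts and percentages (half-up, 1 decimal) of positive / negative /
#' inconclusive reports, overall and per cohort tag. \code{pct_conclusive}
#' is the share of samples with a conclusive (positive or negative) outcome.
#'
#' @param reports list of \linkS4class{EpisignReport}.
#' @param sheet optional sample sheet supplying the cohort tag per sample;
#'   without it all samples fall under \code{"overall"} only.
#' @return data.frame with one row per cohort tag plus \code{"overall"}.
#' @export
summarizeCohort <- function(reports, sheet = NULL) {
  if (!length(reports))
    return(data.frame(cohort = character(), n = integer(),
                      positive = integer(), negative = integer(),
                      inconclusive = integer(), pct_positive = numeric(),
                      pct_negative = numeric(), pct_inconclusive = numeric(),
                      pct_conclusive = numeric()))
  ids <- vapply(reports, function(r) r@sampleId, "")
  status <- vapply(reports, function(r) r@finalStatus, "")
  tag <- rep("overall", length(ids))
  if (!is.null(sheet)) {
    m <- match(ids, sheet$sample_id)
    tag <- ifelse(is.na(m), "unknown", sheet$cohort[m])
  }
  oneRow <- function(name, st) {
    n <- length(st)
    np <- sum(st == "positive"); nn <- sum(st == "negative")
    ni <- sum(st == "inconclusive")
    data.frame(cohort = name, n = n, positive = np, negative = nn,
               inconclusive = ni,
               pct_positive = percentHalfUp(100 * np / n),
               pct_negative = percentHalfUp(100 * nn / n),
               pct_inconclusive = percentHalfUp(100 * ni / n),
               pct_conclusive = percentHalfUp(100 * (np + nn) / n))
  }
  out <- oneRow("overall", status)
  if (!is.null(sheet))
    for (tg in unique(tag)) out <- rbind(out, oneRow(tg, status[tag == tg]))
  rownames(out) <- NULL
  out
}
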