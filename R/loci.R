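# Screening of imprinted DMRs and repeat-expansion promoter loci by
# locus-mean methylation against the control reference, with a
# linear-mixture estimate of the aberrant cell fraction.

#' Mean methylation of a sample at a registered locus
#'
#' @param sampleBeta named numeric vector of beta values.
#' @param annotation probe annotation data.frame (see
#'   \code{\link{readProbeAnnotation}}).
#' @param locusName registered locus name (the part after the colon in
#'   \code{region_tag}).
#' @return mean beta over the locus's non-missing probes.
#' @export
summarizeLocus <- function(sampleBeta, annotation, locusName) {
  tag <- sub("^[a-z_]+:", "", annotation$region_tag)
  probes <- annotation$probe_id[annotation$region_tag != "none" & tag == locusName]
  v <- sampleBeta[intersect(probes, names(sampleBeta))]
  v <- v[!is.na(v)]
  if (length(v) < 3)
    .stopc("episcreen_locus_coverage_error",
           "locus %s has %d observed probe(s); need >= 3", locusName, length(v))
  mean(v)
}

#' Assess a locus mean against its control reference
#'
#' Standardizes the observed locus mean, \eqn{z = (obs - control\_mean) /
#' control\_sd}, and calls hyper-/hypomethylation when both \eqn{|z|} exceeds
#' \code{zCut} and the absolute beta difference exceeds \code{deltaCut} (the
#' dual guard keeps tiny control SDs from inflating z into calls). For
#' imprinted DMRs the aberrant cell fraction is estimated under the linear
#' two-population mixture: \eqn{|obs - control\_mean| / |target -
#' control\_mean|} with target 1 (hyper) or 0 (hypo), clipped to [0,1]; an
#' estimated fraction below 0.2 is reported \code{indeterminate} — below the
#' detection floor that normal control variability imposes on low-level
#' mosaicism. Female samples at repeat loci are \code{indeterminate}
#' (the unaffected X masks the carrier allele).
#'
#' @param observedMean observed locus mean beta.
#' @param controlMean,controlSd control reference mean and SD of the locus
#'   mean (\code{controlSd > 0}).
#' @param locusType \code{"imprinted_dmr"} or \code{"repeat_locus"}.
#' @param sex sample sex (\code{"M"}, \code{"F"}, \code{"unknown"}).
#' @param locusName locus name carried into the result.
#' @param zCut z-score cutoff (default 3).
#' @param deltaCut absolute beta-difference cutoff (default 0.10).
#' @return one-row data.frame: locus, type, observed_mean, control_mean,
#'   control_sd, z, estimated_aberrant_fraction, call.
#' @export
assessLocus <- function(observedMean, controlMean, controlSd, locusType,
                        sex = "unknown", locusName = NA_character_,
                        zCut = 3, deltaCut = 0.10) {
  if (is.na(controlSd) || controlSd <= 0)
    .stopc("episcreen_reference_error", "controlSd must be > 0, got %s",
           format(controlSd))
  locusType <- match.arg(locusType, .LOCUS_TYPES)
  z <- (observedMean - controlMean) / controlSd
  delta <- observedMean - controlMean
  normal <- abs(z) <= zCut && abs(delta) <= deltaCut
  aberrant <- abs(z) > zCut && abs(delta) > deltaCut
  direction <- if (delta > 0) "hypermethylated" else "hypomethylated"
  frac <- NA_real_
  if (locusType == "imprinted_dmr") {
    target <- if (delta > 0) 1 else 0
    frac <- min(1, max(0, abs(delta) / abs(target - controlMean)))
  }
  call <- if (normal) "normal"
          else if (!aberrant) "indeterminate"  # z and delta disagree
          else if (locusType == "repeat_locus" && sex == "F") "indeterminate"
          else if (locusType == "imprinted_dmr" && frac < 0.2) "indeterminate"
          else direction
  data.frame(locus = locusName, type = locusType, observed_mean = observedMean,
             control_mean = controlMean, control_sd = controlSd, z = z,
             estimated_aberrant_fraction = frac, call = call,
             stringsAsFactors = FALSE)
}

#' Screen all registered loci for one sample
#'
#' Runs \code{\link{summarizeLocus}} and \code{\link{assessLocus}} for every
#' locus in the knowledge database's registry. Loci with insufficient probe
#' coverage are reported with call \code{"coverage_error"} rather than
#' aborting the screen.
#'
#' @param kdb a \linkS4class{KnowledgeDatabase} with a locus registry.
#' @param cohort a \linkS4class{MethylCohort}.
#' @param sampleId sample to screen.
#' @param zCut,deltaCut see \code{\link{assessLocus}}.
#' @return data.frame of per-locus results (zero rows if no loci registered).
#' @export
screenLoci <- function(kdb, cohort, sampleId, zCut = 3, deltaCut = 0.10) {
  reg <- locusRegistry(kdb)
  if (!nrow(reg)) return(assessLocus(0.5, 0.5, 1, "imprinted_dmr")[0, ])
  cohort <- validateCohort(cohort)
  sheet <- sampleSheet(cohort)
  sex <- sheet$sex[match(sampleId, sheet$sample_id)]
  ann <- probeAnnotation(cohort)
  v <- betaValues(cohort)[, sampleId]
  out <- lapply(seq_len(nrow(reg)), function(i) {
    obs <- tryCatch(summarizeLocus(v, ann, reg$name[i]),
                    episcreen_locus_coverage_error = function(e) NA_real_)
    if (is.na(obs))
      return(data.frame(locus = reg$name[i], type = reg$type[i],
                        observed_mean = NA_real_,
                        control_mean = reg$control_mean[i],
                        control_sd = reg$control_sd[i], z = NA_real_,
                        estimated_aberrant_fraction = NA_real_,
                        call = "coverage_error", stringsAsFactors = FALSE))
    assessLocus(obs, reg$control_mean[i], reg$control_sd[i], reg$type[i],
                sex = sex, locusName = reg$name[i], zCut = zCut,
                deltaCut = deltaCut)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
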