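# Versioned on-disk knowledge database (KDB).
# Layout: <path>/<version>/manifest.json
#                          signatures/<disorder>.json
#                          classifiers/<disorder>.json
#                          control_reference.csv
#                          locus_registry.csv
# JSON numbers are written at full double precision so weights and Platt
# parameters round-trip to 1e-12.

#' Assemble a knowledge database
#'
#' Builds a \linkS4class{KnowledgeDatabase} from signatures, trained
#' classifiers and the reference cohort: the per-probe control reference
#' (mean/SD over reference controls, for all signature probes and all probes
#' tagged with a registered locus) and the locus registry (per-locus control
#' locus-mean statistics) are computed here.
#'
#' @param version version string.
#' @param signatures list of \linkS4class{Episignature}.
#' @param classifiers list of \linkS4class{TrainedClassifier} (may be empty).
#' @param cohort the reference \linkS4class{MethylCohort} used for training;
#'   its reference controls define the control reference and locus registry.
#' @return a \linkS4class{KnowledgeDatabase}.
#' @export
buildKnowledgeDatabase <- function(version, signatures, classifiers = list(),
                                   cohort = NULL) {
  names(signatures) <- vapply(signatures, disorderId, "")
  names(classifiers) <- vapply(classifiers, disorderId, "")
  ctrlRef <- data.frame(probe_id = character(), mean = numeric(), sd = numeric())
  registry <- data.frame(name = character(), type = character(),
                         n_probes = integer(), control_mean = numeric(),
                         control_sd = numeric())
  if (!is.null(cohort)) {
    cohort <- validateCohort(cohort)
    sheet <- sampleSheet(cohort)
    ctrlIds <- sheet$sample_id[sheet$role == "reference_control"]
    ann <- probeAnnotation(cohort)
    tagged <- ann$probe_id[ann$region_tag != "none"]
    probes <- unique(c(unlist(lapply(signatures, probeIds)), tagged))
    probes <- intersect(rownames(cohort), probes)
    if (length(ctrlIds) && length(probes)) {
      b <- betaValues(cohort)[probes, ctrlIds, drop = FALSE]
      ctrlRef <- data.frame(probe_id = probes,
                            mean = rowMeans(b, na.rm = TRUE),
                            sd = apply(b, 1, stats::sd, na.rm = TRUE),
                            row.names = NULL)
    }
    if (length(tagged) && length(ctrlIds)) {
      tags <- ann$region_tag[match(tagged, ann$probe_id)]
      registry <- do.call(rbind, lapply(unique(tags), function(tag) {
        p <- tagged[tags == tag]
        lm <- colMeans(betaValues(cohort)[p, ctrlIds, drop = FALSE], na.rm = TRUE)
        parts <- strsplit(tag, ":", fixed = TRUE)[[1]]
        data.frame(name = parts[2], type = parts[1], n_probes = length(p),
                   control_mean = mean(lm), control_sd = stats::sd(lm))
      }))
    }
  }
  methods::new("KnowledgeDatabase", version = version, signatures = signatures,
               classifiers = classifiers, controlReference = ctrlRef,
               locusRegistry = registry)
}

.sigToList <- function(s) list(
  disorder_id = s@disorderId, version = s@version, probe_ids = s@probeIds,
  control_mean = s@controlMean, case_mean = s@caseMean, delta = s@delta,
  selection_stat = s@selectionStat, granularity = s@granularity,
  sensitivity_class = s@sensitivityClass,
  n_cases = s@nCases, n_controls = s@nControls)

.sigFromList <- function(l) methods::new("Episignature",
  disorderId = l$disorder_id, version = l$version,
  probeIds = as.character(l$probe_ids),
  controlMean = as.numeric(l$control_mean), caseMean = as.numeric(l$case_mean),
  delta = as.numeric(l$delta), selectionStat = as.numeric(l$selection_stat),
  granularity = l$granularity, sensitivityClass = l$sensitivity_class,
  nCases = as.integer(l$n_cases), nControls = as.integer(l$n_controls))

.clfToList <- function(c) list(
  disorder_id = c@disorderId, probe_ids = c@probeIds, weights = c@weights,
  bias = c@bias, platt = list(A = c@platt@A, B = c@platt@B),
  thresholds = list(t_pos = c@thresholds@tPos, t_neg = c@thresholds@tNeg,
                    replicate_tol = c@thresholds@replicateTol),
  training_meta = c@trainingMeta)

.clfFromList <- function(l) methods::new("TrainedClassifier",
  disorderId = l$disorder_id, probeIds = as.character(l$probe_ids),
  weights = as.numeric(l$weights), bias = as.numeric(l$bias),
  platt = methods::new("PlattParams", A = as.numeric(l$platt$A),
                       B = as.numeric(l$platt$B)),
  thresholds = thresholdConfig(tPos = as.numeric(l$thresholds$t_pos),
                               tNeg = as.numeric(l$thresholds$t_neg),
                               replicateTol = as.numeric(l$thresholds$replicate_tol)),
  trainingMeta = as.list(l$training_meta))

.writeJSON <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
}

#' Persist a knowledge database to disk
#'
#' Writes one directory per version under \code{path}: a JSON manifest, one
#' signature and one classifier file per disorder, and CSVs for the control
#' reference and locus registry. \code{loadKDB(persistKDB(kdb, path))}
#' reproduces signatures, weights, Platt parameters and thresholds to 1e-12.
#'
#' @param kdb a \linkS4class{KnowledgeDatabase}.
#' @param path store root directory.
#' @return the stored version string, invisibly.
#' @export
persistKDB <- function(kdb, path) {
  methods::validObject(kdb)
  vdir <- file.path(path, kdb@version)
  dir.create(file.path(vdir, "signatures"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(vdir, "classifiers"), recursive = TRUE, showWarnings = FALSE)
  manifest <- list(version = kdb@version,
                   signatures = as.list(names(kdb@signatures)),
                   classifiers = as.list(names(kdb@classifiers)))
  .writeJSON(manifest, file.path(vdir, "manifest.json"))
  for (s in kdb@signatures)
    .writeJSON(.sigToList(s), file.path(vdir, "signatures",
                                        paste0(s@disorderId, ".json")))
  for (c in kdb@classifiers)
    .writeJSON(.clfToList(c), file.path(vdir, "classifiers",
                                        paste0(c@disorderId, ".json")))
  .writeCsvFull(kdb@controlReference, file.path(vdir, "control_reference.csv"))
  .writeCsvFull(kdb@locusRegistry, file.path(vdir, "locus_registry.csv"))
  invisible(kdb@version)
}

.writeCsvFull <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- format(out[[j]], digits = 17, trim = TRUE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Load a knowledge database from disk
#'
#' @param path store root directory.
#' @param version version to load; default: the lexicographically latest
#'   version directory present.
#' @return a \linkS4class{KnowledgeDatabase}.
#' @export
loadKDB <- function(path, version = NULL) {
  if (is.null(version)) {
    vs <- list.dirs(path, recursive = FALSE, full.names = FALSE)
    if (!length(vs)) .stopc("episcreen_corrupt_store", "no versions under %s", path)
    version <- sort(vs)[length(vs)]
  }
  vdir <- file.path(path, version)
  mpath <- file.path(vdir, "manifest.json")
  if (!file.exists(mpath))
    .stopc("episcreen_corrupt_store", "missing manifest: %s", mpath)
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  readOne <- function(kind, id) {
    f <- file.path(vdir, kind, paste0(id, ".json"))
    if (!file.exists(f))
      .stopc("episcreen_corrupt_store", "missing component file: %s", f)
    jsonlite::read_json(f, simplifyVector = TRUE)
  }
  sigs <- lapply(manifest$signatures, function(id) .sigFromList(readOne("signatures", id)))
  clfs <- lapply(manifest$classifiers, function(id) .clfFromList(readOne("classifiers", id)))
  names(sigs) <- vapply(sigs, disorderId, "")
  names(clfs) <- vapply(clfs, disorderId, "")
  ctrlRef <- utils::read.csv(file.path(vdir, "control_reference.csv"),
                             stringsAsFactors = FALSE)
  registry <- utils::read.csv(file.path(vdir, "locus_registry.csv"),
                              stringsAsFactors = FALSE)
  missingSig <- setdiff(vapply(clfs, disorderId, ""), vapply(sigs, disorderId, ""))
  if (length(missingSig))
    .stopc("episcreen_integrity_error",
           "classifier(s) reference absent signature(s): %s",
           paste(missingSig, collapse = ", "))
  kdb <- methods::new("KnowledgeDatabase", version = manifest$version,
                      signatures = sigs, classifiers = clfs,
                      controlReference = ctrlRef, locusRegistry = registry)
  methods::validObject(kdb)
  kdb
}
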