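# Shared fixtures, built in code and memoized for the test run.

.fixtures <- new.env(parent = emptyenv())

# a small trained 3-disorder panel reused across classify/evidence/report tests
smallPanel <- function() {
  if (is.null(.fixtures$panel)) {
    cfg <- simulationConfig(
      nBackgroundProbes = 1500,
      disorders = list(
        list(disorderId = "DA", nSignatureProbes = 60, delta = 0.15, nCases = 12),
        list(disorderId = "DB", nSignatureProbes = 60, delta = 0.15, nCases = 12),
        list(disorderId = "DC", nSignatureProbes = 60, delta = 0.15, nCases = 12)),
      nControls = 40, technicalSd = 0.01, seed = 202)
    cohort <- simulateCohort(cfg)
    sigs <- lapply(c("DA", "DB", "DC"), function(d)
      selectSignatureProbes(cohort, d, version = "1"))
    names(sigs) <- c("DA", "DB", "DC")
    clfs <- trainClassifiers(cohort, sigs, cvFolds = 6, seed = 3, kdbVersion = "1")
    .fixtures$panel <- list(
      cohort = cohort, sigs = sigs, clfs = clfs,
      kdb = buildKnowledgeDatabase("1", sigs, clfs, cohort))
  }
  .fixtures$panel
}

# minimal hand-built cohort pieces for io-level tests
tinySheet <- function(ids, roles = "test", disorders = "",
                      replicate_of = "", sex = "M", cohort = "simulated") {
  data.frame(sample_id = ids, sex = sex, age = 30, batch = "b1",
             role = roles, replicate_of = replicate_of,
             disorder_label = disorders, cohort = cohort,
             stringsAsFactors = FALSE)
}

tinyBeta <- function(nProbes, ids, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(nProbes * length(ids)), nProbes, length(ids),
              dimnames = list(sprintf("cg%08d", seq_len(nProbes)), ids))
  m
}

.withSeedTest <- function(seed, expr) {
  set.seed(seed)
  expr
}

# case/control mean profiles of one disorder over its classifier probes
panelProfiles <- function(panel, disorder) {
  sig <- panel$sigs[[disorder]]
  list(case = stats::setNames(sig@caseMean, sig@probeIds),
       control = stats::setNames(sig@controlMean, sig@probeIds))
}
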