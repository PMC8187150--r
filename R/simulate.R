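# Synthetic-cohort simulator with known ground truth.
#
# Generative model:
#   * background probes: three-component Beta mixture (near-0 / near-1 /
#     intermediate), the canonical genome-wide bimodal beta distribution;
#   * each disorder's signature probes: baseline drawn from the intermediate
#     methylation range, shifted by the disorder's delta in its cases
#     (shift on the beta scale, clipped to [0,1] with a warning if it clips);
#   * imprinted DMR probes: baseline mean 0.5; repeat-locus probes: baseline
#     near 0, aberrant carriers pulled toward a configured high mean;
#   * loci carry a per-sample biological offset (biologicalSd) on top of
#     probe-level technical noise, emulating normal inter-individual
#     variability of locus means;
#   * mosaic and dosage-diluted samples: linear mixtures of case and control
#     profiles;
#   * technical replicates share their source sample's biology and differ
#     only by technical noise.
#
# Per-sample RNG streams are derived by stable hashing of the sample id, so
# adding samples never perturbs existing ones and the whole cohort is
# reproducible from (config, seed).

#' Build a simulation configuration
#'
#' Defaults describe the package's standard validation panel: three disorders
#' with 200 signature probes each at a beta shift of 0.15, 20 reference cases
#' per disorder, 100 reference controls, 20,000 background probes and
#' technical noise SD 0.01 (beta units), seed 42.
#'
#' @param nBackgroundProbes background (null) probe count.
#' @param disorders list of lists with fields \code{disorderId},
#'   \code{nSignatureProbes}, \code{delta} (mean beta shift, in (-1,1)) and
#'   \code{nCases}.
#' @param nControls reference control count.
#' @param technicalSd technical noise SD in beta units.
#' @param batchEffects optional named numeric vector of per-batch beta
#'   offsets; samples are assigned to batches round-robin.
#' @param mosaicSamples list of lists \code{(disorderId, fraction)}; each adds
#'   one test sample carrying the disorder profile in that fraction of cells.
#' @param dilutionSamples list of lists \code{(disorderId, dosageFactor)};
#'   each adds one test sample whose signature shift is scaled by
#'   \code{dosageFactor} (0.5 emulates an X-linked heterozygous female, where
#'   the unaffected allele dilutes the signal).
#' @param imprintedLoci list of lists \code{(name, nProbes, biologicalSd,
#'   aberrantSamples)} where \code{aberrantSamples} is a list of
#'   \code{(direction, fraction)} with direction \code{"hyper"} or
#'   \code{"hypo"}; baseline locus mean is 0.5.
#' @param repeatLoci list of lists \code{(name, nProbes, biologicalSd,
#'   highMean, aberrantSamples)}; baseline locus mean is \code{lowMean}
#'   (default 0.05), aberrant carriers move toward \code{highMean}
#'   (default 0.85).
#' @param replicatePairs number of technical replicate pairs to add
#'   (replicating the first samples of the cohort).
#' @param seed integer seed recorded in the output metadata.
#' @return a validated \code{SimulationConfig} (list).
#' @export
simulationConfig <- function(nBackgroundProbes = 20000,
                             disorders = list(
                               list(disorderId = "DIS1", nSignatureProbes = 200,
                                    delta = 0.15, nCases = 20),
                               list(disorderId = "DIS2", nSignatureProbes = 200,
                                    delta = 0.15, nCases = 20),
                               list(disorderId = "DIS3", nSignatureProbes = 200,
                                    delta = 0.15, nCases = 20)),
                             nControls = 100,
                             technicalSd = 0.01,
                             batchEffects = NULL,
                             mosaicSamples = list(),
                             dilutionSamples = list(),
                             imprintedLoci = list(),
                             repeatLoci = list(),
                             replicatePairs = 0,
                             seed = 42) {
  cfg <- list(nBackgroundProbes = nBackgroundProbes, disorders = disorders,
              nControls = nControls, technicalSd = technicalSd,
              batchEffects = batchEffects, mosaicSamples = mosaicSamples,
              dilutionSamples = dilutionSamples, imprintedLoci = imprintedLoci,
              repeatLoci = repeatLoci, replicatePairs = replicatePairs,
              seed = seed)
  .checkConfig(cfg)
  structure(cfg, class = "SimulationConfig")
}

.checkConfig <- function(cfg) {
  stopifnot(cfg$nBackgroundProbes >= 0, cfg$nControls >= 0,
            cfg$replicatePairs >= 0)
  if (cfg$technicalSd < 0)
    .stopc("episcreen_range_error", "technicalSd must be >= 0")
  for (d in cfg$disorders) {
    if (abs(d$delta) >= 1)
      .stopc("episcreen_range_error", "disorder delta must be in (-1,1)")
    stopifnot(d$nSignatureProbes >= 1, d$nCases >= 0)
  }
  for (m in cfg$mosaicSamples)
    if (m$fraction < 0 || m$fraction > 1)
      .stopc("episcreen_range_error", "mosaic fraction must be in [0,1]")
  for (d in cfg$dilutionSamples)
    if (d$dosageFactor < 0 || d$dosageFactor > 1)
      .stopc("episcreen_range_error", "dosageFactor must be in [0,1]")
  for (l in c(cfg$imprintedLoci, cfg$repeatLoci))
    for (a in (l$aberrantSamples %||% list()))
      if (a$fraction <= 0 || a$fraction > 1)
        .stopc("episcreen_range_error", "aberrant locus fraction must be in (0,1]")
  invisible(cfg)
}

#' Linear mosaic mixture of two methylation profiles
#'
#' Models a sample in which only \code{fraction} of cells carry the causal
#' alteration: \eqn{\beta = fraction \cdot \beta_{case} + (1-fraction) \cdot
#' \beta_{control}} elementwise (linear allele-dosage mixing).
#'
#' @param caseProfile,controlProfile numeric beta vectors over the same probes.
#' @param fraction mixing fraction in [0,1].
#' @return mixed beta vector.
#' @export
mixMosaic <- function(caseProfile, controlProfile, fraction) {
  if (length(caseProfile) != length(controlProfile))
    .stopc("episcreen_format_error", "profiles differ in length")
  if (length(fraction) != 1 || is.na(fraction) || fraction < 0 || fraction > 1)
    .stopc("episcreen_range_error", "fraction must be in [0,1], got %s",
           format(fraction))
  fraction * caseProfile + (1 - fraction) * controlProfile
}

#' Add clipped Gaussian technical noise to a profile
#'
#' @param profile numeric beta vector.
#' @param sd noise SD in beta units (>= 0).
#' @param seed integer seed; the same (profile, sd, seed) always yields the
#'   same output.
#' @return noisy profile, clipped to [0,1].
#' @export
applyTechnicalNoise <- function(profile, sd, seed) {
  if (sd < 0) .stopc("episcreen_range_error", "sd must be >= 0, got %g", sd)
  if (sd == 0) return(profile)
  .withSeed(seed, .clip01(profile + stats::rnorm(length(profile), 0, sd)))
}

# deterministic per-sample biology: baseline + disorder shift (scaled by
# dosage), mixed by mosaic fraction, plus per-sample locus offsets
.biologyProfile <- function(base, sigIdx, truthRow, lociIdx, cfg) {
  prof <- base
  did <- truthRow$disorder_id
  if (nzchar(did)) {
    idx <- sigIdx[[did]]
    delta <- cfg$deltaByDisorder[[did]] * truthRow$dosage_factor
    shifted <- prof
    shifted[idx] <- shifted[idx] + delta
    clipped <- .clip01(shifted)
    if (any(clipped != shifted)) {
      .warnc("episcreen_clip_warning",
             "planted shift for %s clipped to [0,1] on %d probe(s)",
             did, sum(clipped != shifted))
    }
    prof <- mixMosaic(clipped, prof, truthRow$mosaic_fraction)
  }
  # locus aberration: pull locus probes toward the target mean
  if (nzchar(truthRow$locus_name)) {
    li <- lociIdx[[truthRow$locus_name]]
    target <- if (truthRow$locus_direction == "hyper") li$high else li$low
    aberr <- prof
    aberr[li$idx] <- target
    prof <- mixMosaic(aberr, prof, truthRow$locus_fraction)
  }
  # per-sample biological offset at every locus, shared by replicates
  bioSeed <- .deriveSeed(cfg$seed, "bio", truthRow$bio_id)
  offsets <- .withSeed(bioSeed, stats::rnorm(length(lociIdx)))
  for (k in seq_along(lociIdx)) {
    li <- lociIdx[[k]]
    prof[li$idx] <- .clip01(prof[li$idx] + offsets[k] * li$biologicalSd)
  }
  prof
}

#' Simulate a methylation cohort with ground truth
#'
#' Generates a \linkS4class{MethylCohort} whose metadata carries the
#' simulation config and a truth table (per sample: disorder, mosaic
#' fraction, dosage factor, locus aberration). Identical (config, seed) give
#' bitwise-identical output.
#'
#' @param config a \code{\link{simulationConfig}}.
#' @return a validated \linkS4class{MethylCohort}.
#' @export
simulateCohort <- function(config) {
  cfg <- .checkConfig(config)
  # ---- probe layout ---------------------------------------------------
  nBg <- cfg$nBackgroundProbes
  sigN <- vapply(cfg$disorders, function(d) as.integer(d$nSignatureProbes), 1L)
  lociSpecs <- c(lapply(cfg$imprintedLoci, function(l)
                   list(name = l$name, type = "imprinted_dmr",
                        nProbes = l$nProbes, low = 0, high = 1,
                        baseline = 0.5,
                        biologicalSd = l$biologicalSd %||% 0.02)),
                 lapply(cfg$repeatLoci, function(l)
                   list(name = l$name, type = "repeat_locus",
                        nProbes = l$nProbes, low = l$lowMean %||% 0.05,
                        high = l$highMean %||% 0.85,
                        baseline = l$lowMean %||% 0.05,
                        biologicalSd = l$biologicalSd %||% 0.01)))
  lociN <- vapply(lociSpecs, function(l) as.integer(l$nProbes), 1L)
  nProbes <- nBg + sum(sigN) + sum(lociN)
  probeIds <- sprintf("cg%08d", seq_len(nProbes))

  set.seed(cfg$seed)
  # background: bimodal Beta mixture 0.45 / 0.45 / 0.10
  comp <- sample.int(3, nBg, replace = TRUE, prob = c(0.45, 0.45, 0.10))
  base <- numeric(nProbes)
  base[seq_len(nBg)] <- c(stats::rbeta(nBg, 2, 20), stats::rbeta(nBg, 20, 2),
                          stats::rbeta(nBg, 8, 8))[seq_len(nBg) + (comp - 1) * nBg]
  sigIdx <- list()
  off <- nBg
  cfg$deltaByDisorder <- list()
  for (i in seq_along(cfg$disorders)) {
    d <- cfg$disorders[[i]]
    idx <- off + seq_len(sigN[i])
    # intermediate baselines so the planted shift is realized unclipped
    lo <- 0.10 + max(0, -d$delta)
    hi <- 0.90 - max(0, d$delta)
    base[idx] <- stats::runif(sigN[i], lo, hi)
    sigIdx[[d$disorderId]] <- idx
    cfg$deltaByDisorder[[d$disorderId]] <- d$delta
    off <- off + sigN[i]
  }
  lociIdx <- list()
  for (i in seq_along(lociSpecs)) {
    l <- lociSpecs[[i]]
    idx <- off + seq_len(lociN[i])
    base[idx] <- l$baseline
    lociIdx[[l$name]] <- list(idx = idx, low = l$low, high = l$high,
                              type = l$type, biologicalSd = l$biologicalSd)
    off <- off + lociN[i]
  }

  # ---- annotation -----------------------------------------------------
  ann <- data.frame(probe_id = probeIds,
                    chrom = paste0("chr", 1 + (seq_len(nProbes) - 1) %% 22),
                    pos = 1000L + 137L * seq_len(nProbes),
                    gene = "", region_tag = "none", on_chrX = FALSE,
                    stringsAsFactors = FALSE)
  for (did in names(sigIdx)) ann$gene[sigIdx[[did]]] <- paste0("GENE_", did)
  for (nm in names(lociIdx)) {
    li <- lociIdx[[nm]]
    ann$region_tag[li$idx] <- paste0(li$type, ":", nm)
    ann$chrom[li$idx] <- if (li$type == "repeat_locus") "chrX" else "chr15"
    ann$on_chrX[li$idx] <- li$type == "repeat_locus"
  }

  # ---- samples & truth ------------------------------------------------
  truth <- list()
  addTruth <- function(id, role, disorder = "", mosaic = 0, dosage = 1,
                       locus = "", dir = "", lfrac = 0, sex = NULL) {
    truth[[length(truth) + 1]] <<- data.frame(
      sample_id = id, role = role, disorder_id = disorder,
      mosaic_fraction = mosaic, dosage_factor = dosage, locus_name = locus,
      locus_direction = dir, locus_fraction = lfrac,
      sex = sex %||% c("M", "F")[1 + length(truth) %% 2],
      bio_id = id, stringsAsFactors = FALSE)
  }
  for (i in seq_len(cfg$nControls))
    addTruth(sprintf("ctrl_%03d", i), "reference_control")
  for (d in cfg$disorders)
    for (i in seq_len(d$nCases))
      addTruth(sprintf("case_%s_%03d", d$disorderId, i), "reference_case",
               disorder = d$disorderId, mosaic = 1)
  for (i in seq_along(cfg$mosaicSamples)) {
    m <- cfg$mosaicSamples[[i]]
    addTruth(sprintf("mosaic_%s_%02d", m$disorderId, i), "test",
             disorder = m$disorderId, mosaic = m$fraction)
  }
  for (i in seq_along(cfg$dilutionSamples)) {
    d <- cfg$dilutionSamples[[i]]
    addTruth(sprintf("dilut_%s_%02d", d$disorderId, i), "test",
             disorder = d$disorderId, mosaic = 1, dosage = d$dosageFactor,
             sex = "F")
  }
  for (l in c(cfg$imprintedLoci, cfg$repeatLoci)) {
    abl <- l$aberrantSamples %||% list()
    for (i in seq_along(abl)) {
      a <- abl[[i]]
      addTruth(sprintf("locus_%s_%02d", l$name, i), "test",
               locus = l$name, dir = a$direction %||% "hyper",
               lfrac = a$fraction, sex = a$sex %||% "M")
    }
  }
  truth <- do.call(rbind, truth)
  if (is.null(truth))
    truth <- data.frame(sample_id = character(), role = character(),
                        disorder_id = character(), mosaic_fraction = numeric(),
                        dosage_factor = numeric(), locus_name = character(),
                        locus_direction = character(), locus_fraction = numeric(),
                        sex = character(), bio_id = character())
  if (cfg$replicatePairs > nrow(truth))
    .stopc("episcreen_range_error",
           "replicatePairs (%d) exceeds cohort size (%d)",
           cfg$replicatePairs, nrow(truth))
  if (cfg$replicatePairs > 0) {
    src <- truth[seq_len(cfg$replicatePairs), , drop = FALSE]
    rep <- src
    rep$sample_id <- paste0(src$sample_id, "_rep")
    rep$role <- "replicate"
    rep$bio_id <- src$sample_id
    truth <- rbind(truth, rep)
  }

  # ---- batches --------------------------------------------------------
  batches <- cfg$batchEffects
  if (is.null(batches)) batches <- c(b1 = 0)
  if (is.null(names(batches))) names(batches) <- paste0("b", seq_along(batches))
  truth$batch <- names(batches)[1 + (seq_len(nrow(truth)) - 1) %% length(batches)]

  # ---- beta values ----------------------------------------------------
  beta <- matrix(NA_real_, nProbes, nrow(truth),
                 dimnames = list(probeIds, truth$sample_id))
  for (j in seq_len(nrow(truth))) {
    row <- truth[j, ]
    bio <- .biologyProfile(base, sigIdx, row, lociIdx, cfg)
    bio <- .clip01(bio + batches[[row$batch]])
    beta[, j] <- applyTechnicalNoise(bio, cfg$technicalSd,
                                     .deriveSeed(cfg$seed, "noise", row$sample_id))
  }

  sheet <- data.frame(
    sample_id = truth$sample_id, sex = truth$sex,
    age = 5 + (seq_len(nrow(truth)) * 7) %% 60, batch = truth$batch,
    role = truth$role,
    replicate_of = ifelse(truth$role == "replicate", truth$bio_id, ""),
    disorder_label = ifelse(truth$role == "reference_case", truth$disorder_id, ""),
    cohort = "simulated", stringsAsFactors = FALSE)

  MethylCohort(beta, sheet, ann,
               metadata = list(truth = truth[, setdiff(colnames(truth), "batch")],
                               config = cfg, seed = cfg$seed))
}
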