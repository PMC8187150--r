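---
title: "Methods: episignature discovery, calibrated classification, and locus screening"
author: "episcreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: episignature discovery, calibrated classification, and locus screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcreen)
```

## The problem

A growing number of Mendelian neurodevelopmental disorders leave a
reproducible genome-wide DNA methylation pattern — an *episignature* — in
peripheral blood. Because the pattern is detectable on a standard methylation
array, it can be used as a functional biomarker: to reclassify variants of
unknown significance in signature-bearing genes, to screen undiagnosed
patients against a panel of disorders at once, and to pick up imprinting
defects and repeat-expansion promoter hypermethylation in the same assay.
`episcreen` implements this workflow end to end on probe-by-sample matrices
of beta values ($\beta \in [0,1]$, the fraction of methylated signal at a
CpG probe): signature discovery from reference cohorts, calibrated
per-disorder classification, unsupervised secondary evidence, targeted locus
screening, and a rule-based three-way report.

All development and validation run against a synthetic-cohort simulator with
known ground truth; no patient data ships with the package.

## Signature discovery

For one disorder, reference cases are compared with reference controls
probe-by-probe using a Welch two-sample test on beta values with
Benjamini–Hochberg correction. A probe enters the signature when

* $|\bar\beta_{case} - \bar\beta_{ctrl}| \ge$ `minAbsDelta` (default 0.10
  beta units) — an effect-size floor, because array-scale testing yields
  statistically significant but biologically trivial differences; and
* BH-adjusted $p \le$ `alpha` (default 0.01).

Surviving probes are ranked by $|\Delta\beta| \cdot (-\log_{10} p)$ with
probe-id tie-breaking and truncated to `maxProbes` (default 500), so the
selection is deterministic down to probe order. Signatures from fewer than
10 cases or with fewer than 50 probes are classed `moderate` rather than
`robust`: small reference cohorts and small probe sets give
reduced-intensity signatures and lower sensitivity. The clinical pipelines
this design follows do not publish their exact selection thresholds; the
defaults here are declared substitutes held behind `selectionParams()`, so a
moderated-variance engine could replace the Welch test without touching the
interface. Control matching by age/sex/batch is reduced to "all reference
controls"; full matched-control selection is out of scope.

`mergeSignatures()` builds coarser-granularity signatures (e.g. one
signature for a protein complex whose subunit genes share a pattern) as the
probe union with sample-count-weighted means.

## Classification and the MVP score

Each disorder gets a one-vs-rest linear support-vector machine over its
signature probes: positive class = that disorder's reference cases, negative
class = all other disorders' cases plus all controls, so specificity against
*other* syndromes is trained in, not just case/control separation. The
margin fit uses a linear kernel, $C = 1$, balanced class weights and no
feature rescaling (beta values are already bounded and commensurate); with
hundreds of probes and tens of samples the problem is linearly separable and
a linear margin is the conservative choice. Weights and bias are extracted
so a stored classifier scores a sample by a plain dot product
$f = w \cdot \beta + b$.

Decision values are mapped to a **methylation variant pathogenicity (MVP)
score** in $[0,1]$ by Platt scaling:

$$\mathrm{MVP}(f) = \frac{1}{1 + e^{A f + B}}$$

with $(A, B)$ maximizing the Bernoulli likelihood under Platt's smoothed
targets $t_+ = (N_+ + 1)/(N_+ + 2)$, $t_- = 1/(N_- + 2)$ — the smoothing is
what keeps scores off the degenerate 0/1 asymptotes when training data are
perfectly separated. Calibration uses out-of-fold decision values from
stratified cross-validation (default 10-fold) to avoid the optimism of
calibrating on in-sample decisions; the final weights are then refitted on
all reference data. The logistic is evaluated through a numerically guarded
form so arbitrarily large $|f|$ saturate instead of overflowing.

Scores map to categories with the reporting thresholds: MVP $> 0.5$
positive, $< 0.1$ negative, the closed band $[0.1, 0.5]$ inconclusive (the
boundaries themselves are inconclusive — a deliberate, literal reading of
the banding convention). A disorder whose signature has less than 90% of its
probes observed in a sample is flagged as a coverage failure for that
disorder only; missing probes above the floor are mean-imputed from the
control reference. The 90% floor is a package decision protecting the
fixed-length dot product; it is configurable.

## Secondary evidence: clustering and MDS

Expert review of these assays leans on two unsupervised displays: Ward
hierarchical clustering of the test sample with the disorder's references,
and a 2-D embedding (classical metric MDS / principal coordinates on
Euclidean distances over signature probes). `episcreen` reproduces both and
quantifies the visual pattern with a margin statistic,

$$m = \frac{d_{ctrl} - d_{case}}{\max(d_{ctrl}, d_{case})} \in [-1, 1],$$

distance of the test sample to the case vs control reference centroids. The
dendrogram cut at $k = 2$ gives the side assignment; $|m| <$ `marginFloor`
(default 0.2) yields the call `intermediate` — the machine-checkable version
of "the sample plots between the cases and the controls", the canonical
mosaic/partial-signature pattern. Ward/Euclidean linkage was chosen for its
stability on bounded features; the embedding's axis sign is fixed by forcing
the case centroid positive so results are deterministic.

## Locus screening and mosaic fraction

Imprinted DMRs (normally near $\beta = 0.5$ in blood) and repeat-expansion
promoter loci (normally unmethylated; hypermethylated in affected males) are
screened by locus-mean methylation against control reference statistics:
$z = (\bar\beta_{obs} - \mu_{ctrl})/\sigma_{ctrl}$, calling
hyper-/hypomethylation only when **both** $|z| >$ `zCut` (default 3) and
$|\bar\beta_{obs} - \mu_{ctrl}| >$ `deltaCut` (default 0.10) — z alone is
fragile when the control SD is tiny, the beta difference alone when it is
large. For imprinted loci the aberrant cell fraction is estimated under the
same linear two-population mixture the simulator uses:
$\hat\phi = |\bar\beta_{obs} - \mu_{ctrl}| / |\,\mathrm{target} -
\mu_{ctrl}|$ with target 1 (gain) or 0 (loss). Estimates below 0.2 are
reported `indeterminate`: with realistic control locus-mean variability
(SD ≈ 0.02) low-level mosaicism is not reliably separable from normal
variation, which is exactly the ~20% detection floor the package's power
tests operationalize. Female samples at repeat loci are always
`indeterminate` — the unaffected X chromosome masks a full mutation's
methylation signal.

## Report composition

The three evidence streams combine by fixed rules, applied in order (first
match decides): (1) positive score confirmed by clustering → **positive**;
(2) positive score clustering with controls → **inconclusive**, flagged
discordant; (3) all scores negative but an intermediate cluster position
trending case-ward → **inconclusive**; (4) any score in the band →
**inconclusive**; (5) any non-normal locus call → **positive** for that
locus; (6) otherwise **negative**. Published case series include
inconclusive calls that rest on expert phenotype judgment; the package
deliberately encodes only the evidence-level patterns and surfaces
`review_flags` instead of attempting phenotype reasoning. Two declared
choices in the rule order: multiple simultaneous positives are all reported
(no argmax suppression, matching one-vs-rest independence) with a review
flag; and an inconclusive-band episignature score takes precedence over a
locus positive because the rules run strictly in sequence.

Technical replicates are concordant when no disorder's MVP differs by more
than 0.05 and no category flips. Cohort summaries round percentages half-up
to one decimal, the convention of the printed diagnostic-yield figures.

## The simulator: what it emulates and what it does not

`simulateCohort()` generates the package's entire test substrate:

* background probes from a three-component Beta mixture (weights
  0.45/0.45/0.10 near-0/near-1/intermediate), the canonical bimodal
  genome-wide beta distribution;
* disorder signature probes with baselines drawn from the intermediate
  range $[0.1,\, 0.9 - |\Delta|]$ and the planted shift $\Delta$ added in
  cases — intermediate baselines so the planted effect is realized without
  clipping and delta-recovery oracles are exact; clipping remains as a
  guarded contract for extreme configurations;
* imprinted DMRs at baseline 0.5 and repeat loci near 0.05 with carriers
  pulled toward 0.85, each locus with a per-sample biological offset
  (`biologicalSd`, default 0.02 for DMRs) emulating normal inter-individual
  variability of locus means;
* mosaic and dosage-diluted samples as exact linear mixtures (a dosage
  factor of 0.5 models an X-linked heterozygous female whose unaffected
  allele halves the signal);
* additive Gaussian technical noise (SD `technicalSd`, default 0.01 beta
  units, clipped to $[0,1]$) — the magnitude is a stand-in, since replicate
  noise is not characterized quantitatively in the source material —
  with technical replicates sharing their source sample's biology draw.

Per-sample RNG streams are derived by stable hashing of sample ids, so
adding a sample never perturbs existing ones and a (config, seed) pair is
bitwise reproducible. Shifts are applied on the beta scale rather than the
logit/M-value scale — simpler ground truth for recovery tests, and a noted
deviation from common M-value practice.

What the simulator does *not* model: probe-level biological covariance,
cell-type composition, age/sex methylation drift, and array chemistry
artefacts beyond additive batch offsets. Passing tests therefore demonstrate
correctness of the algorithms under idealized independence assumptions, not
clinical performance on real arrays, where correlated probes and confounders
make both discovery and calibration harder.

## Validation sizes and numerical choices

The package's standard validation panel is 3 disorders × 20 cases, 100
controls, 200 signature probes per disorder at $\Delta = 0.15$, 20,000
background probes, technical SD 0.01, seed 42; end-to-end tests hold out 5
cases per disorder and 20 controls. Multi-seed property tests (probe
recovery, mosaic monotonicity, replicate concordance, locus power) use 20
seeds with proportionally smaller cohorts, sizes chosen once as
representative and kept fixed. Other numerical choices: p-values are carried
in log space so extreme separations keep a finite selection ranking;
degenerate zero-variance probes get $t = 0$ when the means agree; the Platt
optimizer is BFGS with analytic gradients from $A = 0$,
$B = \log((N_-+1)/(N_++1))$; the knowledge database serializes numbers at
full double precision (round-trip to $10^{-12}$).

## Known limitations

* Signature discovery assumes the reference controls are an adequate
  covariate match; no surrogate-variable or cell-composition correction.
* The linear mixture model for mosaic fraction ignores probe-specific
  dynamic range; on real data fractions below ~0.2 remain undetectable and
  the estimator is calibrated only against the simulator's own assumptions.
* Classifiers are trained on beta values; an M-value variant may behave
  differently near the 0/1 boundaries.
* The report rules encode evidence patterns only; they do not replace
  clinical sign-out.
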