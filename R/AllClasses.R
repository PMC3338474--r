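## S4 containers for the pipeline's central results.

#' Backcross breeding design
#'
#' Describes the map geometry and breeding depth of a congenic construction:
#' a donor-strain locus selected through \code{generations} backcross meioses
#' on a chromosome of \code{chromLengthCM} centimorgans, the locus sitting
#' \code{locusCM} from the proximal end. \code{mbPerCM} converts map to
#' physical distance (mouse: ~2 Mb per cM).
#'
#' @slot generations integer, number of backcross meioses (>= 1).
#' @slot locusCM numeric, map position of the selected locus in cM.
#' @slot chromLengthCM numeric, total chromosome map length in cM.
#' @slot mbPerCM numeric, physical Mb per cM.
#' @slot replicates integer, Monte-Carlo replicate count.
#' @slot seed integer, RNG seed for the simulator.
#' @exportClass BackcrossDesign
setClass("BackcrossDesign",
  representation(
    generations = "integer", locusCM = "numeric", chromLengthCM = "numeric",
    mbPerCM = "numeric", replicates = "integer", seed = "integer"
  ),
  prototype(
    generations = 16L, locusCM = 17, chromLengthCM = 80,
    mbPerCM = 2, replicates = 20000L, seed = 1L
  )
)

setValidity("BackcrossDesign", function(object) {
  msg <- character()
  if (length(object@generations) != 1L || is.na(object@generations) ||
      object@generations < 1L)
    msg <- c(msg, "generations must be a single integer >= 1")
  if (!is.finite(object@locusCM) || !is.finite(object@chromLengthCM))
    msg <- c(msg, "map geometry must be finite")
  else if (object@locusCM < 0 || object@locusCM > object@chromLengthCM)
    msg <- c(msg, "locusCM must lie in [0, chromLengthCM]")
  if (!is.finite(object@mbPerCM) || object@mbPerCM < 0)
    msg <- c(msg, "mbPerCM must be non-negative and finite")
  if (object@replicates < 1L)
    msg <- c(msg, "replicates must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a BackcrossDesign
#'
#' @param generations number of backcross meioses (the mouse congenic strain
#'   analysed here used 16).
#' @param locusCM map position of the selected locus in cM from the proximal
#'   chromosome end.
#' @param chromLengthCM total chromosome map length in cM.
#' @param mbPerCM Mb of DNA per cM (default 2, the mouse genome-wide figure).
#' @param replicates Monte-Carlo replicates for \code{\link{simulateBackcross}}.
#' @param seed RNG seed.
#' @return A \code{BackcrossDesign} object.
#' @examples
#' backcrossDesign(16, 17, 80)
#' @export
backcrossDesign <- function(generations = 16L, locusCM = 17,
                            chromLengthCM = 80, mbPerCM = 2,
                            replicates = 20000L, seed = 1L) {
  new("BackcrossDesign",
      generations = as.integer(generations), locusCM = as.numeric(locusCM),
      chromLengthCM = as.numeric(chromLengthCM), mbPerCM = as.numeric(mbPerCM),
      replicates = as.integer(replicates), seed = as.integer(seed))
}

setMethod("show", "BackcrossDesign", function(object) {
  cat("BackcrossDesign: N =", object@generations, "generations;",
      "locus at", object@locusCM, "cM on a", object@chromLengthCM,
      "cM chromosome;", object@mbPerCM, "Mb/cM\n")
})

#' Retained flanking donor-length statistics
#'
#' Mean and standard deviation of the combined (both flanks) donor-derived
#' heterozygous length retained around the selected locus, in cM.
#' \code{nSamples} is 0 for analytic results; for simulations, \code{samples}
#' holds the replicate-level combined lengths.
#'
#' @slot meanCM numeric, mean combined flanking length (cM).
#' @slot sdCM numeric, its standard deviation (cM).
#' @slot perSideMeans named numeric of length 2 (proximal, distal).
#' @slot nSamples integer.
#' @slot samples numeric vector of replicate combined lengths (may be empty).
#' @exportClass FlankingLengthStats
setClass("FlankingLengthStats",
  representation(meanCM = "numeric", sdCM = "numeric",
                 perSideMeans = "numeric", nSamples = "integer",
                 samples = "numeric"))

setValidity("FlankingLengthStats", function(object) {
  msg <- character()
  if (object@meanCM < 0) msg <- c(msg, "meanCM must be >= 0")
  if (object@sdCM < 0) msg <- c(msg, "sdCM must be >= 0")
  if (length(object@perSideMeans) != 2L)
    msg <- c(msg, "perSideMeans must have length 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FlankingLengthStats", function(object) {
  kind <- if (object@nSamples > 0L)
    sprintf("Monte-Carlo (%d replicates)", object@nSamples) else "analytic"
  cat(sprintf(
    "FlankingLengthStats (%s): mean %.2f cM, SD %.2f cM (proximal %.2f + distal %.2f)\n",
    kind, object@meanCM, object@sdCM,
    object@perSideMeans[["proximal"]], object@perSideMeans[["distal"]]))
})

#' @describeIn FlankingLengthStats-class mean combined flanking length (cM)
#' @param object a \code{FlankingLengthStats}
#' @export
meanCM <- function(object) object@meanCM

#' @describeIn FlankingLengthStats-class SD of combined flanking length (cM)
#' @export
sdCM <- function(object) object@sdCM

#' Physical size bounds of the transferred segment
#'
#' Mean +/- one SD of the retained map length, converted to Mb.
#'
#' @slot minMb numeric, lower bound (clamped at 0).
#' @slot maxMb numeric, upper bound.
#' @exportClass SegmentSizeBounds
setClass("SegmentSizeBounds",
  representation(minMb = "numeric", maxMb = "numeric"))

setValidity("SegmentSizeBounds", function(object) {
  if (object@minMb < 0 || object@minMb > object@maxMb)
    "need 0 <= minMb <= maxMb" else TRUE
})

setMethod("show", "SegmentSizeBounds", function(object) {
  cat(sprintf("SegmentSizeBounds: %.1f - %.1f Mb\n", object@minMb, object@maxMb))
})

#' Transferred-segment inference report
#'
#' Result of \code{\link{inferSegment}}: the minimal interval (outermost
#' donor-called markers), the maximal interval (bounded by the innermost
#' recipient-called flanking markers or the region ends), localized
#' crossover intervals, and the "functional" size -- the portion of the
#' maximal interval where the two parent strains differ in subspecies origin
#' (identity-by-descent stretches carry no information and are masked).
#'
#' @slot minimalInterval numeric(2), Mb.
#' @slot maximalInterval numeric(2), Mb.
#' @slot crossoverIntervals data.frame with columns side, startMb, endMb.
#' @slot functionalSizeMb numeric.
#' @slot ibdMaskedMb numeric, IBD length inside the maximal interval.
#' @slot unboundedLeft logical, TRUE when the proximal flank runs into IBD
#'   with no recipient-called marker, so no left coordinate exists.
#' @slot notes character, e.g. assembly gaps intersecting crossover intervals.
#' @slot calls data.frame of per-marker origin calls.
#' @exportClass TransferredSegmentReport
setClass("TransferredSegmentReport",
  representation(minimalInterval = "numeric", maximalInterval = "numeric",
                 crossoverIntervals = "data.frame", functionalSizeMb = "numeric",
                 ibdMaskedMb = "numeric", unboundedLeft = "logical",
                 notes = "character", calls = "data.frame"))

setValidity("TransferredSegmentReport", function(object) {
  msg <- character()
  if (length(object@minimalInterval) == 2L &&
      length(object@maximalInterval) == 2L &&
      all(is.finite(c(object@minimalInterval, object@maximalInterval)))) {
    if (object@minimalInterval[1] < object@maximalInterval[1] - 1e-9 ||
        object@minimalInterval[2] > object@maximalInterval[2] + 1e-9)
      msg <- c(msg, "minimal interval must lie within maximal interval")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TransferredSegmentReport", function(object) {
  cat("TransferredSegmentReport\n")
  cat(sprintf("  minimal interval: %.2f - %.2f Mb\n",
              object@minimalInterval[1], object@minimalInterval[2]))
  cat(sprintf("  maximal interval: %.2f - %.2f Mb%s\n",
              object@maximalInterval[1], object@maximalInterval[2],
              if (object@unboundedLeft) " (left boundary unbounded within IBD)" else ""))
  cat(sprintf("  functional size: %.1f Mb (~%d Mb); IBD masked: %.1f Mb\n",
              object@functionalSizeMb, round(object@functionalSizeMb),
              object@ibdMaskedMb))
  if (nrow(object@crossoverIntervals))
    for (i in seq_len(nrow(object@crossoverIntervals)))
      cat(sprintf("  crossover (%s): %.2f - %.2f Mb\n",
                  object@crossoverIntervals$side[i],
                  object@crossoverIntervals$startMb[i],
                  object@crossoverIntervals$endMb[i]))
  for (n in object@notes) cat("  note:", n, "\n")
})

#' @describeIn TransferredSegmentReport-class functional segment size in Mb
#' @param object a \code{TransferredSegmentReport}
#' @export
functionalSizeMb <- function(object) object@functionalSizeMb

#' Candidate signal-gene triage report
#'
#' Per-gene ledger of pass/fail for each staged filter (region, intensity,
#' gland expression, localization, divergence, proteome) and the final
#' candidate set. The final set always equals the conjunction of recorded
#' passes, so the ledger replays to the candidate list exactly.
#'
#' @slot ledger data.frame, one row per gene, logical columns per filter.
#' @slot candidates character, final candidate genes.
#' @slot glandCounts data.frame of gland-pattern categories with percentages.
#' @slot params list of filter parameters used.
#' @exportClass CandidateReport
setClass("CandidateReport",
  representation(ledger = "data.frame", candidates = "character",
                 glandCounts = "data.frame", params = "list"))

setValidity("CandidateReport", function(object) {
  led <- object@ledger
  passCols <- grep("^pass_", names(led), value = TRUE)
  if (nrow(led) && length(passCols)) {
    finals <- led$gene[apply(as.matrix(led[passCols]), 1L, all)]
    if (!setequal(finals, object@candidates))
      return("candidates must equal the genes passing every filter")
  }
  TRUE
})

setMethod("show", "CandidateReport", function(object) {
  cat("CandidateReport:", nrow(object@ledger), "genes examined;",
      length(object@candidates), "candidates\n")
  if (length(object@candidates))
    cat("  candidates:", paste(sort(object@candidates), collapse = ", "), "\n")
})

#' @describeIn CandidateReport-class final candidate gene set
#' @param object a \code{CandidateReport}
#' @export
candidates <- function(object) object@candidates

#' Pairwise coding-sequence substitution summary
#'
#' Counts from a codon-aware comparison of two in-frame allelic coding
#' sequences: nucleotide substitutions classified synonymous vs
#' nonsynonymous (a site is nonsynonymous if exchanging that single
#' nucleotide, others held at the first sequence's state, changes the encoded
#' amino acid), codons whose translations differ, and the Grantham
#' conservative/radical split of those amino acid replacements.
#'
#' @slot gene character label.
#' @slot nNonsynNt integer.
#' @slot nSynNt integer.
#' @slot nAaChanges integer.
#' @slot nConservative integer.
#' @slot nRadical integer.
#' @slot changes data.frame with per-event detail (codon, position, from, to).
#' @exportClass SubstitutionSummary
setClass("SubstitutionSummary",
  representation(gene = "character", nNonsynNt = "integer", nSynNt = "integer",
                 nAaChanges = "integer", nConservative = "integer",
                 nRadical = "integer", changes = "data.frame"))

# Note: nAaChanges can rarely exceed nNonsynNt -- a multi-hit codon whose
# single-site exchanges are each synonymous can still change the amino acid
# (e.g. CTA Leu -> TTT Phe), so no ordering between the two is enforced.
setValidity("SubstitutionSummary", function(object) {
  if (object@nConservative + object@nRadical != object@nAaChanges)
    "conservative + radical must equal nAaChanges" else TRUE
})

setMethod("show", "SubstitutionSummary", function(object) {
  cat(sprintf(
    "SubstitutionSummary [%s]: %d nonsyn nt (%d aa changes: %d conservative, %d radical), %d syn nt\n",
    object@gene, object@nNonsynNt, object@nAaChanges, object@nConservative,
    object@nRadical, object@nSynNt))
})

#' Gene-tree vs species-tree congruence report
#'
#' @slot gene character label.
#' @slot congruent logical; TRUE iff every non-trivial gene-tree split is
#'   compatible with the species tree (polytomies count any resolution as
#'   compatible).
#' @slot displacedTaxa character; minimal greedy leaf set whose removal
#'   restores congruence (empty when congruent).
#' @slot rfDistance integer; number of gene-tree splits incompatible with the
#'   species tree.
#' @exportClass CongruenceReport
setClass("CongruenceReport",
  representation(gene = "character", congruent = "logical",
                 displacedTaxa = "character", rfDistance = "integer"))

setMethod("show", "CongruenceReport", function(object) {
  cat(sprintf("CongruenceReport [%s]: %s (rf = %d)%s\n", object@gene,
              if (object@congruent) "congruent" else "NOT congruent",
              object@rfDistance,
              if (length(object@displacedTaxa))
                paste0("; displaced: ",
                       paste(object@displacedTaxa, collapse = ", ")) else ""))
})

#' Codon site-model fit (M8 or M8A)
#'
#' Maximum-likelihood fit of a Goldman-Yang codon model whose
#' nonsynonymous/synonymous ratio varies across sites: a discretized
#' Beta(p, q) class on (0, 1) with weight p0, plus one extra class with ratio
#' omegaS carrying weight 1 - p0. M8 estimates omegaS >= 1; M8A fixes
#' omegaS = 1 (the neutral null).
#'
#' @slot model character, "M8" or "M8A".
#' @slot kappa numeric, transition/transversion rate ratio.
#' @slot p0 numeric, beta-class weight.
#' @slot p,q numeric, beta shape parameters.
#' @slot omegaS numeric, selected-class dN/dS.
#' @slot tau numeric, global branch-length scale relative to the guide fit.
#' @slot classOmegas numeric, per-class dN/dS (K beta bins + selected class).
#' @slot classProps numeric, class weights (sum to 1).
#' @slot logLik numeric, maximized log-likelihood.
#' @slot sitePosterior numeric, per-site posterior probability of the
#'   selected class (naive empirical Bayes at the MLEs).
#' @slot details list: codon frequencies, tree, convergence info.
#' @exportClass SiteModelFit
setClass("SiteModelFit",
  representation(model = "character", kappa = "numeric", p0 = "numeric",
                 p = "numeric", q = "numeric", omegaS = "numeric",
                 tau = "numeric", classOmegas = "numeric",
                 classProps = "numeric", logLik = "numeric",
                 sitePosterior = "numeric", details = "list"))

setValidity("SiteModelFit", function(object) {
  msg <- character()
  if (!object@model %in% c("M8", "M8A", "M0"))
    msg <- c(msg, "model must be one of M8, M8A, M0")
  if (length(object@classProps) &&
      abs(sum(object@classProps) - 1) > 1e-6)
    msg <- c(msg, "class proportions must sum to 1")
  if (object@model == "M8" && object@omegaS < 1 - 1e-8)
    msg <- c(msg, "M8 requires omegaS >= 1")
  if (length(object@sitePosterior) && any(!is.na(object@sitePosterior)) &&
      (min(object@sitePosterior, na.rm = TRUE) < -1e-9 ||
       max(object@sitePosterior, na.rm = TRUE) > 1 + 1e-9))
    msg <- c(msg, "site posteriors must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SiteModelFit", function(object) {
  cat(sprintf("SiteModelFit [%s]: logLik %.4f; kappa %.3f\n",
              object@model, object@logLik, object@kappa))
  if (object@model != "M0")
    cat(sprintf(
      "  p0 %.3f, beta(p = %.3f, q = %.3f), omega_s %.3f (weight %.3f)\n",
      object@p0, object@p, object@q, object@omegaS, 1 - object@p0))
})

#' @describeIn SiteModelFit-class maximized log-likelihood
#' @param object a \code{SiteModelFit}
#' @export
fitLogLik <- function(object) object@logLik

#' Positive-selection test result (M8 vs M8A)
#'
#' @slot fitM8,fitM8A the two \code{SiteModelFit}s.
#' @slot lrtStat numeric, 2 * (logLik M8 - logLik M8A), clamped at 0.
#' @slot pValue numeric, one-sided chi-square (1 df) tail probability.
#' @slot percentSelected numeric, selected-class weight x 100 under M8.
#' @slot omegaSelected numeric, M8 selected-class dN/dS.
#' @slot bebTable data.frame of Bayes-empirical-Bayes site calls
#'   (site, label, posterior, tier).
#' @exportClass SelectionTestResult
setClass("SelectionTestResult",
  representation(fitM8 = "ANY", fitM8A = "ANY", lrtStat = "numeric",
                 pValue = "numeric", percentSelected = "numeric",
                 omegaSelected = "numeric", bebTable = "data.frame"))

setMethod("show", "SelectionTestResult", function(object) {
  cat(sprintf(
    "SelectionTestResult: 2*dlnL = %.4f, p = %.4g; omega_s = %.3f (%.1f%% of codons)\n",
    object@lrtStat, object@pValue, object@omegaSelected,
    object@percentSelected))
  if (nrow(object@bebTable)) {
    top <- object@bebTable[object@bebTable$posterior > 0.9, , drop = FALSE]
    if (nrow(top))
      cat("  BEB sites (p > 0.90):", paste(top$label, collapse = ", "), "\n")
  }
})

#' @describeIn SelectionTestResult-class LRT p-value
#' @param object a \code{SelectionTestResult}
#' @export
pValue <- function(object) object@pValue
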