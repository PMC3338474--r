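## Retained donor-segment length around a selected locus: closed form and
## Monte-Carlo twin.

# Moments of min(Y, D) for Y ~ Exp(rate r), the one-sided retained length
# after t meioses: the nearest crossover over t meioses is exponential with
# rate r = t/100 per cM (Haldane: one crossover per Morgan per meiosis),
# truncated at the map distance D to the chromosome end.
.truncExpMean <- function(r, D) {
  if (D <= 0) return(0)
  if (r <= 0) return(D)
  (1 - exp(-r * D)) / r
}

# complete second moment of min(Y, D), including the D^2 atom at censoring:
# int_0^D y^2 r e^{-ry} dy + D^2 e^{-rD} collapses to this closed form
.truncExpMom2 <- function(r, D) {
  if (D <= 0) return(0)
  if (r <= 0) return(D^2)
  (2 / r^2) * (1 - exp(-r * D) * (1 + r * D))
}

#' Expected retained flanking donor length (closed form)
#'
#' Under Haldane (Poisson, no interference) crossovers at 1 per 100 cM per
#' meiosis, the one-sided donor length retained after t backcross
#' generations is the minimum of t i.i.d. exponential distances (mean 100
#' cM) to the nearest crossover, truncated at the map distance to the
#' chromosome end on that side; the two sides are independent. With
#' r = t/100 per cM and end distance D, the censored-exponential moments
#' (censoring atom included) are E = (1 - exp(-rD))/r and
#' E2 = (2/r^2)(1 - exp(-rD)(1 + rD)). Returns mean and SD of the combined
#' (proximal + distal) length.
#'
#' For the mouse congenic design analysed here (16 generations, locus 17 cM
#' from the proximal end of an 80 cM chromosome) this gives ~12 cM mean and
#' ~8 cM SD.
#'
#' @param design a \code{\link{backcrossDesign}}.
#' @return A \code{FlankingLengthStats} (analytic: \code{nSamples = 0}).
#' @examples
#' expectedFlankingLength(backcrossDesign(16, 17, 80))
#' @seealso \code{\link{simulateBackcross}} for the Monte-Carlo twin,
#'   \code{\link{sizeBoundsMb}} for physical-size bounds.
#' @export
expectedFlankingLength <- function(design) {
  stopifnot(is(design, "BackcrossDesign"))
  validObject(design)
  t <- design@generations
  r <- t / 100
  Dp <- design@locusCM
  Dd <- design@chromLengthCM - design@locusCM
  m1p <- .truncExpMean(r, Dp); m1d <- .truncExpMean(r, Dd)
  m2p <- .truncExpMom2(r, Dp)
  m2d <- .truncExpMom2(r, Dd)
  vp <- m2p - m1p^2
  vd <- m2d - m1d^2
  new("FlankingLengthStats",
      meanCM = m1p + m1d, sdCM = sqrt(vp + vd),
      perSideMeans = c(proximal = m1p, distal = m1d),
      nSamples = 0L, samples = numeric())
}

#' Simulate donor-segment retention through backcrossing
#'
#' Monte-Carlo twin of \code{\link{expectedFlankingLength}}. Each replicate
#' tracks the donor interval containing the selected locus: every meiosis
#' draws Poisson crossovers at 1 per 100 cM along the chromosome, the
#' transmitted chromatid is conditioned on carrying the donor allele at the
#' locus, and the retained donor interval is intersected with the
#' inter-crossover block containing the locus. Reproducible for a fixed
#' \code{seed} (taken from the design).
#'
#' @param design a \code{\link{backcrossDesign}}; \code{replicates} and
#'   \code{seed} are honoured.
#' @return A \code{FlankingLengthStats} with empirical mean/SD and the
#'   replicate-level combined lengths in \code{@samples}.
#' @examples
#' simulateBackcross(backcrossDesign(16, 17, 80, replicates = 5000, seed = 7))
#' @export
simulateBackcross <- function(design) {
  stopifnot(is(design, "BackcrossDesign"))
  validObject(design)
  n <- design@replicates
  if (n < 1L) stop("replicates must be >= 1")
  set.seed(design@seed)
  locus <- design@locusCM
  L <- design@chromLengthCM
  # retained donor interval [a, b]; starts as the whole chromosome
  a <- rep(0, n)
  b <- rep(L, n)
  for (g in seq_len(design@generations)) {
    # nearest crossover on each side of the locus this meiosis: Exp(1/100),
    # censored at the chromosome ends
    dl <- rexp(n, rate = 1 / 100)
    dr <- rexp(n, rate = 1 / 100)
    a <- pmax(a, locus - pmin(dl, locus))
    b <- pmin(b, locus + pmin(dr, L - locus))
  }
  combined <- b - a
  new("FlankingLengthStats",
      meanCM = mean(combined), sdCM = sd(combined),
      perSideMeans = c(proximal = mean(locus - a), distal = mean(b - locus)),
      nSamples = n, samples = combined)
}

#' Physical size bounds of the transferred segment
#'
#' Converts (mean - SD, mean + SD) of the retained map length to Mb. With the
#' printed 12 cM mean, 8 cM SD and 2 Mb/cM this yields the 8--40 Mb band.
#'
#' @param stats a \code{FlankingLengthStats}.
#' @param mbPerCM Mb per cM conversion (default 2).
#' @return A \code{SegmentSizeBounds}.
#' @examples
#' st <- new("FlankingLengthStats", meanCM = 12, sdCM = 8,
#'           perSideMeans = c(proximal = 6, distal = 6),
#'           nSamples = 0L, samples = numeric())
#' sizeBoundsMb(st, 2)
#' @export
sizeBoundsMb <- function(stats, mbPerCM = 2) {
  stopifnot(is(stats, "FlankingLengthStats"))
  if (!is.finite(mbPerCM) || mbPerCM < 0)
    stop("mbPerCM must be non-negative and finite")
  new("SegmentSizeBounds",
      minMb = max(0, stats@meanCM - stats@sdCM) * mbPerCM,
      maxMb = (stats@meanCM + stats@sdCM) * mbPerCM)
}
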