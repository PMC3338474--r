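## Introgressed-segment inference from strain SNP haplotypes, with
## subspecies-ancestry IBD masking.
##
## Coordinates are Mb floats, intervals half-open [start, end). A marker's
## haplotypes are SNP allele strings compared site-wise; a single discordant
## informative site makes the call ambiguous (markers are treated as whole
## haplotypes, not majority-voted).

.hapChars <- function(x) strsplit(toupper(x), "")[[1]]

.callOne <- function(donor, recipient, congenic) {
  d <- .hapChars(donor); r <- .hapChars(recipient); cg <- .hapChars(congenic)
  if (length(d) != length(r) || length(d) != length(cg))
    stop("haplotype strings must have equal length")
  informative <- which(d != r & d != "N" & r != "N")
  if (!length(informative)) return("uninformative")
  known <- informative[cg[informative] != "N"]
  if (!length(known)) return("ambiguous")
  md <- all(cg[known] == d[known])
  mr <- all(cg[known] == r[known])
  if (md && !mr) "donor" else if (mr && !md) "recipient" else "ambiguous"
}

#' Call donor/recipient origin of each marker in the congenic strain
#'
#' Compares the congenic strain's SNP haplotype with the donor and recipient
#' parental haplotypes at each marker. A marker is called \code{donor} when
#' the congenic haplotype matches the donor at every informative site (sites
#' where the parents differ), \code{recipient} symmetrically,
#' \code{ambiguous} when informative sites disagree with both, and
#' \code{uninformative} when the parents are identical. \code{N} denotes an
#' unknown allele and is skipped.
#'
#' @param markers data.frame with columns \code{name}, \code{chrom},
#'   \code{pos_mb}, \code{donor_hap}, \code{recipient_hap},
#'   \code{congenic_hap}.
#' @return The marker data.frame with an added \code{call} column.
#' @examples
#' m <- data.frame(name = "Siglece", chrom = "chr7", pos_mb = 50.9,
#'                 donor_hap = "ACGT", recipient_hap = "ATGT",
#'                 congenic_hap = "ATGT")
#' callOrigins(m)$call
#' @export
callOrigins <- function(markers) {
  need <- c("name", "chrom", "pos_mb", "donor_hap", "recipient_hap",
            "congenic_hap")
  if (!all(need %in% names(markers)))
    stop("markers must have columns: ", paste(need, collapse = ", "))
  markers$call <- vapply(seq_len(nrow(markers)), function(i)
    .callOne(markers$donor_hap[i], markers$recipient_hap[i],
             markers$congenic_hap[i]), character(1))
  markers[order(markers$pos_mb), , drop = FALSE]
}

# label of a strain's ancestry at point x (midpoint lookup); "unknown" when
# no interval covers x
.trackLabelAt <- function(track, x) {
  hit <- which(track$start_mb <= x & x < track$end_mb)
  if (length(hit)) track$subspecies[hit[1]] else "unknown"
}

#' Length where two ancestry tracks differ in subspecies origin
#'
#' Sums the sub-interval lengths inside \code{interval} where the two parent
#' strains' subspecies-ancestry assignments differ. Stretches where both
#' strains carry the same subspecies are identity-by-descent for this
#' purpose and contribute nothing: markers there cannot distinguish donor
#' from recipient. By default \code{unknown} ancestry never counts as
#' differing (conservative).
#'
#' @param tracks data.frame with columns \code{strain}, \code{chrom},
#'   \code{start_mb}, \code{end_mb}, \code{subspecies}; exactly two strain
#'   labels.
#' @param interval numeric(2), Mb, half-open.
#' @param unknownDiffers logical; if TRUE, \code{unknown} vs anything counts
#'   as differing.
#' @return Length in Mb.
#' @examples
#' tr <- data.frame(strain = rep(c("DBA", "C3H"), each = 1), chrom = "chr7",
#'                  start_mb = 0, end_mb = 60,
#'                  subspecies = c("musculus", "domesticus"))
#' functionalSize(tr, c(17.3, 50.9))
#' @export
functionalSize <- function(tracks, interval, unknownDiffers = FALSE) {
  if (interval[2] < interval[1]) stop("inverted interval")
  strains <- unique(tracks$strain)
  if (length(strains) != 2L) stop("tracks must cover exactly two strains")
  t1 <- tracks[tracks$strain == strains[1], , drop = FALSE]
  t2 <- tracks[tracks$strain == strains[2], , drop = FALSE]
  cuts <- sort(unique(c(interval,
                        t1$start_mb, t1$end_mb, t2$start_mb, t2$end_mb)))
  cuts <- cuts[cuts >= interval[1] & cuts <= interval[2]]
  if (length(cuts) < 2L) return(0)
  total <- 0
  for (i in seq_len(length(cuts) - 1L)) {
    mid <- (cuts[i] + cuts[i + 1L]) / 2
    l1 <- .trackLabelAt(t1, mid); l2 <- .trackLabelAt(t2, mid)
    differs <- if (l1 == "unknown" || l2 == "unknown")
      unknownDiffers && l1 != l2 else l1 != l2
    if (differs) total <- total + (cuts[i + 1L] - cuts[i])
  }
  total
}

#' Infer the transferred segment from origin calls
#'
#' Builds the minimal interval (outermost donor-called markers) and the
#' maximal interval (bounded by the innermost recipient-called markers
#' flanking the donor run, or by the region ends), localizes each
#' donor-to-recipient transition as a crossover interval, and computes the
#' "functional" size: the portion of the maximal interval where the two
#' parental ancestry tracks assign different subspecies. Assembly gaps
#' overlapping a crossover interval are reported as resolution limits in
#' \code{notes}, never subtracted from the size. When the proximal flank has
#' no recipient-called marker and runs into identity-by-descent, the left
#' boundary is flagged unbounded rather than given a coordinate.
#'
#' @param calls output of \code{\link{callOrigins}} (data.frame with a
#'   \code{call} column), single chromosome.
#' @param tracks parental ancestry tracks as in \code{\link{functionalSize}}.
#' @param gaps optional data.frame of assembly gaps (\code{chrom},
#'   \code{start_mb}, \code{end_mb}).
#' @param region numeric(2); the chromosome span under consideration, Mb.
#' @return A \code{\linkS4class{TransferredSegmentReport}}, or (with zero
#'   donor calls) a report whose intervals are \code{NA} and whose notes say
#'   "no donor segment".
#' @export
inferSegment <- function(calls, tracks, gaps = NULL, region) {
  stopifnot(all(c("pos_mb", "call") %in% names(calls)))
  calls <- calls[order(calls$pos_mb), , drop = FALSE]
  donors <- which(calls$call == "donor")
  if (!length(donors)) {
    return(new("TransferredSegmentReport",
               minimalInterval = c(NA_real_, NA_real_),
               maximalInterval = c(NA_real_, NA_real_),
               crossoverIntervals = data.frame(side = character(),
                                               startMb = numeric(),
                                               endMb = numeric()),
               functionalSizeMb = 0, ibdMaskedMb = 0, unboundedLeft = FALSE,
               notes = "no donor segment", calls = calls))
  }
  lo <- donors[1]; hi <- donors[length(donors)]
  minimal <- c(calls$pos_mb[lo], calls$pos_mb[hi])
  recLeft <- which(calls$call == "recipient" & seq_len(nrow(calls)) < lo)
  recRight <- which(calls$call == "recipient" & seq_len(nrow(calls)) > hi)
  maximal <- c(if (length(recLeft)) calls$pos_mb[max(recLeft)] else region[1],
               if (length(recRight)) calls$pos_mb[min(recRight)] else region[2])
  xo <- data.frame(side = character(), startMb = numeric(), endMb = numeric())
  if (length(recLeft))
    xo <- rbind(xo, data.frame(side = "proximal",
                               startMb = calls$pos_mb[max(recLeft)],
                               endMb = minimal[1]))
  if (length(recRight))
    xo <- rbind(xo, data.frame(side = "distal", startMb = minimal[2],
                               endMb = calls$pos_mb[min(recRight)]))
  # unbounded left: no recipient marker proximally and the flank is IBD
  unboundedLeft <- !length(recLeft) &&
    functionalSize(tracks, c(region[1], minimal[1])) < (minimal[1] - region[1]) - 1e-9
  fs <- functionalSize(tracks, maximal)
  ibd <- (maximal[2] - maximal[1]) - fs
  notes <- character()
  if (unboundedLeft)
    notes <- c(notes, "left boundary unbounded within IBD")
  if (!is.null(gaps) && nrow(gaps) && nrow(xo)) {
    for (i in seq_len(nrow(xo))) for (j in seq_len(nrow(gaps))) {
      if (gaps$start_mb[j] < xo$endMb[i] && gaps$end_mb[j] > xo$startMb[i])
        notes <- c(notes, sprintf(
          "assembly gap %.1f-%.1f Mb overlaps %s crossover interval; resolution limited",
          gaps$start_mb[j], gaps$end_mb[j], xo$side[i]))
    }
  }
  new("TransferredSegmentReport",
      minimalInterval = minimal, maximalInterval = maximal,
      crossoverIntervals = xo, functionalSizeMb = fs, ibdMaskedMb = ibd,
      unboundedLeft = unboundedLeft, notes = notes, calls = calls)
}
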